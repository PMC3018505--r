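# Three equally weighted, well-separated clusters with risks 0.05/0.10/0.25.
# Each cluster concentrates (probability 0.8) on its own category of every
# covariate, so profiles are close to linearly separable and recovery should
# be near-perfect. Planted odds ratio of cluster 3 vs cluster 1 is
# (0.25*0.95)/(0.05*0.75) = 6.33.
n_subjects: 900
weights: [0.3334, 0.3333, 0.3333]
theta: [0.05, 0.10, 0.25]
covariates:
  - name: c1
    kind: nominal
    n_categories: 2
    phi:
      - [0.80, 0.20]
      - [0.20, 0.80]
      - [0.50, 0.50]
  - name: c2
    kind: ordinal
    n_categories: 4
    phi:
      - [0.80, 0.10, 0.05, 0.05]
      - [0.05, 0.80, 0.10, 0.05]
      - [0.05, 0.05, 0.10, 0.80]
  - name: c3
    kind: ordinal
    n_categories: 3
    phi:
      - [0.80, 0.15, 0.05]
      - [0.05, 0.80, 0.15]
      - [0.05, 0.15, 0.80]
  - name: c4
    kind: ordinal
    n_categories: 4
    phi:
      - [0.70, 0.20, 0.05, 0.05]
      - [0.05, 0.20, 0.70, 0.05]
      - [0.05, 0.05, 0.20, 0.70]
  - name: c5
    kind: ordinal
    n_categories: 3
    phi:
      - [0.80, 0.15, 0.05]
      - [0.15, 0.80, 0.05]
      - [0.05, 0.15, 0.80]
  - name: c6
    kind: ordinal
    n_categories: 3
    phi:
      - [0.70, 0.20, 0.10]
      - [0.10, 0.70, 0.20]
      - [0.10, 0.20, 0.70]
  - name: c7
    kind: nominal
    n_categories: 2
    phi:
      - [0.85, 0.15]
      - [0.15, 0.85]
      - [0.50, 0.50]
  - name: c8
    kind: nominal
    n_categories: 2
    phi:
      - [0.20, 0.80]
      - [0.80, 0.20]
      - [0.50, 0.50]
  - name: c9
    kind: ordinal
    n_categories: 3
    phi:
      - [0.10, 0.80, 0.10]
      - [0.80, 0.10, 0.10]
      - [0.10, 0.10, 0.80]
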