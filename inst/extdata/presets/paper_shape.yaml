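# Synthetic scenario shaped like a nested case-control air pollution study:
# nine covariates (three binary, four 3-level, two 4-level), three clusters
# of relative size 96/112/621 with risks 0.15/0.12/0.09. Cluster 1 is the
# high-risk, traffic-exposed profile; cluster 3 the large low-exposure one.
# MCAR missingness: 34% on the 4-level ordinal exposure (pm10), 6% on no2.
n_subjects: 829
weights: [0.1158, 0.1351, 0.7491]
theta: [0.15, 0.12, 0.09]
covariates:
  - name: mainroad
    kind: nominal
    n_categories: 2
    phi:
      - [0.30, 0.70]
      - [0.75, 0.25]
      - [0.85, 0.15]
  - name: pm10
    kind: ordinal
    n_categories: 4
    missing_rate: 0.34
    phi:
      - [0.05, 0.15, 0.35, 0.45]
      - [0.15, 0.55, 0.20, 0.10]
      - [0.55, 0.30, 0.10, 0.05]
  - name: no2
    kind: ordinal
    n_categories: 3
    missing_rate: 0.06
    phi:
      - [0.05, 0.25, 0.70]
      - [0.15, 0.60, 0.25]
      - [0.60, 0.30, 0.10]
  - name: pawork
    kind: ordinal
    n_categories: 4
    phi:
      - [0.20, 0.25, 0.35, 0.20]
      - [0.15, 0.25, 0.40, 0.20]
      - [0.40, 0.30, 0.20, 0.10]
  - name: paleis
    kind: ordinal
    n_categories: 3
    phi:
      - [0.35, 0.35, 0.30]
      - [0.35, 0.35, 0.30]
      - [0.30, 0.35, 0.35]
  - name: bmi
    kind: ordinal
    n_categories: 3
    phi:
      - [0.40, 0.40, 0.20]
      - [0.40, 0.40, 0.20]
      - [0.45, 0.40, 0.15]
  - name: gstm1
    kind: nominal
    n_categories: 2
    phi:
      - [0.45, 0.55]
      - [0.55, 0.45]
      - [0.50, 0.50]
  - name: xrcc1
    kind: nominal
    n_categories: 2
    phi:
      - [0.85, 0.15]
      - [0.85, 0.15]
      - [0.85, 0.15]
  - name: ralc
    kind: ordinal
    n_categories: 3
    phi:
      - [0.30, 0.30, 0.40]
      - [0.40, 0.30, 0.30]
      - [0.33, 0.33, 0.34]
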