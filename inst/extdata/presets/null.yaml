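# Null scenario: one generating cluster, no risk structure. Nine covariates
# with population-typical marginal frequencies; constant risk 0.1.
n_subjects: 545
weights: [1.0]
theta: [0.1]
covariates:
  - name: mainroad
    kind: nominal
    n_categories: 2
    phi:
      - [0.80, 0.20]
  - name: pm10
    kind: ordinal
    n_categories: 4
    phi:
      - [0.40, 0.35, 0.15, 0.10]
  - name: no2
    kind: ordinal
    n_categories: 3
    phi:
      - [0.45, 0.35, 0.20]
  - name: pawork
    kind: ordinal
    n_categories: 4
    phi:
      - [0.35, 0.30, 0.25, 0.10]
  - name: paleis
    kind: ordinal
    n_categories: 3
    phi:
      - [0.33, 0.34, 0.33]
  - name: bmi
    kind: ordinal
    n_categories: 3
    phi:
      - [0.42, 0.40, 0.18]
  - name: gstm1
    kind: nominal
    n_categories: 2
    phi:
      - [0.50, 0.50]
  - name: xrcc1
    kind: nominal
    n_categories: 2
    phi:
      - [0.85, 0.15]
  - name: ralc
    kind: ordinal
    n_categories: 3
    phi:
      - [0.33, 0.33, 0.34]
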