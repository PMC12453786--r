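seed: 1
feature_specs:
- name: Age
  kind: numeric
  lo: 20.0
  hi: 80.0
  mean: 29.905
  sd: 17.649
  missing_rate: 0.0
- name: Gender
  kind: binary
  mean: 0.509
  missing_rate: 0.0
- name: ESR
  kind: numeric
  lo: 0.0001
  hi: 49.99
  mean: 24.698
  sd: 14.38
  missing_rate: 0.09
- name: CRP
  kind: numeric
  lo: 0.1018
  hi: 29.99
  mean: 13.299
  sd: 10.37
  missing_rate: 0.2
- name: RF
  kind: numeric
  lo: 0.0043
  hi: 39.99
  mean: 19.691
  sd: 11.51
  missing_rate: 0.11
- name: Anti-CCP
  kind: numeric
  lo: 0.0002
  hi: 39.99
  mean: 19.755
  sd: 11.58
  missing_rate: 0.27
- name: HLA-B27
  kind: binary
  mean: 0.635
  missing_rate: 0.16
- name: ANA
  kind: binary
  mean: 0.6124
  missing_rate: 0.31
- name: Anti-Ro
  kind: binary
  mean: 0.6348
  missing_rate: 0.24
- name: Anti-La
  kind: binary
  mean: 0.577
  missing_rate: 0.25
- name: Anti-dsDNA
  kind: binary
  mean: 0.59
  missing_rate: 0.39
- name: Anti-Sm
  kind: binary
  mean: 0.553
  missing_rate: 0.43
- name: C3
  kind: numeric
  lo: 50.0
  hi: 205.94
  mean: 132.43
  sd: 36.28
  missing_rate: 0.14
- name: C4
  kind: numeric
  lo: 5.0
  hi: 74.98
  mean: 38.8
  sd: 20.06
  missing_rate: 0.17
class_profiles:
- label: RA
  'n': 2848
  num_shifts:
    ESR: 4.0
    CRP: 2.0
    RF: 8.0
    Anti-CCP: 8.0
  bin_probs:
    Gender: 0.45
    HLA-B27: 0.55
    ANA: 0.6
    Anti-Ro: 0.6
    Anti-La: 0.55
    Anti-dsDNA: 0.58
    Anti-Sm: 0.55
- label: AS
  'n': 2127
  num_shifts:
    Age: -5.0
    ESR: 2.0
    CRP: 2.0
    RF: -6.0
    Anti-CCP: -6.0
  bin_probs:
    Gender: 0.7
    HLA-B27: 0.92
    ANA: 0.55
    Anti-Ro: 0.6
    Anti-La: 0.55
    Anti-dsDNA: 0.58
    Anti-Sm: 0.55
- label: SS
  'n': 1852
  num_shifts:
    Age: 5.0
    ESR: 3.0
    RF: 2.0
  bin_probs:
    Gender: 0.3
    HLA-B27: 0.55
    ANA: 0.85
    Anti-Ro: 0.92
    Anti-La: 0.88
    Anti-dsDNA: 0.58
    Anti-Sm: 0.55
- label: PA
  'n': 1783
  num_shifts:
    ESR: 1.0
    CRP: 3.0
    RF: -5.0
    Anti-CCP: -5.0
  bin_probs:
    Gender: 0.55
    HLA-B27: 0.7
    ANA: 0.55
    Anti-Ro: 0.6
    Anti-La: 0.55
    Anti-dsDNA: 0.58
    Anti-Sm: 0.55
- label: 'N'
  'n': 1604
  num_shifts:
    ESR: -10.0
    CRP: -7.0
    RF: -8.0
    Anti-CCP: -8.0
    C3: 5.0
  bin_probs:
    Gender: 0.55
    HLA-B27: 0.35
    ANA: 0.3
    Anti-Ro: 0.35
    Anti-La: 0.3
    Anti-dsDNA: 0.35
    Anti-Sm: 0.32
- label: SLE
  'n': 1355
  num_shifts:
    Age: -5.0
    ESR: 4.0
    C3: -30.0
    C4: -12.0
  bin_probs:
    Gender: 0.1
    HLA-B27: 0.55
    ANA: 0.95
    Anti-Ro: 0.8
    Anti-La: 0.7
    Anti-dsDNA: 0.93
    Anti-Sm: 0.9
- label: ReA
  'n': 516
  num_shifts:
    Age: -8.0
    ESR: 2.0
    CRP: 4.0
    RF: -6.0
    Anti-CCP: -6.0
  bin_probs:
    Gender: 0.75
    HLA-B27: 0.85
    ANA: 0.55
    Anti-Ro: 0.6
    Anti-La: 0.55
    Anti-dsDNA: 0.58
    Anti-Sm: 0.55
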