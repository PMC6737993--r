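format: quefts_coefficients
version: 1
sets:
- coefficients:
    zone: NGS
    source: parameterized
    ymax: 10000.0
    a:
      'N': 35.0
      P: 200.0
      K: 25.0
    d:
      'N': 79.0
      P: 527.0
      K: 117.0
    r:
      'N': 4.0
      P: 0.5
      K: 4.5
    recovery:
      'N': 0.41999999999999998
      P: 0.16
      K: 0.54000000000000004
  supply_equations:
    'N':
      nutrient: 'N'
      family: linear
      intercept: -20.53999999999999915
      R2: 0.56999999999999995
      terms:
      - var: OC_tot
        coef: 0.59999999999999998
        power: 1.0
      - var: N_tot
        coef: 130.91999999999998749
        power: 1.0
    P:
      nutrient: P
      family: linear
      intercept: -12.16000000000000014
      R2: 0.60999999999999999
      terms:
      - var: pH
        coef: 2.70999999999999996
        power: 1.0
      - var: P_av
        coef: 0.70999999999999996
        power: 1.0
    K:
      nutrient: K
      family: linear
      intercept: 27.10000000000000142
      R2: 0.55000000000000004
      terms:
      - var: K_exch
        coef: 246.21999999999999886
        power: 1.0
- coefficients:
    zone: SS
    source: parameterized
    ymax: 10000.0
    a:
      'N': 32.0
      P: 164.0
      K: 24.0
    d:
      'N': 79.0
      P: 528.0
      K: 136.0
    r:
      'N': 6.09999999999999964
      P: 0.80000000000000004
      K: 7.29999999999999982
    recovery:
      'N': 0.32000000000000001
      P: 0.08
      K: 0.37
  supply_equations:
    'N':
      nutrient: 'N'
      family: polynomial
      intercept: 11.64000000000000057
      R2: 0.52000000000000002
      terms:
      - var: N_tot
        coef: 155.40999999999999659
        power: 3.0
    P:
      nutrient: P
      family: polynomial
      intercept: -4.11000000000000032
      R2: 0.66000000000000003
      terms:
      - var: pH
        coef: 1.39999999999999991
        power: 1.0
      - var: P_av
        coef: 0.0005
        power: 3.0
    K:
      nutrient: K
      family: linear
      intercept: 228.72999999999998977
      R2: 0.59999999999999998
      terms:
      - var: pH
        coef: -35.29999999999999716
        power: 1.0
      - var: K_exch
        coef: 275.30000000000001137
        power: 1.0
- coefficients:
    zone: All
    source: parameterized
    ymax: 10000.0
    a:
      'N': 35.0
      P: 199.0
      K: 24.0
    d:
      'N': 79.0
      P: 528.0
      K: 124.0
    r:
      'N': 4.0
      P: 0.5
      K: 4.5
    recovery:
      'N': 0.40000000000000002
      P: 0.14999999999999999
      K: 0.52000000000000002
  supply_equations:
    'N':
      nutrient: 'N'
      family: polynomial
      intercept: 9.5600000000000005
      R2: 0.56000000000000005
      terms:
      - var: N_tot
        coef: 147.28000000000000114
        power: 2.0
    P:
      nutrient: P
      family: linear
      intercept: -8.34999999999999964
      R2: 0.5
      terms:
      - var: pH
        coef: 2.20000000000000018
        power: 1.0
      - var: P_av
        coef: 0.42999999999999999
        power: 1.0
    K:
      nutrient: K
      family: linear
      intercept: 26.35000000000000142
      R2: 0.52000000000000002
      terms:
      - var: K_exch
        coef: 247.96999999999999886
        power: 1.0
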