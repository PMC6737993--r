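format: quefts_coefficients
version: 1
sets:
- coefficients:
    zone: NGS
    source: janssen_default
    ymax: 10000.0
    a:
      'N': 30.0
      P: 200.0
      K: 30.0
    d:
      'N': 70.0
      P: 600.0
      K: 120.0
    r:
      'N': 5.0
      P: 0.40000000000000002
      K: 2.0
    recovery:
      'N': 0.5
      P: 0.10000000000000001
      K: 0.5
  supply_equations:
    'N':
      nutrient: 'N'
      family: linear
      intercept: 22.80000000000000071
      R2: 0.11
      terms:
      - var: OC_tot
        coef: 2.54000000000000004
        power: 1.0
    P:
      nutrient: P
      family: linear
      intercept: 5.45999999999999996
      R2: 0.56999999999999995
      terms:
      - var: OC_tot
        coef: -0.22
        power: 1.0
      - var: P_av
        coef: 0.71999999999999997
        power: 1.0
    K:
      nutrient: K
      family: linear
      intercept: 37.53000000000000114
      R2: 0.46000000000000002
      terms:
      - var: OC_tot
        coef: -1.60000000000000009
        power: 1.0
      - var: K_exch
        coef: 248.05000000000001137
        power: 1.0
- coefficients:
    zone: SS
    source: janssen_default
    ymax: 10000.0
    a:
      'N': 30.0
      P: 200.0
      K: 30.0
    d:
      'N': 70.0
      P: 600.0
      K: 120.0
    r:
      'N': 5.0
      P: 0.40000000000000002
      K: 2.0
    recovery:
      'N': 0.5
      P: 0.10000000000000001
      K: 0.5
  supply_equations:
    'N':
      nutrient: 'N'
      family: linear
      intercept: 24.87000000000000099
      R2: 0.03
      terms:
      - var: OC_tot
        coef: 0.60999999999999999
        power: 1.0
    P:
      nutrient: P
      family: linear
      intercept: 3.29000000000000004
      R2: 0.56000000000000005
      terms:
      - var: OC_tot
        coef: -0.11
        power: 1.0
      - var: P_av
        coef: 0.31
        power: 1.0
    K:
      nutrient: K
      family: linear
      intercept: 39.13000000000000256
      R2: 0.35999999999999999
      terms:
      - var: OC_tot
        coef: -2.5
        power: 1.0
      - var: K_exch
        coef: 237.21000000000000796
        power: 1.0
- coefficients:
    zone: All
    source: janssen_default
    ymax: 10000.0
    a:
      'N': 30.0
      P: 200.0
      K: 30.0
    d:
      'N': 70.0
      P: 600.0
      K: 120.0
    r:
      'N': 5.0
      P: 0.40000000000000002
      K: 2.0
    recovery:
      'N': 0.5
      P: 0.10000000000000001
      K: 0.5
  supply_equations:
    'N':
      nutrient: 'N'
      family: linear
      intercept: 22.05999999999999872
      R2: 0.10000000000000001
      terms:
      - var: OC_tot
        coef: 2.35999999999999988
        power: 1.0
    P:
      nutrient: P
      family: linear
      intercept: 4.74000000000000021
      R2: 0.34999999999999998
      terms:
      - var: OC_tot
        coef: 0.01
        power: 1.0
      - var: P_av
        coef: 0.41999999999999998
        power: 1.0
    K:
      nutrient: K
      family: linear
      intercept: 36.22999999999999687
      R2: 0.42999999999999999
      terms:
      - var: OC_tot
        coef: -1.53000000000000003
        power: 1.0
      - var: K_exch
        coef: 248.41999999999998749
        power: 1.0
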