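variables:
- P
- F
time_mode: discrete
known_constants:
  mP: 0.10000000000000001
  rP: 0.90000000000000002
  fin: 0.05
  rF: 1.0
  KF: 1.0
processes:
- name: recruitment
  sign: gain
  target: P
  depends_on:
  - P
  - F
  observability: inferred_by_balance
  assumptions:
    P: linear
    F: free
- name: natural_mortality
  sign: loss
  target: P
  depends_on:
  - P
  observability: known_form
  form:
    kind: linear
    of: P
    rate: mP
- name: catch
  sign: loss
  target: P
  depends_on: []
  observability: observed
  drifting: yes
- name: influx
  sign: gain
  target: F
  depends_on: []
  observability: known_form
  form:
    kind: constant
    value: fin
- name: growth
  sign: gain
  target: F
  depends_on:
  - F
  observability: known_form
  form:
    kind: logistic
    of: F
    r: rF
    K: KF
- name: predation
  sign: loss
  target: F
  depends_on:
  - F
  - P
  observability: inferred_by_balance
  assumptions:
    P: linear
    F: free
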