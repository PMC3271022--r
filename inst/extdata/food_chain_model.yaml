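variables:
- X
- 'Y'
- Z
time_mode: continuous
known_constants:
  e1: 0.59999999999999998
  e2: 0.69999999999999996
  mY: 0.08
processes:
- name: production
  sign: gain
  target: X
  depends_on:
  - X
  observability: inferred_by_balance
  assumptions:
    X: free
- name: grazing
  sign: loss
  target: X
  depends_on:
  - X
  - 'Y'
  observability: known_form
  form:
    kind: scaled_process
    process: assimilation
    scale: e1
    op: divide
- name: assimilation
  sign: gain
  target: 'Y'
  depends_on:
  - X
  - 'Y'
  observability: inferred_by_balance
  assumptions:
    'Y': linear
    X: free
- name: predation_loss
  sign: loss
  target: 'Y'
  depends_on:
  - 'Y'
  - Z
  observability: known_form
  form:
    kind: scaled_process
    process: top_intake
    scale: e2
    op: divide
- name: mortality_Y
  sign: loss
  target: 'Y'
  depends_on:
  - 'Y'
  observability: known_form
  form:
    kind: linear
    of: 'Y'
    rate: mY
- name: top_intake
  sign: gain
  target: Z
  depends_on:
  - 'Y'
  - Z
  observability: inferred_by_balance
  assumptions:
    Z: linear
    'Y': free
- name: top_mortality
  sign: loss
  target: Z
  depends_on:
  - Z
  observability: observed
  assumptions:
    Z: linear
  drifting: yes
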