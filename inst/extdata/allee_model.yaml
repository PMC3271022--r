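variables:
- A
time_mode: continuous
known_constants: []
processes:
- name: births
  sign: gain
  target: A
  depends_on:
  - A
  observability: observed
  assumptions:
    A: free
- name: deaths
  sign: loss
  target: A
  depends_on:
  - A
  observability: inferred_by_balance
  assumptions:
    A: linear
  drifting: yes
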