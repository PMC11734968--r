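variables:
- name: MWB
  domain: continuous
  display_group: outcomes
- name: QoL
  domain: continuous
  display_group: outcomes
- name: DEP
  domain: continuous
  display_group: mental_health
- name: SE
  domain: continuous
  display_group: coping
- name: HEA
  domain: continuous
  display_group: lifestyle
- name: PND
  domain: categorical
  levels:
  - '0'
  - '1'
  - '2'
  - '3'
  - '4'
  - '5'
  - '6'
  - '7'
  display_group: health
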