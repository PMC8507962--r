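name: reform (CBS + IPI + ICMS)
components:
- name: cbs_ad_valorem
  kind: ad_valorem
  rate: 0.22
  base: highest_national_brand_price
  level: federal
- name: cbs_specific
  kind: specific
  amount: 1.1
  level: federal
- name: ipi_ad_valorem
  kind: ad_valorem
  rate: 0.1425
  base: local_retail_price
  level: federal
- name: ipi_specific
  kind: specific
  amount: 1.5
  level: federal
- name: icms
  kind: ad_valorem
  rate: 0.25
  base: local_retail_price
  level: state
state_overrides:
  AC:
    icms: 0.25
  AP:
    icms: 0.25
  AM:
    icms: 0.25
  PA:
    icms: 0.25
  RO:
    icms: 0.25
  RR:
    icms: 0.25
  TO:
    icms: 0.25
  AL:
    icms: 0.265
  MA:
    icms: 0.265
  PI:
    icms: 0.265
  PB:
    icms: 0.265
  SE:
    icms: 0.265
  CE:
    icms: 0.265
  RN:
    icms: 0.265
  PE:
    icms: 0.265
  BA:
    icms: 0.265
  ES:
    icms: 0.245
  MG:
    icms: 0.245
  SP:
    icms: 0.245
  RJ:
    icms: 0.28
  PR:
    icms: 0.25
  SC:
    icms: 0.25
  RS:
    icms: 0.25
  MS:
    icms: 0.27
  GO:
    icms: 0.26
  MT:
    icms: 0.26
  DF:
    icms: 0.26
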