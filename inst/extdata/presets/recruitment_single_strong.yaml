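"n": 50
mechanism: recruitment
enzymes: single_mt
initiation_sites:
  Mt: 25
rates:
  k_on: 2.4
  k_recruitment: 4.8
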