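"n": 50
mechanism: diffusion
enzymes: dual
initiation_sites:
  Mt: 5
  At: 45
rates:
  k_on: 0.01
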