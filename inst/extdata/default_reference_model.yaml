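# Synthetic stand-in for the (unpublished) reference-sample correlations:
# exchangeable, one value within a function, one across functions.
tasks:
  object_recognition: [VISM, NOISE, OVERL, VIEW, DEVOS]
  motion: [GM, MDF, MS]
  attention: [SEARCH5, SEARCH10, SEARCH20]
  visuomotor: [BEERY, MOSAICS]
correlation:
  rho_within: 0.3
  rho_between: 0.1
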