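# example inter-individual variability: 30% CV lognormal on ke and Vd
cv:
  ke: 0.3
  vd: 0.3
n_subjects: 300
seed: 1
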