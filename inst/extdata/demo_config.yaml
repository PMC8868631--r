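outputDir: demo_run
seed: 42
panelCounts: {Bacteria: 4, Archaea: 2, SAR: 4, Amorphea: 6}
nFamilies: 3
nDecoys: 10
dup: 0.1
loss: 0.1
transfer: 0.05
seqLength: 120
subRate: 0.3
motifs:
- pattern: DPPW
  pos: 30
bootstrap: 100
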