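Place PDB coordinate files here to reproduce the published structure
comparisons (none are bundled; they must be downloaded from the RCSB
PDB, https://www.rcsb.org):

  6zcn.pdb   human YTHDC1 YTH domain        (chain A)
  6zot.pdb   human YTHDF3 YTH domain        (chain B)
  6p0g.pdb   Toxoplasma gondii McrB N-lobe  (chain A)
  2p5d.pdb   M. jannaschii MJECL36          (chain A)
  dam.pdb    E. coli Dam MTase              (user-supplied identifier)
  rlmj.pdb   E. coli RlmJ MTase             (user-supplied identifier)

With the first four files present, the acceptance script reports the
YTH-family RMSD comparisons; with dam.pdb/rlmj.pdb it also reports the
Dam/RlmJ superposition.
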