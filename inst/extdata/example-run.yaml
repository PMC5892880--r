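# Example pipeline configuration: a small UV-like dose series.
generator:
  nCrystals: 4
  nExposures: 3
  dosePerExposure: 1.16
  nAtoms: 60
  nSSites: 4
  cell: [26.0, 28.0, 24.0]
  dHalf: 2.63
  completeness: 0.7
  targetIsig: 15.0
  dMin: 2.2
substructure:
  ntry: 20
  nFind: 4
  dMin: 2.3
phasing:
  solventFraction: 0.5
  dmCycles: 5
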