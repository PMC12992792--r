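# Five-species germline piRNA precursor biogenesis screen design.
# Divergence times (million years) are approximate literature values.
species:
  Dmel: D. melanogaster
  Dsim: D. simulans
  Dere: D. erecta
  Dper: D. persimilis
  Dvir: D. virilis
genes: [Rhi, Kipf, Del, Cuff, Moon, TfIIA-S, Trf2, CtBP, Boot, Nxf3, UAP56]
absences:
  - {gene: Kipf, species: Dper}
  - {gene: Kipf, species: Dvir}
divergence_my:
  Dmel-Dsim: 5
  Dmel-Dere: 13
  Dsim-Dere: 13
  Dmel-Dper: 30
  Dsim-Dper: 30
  Dere-Dper: 30
  Dmel-Dvir: 40
  Dsim-Dvir: 40
  Dere-Dvir: 40
  Dper-Dvir: 40
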