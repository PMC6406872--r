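system: HepaRG
protein_per_cell_pg: 285
cell_radius_um: 8.4
seeded_cells: 480000
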