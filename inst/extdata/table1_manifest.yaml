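# Structure-selection manifest for the curated handedness data set.
#
# One entry per structure component: structural class (LHG4/RHG4/ZDNA/BDNA,
# label 0 for the left-handed classes), and the residue selection. G4
# entries list their tetrad guanines explicitly as chain:resseq; duplex
# entries use "all-complete" (every nucleotide passes here, terminal
# residues with missing angles are dropped downstream).
#
# IMPORTANT: the source study does not enumerate per-structure residue
# selections. The G4 lists below are reconstructed from the published
# sequences (tract guanines by 1-based sequence position on chain A) and
# will usually need editing to match the deposited chain IDs and author
# residue numbering of each PDB entry before use on real files. 6QJO
# appears twice: its left- and right-handed components are separate
# dataset entries.
- pdb_id: 6FQ2
  structural_class: LHG4
  residues: [A:2, A:3, A:5, A:6, A:8, A:9, A:11, A:12, A:15, A:17, A:18, A:20, A:21, A:23, A:24, A:26]
- pdb_id: 7DFY
  structural_class: LHG4
  residues: [A:1, A:3, A:4, A:6, A:7, A:9, A:10, A:12]
- pdb_id: 4U5M
  structural_class: LHG4
  residues: [A:1, A:3, A:4, A:6, A:7, A:9, A:10, A:12, A:15, A:17, A:18, A:20, A:21, A:23, A:24, A:26]
- pdb_id: 6GZ6
  structural_class: LHG4
  residues: [A:1, A:2, A:5, A:6, A:10, A:11, A:14, A:15, A:17, A:19, A:20, A:22, A:23, A:25, A:26, A:28]
- pdb_id: 6QJO
  structural_class: LHG4
  residues: [A:14, A:16, A:17, A:19, A:20, A:22, A:23, A:25]
- pdb_id: 6QJO
  structural_class: RHG4
  residues: [A:1, A:2, A:4, A:6, A:8, A:9, A:11, A:12]
- pdb_id: 7D5D
  structural_class: LHG4
  residues: [A:1, A:2, A:4, A:6, A:8, A:10, A:12, A:13, A:15, A:17, A:18, A:20, A:21, A:23, A:24, A:26]
- pdb_id: 7D5E
  structural_class: LHG4
  residues: [A:2, A:3, A:5, A:6, A:8, A:9, A:11, A:12, A:15, A:17, A:18, A:20, A:21, A:23, A:24, A:26]
- pdb_id: 7KLP
  structural_class: RHG4
  residues: [A:2, A:3, A:4, A:8, A:9, A:10, A:14, A:15, A:16, A:20, A:21, A:22]
- pdb_id: 6N65
  structural_class: RHG4
  residues: [A:2, A:3, A:4, A:6, A:7, A:9, A:11, A:12, A:13, A:18, A:19, A:20]
- pdb_id: 3T5E
  structural_class: RHG4
  residues: [A:2, A:3, A:4, A:8, A:9, A:10, A:14, A:15, A:16, A:20, A:21, A:22]
- pdb_id: 6H5R
  structural_class: RHG4
  residues: [A:3, A:4, A:5, A:9, A:10, A:11, A:15, A:16, A:17, A:21, A:22, A:23]
- pdb_id: 4FXM
  structural_class: RHG4
  residues: [A:2, A:3, A:4, A:8, A:9, A:10, A:14, A:15, A:16, A:20, A:21, A:22]
- pdb_id: 2N3M
  structural_class: RHG4
  residues: [A:1, A:2, A:4, A:5, A:7, A:8, A:11, A:14, A:16, A:17, A:19, A:20, A:22]
- {pdb_id: 3P4J, structural_class: ZDNA, residues: all-complete}
- {pdb_id: 4OCB, structural_class: ZDNA, residues: all-complete}
- {pdb_id: 4FS6, structural_class: ZDNA, residues: all-complete}
- {pdb_id: 4FS5, structural_class: ZDNA, residues: all-complete}
- {pdb_id: 4HIG, structural_class: ZDNA, residues: all-complete}
- {pdb_id: 4HIF, structural_class: ZDNA, residues: all-complete}
- {pdb_id: 7JY2, structural_class: ZDNA, residues: all-complete}
- {pdb_id: 7ATG, structural_class: ZDNA, residues: all-complete}
- {pdb_id: 1BNA, structural_class: BDNA, residues: all-complete}
- {pdb_id: 2BNA, structural_class: BDNA, residues: all-complete}
- {pdb_id: 3BNA, structural_class: BDNA, residues: all-complete}
- {pdb_id: 4BNA, structural_class: BDNA, residues: all-complete}
- {pdb_id: 5BNA, structural_class: BDNA, residues: all-complete}
- {pdb_id: 1D60, structural_class: BDNA, residues: all-complete}
- {pdb_id: 1SGS, structural_class: BDNA, residues: all-complete}
- {pdb_id: 1DC0, structural_class: BDNA, residues: all-complete}
- {pdb_id: 1D8G, structural_class: BDNA, residues: all-complete}
- {pdb_id: 5DNB, structural_class: BDNA, residues: all-complete}
- {pdb_id: 436D, structural_class: BDNA, residues: all-complete}
- {pdb_id: 4C64, structural_class: BDNA, residues: all-complete}
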