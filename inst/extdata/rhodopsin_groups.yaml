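# Functional grouping of rhodopsin/opsin PDB entries. Group membership is
# configuration, not computation: fill in / edit the member lists to match
# the entries you have downloaded. Template below:
#   group 1 — ground-state rhodopsin and early (batho/lumi) intermediates
#   group 2 — structures with elongated cytoplasmic TM5/TM6
#   group 3 — opsin and metarhodopsin II (tilted TM6), including the
#             photoactivated-in-crystallo 2I37 chains
groups:
  - id: 1
    description: ground state + batho/lumi intermediates
    members:
      - {pdb: 1F88}
      - {pdb: 1HZX}
      - {pdb: 1L9H}
      - {pdb: 1U19}
      - {pdb: 1GZM}
      - {pdb: 2G87}
      - {pdb: 2HPY}
      - {pdb: 2PED}
  - id: 2
    description: elongated cytoplasmic TM5/TM6
    members:
      - {pdb: 2J4Y}
      - {pdb: 4A4M}
  - id: 3
    description: opsin / metarhodopsin II (tilted TM6) + 2I37
    members:
      - {pdb: 3CAP}
      - {pdb: 3DQB}
      - {pdb: 3PQR}
      - {pdb: 3PXO}
      - {pdb: 2I37}
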