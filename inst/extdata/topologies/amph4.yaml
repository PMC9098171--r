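# Synthetic 4-bead model amphiphile (one hydrophilic OH head, three
# hydrophobic T tail beads). Not a real surfactant: used for desk-scale
# self-assembly demonstrations and tests, where its strongly hydrophobic
# tail drives micellization in short runs.
name: AMPH4
molar_mass: 200.0
approximate: true
beads: [OH, T, T, T]
head_beads: [OH]
tail_beads: [T]
bonds:
  - {i: 1, j: 2, r0: 0.5}
  - {i: 2, j: 3, r0: 0.5}
  - {i: 3, j: 4, r0: 0.5}
angles:
  - {i: 2, j: 3, k: 4, theta0_deg: 180}
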