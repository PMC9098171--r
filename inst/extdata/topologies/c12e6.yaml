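# Approximate coarse-grained topology for hexaethylene glycol monododecyl
# ether (C12E6). Bead sequence and r0/theta0 are placeholders (see
# gluco8.yaml). The EO beads form the hydrophilic ethoxylate head.
name: C12E6
molar_mass: 450.7
approximate: true
beads: [OH, EO, EO, EO, EO, EO, EO, C2, C2, C2, C2, C2, T]
head_beads: [OH, EO]
tail_beads: [C2, T]
bonds:
  - {i: 1, j: 2, r0: 0.5}
  - {i: 2, j: 3, r0: 0.5}
  - {i: 3, j: 4, r0: 0.5}
  - {i: 4, j: 5, r0: 0.5}
  - {i: 5, j: 6, r0: 0.5}
  - {i: 6, j: 7, r0: 0.5}
  - {i: 7, j: 8, r0: 0.5}
  - {i: 8, j: 9, r0: 0.5}
  - {i: 9, j: 10, r0: 0.5}
  - {i: 10, j: 11, r0: 0.5}
  - {i: 11, j: 12, r0: 0.5}
  - {i: 12, j: 13, r0: 0.5}
angles:
  - {i: 8, j: 9, k: 10, theta0_deg: 180}
  - {i: 9, j: 10, k: 11, theta0_deg: 180}
  - {i: 10, j: 11, k: 12, theta0_deg: 180}
  - {i: 11, j: 12, k: 13, theta0_deg: 180}
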