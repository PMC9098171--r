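# Approximate coarse-grained topology for n-octanoyl-N-methylglucamine
# (MEGA8). Bead sequence and r0/theta0 are placeholders (see gluco8.yaml).
name: MEGA8
molar_mass: 321.4
approximate: true
beads: [OH, OH, OHp, AM3, C2, C2, T]
head_beads: [OH, OHp, AM3]
tail_beads: [C2, T]
bonds:
  - {i: 1, j: 2, r0: 0.5}
  - {i: 2, j: 3, r0: 0.5}
  - {i: 3, j: 4, r0: 0.5}
  - {i: 4, j: 5, r0: 0.5}
  - {i: 5, j: 6, r0: 0.5}
  - {i: 6, j: 7, r0: 0.5}
angles:
  - {i: 5, j: 6, k: 7, theta0_deg: 180}
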