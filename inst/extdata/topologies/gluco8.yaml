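# Approximate coarse-grained topology for n-octyl glucopyranoside (GLUCO8).
# Bead sequence and equilibrium geometry are approximations: the published
# bead diagram is pictorial and r0/theta0 come from an external assignment
# method, so the values below are placeholders suitable for demonstration
# and testing, not production parameterization.
name: GLUCO8
molar_mass: 292.4
approximate: true
beads: [OHp, OH, C2, C2, C2, T]
head_beads: [OHp, OH]
tail_beads: [C2, T]
bonds:
  - {i: 1, j: 2, r0: 0.5}
  - {i: 2, j: 3, r0: 0.5}
  - {i: 3, j: 4, r0: 0.5}
  - {i: 4, j: 5, r0: 0.5}
  - {i: 5, j: 6, r0: 0.5}
angles:
  - {i: 3, j: 4, k: 5, theta0_deg: 180}
  - {i: 4, j: 5, k: 6, theta0_deg: 180}
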