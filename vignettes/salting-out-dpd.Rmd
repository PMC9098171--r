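---
title: "Methods: parameterizing ion-surfactant interactions from salting-out data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parameterizing ion-surfactant interactions from salting-out data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(setsolv)
```

## The problem

Added salt lowers the critical micelle concentration (CMC) of nonionic
surfactants, and it does so log-linearly: the Setschenow relation

$$\ln\!\frac{\mathrm{CMC}}{\mathrm{CMC}_0} = -k_s\,C_\mathrm{salt}$$

defines a salt- and surfactant-specific coefficient $k_s$ (M$^{-1}$),
positive for salting out. The ordering of ions by $k_s$ follows the
Hofmeister series. In dissipative particle dynamics (DPD), where ions are
conventionally modelled as charged water beads, this ion specificity is
absent by construction. This package implements a workflow that restores
it: simulate surfactant self-assembly with explicit salt, extract the CMC
from aggregation statistics, measure the simulated $k_s$, and use the
mapping between $k_s$ and the ion-tail repulsion amplitudes to assign
ion-specific short-range parameters from experimental salting-out data.

## The simulation model

Beads interact through the standard Groot-Warren soft repulsion with
per-pair range,

$$ u_{ij}(r) = \tfrac{1}{2} a_{ij} R_{ij} \left(1 - r/R_{ij}\right)^2,
\qquad r < R_{ij}, $$

so the force is $a_{ij}(1 - r/R_{ij})\hat r$. Chemical specificity lives
entirely in the amplitude $a_{ij}$ (in $k_BT$) and range $R_{ij}$ (in
$r_c$); the packaged force field ships the published table of 10 self and
30 cross pairs for the water (W), tail (T, T2, C2) and head-group (AM3,
OH, OH$'$, OH2, AC$'$, EO) bead types. Bonds are harmonic,
$\tfrac12 k_b (r - r_0)^2$ with $k_b = 150\,k_BT/r_c^2$, and angles
$\tfrac12 k_a (\theta - \theta_0)^2$ with $k_a = 5\,k_BT$. The
equilibrium values $r_0$, $\theta_0$ are not published for these
molecules; the shipped topology files carry placeholder values
($r_0 = 0.5\,r_c$, $\theta_0 = 180^\circ$ on tail triples) and are
labelled approximate throughout — the published bead diagrams are
pictorial, so the bead sequences themselves are reasonable
reconstructions, not transcriptions.

Temperature is held at $k_BT = 1$ by the pairwise DPD thermostat
(dissipative force $-\gamma w^2(r) (\hat r \cdot v_{ij})\hat r$, random
force $\sigma w(r) \theta_{ij} \Delta t^{-1/2} \hat r$ with
$\sigma^2 = 2\gamma k_BT$ and $w(r) = 1 - r$). The friction $\gamma =
4.5$ is the conventional DPD default; the source force field does not
state it, and since the thermostat is momentum-conserving it affects
dynamics but not equilibrium averages. The random deviate $\theta_{ij}$
is uniform with unit variance (only its first two moments matter for the
stationary distribution). Integration is velocity Verlet with the
dissipative force evaluated at half-step velocities, $\Delta t = 0.01$.
A per-step displacement above $0.5\,r_c$ aborts the run as unstable — an
engineering guard, not a physical parameter.

At the reference state (all $a = 25$, $R = 1$, reduced density
$\rho r_c^3 = 3$) the virial pressure of pure DPD water is the known
benchmark 23.7 in reduced units; `measure_observables()` on a 3000-bead
box reproduces it, and the optional Berendsen-style barostat (isotropic
rescaling toward a target pressure, default 23.7) recovers density
3.00. NVT at density 3 is the default test mode because the model is
constructed so both ensembles agree for water; the production protocol
this package scales down from used NPT.

## Units

One water bead represents $N_m = 2$ water molecules. With
$V_m = 18 \times 10^{-6}\,$m$^3$/mol and $\rho r_c^3 = 3$, the identity
$N_A r_c^3 = \rho r_c^3 N_m V_m$ gives $N_A r_c^3 \approx 0.108$ L/mol
and $r_c = 5.64$ Å. Salt molarity converts to ion-pair counts through
the same volume: 1.0 M in an $L = 30\,r_c$ box is 2916 cation/anion bead
pairs, inserted by replacing water beads ("salt beads" are counted as
formula units, since experimental coefficients are per mole of salt; a
switch to individual-ion counting would halve the mapping and is
deliberately not the default). Molar and molal scales are not
distinguished, consistent with the accuracy of the underlying data at
concentrations up to a few molar.

## Electrostatics

Ions are charged water beads: valence $\pm 1$, all short-range
parameters inherited from W except explicitly overridden ion-tail
amplitudes. Point charges between soft beads would collapse, so charges
are Slater-smeared:

$$ u(r) = \frac{\Gamma q_i q_j}{4\pi r}
  \left[1 - (1 + \beta^* r)\, e^{-2\beta^* r}\right], $$

finite at contact ($u(0) = \Gamma q_i q_j \beta^*/4\pi$) with the bare
Coulomb tail, $\beta^* = 0.929\,r_c^{-1}$. The coupling
$\Gamma = e^2 / (k_BT \varepsilon_0 \varepsilon_r r_c)$ is 15.96 from
CODATA constants at 298 K, $\varepsilon_r = 78.3$; the conventional
rounded value 15.94 is kept as the simulation default (the 0.1%
difference is far below every observable's statistical error).

Periodicity is handled by Ewald summation of the point-charge part
(real-space erfc with cutoff $3.0\,r_c$, reciprocal sum over
$|k| \le 5\,r_c^{-1}$, self term) plus the short-range smearing
correction $u_\mathrm{slater} - u_\mathrm{coulomb}$, which decays as
$e^{-2\beta^* r}$. Two numerical choices matter:

* The splitting width $\alpha$ is a free parameter of the decomposition;
  the default $1.0\,r_c^{-1}$ keeps $\mathrm{erfc}(\alpha \cdot 3.0)$
  below $3\times 10^{-5}$. Exact $\alpha$-independence holds only when
  both halves of the split are converged; the property test therefore
  uses enlarged cutoffs (real $5\,r_c$, reciprocal $12\,r_c^{-1}$),
  while the production defaults above trade ~$10^{-3}$ relative accuracy
  for speed, adequate because the reciprocal-space resolution has no
  detectable effect on neutral-surfactant observables (asserted as an
  exact no-op test on a salt-free system).
* The smearing correction is small but not negligible at $3\,r_c$
  (~$6\times10^{-3}\,k_BT$ per pair), so it carries its own
  convergence-based cutoff ($8\,r_c$ by default, summed over periodic
  image shells when the box is smaller). This is what lets the total
  energy match a brute-force lattice sum at $10^{-4}$.

## CMC extraction

Surfactant aggregates are identified per frame by single-linkage
clustering on tail-bead contacts: two molecules join the same aggregate
when any pair of their tail beads lies within $1.0\,r_c$ (minimum
image), closed transitively. The source analysis tool does not document
its criterion; tail contact is chosen because the micelle is defined by
its hydrophobic core, and both the cutoff and the bead set are
configurable. Aggregate sizes pooled over post-equilibration frames give
the aggregation-number distribution $P(N)$, molecule-weighted by default
(aggregate weighting is available; the two differ by a factor of $N$).

$N_\mathrm{cut}$, separating free surfactant from micelles, is the
minimum of the smoothed $P(N)$ (moving average, window 3) strictly
between the monomer mode and the largest micellar mode. When the minimum
is attained on a contiguous run of equally depleted sizes — the usual
case, since the depleted region is often entirely empty at desk scale —
the run's midpoint is taken; an isolated minimum is taken as is, ties
toward smaller $N$. A monotone distribution (no micelles yet) falls back
to $N_\mathrm{cut} = 10$ with a warning rather than failing. The CMC is
the mean number of molecules in aggregates with $N < N_\mathrm{cut}$
(monomers *and* submicellar aggregates), converted to mol/L through the
box volume; runs at several loadings are averaged. The equilibration
discard defaults to 1/8 of the run, the same fraction the full-scale
protocol discards ($5\times10^5$ of $4\times10^6$ steps).

## The separable salting-out model

The link between simulation parameters and experiment is

$$ k_s = A \left( \frac{1}{a_+} + \frac{1}{a_-} \right) + B, $$

where $a_\pm$ are the cation-tail and anion-tail repulsion amplitudes
and $A$ (M$^{-1} k_BT$), $B$ (M$^{-1}$) are surfactant constants. Before
anything was built on it, this form was verified to reproduce every
published calculated coefficient for the 25 monovalent
surfactant-salt systems within the 0.02 tolerance implied by the
2-decimal rounding of the printed inputs. $A < 0$ for all four
surfactants, so weaker ion-tail repulsion means weaker salting out, and
a salt's effect is the sum of independent cation and anion terms.

Fitting has two directions, both exposed:

* `fit_surfactant_AB()`: with ion amplitudes fixed, $k_s$ is linear in
  $(A, B)$ — ordinary least squares.
* `fit_ion_amplitudes()`: with $(A, B)$ fixed, bounded
  Levenberg-Marquardt least squares over all (surfactant, salt) rows,
  bounds $[35, 150]\,k_BT$ matching the screened range. The published
  workflow used a spreadsheet generalized-reduced-gradient solver; only
  the minimizer matters, not the algorithm.

One identifiability fact deserves emphasis: the model sees ions only
through $1/a_+ + 1/a_-$, so shifting every cation reciprocal by
$+\delta$ and every anion reciprocal by $-\delta$ changes nothing. The
published ion table is one representative of this one-parameter family.
`fit_ion_amplitudes()` therefore pins the gauge with an `anchor`
(default: chloride at its published $94\,k_BT$, chloride being the
counter-ion common to most measured salts); with the anchor, refitting
the packaged experimental table reproduces the published amplitudes to
within a couple of $k_BT$ and preserves the cation ordering
Na$^+$ > K$^+$ > Cs$^+$ > Li$^+$. Fitting without an anchor is allowed
but warns, and ion couples that only ever occur together are reported
as weakly identified. Fluoride is excluded from fitting by default (its
required amplitude exceeds the physically sensible range — the
underlying model cannot represent it), and divalent-salt rows ship in
the data file flagged out of scope.

## Synthetic fixtures

Two generators make every analysis stage testable without long
simulations, and both are seed-deterministic:

* `generate_micelle_trajectory()` plants micelles geometrically: tail
  beads of one micelle are packed in a ball of radius $0.45\,r_c$ (any
  two within $0.9\,r_c$, so single-linkage connectivity at the
  $1.0\,r_c$ cutoff is guaranteed by construction), monomers at least
  $3\,r_c$ from every micelle and $2.5\,r_c$ from each other, so the
  planted partition is the unique correct clustering. These fixtures
  test the analysis code, not the physics: they have no realistic shape
  fluctuations, no exchange dynamics, and no submicellar population
  unless planted.
* `generate_ks_dataset()` emits CMC series following
  $\ln(\mathrm{CMC}/\mathrm{CMC}_0) = -k_s C$ with $k_s$ from a planted
  separable model, optional lognormal noise on the CMCs, in the exact
  file formats the fitting functions read. At zero noise the full
  fitting pipeline is an exact inverse.

Passing on these fixtures demonstrates correctness of the machinery, not
that a short desk-scale simulation reaches the statistical quality of
the full-scale protocol (81,000 beads, $4\times10^6$ steps, three
loadings per point); reproducing the full response surfaces is out of
scope by design.

## Problem sizes and budgets

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest systems where the checked property is unambiguous: pure
water pressure on 3000 beads (L = 10) with 5,000 + 15,000 steps;
thermostat checks on 375 beads; self-assembly demonstration with 150 of
the packaged 4-bead model amphiphiles (3000 beads, $5\times10^4$ steps),
which reliably forms micelles while leaving free monomers; Ewald oracles
on 8-16 charges where direct lattice sums are exact references. The
4-bead amphiphile (one OH head, three strongly hydrophobic T beads) is a
synthetic molecule built from shipped bead types specifically to
micellize quickly; it is not one of the studied surfactants.

## Known limitations

* Topologies for MEGA8, MEGA9, GLUCO8 and C12E6 are approximate
  reconstructions with placeholder bonded geometry; quantitative CMC
  predictions for the real molecules additionally require the original
  bonded-parameter assignment.
* Monovalent ions only; divalent data are carried but never fitted.
* The ion-amplitude gauge is set by convention (chloride anchor), not by
  data.
* Desk-scale simulations demonstrate the workflow; they do not reproduce
  the published response surfaces, which required cluster-scale runs.
* No micelle shape or lifetime analysis; the aggregation criterion is a
  configurable convention, not a measured property.
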