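---
title: "Thermodynamics of a single flexible-semiflexible multiblock copolymer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamics of a single flexible-semiflexible multiblock copolymer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfcopoly)
```

## The model

`sfcopoly` simulates one coarse-grained copolymer chain of `N` hard-sphere
beads (diameter $\sigma = 1$, the length unit) in an implicit solvent.  Bonds
are free within $[0.8\sigma, 1.25\sigma]$ — no elastic energy, and bonded
beads may interpenetrate.  Because the maximal bond length is below
$\sqrt{2}\,\sigma$, bonds cannot cross and the chain is self-avoiding by
construction.  Beads come in two types, semiflexible (S) and flexible (F), in
equal numbers, arranged in regularly alternating blocks of length `b`.

Two square-well terms make up the conformational energy
$U = E_{nv} + E_{st}$:

* **Non-valent contacts.** Every non-bonded pair (chain distance $\ge 2$)
  within $R_{cut} = 1.5\sigma$ contributes $\varepsilon_{ss}$,
  $\varepsilon_{ff}$ or $\varepsilon_{sf}$ by type,
  $E_{nv} = \varepsilon_{ss} n_{ss} + \varepsilon_{ff} n_{ff} +
  \varepsilon_{sf} n_{sf}$.  Solvent selectivity lives entirely in these
  three numbers, tied by the Lorentz–Berthelot rule
  $|\varepsilon_{sf}| = \sqrt{|\varepsilon_{ss}||\varepsilon_{ff}|}$.
  Two presets are built in: *S-attract* $(-4, -2, -1)$ and *F-attract*
  $(-0.25, -0.5, -1)$, both in units of $|\varepsilon_{ff}|$.  The F-attract
  set is stored as integers $(-1, -2, -4)$ with a 0.25 rescaling so the
  energy coordinate of a macrostate stays exactly integer.
* **Bending stiffness.** Valence angles in $[150^\circ, 170^\circ]$ whose
  three beads all lie in one S block each contribute
  $\varepsilon_{st} \le 0$, $E_{st} = \varepsilon_{st} n_{st}$.  A perfectly
  straight chain ($180^\circ$) is *not* favorable; the window prefers
  slightly bent, zig-zag or helical local shapes.  Restricting eligibility
  to all-S triplets is the most conservative reading of "semiflexible
  blocks carry stiffness"; junction angles never count, so
  $n_{st}^{max} = (b-2)N/(2b)$.

Boundary conventions are fixed once for reproducibility: a contact is
$r \le R_{cut}$, hard-sphere validity is $r \ge \sigma$, and the angle window
is closed on both ends.  All are measure-zero choices.

## Flat-histogram sampling

The sampler estimates the two-dimensional density of states
$g(E_{nv}, n_{st})$ by stochastic approximation Monte Carlo.  A trial move
from macrostate $o$ to $n$ is accepted with probability
$\min\{1, g(o)/g(n)\}$, and after *every* trial the resulting macrostate's
log-density is raised by the current gain $\gamma_t$ (and its visit count by
one).  The gain follows $\gamma_t = \gamma_0 \min(1, t_0/t)$ with $t$
counted in sweeps; one sweep (MCS) is $2N$ single-bead displacement trials
(uniform in $[-0.05, 0.05]$ per axis) plus one end-cut-and-regrow trial that
redraws up to `k_max` terminal bonds uniformly with respect to volume from
the spherical bond shell.  Both proposals are symmetric under the Cartesian
measure — the regrow draws bond vectors with constant density on the allowed
shell, and the bond parametrization has unit Jacobian — so the two move
types target the same measure (the suite verifies this by accept-everything
sampling against the closed-form angle statistics).  `k_max` defaults to one
block, a natural mixing scale; any symmetric choice is correct.

Refinement chains stages of decreasing gain, by default
$(\gamma_0, t_0) = (1, 10^3)$ then $(0.01, 10^4)$; each stage restarts the
gain clock and inherits the previous stage's density estimate and
conformation.  Because the density estimate is relative, tables are anchored
to $\max \log g = 0$ on output.  Independent runs (different seeds) are
combined by `average_dos()`: per-macrostate mean of anchored $\log g$ over
the runs that visited the key, with a configurable quorum (default 2)
dropping keys seen in fewer runs, and the cross-run standard deviation kept
as a convergence diagnostic.  The quorum value is plumbing, not physics: it
only filters barely-explored keys out of averaged tables.

Two numerical choices matter in practice:

* **Unseen macrostates** are registered at the log-density of the state the
  walker entered them from.  Registering at the global minimum instead (a
  plausible alternative) proved pathological at larger sizes: with
  $\log g$ spanning hundreds of units, a late-discovered key near the coil
  region would start hundreds of units too low and the walker would stall
  pumping it back up; local continuation keeps the initialization error
  $O(1)$ and measurably sharpens convergence even for 4-bead chains.
* **Exact integer bookkeeping.** The macrostate key stores the raw integer
  contact energy; contact and angle changes are updated incrementally per
  move with pure integer deltas, so no float binning ever occurs.

Production runs freeze a density estimate, sample with the same
acceptance rule without updates, and accumulate per-macrostate means
$\bar A(E_{nv}, n_{st})$ of the morphology observables once per sweep (a
thinned estimator; the macrostate coordinates themselves are exact).  Moves
into macrostates outside the frozen support are rejected and counted.
Macrostates with fewer samples than a floor (default $10^3$) are flagged in
the result.  Because the frozen density is constant within a macrostate,
per-macrostate means are unbiased under *any* frozen estimate — it controls
only coverage and visit rates — so the recommended pattern, implemented by
`pool_observables()`, runs production per refinement run with that run's
own (self-consistent) density and pools the tables with count weighting.
Sampling production against a cross-run *average* density is attractive on
paper but fragile in practice: wherever the runs disagree, the averaged
landscape acquires artificial wells that can trap the walker.  Starting one
segment from the run's final (low-energy) conformation and one from a
fresh stretched chain makes the pooled table cover the full energy range
even when a single walker does not traverse it.

## Canonical analysis

With $U = E_{nv} + \varepsilon_{st} n_{st}$ per macrostate, all canonical
quantities are reweighted sums over the *same* 2D table for any temperature
and any stiffness — this is the point of keeping $n_{st}$ as a separate
coordinate.  `heat_capacity()` uses the fluctuation formula
$C_V = (\langle U^2\rangle - \langle U\rangle^2)/T^2$ with both moments
accumulated in one max-subtracted pass (no catastrophic cancellation at low
$T$); the suite checks it against the Schottky closed form and against
$d\langle U\rangle/dT$.  `macrostate_probability()` gives the distribution
whose mode identifies the region's most probable macrostate.
State diagrams are assembled on a grid of normalized stiffness
$\varepsilon_{st}/\varepsilon_{ff}$ versus normalized inverse temperature
$|\varepsilon_{ff}|/T$; maxima of $C_V$ along either axis (discrete local
maxima after optional moving-average smoothing, each carrying its
topographic prominence) form the transition loci.  No smoothing is applied
by default; detector settings always travel with the output.

## Microcanonical analysis

Projecting the 2D table at fixed $\varepsilon_{st}$ gives the 1D
conformational density $g(U)$; its logarithm is the Boltzmann entropy
$S_B(U)$ and $T^{-1}(U) = dS_B/dU$ by central differences (optional Gaussian
pre-smoothing of $S_B$, width in bins, recorded in the output).  The default
bin width is the smallest gap between attainable $U$ values, so distinct
levels never share a bin; for incommensurate $\varepsilon_{st}$ the fallback
is 0.5.  Transition points are maxima of $dT^{-1}/dU$: a positive peak means
backbending (Maxwell construction — first-order-like), a negative one an
inflection (second-order-like), and $T^* = T(U^*)$.

The true-microcanonical (NVE) density follows by kinetic convolution,
$g(E) \propto \sum_U (E-U)^{d/2-1} g(U)\,\Theta(E-U)$ with $d$ momentum
degrees of freedom (default $3N$; configurable — the published analyses do
not state $d$).  $T^{-1}(E)$ is evaluated *analytically* as the conditional
average of $(d/2-1)/(E-U)$, which makes the single-support ideal-gas law
$T = 2(E-U_0)/(d-2)$ exact on the grid.  The third variant pairs
$T^{-1}(E)$ with $\langle U\rangle(E) = \sum_U U\, p(U|E)$; the convolution
smooths the energy-scale oscillations that appear in $T^{-1}(U)$ at strong
stiffness while leaving transition temperatures in place, and can soften a
weak first-order signal into a second-order one — order labels for small
systems are method-dependent, and the package reports the ensemble tag with
every transition point.

## Morphology and classification

Five criteria drive the taxonomy of coils (I), isotropic globules (II) and
anisotropic globules (III): squared gyration radii of the whole chain and
of each type subset; contact counts (liquid versus frozen packing); shape
from gyration-tensor eigenvalues (asphericity, prolateness); bond
orientational order of the S blocks; and S/F demixing.  Orientational order
uses the traceless tensor of S-block bond directions: the largest eigenvalue
is the nematic order $S_{nem}$, and minus the smallest is a planar order
parameter that flags toroidal winding (tangential bonds give
$S_{nem} \approx 0.25$ but planar order $\approx 0.5$), so either exceeding
its cut marks a globule anisotropic.  Sub-labels use sharp-fold counts
(all-S angles below $90^\circ$), a toroid hole test (no S bead within a
radius of the S centroid), the F–S centroid offset (dumbbell caps), and
S–F contacts per F bead (shell adsorption, distinguishing the primed
loose-shell variant).

The numeric thresholds are *not* published quantities.  They are expressed
scale-free where possible (gyration radii relative to the freely-jointed
reference $n l^2/6$, contacts per bead) and were calibrated once on this
package's own small-chain production runs; every label returns the full
rule trace so users can audit and recalibrate.  Where a transition leaves no
specific-heat maximum (long-block collapse), the temperature derivative of
the reweighted $\langle R_g^2\rangle$ supplies the transition indicator.

## Oracles and what the tests show

Validation deliberately avoids the sampler's own code paths:

* the **phantom chain** (hard spheres and contacts off) has exactly
  binomial stiff-angle statistics with
  $p_0 = (\cos\theta_{min} - \cos\theta_{max})/2 \approx 0.0594$;
* **brute-force growth** samples chains bond-by-bond from the same shell
  measure with hard-sphere rejection, estimating the density of states for
  tiny chains with multinomial errors;
* a **fixed-temperature Metropolis** chain with the same move set
  cross-checks canonical averages with batch-mean error bars;
* closed forms (ideal-gas caloric law, Schottky peak, linear entropy) are
  checked to near machine precision via `analytic_limits_suite()`.

Desk-scale study sizes used by the test suite and the acceptance script:
phantom chains of 6 beads at $\sim 10^6$ sweeps averaged over several
seeds; the 4-bead interacting chain against brute force; an 8-bead chain
for canonical cross-checks at $T \in \{0.5, 1, 2\}$; and a 32-bead,
$b = 8$ chain in the S-attract solvent at a few $10^7$ sweeps for the
qualitative two-transition physics (coil–globule, then liquid–solid at
lower temperature, with the classifier reading I → IIa → IIb along the
most probable macrostates).  These sizes are the package's chosen
desk-scale study conditions; published-scale campaigns
($N = 64$, $\ge 10^{10}$ sweeps, 14–28 independent density estimates) are
cluster work that the same functions support through checkpointed,
independently seeded runs.  Passing desk-scale tests shows the machinery is
correct and the scaled physics qualitatively present; it does not reproduce
published transition coordinates, which require the full campaigns.

## Known limitations

* Single chain only: no explicit solvent, no elastic bonds, no torsions,
  no multi-chain systems.
* The classifier's thresholds are calibrated, not published, constants;
  expect to recalibrate for other chain lengths.
* Helicity is visible in stiff morphologies but not quantified.
* SAMC error decays slowly ($\propto t^{-1/2}$ after the gain plateau);
  under-converged densities show up as spurious specific-heat spikes, so
  always inspect the cross-run standard deviation from `average_dos()` and
  the per-stage flatness diagnostics before trusting a diagram.
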