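# sfcopoly

Single-chain thermodynamics of flexible–semiflexible multiblock copolymers
in selective solvents, by flat-histogram Monte Carlo.

A chain of `N` hard-sphere beads carries two bead types in alternating
blocks of length `b`: flexible (F) and semiflexible (S), the latter with a
square-well bending energy that rewards valence angles in [150°, 170°].
Non-bonded beads within 1.5σ contribute square-well contact energies
(ε_ss, ε_ff, ε_sf), which encode the solvent: the built-in presets are
*S-attract* (−4, −1, −2) and *F-attract* (−0.25, −1, −0.5) in units of
|ε_ff|.  The total conformational energy is

    U = ε_ss·n_ss + ε_ff·n_ff + ε_sf·n_sf + ε_st·n_st

and a macrostate is the pair (E_nv, n_st).  The package estimates the
two-dimensional density of states g(E_nv, n_st) with the Stochastic
Approximation Monte Carlo (SAMC) flat-histogram sampler — acceptance
min{1, g_old/g_new}, per-trial update ln g ← ln g + γ_t on the resulting
macrostate, gain γ_t = γ0·min(1, t0/t) — and from one density table derives,
for *any* temperature and stiffness:

* canonical averages, heat capacity C_V(T, ε_st) and state diagrams over
  (ε_st/ε_ff, |ε_ff|/T) with transition loci from C_V maxima;
* microcanonical caloric curves T⁻¹(U) (NVU) and, via kinetic-energy
  convolution with d degrees of freedom, T⁻¹(E) and T⁻¹(⟨U⟩(E)) (NVE),
  with pseudo-phase transitions located at maxima of dT⁻¹/dU and classified
  first-order (positive peak, backbending) or second-order (negative peak);
* morphology observables (gyration radii and tensor shapes per bead type,
  nematic/planar bond order, contacts, folds, demixing) and a hierarchical
  classifier over the taxonomy Ia–IIIe′ (coils, isotropic globules,
  anisotropic globules), with a full rule trace per label.

Who it is for: polymer/biopolymer simulators studying coil–globule and
liquid–solid pseudo-phase transitions of finite chains, and anyone needing a
compact, validated flat-histogram reference implementation with honest
oracles (closed-form phantom chain, brute-force uniform sampling,
fixed-temperature Metropolis).

## Worked example

Accumulate the density of states of a 16-bead chain (b = 4 blocks,
S-attract solvent), then reweight:

```r
library(sfcopoly)
m    <- sf_model(N = 16, b = 4, preset = "S-attract", eps_st = -2)
sch  <- list(gain_schedule(1, 1e3), gain_schedule(0.1, 1e4),
             gain_schedule(0.01, 1e4))
runs <- lapply(1:2, function(s)
  refine(m, n_mcs = c(1e5, 3e5, 6e5), schedules = sch, seed = s))
dos  <- average_dos(runs)    # two independent determinations, averaged
dos
#> <sf_dos> 729 macrostates, 2e+06 MCS accumulated
#>   Env_raw in [-155, 0], nst in [0, 4], fingerprint 6a97e3e1

hc <- heat_capacity(dos, temperature = c(0.5, 1, 2), eps_st = -2)
round(hc[, c("temperature", "U_mean", "CV")], 2)
#>   temperature  U_mean    CV
#> 1         0.5 -142.18 64.28
#> 2         1.0 -118.50 48.53
#> 3         2.0  -84.04 26.50

pr <- cv_profile_T(dos, eps_st = -2, T_grid = 1 / seq(0.1, 4, by = 0.02),
                   smooth_window = 5, min_prominence = 2)
attr(pr, "maxima")$x
#> [1] 0.8928571 0.5050505

d1 <- project_dos_1d(dos, eps_st = -2)
tr <- classify_transitions(inverse_temperature_U(d1, smooth_bins = 2),
                           min_prominence = 0.05)
tr[order(-tr$peak_height), c("U_star", "T_star", "order")][1:2, ]
#>   U_star    T_star  order
#> 2    -31 4.6748702  first
#> 1   -142 0.5097705 second
```

`U_mean` is the canonical mean conformational energy (units of |ε_ff|) and
`CV` the heat capacity from the fluctuation formula.  This short stiff
chain is already collapsed at T = 2; the two `CV(T)` maxima (T ≈ 0.89 and
T ≈ 0.51) flag successive ordering/freezing rearrangements of the globule,
and the microcanonical analysis locates the high-temperature collapse at
T* ≈ 4.7 (first-order-like backbending, too weak to register in `CV`) plus
the freezing point at T* ≈ 0.51, consistent with the canonical maximum
there.  A run of this length carries a few percent statistical error on
log g (see the `log_g_sd` column of the averaged table).

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/sfcopoly.R refine --N 16 --b 4 --preset S-attract \
        --mcs 100000 --seed 1 --out dos
Rscript inst/cli/sfcopoly.R micro --dos dos.tsv --eps-st -2 --out micro
Rscript inst/cli/sfcopoly.R oracle
```

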