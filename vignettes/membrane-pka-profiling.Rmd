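---
title: "Insertion-resolved pKa profiling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Insertion-resolved pKa profiling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Lysosomotropic drugs are hydrophobic weak bases. Which protonation state
they occupy — and therefore whether they can cross or lodge in a lipid
bilayer — depends not only on pH but on *where* the titrable amine sits
relative to the membrane: desolvation deep in the bilayer stabilises the
neutral species and can pull the amine's pKa several units below its
water-phase value. Constant-pH molecular dynamics (CpHMD) with a pH
replica-exchange (pHRE) ladder samples exactly this coupling, producing
trajectories in which both the protonation state and the position of the
titrable group fluctuate under an imposed pH.

`memtitrate` implements the post-processing that turns such trajectories
into *insertion-resolved titration curves*: a signed depth coordinate for
the titrable group, depth-binned protonation averages with quality gating,
per-bin Henderson–Hasselbalch (HH) fits giving a pKa profile along the
membrane normal, and Bayesian-bootstrap standard errors. Because real
CpHMD data are expensive and not deposited in a reusable form, the package
also contains a desk-scale constant-pH Monte-Carlo sampler with an
*analytically known* depth-dependent pKa, used to validate every stage of
the analysis end to end.

## The insertion coordinate

For each frame the titrable group at `(x, y, z)` is referenced to the
*local* phosphate plane of its own leaflet: the mean z of all
phosphate-group atoms (phosphorus and oxygen) lying within a 6 Å lateral
radius of the group, computed with the minimum-image convention in x/y.
If fewer than 10 atoms fall inside the radius, the 10 laterally closest
atoms are used instead (distance ties broken by `atom_id` so output is
deterministic) and the record is flagged. The signed depth is

    d = ref_z − z   (upper leaflet; mirrored for the lower),

so positive `d` is membrane-internal. Using only nearby lipids makes the
reference robust to membrane deformations; using the titrable group rather
than the whole molecule matters because only that group senses pH.

Design choices the prescription leaves open, and how they are resolved
here: lateral distances are periodic (membranes are simulated under
periodic boundaries); when the 6 Å search succeeds, *all* in-radius atoms
are averaged (no cap); the reference uses only the ligand-side leaflet,
because ligands never cross the midplane in these data and mixing leaflets
would corrupt the reference.

## Binning, gating, and the HH fit

Post-burn-in records are assigned to half-open 1 Å bins `[d_lo, d_hi)`
(width configurable; nothing in the method fixes it, and 1 Å resolves the
profile without starving bins). Within a bin, each (pH, replicate) cell
keeps its mean protonation and frame count. A bin enters the fitting stage
only if it holds

* two or more distinct pH values,
* from two or more distinct replicates, and
* pooled per-pH protonation that does not increase with pH
  ("must decrease" is read as non-increasing: ties pass, with an optional
  tolerance for small rises).

Failing bins carry the statuses `insufficient_pH`,
`insufficient_replicates` or `non_monotonic` and never contribute a pKa.
Pooling weighs replicates equally (a replicate's mean counts once however
many frames it contributed), which matches averaging "average protonation
values" across replicates; frame-weighted pooling is available behind the
`weights = "frame"` flag. The protonation error bar is the standard error
of the mean across replicate means.

The titration model is the Henderson–Hasselbalch equation with a fixed
Hill coefficient of one,

    prot(pH) = 1 / (1 + 10^(pH − pKa)),

fitted by least squares in its single parameter. Numerically, the squared
loss is scanned on a 0.05-unit grid over `[min(pH) − 5, max(pH) + 5]` and
the best grid point is refined with golden-section search to 1e-9; the
coarse scan plays the role of the midpoint-crossing initial guess and
makes the 1-parameter fit immune to local minima. A single point with
protonation strictly inside (0, 1) is solved in closed form. An estimate
pinned to a search boundary (e.g. an all-zero curve) is reported as
`fit_failed`, not as a number.

## Bayesian-bootstrap errors

Per ok bin, the resampling unit is the per-(pH, replicate) mean-protonation
cell — the plain reading of bootstrapping "average protonation samples".
Each of the (default) 1000 bootstraps draws Dirichlet(1, …, 1) weights over
the cells, forms weighted per-pH means, re-applies the monotonicity gate
(coverage gates are unaffected by strictly positive weights), refits the
HH equation and keeps the estimate; the reported error is the standard
deviation of the retained estimates, with dropped bootstraps counted. The
continuous weights avoid the degenerate resamples that break discrete
bootstrapping when a pH level has few replicates. The alternative reading
(resampling per-frame states) would shrink the error by roughly the
within-replicate correlation factor; it was not adopted because the
replicate mean is the natural exchangeable unit in replicated pHRE data.

## The validating sampler

The simulator is deliberately not an MD engine. It is a Metropolis
Monte-Carlo walker per replica in reduced units (kT = 1, one step = one
nominal ps, so the default 20-step exchange and titration periods mirror
attempts every 20 ps), with three coupled moves:

* a joint lateral + normal Gaussian displacement accepted against the
  state's membrane potential evaluated at the analytic local surface;
* a titration flip accepted with
  `min(1, exp(−ΔU) · 10^(Δs (pKa_water − pH)))`, whose fixed-depth
  stationary law is exactly HH at `pKa_true(d)`;
* pH swaps between ladder-adjacent replicas, alternating odd/even pairs,
  accepted with `min(1, 10^(ΔpH · ΔN))` — the standard semi-grand-canonical
  pHRE criterion, with `N` the bound-proton count (here the protonation
  state, single site).

Each state's membrane interaction is a logistic insertion step
parameterised by `well_center`, `well_width`, `well_depth` and
`water_plateau`: energy goes from the water plateau to `−well_depth`
across the switch. With both states switching at the same place, the
ground truth

    pKa_true(d) = pKa_water + (U_neutral(d) − U_protonated(d)) / ln 10

is a single monotone non-increasing sigmoid from `pKa_water` down to a
configured maximal shift (default 3.5 units, inside the 3–4-unit band
such membranes produce). On top of the state-specific steps both states
share an interface attraction (a 2 kT Gaussian well at d = 3 Å emulating
headgroup electrostatics) and two soft exponential confinement walls (at
d = 13 Å, standing in for the bilayer midplane that ligands do not cross,
and at d = −7 Å on the water side). Shared terms cancel *exactly* in the
two-state difference — the code computes state differences from the
state-dependent parts alone, so the ground truth is immune to the
floating-point cancellation the huge wall terms would otherwise cause.
A Gaussian-well parameterisation of the protonated state was rejected
because an interface-centred protonated well necessarily makes the pKa
profile rise before it falls; the shared-interface-well construction keeps
the species' preferred depths (protonated ≈ 3 Å, neutral ≈ 10 Å below the
phosphate plane) while preserving a monotone ground truth.

The synthetic membrane is a geometric stand-in for a 128-lipid bilayer:
64 lattice sites per leaflet in a 62 × 62 Å box, each contributing one P
and three O atoms clustered within 1.5 Å, on a sinusoidally deformed
surface (amplitude 1.5 Å, wavelength 31 Å — commensurate with the box, as
periodicity requires) plus 0.4 Å Gaussian jitter. The deformation
exercises the local-reference rule; the generation parameters are stored
as snapshot metadata so tests can compare pipeline depths against the
analytic surface. At this density the 6 Å search usually yields fewer
than 10 atoms, so the closest-10 fallback is exercised constantly — by
construction, not by accident.

What the generator does *not* emulate: atomistic lipid dynamics and
chemistry, explicit solvent, continuum-electrostatics protonation
energetics, multi-site titration, conformational kinetics (the kinetic
trapping that makes polar drugs slow to insert), or the pKa upsurge at
the membrane surface that stabilised cations show before the desolvation
drop. Passing tests therefore demonstrate that the *analysis* is correct
and well-calibrated on data whose ground truth is known — not that any
specific drug's profile is reproduced, which would require the original
atomistic simulations.

## Default study conditions and problem sizes

The default configuration is 5 replicates × 4 pH replicas × 2·10^5 steps
(the 4-rung, 1.0-unit ladder at pH 7–10 mirrors the range used for
tricyclic-type weak bases with `pKa_water = 9`), with the first half of
every series discarded as equilibration — the analogue of discarding
100 ns of a 200 ns run. Validation checks in the test suite that need
only qualitative behaviour use shorter runs (10^3–10^5 steps); the
stationarity and profile-recovery checks use the full default. Diagnostic
histograms are compared on frames subsampled every 1000 steps, several
times the measured ~190-step depth autocorrelation time, so multinomial
standard errors apply; the water-side pKa is read off the best-sampled
bin entirely in the water phase (centre ≤ −2 Å, where the residual
ground-truth shift is below 0.02 units) rather than the sparse extreme
tail bin.

## Degenerate inputs and edge rules

* A ligand exactly at the bilayer midplane goes to the upper leaflet,
  with a crossing warning.
* A leaflet with fewer than 10 phosphate-group atoms is a data error, not
  a silent fallback.
* `n_steps = 0` yields a valid empty trajectory; empty frame tables
  round-trip through the native format.
* Native-format numbers are serialised with six decimals; "lossless
  round trip" means exact at that precision (10^-6 of the stored units).
* All-protonated or all-neutral curves cannot constrain a pKa and are
  reported as `fit_failed`; a bin whose every bootstrap fails the gates
  raises an explicit "not bootstrappable" error.
* Reproducibility: one base seed fans out to membrane construction,
  per-replicate simulation streams (seeded by `(seed, replicate_id)`),
  and per-bin bootstrap streams; identical `(config, seed)` give
  byte-identical outputs, and the C++ sampler uses hand-written
  uniform/Box–Muller transforms so streams do not depend on the C++
  standard library's distribution implementations.

## Worked example

```{r}
library(memtitrate)

cfg <- sim_config(n_steps = 50000L)        # demo scale
bundle <- run_simulation(cfg)              # synthetic pHRE trajectories
records <- compute_insertion(bundle)       # local-reference depths
profiles <- build_profiles(records, config = cfg)

profiles$pka_profile                       # pKa ± bootstrap SE per bin
true_pka(profiles$pka_profile$d_center, cfg)  # analytic ground truth
plot_pka_profile(profiles, pka_water = cfg$pka_water)
```

The same chain, staged through files with a manifest, is
`run_pipeline(cfg, "out/", seed = 1)`; the scripts under `analysis/`
drive it step by step and narrate what each stage finds.

## Morphometry

The lysosome module is intentionally tiny: given per-condition imaging
summaries (lysosomes per cell, mean lysosomal area in µm²) it derives the
spherical radius from `A = πr²`, the volume `V = 4/3 πr³` (equivalently
`V = (4/3) A^{3/2} / √π`), the total cellular lysosomal volume
(volume × count), and fold changes versus a control condition. Whether
the area fed in is a mean or a median is the caller's labelling choice;
the module does not re-aggregate field-level data, which come from
instrument software. Statistical testing between conditions is out of
scope.

## Known limitations

* The sampler's single collective coordinate cannot reproduce kinetic
  phenomena (insertion barriers, slow equilibration of polar compounds).
* The monotone ground truth omits the near-surface pKa upsurge of real
  cationic amphiphiles; the profiler itself is agnostic, but the bundled
  validation never exercises a non-monotone truth.
* The quality gates assume a monoprotic base; multi-site or anionic
  titration would need a different monotonicity convention and HH form.
* Fixed-column structure-file reading covers the GROMACS coordinate
  format only, and the phosphate atom-name list is force-field specific —
  it must be supplied by the user for real data.
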