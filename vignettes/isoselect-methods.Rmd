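---
title: "Selecting and merging partial microcrystal datasets: methods and design"
author: "isoselect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting and merging partial microcrystal datasets: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoselect)
```

## The problem

In situ serial synchrotron crystallography measures short rotation wedges
(10--140 degrees) from hundreds to thousands of microcrystals. Each crystal
yields a partial, weakly exposed dataset; none is sufficient alone. Phasing —
especially from weak anomalous signals such as native sulfur — depends on
merging many of them, and the merged data are only as good as the subset
chosen: non-isomorphous crystals (different packing, perturbed coordinates)
poison the average, while weak but isomorphous crystals still contribute
signal. `isoselect` implements the selection-and-merging core of that
workflow, plus a structure-factor simulator that makes every stage testable
without beamline data.

## Data model and geometry

Observations are unmerged rows `(h, k, l, I, sigma(I))` per crystal
(`xtal_dataset`), with the unit cell and the point group of the space group.
Resolution comes from the reciprocal metric tensor; we use
`s = sin(theta)/lambda = 1/(2d)` throughout, so every B factor acts on
intensity as `exp(-2 B s^2)`. Only the rotational part of the symmetry is
represented (presets "1", "2", "222"): translations do not move intensities,
and systematic absences belong to the integration stage upstream. The
canonical unique-reflection key is the lexicographically greatest index
triple over the symmetry orbit (including negation when Friedel mates are
merged) — any stable convention works; this one is reproducible and
group-agnostic. Resolution shells default to 10 equal-volume bins (uniform
in `1/d^3`), the scheme scaling programs commonly use; an equal-count scheme
is available when shell populations must match exactly.

## Scaling and merging

Each dataset is related to the running merged reference by a linear scale
and a relative B factor, `I_d(h) ~ k exp(-2 B s^2) I_ref(h)`, fitted by
least squares on `ln(I_d/I_ref)` over reflections stronger than 3 sigma in
both; with fewer than ten strong pairs the B factor is fixed at zero and
only `k` is fitted. The first dataset in presort order seeds the reference
frame with unit scale; each subsequent dataset is scaled against the running
reference and folded in. Merging combines observations per unique key by the
inverse-variance weighted mean with `sigma = (sum 1/sigma_i^2)^(-1/2)`.
Reflections whose merged intensity is negative are retained — truncating
them would bias every downstream intensity statistic.

Quality statistics follow the standard definitions: `R_meas` with the
`sqrt(n/(n-1))` multiplicity correction, `R_pim` with `sqrt(1/(n-1))`, CC1/2
as the Pearson correlation between two seeded random half-splits of each
reflection's observations (we use the definitional split, not the
sigma-tau analytic form; the seed is exposed so results are reproducible),
mean I/sigma on merged entries, and completeness against an exact
theoretical key count obtained by enumerating the full index sphere and
mapping it to the asymmetric unit. Whether Friedel mates count separately in
completeness is a convention choice; both are available via the `anomalous`
flag. Statistics undefined in a shell are reported as `NA`, never as zero.

The two-term error model behind ISa is
`Var(I) = a (sigma_0^2 + b I^2)`: `a` inflates the integration-stage sigmas
and `b` is the fractional systematic error that survives averaging. The
asymptotic signal-to-noise of an infinitely strong reflection is
`ISa = 1/sqrt(a b)`. We fit it by regressing, across intensity bins of
replicate groups, the sample variance on the group-mean `sigma_0^2` and
squared mean intensity; a fit with non-positive coefficients is flagged as
failed rather than silently passed, and such datasets are simply not
ISa-filtered.

## Dataset selection

The pipeline is: (1) optionally drop datasets with ISa below a floor;
(2) presort all datasets ascending by the average of their internal R_meas
over the three lowest-resolution shells (Friedel mates count as equivalents
here — a partial wedge has few other mates), so the cleanest data seed the
reference; datasets with fewer than 20 replicate groups in those shells are
unrankable and go to the back of the queue, flagged; (3) scale and merge
everything into a preliminary reference; (4) compute, for every candidate, a
leave-one-out CC_dataset: the dataset's merged intensities against the
reference built from everyone else, per resolution shell. With few datasets
self-correlation materially inflates CC, so the leave-one-out form is the
statistically safe reading. (5) Reject candidates below the threshold in the
decision shell; (6) re-merge and repeat until membership stops changing.
Datasets rejected by CC are re-evaluated every iteration and may re-enter as
the reference improves — this makes the fixed point order-independent;
unscalable and ISa-rejected datasets never return. A CC exactly at the
threshold is kept. If a step would leave fewer survivors than `min_kept`,
the last valid membership is returned with a warning flag. Selection
statistics are computed Friedel-merged; the `anomalous` flag controls only
the final output.

Three decisions here are genuinely open and exposed as configuration:

* **Decision shell.** Default: the second-lowest of ten equal-volume shells.
  The lowest shell can be dominated by a handful of very strong reflections;
  high-resolution shells are noise-dominated. For small ensembles (few
  pairs per shell) a mid-resolution shell, where coordinate non-isomorphism
  actually expresses itself, discriminates better — the per-shell pair
  counts in the `cc_dataset` output show when that is the case.
* **Threshold.** A fixed number is the baseline behaviour (default 0.5),
  but realistic CC_dataset values crowd into 0.9--1.0, and the workable cutoff
  depends on noise level and contamination — which is why the original
  workflow chose it case by case. `cc_threshold = "auto"` automates that
  choice label-free: each iteration rejects robust outliers below
  `median(CC) - 3 * mad(CC)` (with a small MAD floor so homogeneous
  ensembles are not razor-cut).
* **Statistic.** Raw CC conflates weakness with non-isomorphism: a weak but
  isomorphous dataset has low CC purely from noise attenuation. The
  `"cc_norm"` statistic divides the observed CC by the attenuation implied
  by the paired sigmas (`sqrt((var - mean sigma^2)/var)` per side, floored
  at 5% of the total variance), scoring weak-but-isomorphous data near 1
  while genuine non-isomorphism stays low. This is what makes "reject
  non-isomorphous, retain weak but isomorphous" hold at desk scale; raw CC
  remains the default. When the decision shell's CC is undefined (under
  five pairs), the overall CC stands in.

Convergence is declared on identical membership, not on CC values.

## Anomalous signal

Friedel-separated merged sets yield a Bijvoet table
`d_anom = I(+h) - I(-h)` with propagated sigma; the amplitude-scale
difference `d_anom / (2 sqrt(I))` is carried as a derived column, but the
statistic itself stays on intensities to avoid negative-intensity
truncation. The feasibility estimate is the Hendrickson-style budget
`dF/F = sqrt(N_A/(2 N_T)) * 2 f''/Z_eff` with `Z_eff = 6.7` electrons (the
classic effective normal scattering per protein atom; overridable, since
the estimate is used qualitatively). A small static table ships approximate
`f''` values for S, Se, Hg and W at the four wavelengths relevant to the
supported experiments; near an edge the true value depends on the exact
energy, so override numerically for quantitative work.

Signal accumulation is checked two ways: a split-half correlation of
`d_anom` between two seeded halves of the ensemble (pure noise decorrelates;
genuine signal does not), and — in simulation, where truth is known — the
`1/sqrt(N)` decay of the merged Bijvoet-difference error with the number of
datasets. Full crystallographic `f'/f''`/coordinate refinement is out of
scope; its one-parameter analog, a weighted least-squares scale through the
origin between observed and calculated Bijvoet differences, estimates
`occupancy x (f''_true / f''_assumed)` — the quantity behind a partial
selenomethionine substitution fraction. The substitution percentage itself
is the ratio of refined to reference `f''`, reported to the nearest integer
percent.

## The simulator: what it emulates and what it does not

Ground truth is built from explicit atoms: `n_atoms` random carbon-like
light atoms plus an anomalous substructure, expanded over the point group,
with single-Gaussian form factors `f(s) = z exp(-2 s^2)` — only intensity
statistics matter here, and a Wilson-fit oracle verifies the B-factor
behavior this form implies. Complex structure factors are evaluated at `+h`
and `-h` for every unique key, so Friedel's law holds exactly when `f'' = 0`
and is broken exactly by the substructure when it does not.

Each simulated crystal draws `k ~ lognormal(0, scale_jitter)` and
`B ~ N(0, b_jitter)`, records a random `coverage` fraction of the unique
keys (both Friedel mates of every chosen key), and adds noise with variance
`sigma_floor^2 + alpha I + (gamma I)^2` while *reporting* only the first two
terms — the fractional error `gamma` is precisely what the ISa error model
must discover. The default noise targets a per-dataset mean I/sigma of 3
(the weak, native-SAD-like regime where selection matters most) with
`gamma = 0.03`, i.e. an ISa near 33 for an accurate integration stage.
Contaminants share one perturbed lattice per ensemble: every atom displaced
by a Gaussian of total RMS 0.5 Angstrom, which produces the
resolution-dependent intensity decorrelation that shell-wise CC selection
exploits. The default labelled ensemble is 40 isomorphous plus 10
contaminant crystals at coverage 0.2 on a (60, 70, 80) orthorhombic cell
with 400 light atoms and 8 anomalous sites (`f'' = 4`) to 2.5 Angstrom.

Deliberately *not* modelled: Ewald-sphere geometry and partiality (coverage
is an index subset, the wedge size is metadata only), detector effects, and
radiation damage. The selection statistics depend on coverage and error
structure, not on diffraction geometry — but it means passing tests say
nothing about partiality correction or dose-dependent scaling on real data,
and the 0.5 Angstrom perturbation is a stand-in for real non-isomorphism,
not a calibrated model of it.

## Numerical choices and test scale

Unique keys are encoded as exact doubles (indices to +/-511), so grouping
and matching are exact. Weighted merging, leave-one-out references
(maintained as per-key running sums) and CC computations are
permutation-invariant to 1e-10. Cells must agree within 1% per edge to
merge. Degenerate inputs fail loudly: sigma <= 0 rows name their line
number, empty shells report `NA`, unscalable datasets are excluded with a
reason rather than dropped silently.

The test and acceptance suites run on two problem sizes chosen to keep the
full suite in minutes on one CPU: a small toy (cell 30x35x40, 60 atoms, 4
anomalous sites, d_min 3, ~1000 unique keys) for oracles and properties,
and the default ensemble above (~12,000 keys, 50 crystals) for the
end-to-end selection recovery, which is scored as sensitivity/specificity
against the simulator's labels over repeated master seeds. Anomalous
recovery experiments (the sqrt(N) law; occupancy 0.59 recovery within
+/-0.05) use the small toy with noise set so the merged Bijvoet differences
sit near d/sigma of 2 — weak enough to be honest, strong enough to be
estimable.

## Known limitations

Point-group presets cover the triclinic, monoclinic and orthorhombic cases
the supported space groups need; other symmetries require supplying rotation
matrices explicitly. The error-model fit needs replicate observations
(multiplicity >= 2) inside each dataset — single-pass stills would need the
Friedel-mate replicates the simulator provides. The adaptive threshold
assumes contaminants are a minority (< 50%); a majority-contaminated
ensemble would need a fixed threshold chosen by inspecting the CC
distribution. R_iso compares amplitudes after clamping negative intensities
to zero, which slightly biases it for very weak data.
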