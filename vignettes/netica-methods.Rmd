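---
title: "Methods: group spatial ICA, cPPI and functional complexity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: group spatial ICA, cPPI and functional complexity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netica)
```

This vignette documents the models, numerical choices and design decisions
behind the package, in the spirit of a statistical methods section: what is
computed, under which assumptions, and where the genuinely open choices were
settled.

## The generative model behind the synthetic studies

The simulator treats the brain as `K` latent spatial networks on a voxel
grid. Network `k` has a spatial loading map `s_k` (a Gaussian blob
thresholded to a compact support), and a time course

```
tc_k(t) = Σ_c β_kc x_c(t)  +  Σ_{(i,j,c,γ): k ∈ {i,j}} γ x_c(t) η(t)  +  ε_k(t)
```

where `x_c` is the HRF-convolved regressor of condition `c`, `β` the
condition-beta matrix, `η` a shared latent Gaussian signal injected into
both members of a coupled pair and gated by the modulating condition's
regressor, and `ε` white noise. Voxel data are
`Y = Sᵀ TC + nuisance + noise + baseline` with a linear drift, six AR(1)
"motion-like" series, a global signal and AR CSF/WM/CompCor-like columns as
nuisance (these exact series are returned in the confound tables), a
baseline of 1000 so that percent-of-mean intensity normalization is well
posed, and i.i.d. Gaussian voxel noise of configurable `noise_sd`.

Three choices here are deliberate:

* **Thresholded blobs give super-Gaussian marginals.** Infomax with a
  logistic nonlinearity identifies super-Gaussian sources; sparse maps are
  both realistic for cortical networks and inside the algorithm's
  identifiability class. Gaussian-only sources are rotation-invariant, and
  `infomax_ica()` flags that case instead of pretending to resolve it.
* **Coupling as a gated shared signal.** Adding `γ·x_c(t)·η(t)` to both
  networks of a pair produces covariance between the two time courses that
  exists only when the modulating condition is active — exactly the
  structure a PPI interaction term is built to detect, with ground-truth
  sign and location known to the tests.
* **Identifiability needs as many independent drivers as networks.** If
  `K` networks are driven by fewer than `K` conditions, the time-course
  mixing matrix is rank deficient and no ICA can separate the maps. The
  recovery fixtures therefore use one dominant condition per network
  (diagonal-dominant `β`); this is a property of the model, not a
  convenience.

What the generator does **not** emulate: hemodynamic nonlinearity,
physiological noise spectra, slice timing, or motion as actual spatial
displacement. Tests passing on these simulations demonstrate the
correctness of the estimators under the stated model, not robustness to
every artifact of real acquisitions.

## The decomposition chain

`group_ica()` follows the standard group spatial ICA recipe:

1. **Intensity normalization** scales each voxel series to percent of its
   temporal mean (mean 100). Zero-mean voxels cannot be scaled and are
   dropped from the mask with a logged count.
2. **Session-level PCA** on the time dimension to `k_session` components,
   with projections, row means and retained variance recorded.
   `k_session` may be a number or `"mdl"`, in which case the
   Wax–Kailath minimum-description-length criterion is evaluated on the
   covariance eigenvalue spectrum with voxels as samples: code term
   `−n(T−k)·log(geometric/arithmetic mean of trailing eigenvalues)`,
   penalty `k(2T−k)·log(n)/2`. The criterion assumes i.i.d. samples; no
   autocorrelation subsampling correction is applied, a documented
   simplification.
3. **Concatenation and group PCA** to `k_group`, stacking session-reduced
   matrices along the reduced-time axis. Per-session reduction is the
   default; the ordering of reduction levels is configurable.
4. **Infomax** with the logistic nonlinearity and natural-gradient updates
   over randomly permuted sample blocks. The learning rate starts at
   `0.015/log(K)`, shrinks by 0.5% per pass, halves after an unstable pass,
   and iteration stops when the squared weight change per pass falls below
   `1e-6` or at 512 passes (then flagged). Sources are scaled to unit
   population variance.
5. **Stability** via multi-seed restarts: all runs' sources are pooled,
   clustered by `1 − |cor|` with average linkage into `K` clusters, and
   each cluster's centrotype becomes the consensus source. The quality
   index is mean within-cluster minus mean between-cluster similarity,
   clipped to [0, 1]. This simplifies the original bootstrap scheme to
   restart clustering, which preserves the stability contract at desk
   scale. Note that even identical runs give quality marginally below 1:
   the between-cluster similarity of distinct sources is small but not
   zero.
6. **GICA back-reconstruction.** With session projection `P_i`, group
   projection block `P_g^{(i)}` and group mixing `A = W⁻¹`, session maps
   solve `(P_g^{(i)} A) S_i = X_i` in least squares and session time
   courses are `P_i P_g^{(i)} A`, so `TC_i · S_i` reproduces the session's
   reduced data up to the discarded PCA variance.

Component order and sign are arbitrary in ICA; the package fixes both
deterministically (descending explained variance, ties by first-voxel sign
then index; each map flipped so its largest-|Z| voxel is positive). Maps
are Z-scored within component using the population (1/N) standard
deviation — this is the standardization of a fixed map, not a sampling
inference, so the sample correction would be wrong in spirit.

## Design matrices and temporal sorting

The HRF is the canonical double-gamma (response delay 6 s, undershoot delay
16 s, dispersions 1, ratio 1/6, 32 s support), peaking near 5 s. The
temporal derivative is a finite difference under a 1 s onset shift and the
dispersion derivative a finite difference in the dispersion parameter
(step 0.01). Condition boxcars are built at 16 bins per TR (onset precision
below TR), convolved, and decimated at scan times; zero-duration events
become unit impulses. Events overrunning the run end are clipped with a
warning rather than rejected.

Temporal sorting regresses each component time course on the full design by
OLS. The reference analysis prewhitened with an autoregressive covariance
dictionary; on white-noise simulations OLS is unbiased for the betas, and
the package's acceptance surface is beta recovery, not standard errors —
this substitution is deliberate and documented. Only canonical-basis
("primary") betas enter condition contrasts; derivatives absorb latency and
width misfit and are treated as nuisance. Contrasts are two-sided paired
t-tests across subjects on session-averaged betas, Bonferroni-corrected for
the family size (66 = 11 components × 6 contrasts at study scale). With
only two subjects the pipeline still runs end to end — the t-tests then
have a single degree of freedom and a warning says so.

## Overlap maps

Group component maps are one-sided (positive) one-sample t-tests across
subject-averaged maps, thresholded by Benjamini–Hochberg FDR at q = 0.05
over in-mask voxels per component map, then cluster-filtered at a 20-voxel
minimum under face (6-)adjacency; 18- and 26-connectivity are available
because tool defaults in the field differ. Participation maps are voxel-wise
integer sums of the binarized maps of networks that are significantly
activating (positive contrast) or deactivating (negative) for a task.

## cPPI

For each unordered network pair the PPI terms are element-wise products of
the mean-centered time course and the mean-centered psychological contrast
(target minus control, HRF-convolved). The partial correlation controls for
all design columns, all confound columns, and the `K − 2` remaining network
time courses; sessions are concatenated beforehand. No hemodynamic
deconvolution is applied before forming the products: the component time
courses are latent network signals and the correlational PPI formulation
operates on observed series; a deconvolution hook exists in concept but is
off by default.

Group inference per pair is a one-sample t-test across subjects on
Fisher-z-transformed correlations (variance stabilization; the transform
choice is the package's, as the reference leaves it unstated), with
Bonferroni correction across the three task contrasts. Reported means and
SDs are of raw `r`. Cross-task comparison is a within-subject one-factor
ANOVA per pair (numerator df = #tasks − 1 = 2), Bonferroni over the 55
pairs, with post-hoc paired t-tests at p < 0.05 feeding the task-difference
edge lists.

**Calibration.** The per-subject parametric p-value attached to a PPI-term
partial correlation is anticonservative by construction: both products
share the psychological factor, so the product series are heteroscedastic
and the effective sample size is below `T` (by roughly the kurtosis ratio
of the psychological regressor — a factor ~2 for realistic event designs).
This is why inference is done at the group level, where the across-subject
t-test is calibrated under the null by symmetry: `cppi_null_rejection_rate()`
measures a type-I rate of ~0.05 at the nominal 0.05 over 1000 null
replicates. Per-subject p-values are reported for display scaling only.

## Functional complexity

Positive off-diagonal partial correlations are binned into `m` equal-width
bins **fixed to [0, 1]** — not the data min–max — so the statistic is
comparable across subjects and tasks; this is the main free choice in the
measure and the main obstacle to exactly reproducing any published mean, so
it is configurable. Bins are left-closed/right-open with the last bin
closed (a value of exactly 1 lands in bin `m`). The normalization
`C_m = 2(m−1)/m` is the maximal attainable total deviation from uniformity,
which forces `C = 0` for a one-bin distribution and `C = 1` for exact
uniformity. `C` is averaged over bin counts {10, 15, 20, 25, 30, 35, 40}.

Cross-task comparisons of complexity (and of response times, the behavioral
complexity proxy) are paired t-tests, one-sided by default with the
lower-tail convention `p = P(T ≤ t)`: the reported statistic/p pairs in the
motivating analysis match one-tailed, not two-tailed, areas, and the
package's `t_to_p()` reproduces those mappings to better than 1%.

## Pipeline, seeds and problem sizes

`run_pipeline()` executes simulate → design → ICA → label → activity →
overlap → cPPI → complexity, validates the configuration against a schema
first, writes every artifact with an MD5 manifest, and derives each stage's
seed from the master seed by a stable integer hash (`derive_seed()`), so
stages are independently reproducible and a rerun is byte-identical.

The shipped defaults mirror the reference analysis where a value exists —
FDR q = 0.05, 20-voxel clusters, 20% template threshold, Bonferroni
families 66/55/3, bin counts 10–40, TR 0.5 s, Icasso 50 restarts at study
scale — and desk-scale sizes elsewhere: 20 × 20 × 10 grids, 2–5 subjects,
1–2 sessions, ~500 time points, 5 Icasso restarts. At these sizes the full
pipeline runs in well under a minute and the complete verification suite in
a few minutes on one CPU. The study-scale geometry (49 components, 22
subjects × 12 runs, ~1300 time points per run) is configuration, not code.

## Known limitations

* OLS temporal sorting ignores temporal autocorrelation; standard errors of
  single-subject betas are optimistic (group inference is unaffected in the
  balanced designs used here).
* The MDL order estimate inherits the i.i.d.-sample assumption and will
  overestimate on strongly autocorrelated data.
* Noise-component flagging is a heuristic stand-in for expert visual
  inspection; a manual override file is the authoritative path.
* The synthetic generator's effect sizes for condition-modulated coupling
  are free parameters — no published calibration of cPPI effect sizes
  exists to anchor them — so detection-power results on simulations should
  be read qualitatively.
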