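---
title: "Modelling brain-state dynamics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling brain-state dynamics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`statedyn` analyses the temporal dynamics of large-scale brain networks in
neurodegenerative cohorts. This vignette documents the statistical model,
the parameters that matter, what the synthetic-cohort generator does and
does not emulate, and the numerical and design decisions a maintainer should
know about.

## The model

The input to the pipeline is one matrix per scan of ICA component time
courses (T volumes × C components, in arbitrary signal units) plus cohort
metadata. Each scan is standardized column-wise (mean 0, SD 1 within scan),
and all scans are temporally concatenated. A K-state hidden Markov model
with multivariate Gaussian emissions is then fitted at the group level:

* hidden states follow a first-order Markov chain with initial distribution
  π and row-stochastic transition matrix A;
* observations in state *k* are drawn from N(μₖ, Σ) with **one covariance
  matrix Σ shared by all states**, so states are distinguished by their mean
  activation pattern only. This keeps the state definition interpretable as
  "which networks are up- or down-regulated" and sharply reduces the
  parameter count relative to per-state covariances.

Estimation is maximum-likelihood EM (Baum–Welch). The E-step runs scaled
forward–backward recursions per scan (restarting at scan boundaries so no
transitions are modelled across subjects); the M-step re-estimates π from
scan-initial posteriors, A from pooled expected transition counts, μₖ from
posterior-weighted means, and Σ pooled over states:
Σ = (1/T)·Σₜ Σₖ γₜₖ (xₜ−μₖ)(xₜ−μₖ)ᵀ. A deliberate design decision is to use
plain EM rather than the variational-Bayes scheme of the established HMM
toolboxes: the package's downstream quantities depend only on γ, ξ and A,
EM is fully specified by the likelihood, and its monotonicity gives a sharp
internal correctness check (the log-likelihood trace is asserted
non-decreasing in the tests).

Because state labels are arbitrary, all comparisons across runs or against
a simulation ground truth first align states with the Hungarian algorithm on
Euclidean distances between state means (`match_states()`).

### Temporal-dynamics metrics

All metrics are computed from the *soft* posteriors (γ, ξ), not hard state
assignments; a Viterbi-based alternative is available behind
`method = "viterbi"` in `compute_metrics()` for sensitivity analyses.
Fractional occupancy is the mean of γ over time; the switching rate divides
the expected off-diagonal transition mass by (T−1)·TR seconds, so scans
acquired at different repetition times are directly comparable — the TR
adjustment is an exact division, not a rescaling to a reference TR. The
per-subject transition matrix row-normalizes ξ; a state that a subject's
posterior never leaves from (zero expected outgoing mass) cannot be
normalized, and that row is taken from the group model and flagged rather
than invented.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| K (`n_states`) | 6 | states | standard model order for interpretable whole-brain dynamics |
| EM restarts | 5 | – | k-means initialization is local; restarts guard against poor optima |
| EM tolerance | 1e-5 | relative log-likelihood | past this, metric changes are far below sampling noise |
| ridge | 1e-6·tr(Σ)/C | signal² | keeps Σ invertible on degenerate posteriors |
| PCA α | 1 | – | linear case of the α-transformation; zero-safe on observed compositions |
| permutations | 5000 | – | FWE p resolution 1/5001 |
| FDR / FWE levels | 0.05 | – | conventional |
| QC bounds | placeholders | %, mm, signal units | study-specific published thresholds should be supplied; mean-FD filtering is off by default (sensitivity re-run only) |

## Compositional PCA

Fractional occupancies sum to one, so Euclidean PCA on raw occupancies is
ill-posed. The α-transformation maps each composition through a power
transform and an orthonormal Helmert sub-basis (rows sum to zero,
HHᵀ = I); at α = 1 the map is linear, z = H(Kx − 1), and the uniform
composition maps exactly to the origin. PCA is run on the centered
coordinates; the number of retained components is chosen by MacArthur's
broken-stick criterion (the longest leading run of eigenvalue proportions
exceeding the stick expectations). Two edge conventions are fixed by design:

* if no component beats its stick expectation, **one component is retained
  anyway** and flagged — downstream models need at least one score, and the
  first component is still the best single axis;
* varimax rotation is applied to the retained loadings (identity when one
  component is retained), with Kaiser normalization off by default; rotated
  scores feed all later models. Scores are computed in transform space;
  loadings are mapped back to state space through Hᵀ for display only.
* component signs are fixed so the largest-magnitude state loading is
  positive, making scores reproducible across runs.

## Cross-sectional inference

Group contrasts on metrics use `metric ~ group + age + sex + (1 | site)`
with Satterthwaite denominator degrees of freedom, falling back to (or
explicitly requesting) a fixed-effects ANCOVA when only one site exists.
Age curvature is tested on orthogonal polynomials with maximum-likelihood
fits compared by likelihood ratio and AIC.

The K² transition/persistence probabilities are interdependent, so group
differences are tested jointly by a max-statistic permutation test: age and
sex are handled by the Freedman–Lane scheme (permute residuals of the
covariates-only model, re-attach the reduced fit, refit the full model), and
the null distribution of the maximum |t| over all cells provides
family-wise-error-corrected p values covering both contrast directions.
p values use the +1 smoothing, so their floor is 1/(n_perm+1). When no
covariates are supplied and the number of distinct group-label splits is at
most `n_perm`, the exact distribution is enumerated instead (and flagged).
Permutations are unrestricted by default; an exchangeability-block argument
restricts them (e.g. within site) when desired. With estimated nuisance
covariates Freedman–Lane is exact only asymptotically; the null calibration
measured in the acceptance suite (200 cohorts × 500 permutations) is the
empirical check that the realized family-wise error sits at its nominal 5%.

## Two-step longitudinal prediction

Stage one fits `score ~ time + (time | subject)` across all retained
participants of the modelled sample; each subject's annual slope is the
fixed slope plus the conditional (shrunken) random-slope prediction. This is
a deliberate reading of the random-slope notation: shrinkage toward the
population slope is inherent to the mixed model, and subjects with a single
visit receive the population slope (maximally shrunk) rather than being
dropped. A singular random-effect covariance triggers a refit with
independent random effects. Subjects at an outcome's floor (or ceiling, for
timed tests) at baseline are removed for that outcome only before fitting.

Stage two regresses slopes on baseline component scores with baseline age,
sex and site as covariates of no interest. Site enters as a fixed
categorical covariate at this stage (a choice; single-site samples drop it
silently). All continuous variables are z-scored within the modelled sample
so reported betas are standardized. Three model forms are provided: score
main effect, score×age, and score×age×group, the last two reporting the
interaction as the headline term. "Baseline" scores come from each
subject's earliest scan passing motion QC (`select_analysis_scan(...,
"earliest")`); cross-sectional analyses use the latest passing scan, with
ties broken by larger volume count then lexicographic scan id. Motion QC
itself excludes a scan iff any active index *strictly* exceeds its bound
(boundary scans are kept).

## The synthetic cohort generator

`simulate_cohort()` generates everything the pipeline consumes: a
ground-truth HMM, per-subject state paths and emission time courses, cohort
metadata (ages, sex, sites with different repetition times, mutation
labels), motion indices with a configurable fraction exceeding QC bounds,
and annual-visit cognitive scores. Its defaults are the study conditions the
validation suite runs under:

* group sizes 120/120/60 (non-carrier / presymptomatic / symptomatic) with
  14 converters among the presymptomatic group; symptomatic subjects older
  (63 ± 8.2 y) than presymptomatic (45 ± 12) and non-carriers (48 ± 13), so
  age-confounding behaviour is testable;
* K = 6 states over C = 24 channels, T = 300 volumes per scan, five sites
  with TR between 2.2 and 2.5 s;
* baseline persistence 0.55, i.e. mean state dwell ≈ 2.2 volumes (≈ 5 s at
  TR 2.2 s), at the faster end of reported resting-state dwell times. This
  value was fixed by a design-stage power analysis: occupancy estimates from
  a T = 300 scan become noisier as persistence grows (autocorrelation), and
  at persistence 0.55 the planted converter effect below is detectable with
  ~85% power at 14 vs 150 subjects, whereas slower dynamics would make that
  planted effect undetectable at the study's own sample sizes;
* the symptomatic group effect is a persistence increment of 0.1752 on the
  target state (state 2), chosen analytically so the state's stationary
  occupancy rises by 0.08 above the uniform 1/6; converters receive half the
  increment ("late presymptomatic" intermediate phenotype, a free parameter
  of the design, not an inference);
* annual cognitive decline of −1.5 points/year in symptomatic subjects, with
  the subject-level slope tied to true target-state occupancy deviation at
  −12 points/year per occupancy unit, between-subject slope SD 0.5 and
  visit noise SD 1 over 4 annual visits.

Group effects are planted *mechanistically* — through the transition matrix,
not by adding means to metrics — so the same planted cohort exercises the
occupancy, transition-matrix and longitudinal analyses coherently.

What the generator does **not** emulate: spatial structure (no images, maps
or ICA mixing), scanner physics and physiological noise, site effects beyond
repetition time, autocorrelated emission noise within states,
missing-visit patterns, and floor-censored score distributions (floors are
exercised with explicit fixtures instead). Passing tests therefore show that
the estimators and tests behave correctly for Markov-switching Gaussian
data under realistic group designs; they do not certify preprocessing or
ICA-level robustness on real scans.

## Numerical choices

* Forward–backward uses per-timepoint scaling with a rowwise max-shift of
  the log-densities, safe for T up to 10⁵; correctness is asserted against
  exhaustive path enumeration on all instances with K^T ≤ 4096.
* Emission densities use Cholesky solves; a singular shared covariance is a
  hard error advising more ridge regularization.
* k-means initialization, diagonal-0.9 transition start, uniform π, pooled
  covariance start; restarts are seeded from one user seed, so fits are
  bit-reproducible.
* The EM convergence test is relative log-likelihood change; non-convergence
  returns the model with a warning flag rather than failing.
* The pipeline writes plain-text tables with deterministic formatting and
  logs seeds and a configuration hash (excluding file paths), so reruns with
  one seed are byte-identical — wall-clock times are deliberately kept out
  of result files.

## Validation problem sizes

The acceptance suite runs the forward–backward oracle on all K^T ≤ 4096
cases sampled over K ∈ {2,…,6}; parameter recovery on 30 scans × 300
volumes (K = 4, C = 8, persistence 0.85, mean separation 2 z-units);
permutation-test calibration on 200 null cohorts of 30 subjects × 500
permutations; symptomatic-effect power on 50 replicates at 50 subjects per
group; converter power on 200 replicates at 14 vs 150; and the
score-to-slope link on 50 replicates at the generator defaults. Power
replicates compute metrics from the generator's true state paths — the
separate recovery check establishes that fitted soft occupancies track true
occupancies (r > 0.95), so planting and detection are validated without
refitting an HMM hundreds of times.

## Known limitations

* The shared-covariance Gaussian HMM ignores within-state autocorrelation;
  states that differ mainly in spectral content will not be separated.
* Model order K is fixed by design, not selected from data.
* Freedman–Lane calibration is asymptotic in the presence of continuous
  covariates; very small groups should prefer the covariate-free exact
  enumeration.
* Stage-two standard errors treat stage-one slopes as known; shrinkage
  makes this conservative for extreme subjects but it is still a two-step
  approximation rather than a joint model.
* Scanner harmonization is limited to site intercepts (stage one random,
  stage two fixed); no ComBat-style harmonization is provided.
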