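# statedyn

Temporal dynamics of large-scale brain networks from resting-state fMRI
component time courses, for studies of frontotemporal dementia (FTD) and
other neurodegenerative cohorts with presymptomatic mutation carriers.

Resting brain activity can be described as a sequence of recurring network
*states*. `statedyn` implements the full analysis chain for testing whether
the temporal dynamics of those states differ between diagnostic groups and
predict later cognitive decline:

1. **Hidden Markov model.** A K-state multivariate Gaussian HMM (default
   K = 6) is fitted by Baum–Welch EM to temporally concatenated, per-scan
   standardized ICA component time courses, with one covariance matrix
   shared by all states: observation *x<sub>t</sub>* | state *k* ~
   N(μ<sub>k</sub>, Σ). Forward–backward recursions restart at scan
   boundaries, so no transitions are modelled across subjects.
2. **Temporal-dynamics metrics.** Per scan: fractional occupancy
   FO<sub>k</sub> = (1/T) Σ<sub>t</sub> γ<sub>tk</sub>, the TR-adjusted
   switching rate SR = Σ<sub>i≠j</sub> ξ<sub>ij</sub> / ((T−1)·TR) in s⁻¹,
   and the row-normalized K×K transition/persistence probability matrix.
   State activation maps are component maps weighted by the state means.
3. **Compositional PCA.** Occupancies live on a simplex; they are mapped
   through the α-transformation (α = 1, z = H(Kx − 1) with an orthonormal
   Helmert basis H), reduced by PCA, the number of components chosen by the
   broken-stick criterion, and varimax-rotated.
4. **Group inference.** Mixed-effects models (site random intercept,
   Satterthwaite degrees of freedom) or fixed-effects ANCOVA for group
   contrasts on occupancies, switching rates and component scores;
   quadratic-age model comparison and group-by-age interactions on
   orthogonal polynomials; a max-statistic permutation test with
   Freedman–Lane nuisance handling for the K² transition/persistence
   probabilities (family-wise error control across all cells and both
   directions); Benjamini–Hochberg FDR elsewhere.
5. **Two-step longitudinal prediction.** Stage one estimates per-subject
   annual rates of cognitive change from `score ~ time + (time | subject)`;
   stage two regresses those (shrunken) slopes on baseline component scores
   with age, sex and site as covariates, optionally with score×age and
   score×age×group interactions, reporting standardized betas. Subjects at
   floor scores at baseline are removed per outcome first.

Because the motivating cohort data are not public, the package ships a
first-class synthetic-cohort generator (`cohort_spec()`, `simulate_cohort()`)
that plants known group effects — a persistence-probability increment on a
target state for symptomatic subjects (half dose for presymptomatic subjects
who later convert) and a link from true target-state occupancy to the annual
cognitive slope — so that every stage of the pipeline can be validated
end-to-end.

## Worked example

Simulate a cohort with a planted occupancy elevation in symptomatic
subjects, fit the HMM, and test per-state group differences:

```r
library(statedyn)
library(dplyr)

spec <- cohort_spec(group_sizes = c("non-carrier" = 30,
                                    "presymptomatic" = 30,
                                    "symptomatic" = 20),
                    n_converters = 5, n_channels = 8, t_per_scan = 200,
                    seed = 42)
sim <- simulate_cohort(spec)

std   <- lapply(sim$timecourses, standardize_timecourse)
st    <- concatenate_scans(std)
model <- fit_hmm(st$data, st$boundaries, K = 6, n_restarts = 2, seed = 42)
model
#> Gaussian HMM: 6 states, 8 channels, shared covariance
#> Persistence probabilities: 0.558 0.546 0.527 0.536 0.549 0.605
#> Fit: logLik -157617.72 after 9 EM iterations (converged)

# align fitted state labels with the generator's states, then tabulate
col_sd <- apply(do.call(rbind, sim$timecourses), 2, sd)
model  <- relabel_states(model,
            match_states(sweep(sim$truth$means, 2, col_sd, "/"),
                         model$means))
metrics <- compute_metrics(model, std,
                           setNames(sim$cohort$repetition_time,
                                    sim$cohort$scan_id))

d <- inner_join(metrics, sim$cohort, by = "scan_id")
res <- bind_rows(lapply(paste0("FO_", 1:6), function(m)
  mutate(fit_metric_model(d, m), metric = m, .before = 1)))
res$p_adjusted <- fdr_adjust(res$p_value)
res
#> # A tibble: 6 × 8
#>   metric effect statistic   df1   df2      p_value   p_adjusted effect_size
#> 1 FO_1   group      3.02      2  73.5 0.0549       0.110             0.0759
#> 2 FO_2   group     23.2       2  75.0 0.0000000146 0.0000000876      0.382
#> 3 FO_3   group      6.96      2  72.8 0.00172      0.00515           0.161
#> 4 FO_4   group      0.589     2  75.0 0.558        0.563             0.0155
#> 5 FO_5   group      2.24      2  75.0 0.114        0.171             0.0563
#> 6 FO_6   group      0.578     2  75.0 0.563        0.563             0.0152
```

State 2 is the generator's target state: its fractional occupancy is
elevated in symptomatic subjects (F = 23.2, FDR-adjusted p ≈ 9×10⁻⁸,
partial η² = 0.38), and the compensatory reduction appears in state 3. The
whole chain — QC, fit, metrics, PCA, cross-sectional statistics and
longitudinal prediction — can also be run in one call via
`run_pipeline(pipeline_config(...))` or the thin command-line driver in
`inst/scripts/statedyn-pipeline.R`.

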