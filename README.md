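# moleratdemog

Demographic inference for longitudinal capture–mark–recapture studies of
social mole-rats (and similar group-living species observed through
periodic trapping). Wild Damaraland mole-rat populations are sampled in
discrete "trapping windows" every 6–12 months, so survival, dispersal,
reproduction and growth are all seen as *panel data*: states and sizes at
irregular capture times, never the transitions themselves. This package
implements the four statistical analyses such a study needs, for field
ecologists and biostatisticians working with this kind of data:

1. **State-structured survivorship** — a continuous-time multi-state Markov
   model over female life-history states (natal non-breeder NB, single
   female SF, breeding female BF, disappeared GONE), with intensities
   `q_rs(z) = exp(theta_rs + beta_rs' z)` and likelihood built from
   `P(t) = exp(tQ)`. Hazard ratios, ratios of disappearance intensities,
   mean sojourn times `-1/q_rr` and state-specific survival
   `S_r(t) = 1 − P_{r,GONE}(t)` all come with delta-method 95% intervals,
   and model curves can be overlaid on empirical Kaplan–Meier estimates.
   A two-state preset estimates time to natal dispersal by sex.
2. **Early-life growth** — the von Bertalanffy interval equation
   `S2 = A' − (A' − S1) e^{−k'D}` with `A' = A + A_GS·GS_z + a_i`,
   `k' = k + k_GS·GS_z + k_i`, fitted as a nonlinear mixed model with
   independent individual random effects on asymptote and rate constant,
   integrated out by Laplace approximation.
3. **Within-group recruitment** — a Poisson GLMM for recruits per
   capture–recapture event with `log(D/182.5)` as exposure offset, group
   random intercepts (adaptive Gauss–Hermite), rainfall-covariate model
   comparison by AIC, and Welch's t-test for the experimental
   new-pair-versus-established-group contrast.
4. **Body-condition allometry** — standardised major axis regressions
   (slope `sign(r)·SD(y)/SD(x)`) of mass on skeletal size with seeded
   bootstrap intervals and a likelihood-based common-versus-separate
   allometry comparison.

A fifth component, the **individual-based simulator**
(`simulate_population()` and the direct generators `simulate_panels()`,
`simulate_growth_intervals()`, `simulate_recruitment_events()`), produces
capture datasets with the same structure and full ground truth, so every
stage of the pipeline is testable end to end without the field data.

## Worked example

```r
library(moleratdemog)

sim   <- simulate_population(study_scale_preset(seed = 1))
panel <- assign_female_states(sim$captures, sim$windows)
fit   <- fit_msm(panel, transition_structure())

qr <- qratio(fit, c(1, 4), c(2, 4))
sprintf("In-group non-breeders disappear %.2f [%.2f, %.2f] times faster than single females",
        qr$ratio, qr$lower, qr$upper)
#> "In-group non-breeders disappear 2.68 [1.58, 4.54] times faster than single females"

s <- vapply(1:3, function(k) survival_from_state(fit, k, 1)$survival, numeric(1))
sprintf("Annual survival: NB %.1f%%, SF %.1f%%, BF %.1f%%", 100*s[1], 100*s[2], 100*s[3])
#> "Annual survival: NB 61.3%, SF 82.0%, BF 83.4%"

so <- sojourn_time(fit, 1)
sprintf("Mean time in the natal non-breeder state: %.2f yr [%.2f, %.2f]",
        so$mean, so$lower, so$upper)
#> "Mean time in the natal non-breeder state: 1.20 yr [1.05, 1.37]"
```

The first line simulates seven years of trapping at the study's scale
(~750 unique individuals); the second converts raw captures into female
state panels, appending a disappearance row after two fully missed
trapping windows and a short right-censor row in the final window; the
third fits the four-state model by maximum likelihood. The printed ratio
says in-group non-breeders vanish from the population substantially faster
than single dispersed females (mostly mortality during later dispersal
attempts), the survival line gives each state's one-year survival from the
fitted intensity matrix, and the sojourn is the expected time a female
remains a natal non-breeder before dispersing, inheriting, or
disappearing.

## The analysis workflow

The numbered scripts under `analysis/` run the whole study pipeline on a
simulated population, writing tidy tables under `results/`:

```sh
Rscript analysis/01_simulate.R         # capture/window/rainfall CSVs + truth
Rscript analysis/02_prepare.R          # state panels, recruitment events, growth intervals
Rscript analysis/03_fit_msm.R          # survivorship + philopatry
Rscript analysis/04_fit_growth.R       # von Bertalanffy fits + predicted curves
Rscript analysis/05_fit_recruitment.R  # Poisson GLMM, rainfall AIC, pairing contrast
Rscript analysis/06_allometry.R        # SMA single vs in-group females
```

`reproduce_field_analysis(data_dir)` runs the same pipeline on the
deposited field dataset once it has been downloaded and mapped to the
package's input schema.

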