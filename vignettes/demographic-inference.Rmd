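---
title: "State-structured demographic inference for social mole-rat populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-structured demographic inference for social mole-rat populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(moleratdemog)
```

`moleratdemog` implements the statistical backbone of a longitudinal
capture-mark-recapture study of Damaraland mole-rats (*Fukomys damarensis*),
a cooperatively breeding subterranean rodent in which each group contains a
single breeding female. Groups are trapped periodically (every 6-12 months,
in "trapping windows"), so every process of interest — survival, dispersal,
recruitment, growth — is observed only at irregular discrete times. The
package provides four model families tailored to that observation scheme,
plus an individual-based generator that produces capture datasets with known
ground truth so every stage of the pipeline can be verified without the
field data.

This vignette documents the models and their assumptions, the tunable
parameters and the defaults chosen, the numerical strategies, and the known
limitations. Everything quantitative shown here is computed by the package's
tests, the numbered scripts under `analysis/`, or `scripts/acceptance.R`;
the vignette itself states no empirical number that those do not produce.

## 1. The four-state survivorship model

Female life histories are coded into four states: natal non-breeder (NB),
single dispersed female (SF), breeding female (BF) and disappeared/dead
(GONE). A continuous-time Markov chain on these states is observed as panel
data: we see the state only at capture times, never the transition times.
The allowed instantaneous transitions are NB→SF, NB→BF, SF→BF and each
live state →GONE; GONE is absorbing. Females that inherit the breeding
position in their natal group are pooled with those that acquire it after
dispersal (both are "breeding female"), which is why NB→BF is allowed.

Transition intensities are log-linear in covariates,
$q_{rs}(z) = \exp(\theta_{rs} + \beta_{rs}^\top z)$, with covariates held
piecewise-constant at their value at each interval's left endpoint. The
likelihood of one female is the product over consecutive observations of
$P_{s_i s_{i+1}}(\Delta t_i) = [\exp(\Delta t_i\,Q(z_i))]_{s_i s_{i+1}}$,
which integrates over all unobserved paths. The matrix exponential is
computed by Pade approximation with scaling and squaring (Armadillo's
`expmat`, shared between the likelihood kernel and `transition_matrix()`);
its correctness is checked against direct numerical integration of the
Kolmogorov forward equations $dP/dt = PQ$ and against the
Chapman-Kolmogorov identity, both to 1e-8.

Maximisation is quasi-Newton (BFGS) on the unconstrained
$(\theta, \beta)$ scale, relative function tolerance 1e-10 with one polish
restart, initialised at crude intensities (observed transition counts over
aggregate time at risk, with a +0.5 pseudo-count so unobserved transitions
start finite). Standard errors come from the inverse of a finite-difference
observed information matrix; when that matrix is singular the fit is
returned with standard errors flagged unavailable rather than failing.
Derived quantities use the delta method on the log scale: hazard ratios
$\exp(\beta \pm 1.96\,\mathrm{se})$, ratios of disappearance intensities
between states, and mean sojourn times $-1/q_{rr}$. Reported ratios and
survival curves are evaluated at covariate value 0, the sample mean on the
z-scored scale. Model-based survival from state $r$ is
$S_r(t) = 1 - P_{r,\mathrm{GONE}}(t)$, overlaid in the analysis scripts on
the empirical Kaplan-Meier estimate (via `survival::survfit`) of time from
state entry to observed disappearance.

**Disappearance and censoring rules.** A female unseen for at least two
consecutive trapping windows at her site contributes an extra GONE row at
the start of the first window following her last capture. Because GONE is
absorbing, a panel observation of GONE at that time has exactly the same
likelihood as an interval-censored statement "entered GONE at some point
before that time", so the panel representation already encodes the
inexactness of the disappearance time; no separate censoring machinery is
needed. A female captured in her site's final window is assumed alive to
that window's end and contributes a same-state row there (at most ~80 days
later). A design alternative — dating disappearance mid-interval — was
considered and rejected since, for an absorbing destination, it changes
nothing in the likelihood beyond relabelling the observation time; the
appended-time convention is the documented default.

**Philopatry preset.** The same machinery with two states (natal / left)
estimates time to departure from the natal group by sex. "Left" is defined
inclusively: first capture outside the natal group, or the disappearance row
when a resident vanishes for two windows. The inclusive definition was
chosen because departure and disappearance are confounded for animals that
die while dispersing; the exclusive definition (observed relocations only)
is recoverable by editing one helper and gives much longer sojourns, since
most dispersal attempts end unobserved.

## 2. Hierarchical von Bertalanffy interval growth

Ages are unknown in the wild, so growth is modelled on capture-recapture
intervals: size at recapture given size at capture,

$$S_2 = A' - (A' - S_1)\,e^{-k' D} + \varepsilon,\qquad
\varepsilon \sim N(0, \sigma^2),$$

with $A' = A + A_{GS}\,GS_z + a_i$ and $k' = k + k_{GS}\,GS_z + k_i$:
population asymptote $A$ (g or mm) and rate constant $k$ (per day; per year
in summaries), group-size effects per standard deviation of group size
(z-scored internally so $A$ and $k$ refer to the mean group size), and
independent zero-mean normal individual deviations on both parameters
(uncorrelated by construction, which stabilises estimation with few
intervals per animal). Intervals between 90 and 365 days qualify; female
body-mass records from the first known breeding capture onward are excluded
to remove pregnancy and status effects (incisor records are not, as
skeletal size is unaffected).

The marginal likelihood integrates the two deviations per individual by
Laplace approximation: a damped Gauss-Newton search finds each individual's
penalised mode (vectorised across individuals; every Newton solve is a
closed-form 2x2), and the Gauss-Newton Hessian supplies the determinant
term. The outer optimisation is BFGS over
$(A, \log k, A_{GS}, k_{GS}, \log sd_a, \log sd_k, \log\sigma)$ with
parameter scaling, started at $A_0 = 1.05\times$ the largest observed size,
$k_0$ from regressing the log remaining-gap decay on interval length,
and variances at 10% of the residual variance of that crude fit. A fitted
random-effect SD below 1e-3 of its natural scale triggers a refit with that
effect dropped (recorded in the fit object); with both dropped the
criterion is exactly nonlinear least squares, which is how the
least-squares collapse is verified to 1e-4. Note that the original field
analyses used first-order conditional linearisation (the `nlme` algorithm);
Laplace was chosen here for its likelihood interpretation, and the test
suite cross-checks the two fitters' fixed effects against each other on
simulated data — point estimates agree closely but not bit-for-bit, which
is why real-data reproduction targets carry a 10% relative tolerance.

Wald standard errors come from a finite-difference Hessian with steps on
the parameter scale (absolute steps would overwhelm $k_{GS}$, which is of
order 1e-4). Predicted trajectories from a 10 g pup — the average mass at
parturition — propagate the fixed-effect covariance through the gradient of
$S(t)$ for a delta-method band, at requested group sizes (4/12/20 in the
analysis script, spanning small to large groups).

## 3. Poisson recruitment with exposure offset

Recruitment events are pairs of captures of the same group 100-365 days
apart with the same resident breeding female, at least one large
(≥ 100 g) male retained, and both group captures complete. New individuals
at the recapture are recruits if strictly lighter than 100 g (males) or
80 g (females) — strict, because ties are not "lighter than" — otherwise
immigrants; the thresholds correspond to roughly one year of growth under
the fitted curves. Counts of recruits are modelled as Poisson with a log
link: fixed effects of group size at first capture, breeding-female mass
and rainfall (all z-scored), a random intercept per group, and
$\log(D/182.5)$ as a fixed offset so the intercept is the log 6-monthly
rate at mean covariates (6 months = 182.5 days). Estimation is adaptive
Gauss-Hermite quadrature via `lme4::glmer` (15 nodes by default — ample
for a single grouping factor; 1 node = Laplace is the speed switch used in
simulation loops), and the zero-variance limit (`random = FALSE`) is the
plain Poisson regression, verified against an independently coded IRLS to
1e-6.

Rainfall enters as the geometric mean of the 12 whole calendar months
preceding the first capture's month, with a +0.1 mm offset inside the log
so zero-rain months are defined (offset added before averaging, subtracted
from the result; configurable). Arithmetic-mean and total-rainfall variants
are compared by AIC over an identical event set. One consequence of
z-scoring worth knowing: with complete 12-month coverage the arithmetic
mean and the total are the same covariate after standardisation, so those
two variants tie exactly and the comparison is effectively geometric versus
arithmetic. The group-size x rainfall interaction is a separate fit, not a
nested selection. Two-sided Wald p-values are reported without multiplicity
correction. The experimental contrast — recruitment of newly created pairs
versus established groups over the same period, both standardised to
recruits per 182.5 days — uses Welch's unequal-variance t-test, with groups
that had a male removed excluded from the established stratum.

## 4. Standardised major axis allometry

Body condition is compared between single and in-group non-breeding
females through the allometry of body mass on skeletal size (incisor width
or body length). The SMA slope treats both variables symmetrically,
$b = \mathrm{sign}(r)\,\mathrm{SD}(y)/\mathrm{SD}(x)$, so it is invariant
to exchanging axes (up to reciprocal) and scale-equivariant. Confidence
intervals are percentile bootstrap over cases resampled within group
(B = 1000, seeded). Whether the two classes share one allometry is judged
by maximum likelihood under a bivariate-normal model: the common model
constrains both groups to one line ($\sigma_y = |b|\,\sigma_x$ and
$\mu_y = a + b\,\mu_x$, per-group means, scales and correlations otherwise
free), giving a likelihood-ratio statistic with 2 degrees of freedom for
two groups, and a small-sample-corrected AIC comparison. Both are reported
because the original model-comparison criterion is not fully specified;
AICc decides the headline "preferred" label since the LR test's 5% level
would reject a shared line for trivially small differences at large n.

## 5. The synthetic generator: what it emulates and what it does not

`simulate_population()` is an exact event-time (Gillespie) individual-based
simulation. All hazards are constant between events, so waiting times are
exponential with the summed rate and the event is chosen proportionally;
covariate effects (group size on disappearance) enter by recomputing rates
after every event. It emulates, with defaults chosen to land near the
study's scale (7 years, two windows per year, ~750 unique individuals,
roughly a third of group captures being singletons, predominantly female):

* groups founded by single dispersing females who are later joined by
  males — joining males are drawn from the live natal-male pool when one is
  available, so male natal departures are observable, with outside
  immigrants created only as a fallback;
* inheritance of the breeding position only while a group lacks a breeding
  female;
* a lone surviving non-breeding female reclassified as a single female
  (the state a field worker would assign her);
* Poisson recruitment per active breeding group, log-linear in group size,
  anchored at about two recruits per six months near the average breeding
  group;
* von Bertalanffy growth of mass and incisor width from a ~10 g birth mass
  with per-individual random asymptotes and rates and group-size effects
  applied at entry;
* periodic trapping windows in which each group is trapped with
  probability 0.8, and 15% of trapped groups lose their largest non-breeder
  to capture evasion (the capture is then flagged incomplete).

Baseline disappearance intensities default to values consistent with the
field study's reported annual survival by state, the growth defaults make
the 80 g / 100 g recruit cutoffs correspond to roughly one year of growth,
and rainfall is seasonal log-normal (wet October-April). The generator's
truth object records exact state-change times, the true state at every
emitted capture, growth random effects and the birth log, which is what the
exact panel-reconstruction tests compare against.

What passing the pipeline on synthetic data does **not** show: estimates
recovered from the full individual-based simulation are *not* expected to
equal the generator dials, for reasons the field study shares. Imperfect
trapping makes a small fraction of two-window absences false
disappearances, inflating all hazards and compressing between-state
intensity ratios; group sizes measured at one capture attenuate group-size
coefficients relative to effects that operate continuously (regression
dilution); and growth group-size effects fixed at an individual's entry are
diluted when regressed on group size at a later capture. The inference
machinery itself is validated separately on clean panel data from
`simulate_panels()`, where 95% Wald intervals achieve nominal coverage
(±4 points over 200 study-scale replicates) and median intensity bias is
under 10%. The generator also simplifies reality: no multi-site structure
by default, no rainfall dependence of dispersal, no heaping or measurement
drift in morphometrics, and no group fission or territory budding.

## 6. Numerical choices and degenerate inputs

* Panel likelihood: collapsed into blocks sharing (elapsed time, covariate
  vector), one matrix exponential per block; observed transitions that are
  impossible under the structure yield -Inf, which the optimiser sees as a
  large penalty, and an explicit error names the offending pair at the
  validation step.
* Recruit classification with a missing mass is an error by default
  (configurable to `immigrant`, matching the over-threshold default the
  cutoffs imply, or `drop`).
* `zscore()` refuses constant vectors; `vif()` reports perfectly collinear
  covariates as infinite; Welch's test returns t = 0, p = 1 for two
  identical constant samples.
* Problem sizes in the test suite (200-replicate coverage at ~420 females,
  400-replicate null calibration at 80 events, 5-replicate growth
  recovery at 200 individuals) were chosen as the smallest designs at which
  the frequentist properties under test are themselves stable.

## 7. Known limitations

* Group-size hazard effects on disappearance are updated at each
  observation (the default; fixing at state entry is possible by freezing
  the covariate column) — which of the two the original analysis used is
  not documented.
* The exact transition diagram of the original supplementary material was
  not available; the structure used here (including NB→BF inheritance) is
  user-overridable via `transition_structure()`.
* Natal-group membership for females first caught as adults is taken to be
  the group of first capture unless an explicit natal mapping is supplied.
* Incomplete group captures contribute their observed size to group-size
  covariates; `incomplete_add_one` adds one under the single-evader
  assumption as a sensitivity switch.
* The Laplace growth fitter's variance components can sit slightly off the
  values a conditional-linearisation fitter returns; fixed effects agree to
  within a few percent in the cross-checks, which bounds the comparability
  of real-data coefficients.
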