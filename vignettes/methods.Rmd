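---
title: "Methods: equipoise modelling for xenotransplant candidate selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: equipoise modelling for xenotransplant candidate selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of its models, the choices behind
them, and what the test suite does and does not establish.

## The decision problem

A kidney-waitlist candidate offered a xenotransplant whose graft is assumed
to function for $n$ years faces a survival trade-off. Staying on the list,
their expected remaining life is the restricted mean survival time (RMST)

$$\mathrm{LE}_{\mathrm{sq}} = \int_0^H S(t)\,dt,$$

the area under their predicted waitlist survival curve up to the horizon
$H$. Accepting the xenograft yields $n$ years of assumed graft function and
then, with probability $p_{\mathrm{relist}}$, a return to the allotransplant
waitlist:

$$\mathrm{LE}_{\mathrm{xeno}}(n) = n + p_{\mathrm{relist}} \cdot
\mathrm{LE}_{\mathrm{relist}}.$$

The candidate *reaches equipoise* (is "viable") at $n$ when
$\mathrm{LE}_{\mathrm{xeno}}(n) > \mathrm{LE}_{\mathrm{sq}}$, with strict
inequality — ties are not viable. Since $n$ is unknown (non-human-primate
benchmarks suggest under two years), everything is swept over
$n \in \{0.5, 1, 1.5, 2, 3, 4, 5\}$. Because
$\mathrm{LE}_{\mathrm{xeno}}$ is strictly increasing in $n$ while
$\mathrm{LE}_{\mathrm{sq}}$ is fixed, viable sets are nested across the
grid; this is asserted as an invariant.

Survival alone under-counts benefits (dialysis independence, quality of
life), and the package makes no claim beyond the survival comparison.

## Time conventions and curves

Time is measured in years from the *prediction snapshot*. Elapsed waiting
time is a covariate, not part of the curve's time axis, because candidates'
health deteriorates with time on the list; the predicted curve at a
patient's own covariates is therefore already the conditional-on-having-
waited curve. `conditional_curve()` additionally implements
$S'(t) = S(e + t)/S(e)$ (and the renormalised incidence analogue) for
conditioning *beyond* the snapshot, e.g. "given three more years of
waiting".

Curves live on a monthly grid (1/12 yr) up to a 25-year horizon and are
carried at their last estimated value to the horizon — no tail
extrapolation; the RMST is therefore conservative for long-lived
candidates. Monthly resolution is appropriate for year-scale claims: the
trapezoidal RMST of an exponential curve is within 0.02% of the closed form
at this step. Both defaults are configurable (`horizon`, `step`).

## Survival estimation

Three targets are modelled on the active population (inactive candidates
are excluded throughout, since they cannot receive offers):
death-or-delisting on the waitlist (death and delisting-for-illness merged
into one absorbing event), time to deceased-donor transplant (death treated
as censoring, matching separate published survival and time-to-transplant
curves; an Aalen–Johansen competing-risks incidence is available via
`km_with_band(competing = TRUE)` for sensitivity), and post-transplant
death (clocked from transplant, with donor quality and age at transplant as
covariates).

Backends: Cox proportional hazards (Efron ties — the default of the major
survival stacks; the choice is otherwise inconsequential here), random
survival forests via ranger, and covariate-free Kaplan–Meier. The forest
records its seed in the model object and discretises event times to the
curve grid before growing — with tens of thousands of distinct continuous
event times a survival forest's node curves become needlessly expensive,
and monthly resolution matches the reporting grid anyway; minimum terminal
node size defaults to 50. Cox curves are
$S(t\mid x) = \exp\{-\Lambda_0(t) e^{\beta^\top x}\}$ with the Breslow
baseline. Collinear covariates are dropped with a warning naming them;
fewer than 50 events triggers a warning, zero events an error.

Variable importance follows each backend's native notion: permutation
importance on Harrell's concordance for the forest (10 permutations per
variable, averaged, on held-out records) and absolute standardized
coefficients $|\hat\beta|\,\mathrm{sd}(x)$ for Cox. The cohort-defining
variable set is the union of the top three variables from the two backends
(`top_k_union()`).

Kaplan–Meier cohort curves carry Greenwood log–log 95% bands. Any estimate
resting on fewer than 15 events is flagged `suppressed` rather than
reported silently — the same small-count rule used by the metrics module.

## The relisting recursion

$\mathrm{LE}_{\mathrm{relist}}$ is computed by a discrete-time semi-Markov
recursion on the monthly grid. Per interval $j$, discrete death and
transplant hazards $h^d_j, h^{tx}_j$ are read off the patient's predicted
curves; the probability $W_j$ of being alive and still waiting propagates
as $W_{j+1} = W_j (1 - h^d_j)(1 - h^{tx}_j)$; and expected life years
accumulate as

$$\mathrm{LE} = \sum_j \tfrac{W_j + W_{j+1}}{2}\,\Delta +
\sum_j W_j\, h^{tx}_j \bigl(1 - \tfrac{h^d_j}{2}\bigr)\,
\mathrm{LE}_{\mathrm{post}}(t_{j+1/2}),$$

the first sum being expected waiting-phase person-years (for everyone,
including the eventually transplanted) and the second the transplant mass
per interval times the post-transplant RMST at the interval midpoint,
truncated at $H - t$. The $(1 - h^d/2)$ factor and midpoint evaluation make
the scheme second-order accurate: against the two-state constant-hazard
closed form
$\frac{1-e^{-aH}}{a} + \int_0^H \lambda e^{-as}\frac{1-e^{-\mu_p(H-s)}}{\mu_p}ds$
(with $a = \mu_w + \lambda$) the recursion agrees to well under 0.1% across
a $3\times3\times3$ hazard grid. Note the transplant term adds the
*post-transplant* expectancy only — waiting-phase years of the transplanted
are already counted by the first sum; adding "elapsed time at transplant"
there would double-count, as the closed form makes explicit.

Post-transplant expectancy inside the recursion depends on transplant
timing only through age at transplant (age at listing + elapsed waiting
time + time in the recursion); all other covariates are frozen at the
snapshot, and in particular the CPRA is held at its pre-xenograft value —
sensitization after exposure to animal organs is a recognised unknown, and
a hook exists for injecting shifts but defaults off. The xenograft years
$n$ are *not* added to age, so the base-scenario
$\mathrm{LE}_{\mathrm{relist}}$ is independent of $n$; this keeps the
equipoise formula's monotonicity in $n$ structural rather than incidental.
Post-transplant RMSTs are evaluated exactly on a half-yearly transplant-
time grid and interpolated to midpoints (the function is smooth in both
arguments); the donor inside the recursion is a reference donor at the
pool's mean quality.

## Incentive scenarios

All scenarios share the recursion and modify only the transplant process;
the relisting death curve always uses waiting time 0, so scenario contrasts
isolate transplant access:

* **base** — waiting-time credit resets to zero at relisting. The contrast
  with accrual only exists if the base does not accrue.
* **inactive_accrual** — the candidate stays inactive (no offers) while the
  xenograft functions but accrues waiting time: the transplant curve is
  predicted at credit $w_0 + n$.
* **living_donor_priority** — priority points equivalent to a former living
  donor, modelled as a proportional transplant-hazard multiplier (default
  5×) applied per interval as $1-(1-h)^m$, which is exactly the identity at
  $m = 1$. Point-based match-run simulation would require allocation
  mechanics that live in restricted offer data; the multiplier is the
  minimal faithful surrogate and is a config knob.
* **highest_priority** — immediate transplant at the top of the list: the
  ABO-compatible donor pool is identified (O→everyone, A→A/AB, B→B/AB,
  AB→AB), the post-transplant RMST computed per donor, and the $q$-th
  percentile taken (nearest rank — deterministic, no interpolation
  ambiguity), $q = 75$ by default.

Under the generator defaults the per-patient ordering base ≤ inactive ≤
living-donor ≤ highest is structural: the transplant waiting-time log-HR
(0.10/yr) and the waiting-time cap (10 yr) keep the accrual multiplier
$e^{0.10(w_0+n)} \le e^{1.5} < 5$, and transplantation improves survival in
the ground truth, so faster access always helps. The incentive report
(fraction of each cohort reaching equipoise per scenario and $n$, with
percentage-point deltas against base) inherits the ordering.

## The synthetic registry

The generator emulates the statistical structure of waitlist registry data
with a known ground truth; it does not mimic any registry's file layouts or
cleaning rules, and the deprivation index is sampled, not constructed from
census inputs. Covariate distributions are chosen to be realistic for a US
kidney waitlist at the defaults (10,000 patients): age mixed over the
18–49 / 50–64 / 65+ bands (30/45/25%), diabetes 45%, blood types
O/A/B/AB = 48/34/14/4%, CPRA zero-inflated with a 5% mass at ≥ 99.5 so the
very-highly-sensitized cohort is populated, waiting time exponential (mean
2 yr, capped at 10), 10% inactive.

Death/delisting and transplant are competing risks generated as independent
latent Weibull proportional-hazards times (shape 1 — exponential — by
default, so memorylessness checks are exact; shapes are configurable for
aging effects), with the observed outcome the earliest of death,
transplant, censoring and the 25-year horizon. Transplanted patients
receive a blood-compatible donor, a post-transplant survival time, a graft
failure indicator (exponential, 0.06/yr) and, among failures, a relisting
indicator from a logistic ground truth. The default hazard coefficients put
higher death risk on age, diabetes, low albumin, deprivation and elapsed
waiting time, and lower transplant access on blood B/O, high CPRA and
diabetes — the direction real registries show. The death-coefficient map
deliberately contains only covariates whose Cox standard error at a
5,000-patient bundle is well below 0.05, so ground-truth recovery within
±0.1 is a property of the estimator rather than a coin flip; low-prevalence
binaries (previous transplant, heart failure) act on the transplant and
post-transplant processes instead. Offer logs arrive per patient-year while
on the list, with per-center Beta-distributed acceptance and opt-in screen
propensities; "marginal" means donor quality below 0.35 (the real
marginality criterion lives in restricted offer data, so it is
parameterized). Randomness is split into named per-table streams so
enlarging one table does not perturb the others; a seed fixes the bundle
bit-for-bit.

What passing tests on this generator shows: the estimators, the equipoise
logic, the recursion, the metrics and the pipeline are correct against
known ground truth and closed forms. What it does not show: performance on
real registry data. The synthetic default population is sicker and relists
more readily than the real waitlist, so viable fractions here are far
higher than the "under 5% at $n<2$" reported on restricted registry data;
reproducing those magnitudes is out of scope, and only the qualitative
structure (fractions rising in $n$; incentive ordering; high hit rate with
low capture rate at small $\tau$) carries over.

## Cohorts, aggressiveness, metrics

The eleven cohorts target candidates with both low survival and low
transplant access: diabetics with blood type B or O in the $[50,64)$ and
$65{+}$ bands (the UNOS reporting bands; intervals half-open as printed),
refined by waiting time ($\ge 3$ vs $< 3$ yr), by the listing center's
aggressiveness tertile, plus CPRA $\ge 99.5$. Membership is conjunctive and
overlapping (3 and 5 refine 1; 4 and 6 refine 2).

Center aggressiveness = (marginal organs accepted / marginal organs
offered to the center's patients) × (mean over the center's patients of the
fraction of the national marginal-organ universe they saw). The product is
bounded by each factor; tertiles are assigned by descending score with ties
broken by center id, extras going to the top then middle tertile — the
classification is invariant under monotone rescaling of scores since only
ranks enter.

Hit rate and capture rate are precision and recall of "predicted RMST
$\le \tau$" against "died or delisted within $\tau$", with inclusive
thresholds ("$\tau$ years or fewer"). Patients censored before $\tau$
without an event are excluded from both denominators: their $\tau$-year
status is unknown, and keeping them would bias the hit rate downward
unverifiably. The policy string is logged in every report. Undefined rates
(empty denominators) are flagged `NA`, never silently zero, and reports
with fewer than 15 correct identifications are flagged suppressed. An
independent brute-force per-patient recount (`oracle_confusion`) must agree
exactly; this is asserted over 100 seeded populations.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → fit → equipoise → cohorts → incentives →
evaluate. Configuration is YAML overlaid on `default_pipeline_config()`
with unknown keys rejected by field path; the grid step is specified as
integer steps per year so it always divides the horizon. Every stage writes
CSV/JSON artifacts plus a manifest of md5 digests; two runs with the same
config and seed are digest-identical (model binaries are excluded from the
digest contract — serialized fit objects are not byte-stable, the tables
are). Exit codes in the CLI wrapper: 2 for config errors, 3 for missing
upstream artifacts.

The default configuration fits Cox models for the curve stack — exactly
reproducible, fast, and sufficient for a proportional-hazards ground truth
— while the variable-importance tables use the forest/Cox pair the top-3
union calls for, with the forest trained on a seeded 4,000-row subsample
and permuted on a disjoint 1,000-row subsample (importance stability, not
curve accuracy, is what that table needs). The forest backend is available
for the curve stack via `model.backend: rsf`. A DeepSurv-style neural
backend is deliberately out of scope; the model contract (`fit_model` /
`predict_curve_matrix`) accommodates one.

Problem sizes used by the test suite — 2,500-patient shared bundles for
module tests, 5,000 × 5 seeds for recovery, 200 × 500 for band coverage,
the 10,000-patient default for the ordering and end-to-end checks — were
chosen so the full suite exercises the default study conditions while
remaining a desk-scale computation.

## Known limitations

* Relisting-probability stratification is a single logistic ground truth
  plus either an individual-level fit or one empirical cohort fraction; the
  finer stratifications used on real registries (and their
  individual-vs-cohort sensitivity) are a config switch away but not
  emulated in the generator.
* The recursion is one concrete instantiation of the post-failure event
  sequence: patients never decline offers, and cohort-level versus
  individual-level transplant curves inside the recursion are supported but
  not separately validated.
* Multi-listing, re-transplant inclusion rules, geography and the
  construction of the deprivation index are out of scope; the offer process
  is a thinned Poisson sketch sufficient for the aggressiveness score, not
  a match-run simulator.
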