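---
title: "Methods: residency metrics, the delta-lognormal detection model, and the reserve-effect bootstrap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: residency metrics, the delta-lognormal detection model, and the reserve-effect bootstrap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reeftrace)
```

`reeftrace` implements the two complementary field assays used to ask whether
a no-take marine reserve benefits a reef-associated shark: passive acoustic
telemetry for individual site-fidelity, and baited remote underwater video
(BRUV) surveys for relative abundance across reserve and fished reefs. This
vignette is the package's account of the statistical methods, the choices
behind them, and what the simulation-based tests do and do not demonstrate.

## 1. From raw detections to daily presence

A fixed array of omnidirectional receivers logs `(timestamp, receiver,
transmitter)` triples whenever a coded transmitter is heard. Two artifacts
contaminate such logs: background noise and *signal collisions*, where
overlapping pulse trains from two transmitters fabricate a code. The standard
screen, implemented in `build_strings()`, keeps only *detection strings* —
runs of two or more detections of one transmitter at one receiver separated
by at most `string_gap_s` seconds — and discards isolated pings.

The transmitters emit with a semi-random delay of 180–360 s. The field
convention never pins down "consecutive", so we set `string_gap_s = 720` s:
twice the maximum nominal delay, which tolerates exactly one missed pulse.
`flag_collisions()` adds the second-order screen: where three or more
transmitters are heard at one receiver within a 600 s neighbourhood, any
string whose largest internal gap exceeds `collision_lag_factor` (default 2)
times the nominal 360 s delay is reported as a candidate fabrication. Both
thresholds are package choices — the screening *logic* is standard, its
constants are not printed anywhere authoritative — and both are arguments.

`daily_presence()` collapses strings to the day scale and attaches the
*eligibility mask*: a day is eligible for a shark when its transmitter is
within battery life (the tagging day plus `battery_days` − 1; V9 = 365 d,
V16 = 540 d) and at least one receiver in the array is operational.
Detections after nominal battery expiry are *retained but flagged*, because
transmitters outlive their rating and monitoring duration should honour the
true last contact, while the residency index must not be diluted by a
denominator the tag could not serve.

## 2. Site-fidelity metrics

For each detected shark:

* **Residency index** `RI = (eligible days with any detection) / (eligible
  days)` — a [0, 1] measure standardised across unequal battery lives.
* **Minimum linear dispersal** (MLD): the greatest great-circle distance
  between two receivers at which the shark was ever detected; a lower bound
  on range extent with set semantics (visit order and frequency are
  irrelevant). A single-receiver shark has MLD 0 by definition; in the
  reference data every shark reached at least two receivers, so this case is
  exercised only synthetically.
* **Monitoring duration**: days from tagging to the last detection string,
  post-expiry included.
* **Monthly occurrence**: days detected per calendar month, binned
  none / 1–7 / 8–14 / >14 for the standard occurrence plot.

Distances use the haversine formula on a sphere of radius 6371.0088 km
(`haversine_km()`). The original workflow measured map distances in a GIS;
at atoll scale (≤ 40 km) the spherical error is far below 1% and the
computation is fully reproducible without GIS assets. Distances are not
routed around land — a deliberate simplification; lagoon receivers a shark
would have to swim around an island to reach are treated as closer than they
functionally are.

`size_regression()` is ordinary least squares of RI or MLD on total length —
the conventional screen for ontogenetic shifts in residency or range.

## 3. The delta-lognormal detection model

Fine-scale fidelity predicts that detection effort concentrates near the
capture site. The response — fraction of days each shark was detected at
each receiver — is zero-heavy and positive, the classic delta-lognormal
situation: model *whether* a shark was ever detected at a receiver with a
logit-link binomial GLM, model the *fraction of days given any detection* as
lognormal, and take the product as the expectation,

$$ E[\mathrm{frac}] = \hat\pi \cdot \exp(\hat\mu + \hat\sigma^2/2). $$

The `exp(\hat\sigma^2/2)` factor is the standard lognormal mean
back-transform; the tradition this model descends from includes it, though
published summaries rarely say whether it was applied, so
`combine_delta(bias_correct = FALSE)` disables it for sensitivity analysis.
Expectations above 1 are clipped with a logged count.

Covariates, assembled by `build_summary()`: log distance from the tagging
point to the receiver (`ldist`, natural log, distance floored at 0.05 km so
a shark tagged on top of a receiver has a finite value), receiver habitat
class (ocean reef / deep lagoon / shallow lagoon), receiver operational days
within the shark's battery window (`days`), shark type (maturity × sex), and
optional random effects for individual sharks and receivers, including a
random `ldist` slope by shark. Fixed-effects stages use `stats::glm`/`lm`;
mixed stages use `lme4` with the Laplace approximation (and maximum
likelihood rather than REML for the Gaussian stage, so information criteria
are comparable within a candidate set). Non-converged mixed fits are flagged
and skipped by selection rather than silently used.

The *sequential* (type-I) analysis of deviance is the table structure this
literature prints: each term's deviance is its reduction given the terms
before it, "percent deviance" is that reduction over the null deviance, and
the decomposition always sums back to the null deviance — asserted on every
fit in the test suite.

**Term inclusion.** The inherited rule — include a variable if it is
significant, explains more than 2% of the variance, and improves AIC or
BIC — cannot be conjunctive, because the workflow it describes retained a
term with p = 0.11. We therefore read it as: *a term enters if it improves
AIC or BIC, or if it is both significant at 0.05 and explains more than 2%
of the null deviance*. The decision function (`inclusion_decision()`) is
pure and exported, so its truth table is directly testable, and
`select_terms()` records the clause that admitted or rejected every term.
Ties in a criterion keep the earlier candidate in declaration order.

Prediction "rounds the expected probability to zero or one": we fix the
threshold at 0.5 with ties counted as present, and report the predicted ×
observed confusion matrix and its accuracy (`predict_presence()`).

## 4. Month-scale retention

`build_monthly_records()` scores each internal-tagged shark as
detected/undetected in each of twelve 30-day blocks after tagging. Blocks
rather than calendar months make "month 3" mean the same thing for a shark
tagged on May 24 and one tagged on December 18; the calendar alignment
remains available (`align = "calendar"`). Months in which the array was
entirely down are dropped, not scored absent — scoring them 0 would
manufacture emigration out of receiver maintenance. Externally tagged
animals are excluded: external attachment sheds on a different schedule and
would confound retention with tag loss. The model itself
(`fit_month_model()`) is a logistic GLM on month number (numeric) and
battery class; `predict_retention_curve()` returns the inverse-logit curve
with a ±2 SE band computed on the linear predictor, so the band respects
(0, 1) and always brackets the point estimate.

## 5. The BRUV reserve analysis

Each baited-video deployment is scored for presence plus two counts: the
most sharks in a single frame (Nmax) and the most distinguishable
individuals across the video (Nmax-A ≥ Nmax). `fit_reserve_glm()` tests the
design's primary factor first: a logistic GLM with the reserve/fished
contrast followed by location nested within stratum
(`presence ~ reserve + reserve:site`), sequential deviance, chi-square
p-values.

**The area-proportional bootstrap.** The fished sites are physically larger
than the reserve sites, so equal deployment counts mean lower sampling
density there — a bias that favours finding a reserve effect. The remedy is
to resample each site down to an area-proportional count (TU 50, SWC 30,
GRMR 25, CCMR 25 in the reference design), refit `presence ~ reserve`, test
the reserve term by likelihood-ratio chi-square at α = 0.05, and report the
fraction of 2000 replicates in which it stays significant.
`bootstrap_density()` draws *with replacement* within site by default — a
stratified bootstrap, which is the procedure whose output matches the
reference analysis — and offers `replace = FALSE` for plain without-
replacement subsampling (under which the significant fraction runs
noticeably higher, since every replicate shares most of its rows with the
full data). The per-replicate model omits the nested location term by
default because subsamples can empty a site's presence cells; `nested =
TRUE` restores it. Per-replicate p-values are retained for audit and the
whole object is bit-reproducible from its seed.

Environmental screening uses `compare_environments()` (one-way ANOVA by
site plus Tukey HSD with family-wise adjustment) and, within the reserve
subset only — fished sites have too few presences to support environmental
terms — `fit_env_glm_reserve_subset()`, a logistic GLM with location, flow,
start temperature and their pairwise interactions.

## 6. The synthetic-data generator

No raw detection log for the reference system is public, so the generator is
the package's test substrate, and its defaults *are* the study conditions:
33 sharks; 21 receivers (15 on a 30 km × 10 km ellipse, 3 deep-lagoon and 3
shallow-lagoon inside); a four-year window; V9 tags with probability 14/34;
pulse delays uniform on 180–360 s with 2–6 pulses per detected day.
Detection structure: each shark is home-centred at its tagging point
(capture locations in this system sit inside the animal's regular range);
ever-detected at a receiver is Bernoulli with logit
`-0.5 - 1.2·ldist + habitat + shark effect` (habitat deficits −0.5 deep
lagoon, −1.0 shallow lagoon; shark SD 1.0); the fraction of days given
detection is lognormal with log-scale mean `-2.5 - 0.6·ldist` and SD 0.8,
clipped at 1 with clips counted. Those constants were fixed once, by two
qualitative calibration targets of the reference system: detection is
near-certain at the tagging site, and the expected fraction of days detected
falls below 10% beyond 1 km. The day count given detection is a
*zero-truncated* binomial over the eligible window, so "drawn as detected"
and "produces at least one detection day" coincide and the generating model
matches the fitted one.

For BRUV, `simulate_bruv()` draws per-site Bernoulli presence (defaults
0.32 / 0.26 / 0.12 / 0.04, the reference per-site rates), a 0.375 chance a
present deployment shows two sharks in frame, Gaussian environmental
covariates per site with the fourth site warmer and more oxygenated, and
`nmax_a ≥ nmax` by construction.

What the generator does *not* emulate: spatial autocorrelation of movement
(days are scattered independently), diel structure, tide or season effects,
receiver-range variation with sea state, and collision artifacts — clean
logs by construction, so the collision screen is tested on constructed
pathological inputs instead. Passing recovery tests therefore demonstrate
that the pipeline recovers the parameters of *this* generating process, not
that the model is correctly specified for any real reef.

## 7. Parameter recovery and calibration

`recovery_report()` is the simulation harness: per replicate it simulates,
ingests, filters, summarises and refits, then reports bias, RMSE and 95%
Wald-interval coverage for the log-distance slope and habitat offsets
(telemetry arm, refitting the shark random intercept whenever the generator
used one), and the significance rate plus log-odds-ratio recovery of the
reserve contrast (BRUV arm, fresh survey per replicate — so with equal
presence probabilities everywhere it measures the test's type-I rate, and
with a real contrast its power).

The shipped checks run 200 telemetry replicates at 30 sharks × 21 receivers
over a one-year window — a problem size chosen to keep the small-sample bias
of logistic MLEs (which pulls slope estimates away from zero on sparse
designs) negligible while the suite stays fast — and 500 null-configuration
BRUV replicates for the α calibration.

## 8. Numerical conventions and degenerate inputs

* Natural logs throughout; distances floored at 0.05 km before logging.
* Timestamps are read in one configured zone with no DST arithmetic; a
  calendar day is the date in that zone; day-spanning strings count for
  every date they touch.
* Zero eligible days makes RI an *error*, never 0; a never-detected shark
  has RI 0 but undefined MLD/duration and is excluded from group summaries
  (matching the 33-of-34 convention of the reference tables).
* Complete separation in a binomial stage warns and stores finite
  coefficients from a small hand-rolled ridge-penalised Newton fall-back;
  the deviance table still comes from the unpenalised fit. Rank deficiency
  is an error naming the aliased columns.
* Exact AIC ties resolve to the earliest candidate in declaration order.
* Every stochastic routine takes a seed and is bit-reproducible from it.

## 9. Known limitations

Great-circle (not around-land) distances; single-zone timestamps; the
fraction-of-days denominator uses receiver uptime within the battery window,
which treats partial-day outages as full days; the bootstrap's per-replicate
model ignores within-site clustering beyond the site draw itself; and the
reference fixtures carry only what the published summary tables print —
coordinates of tagging sites are approximate centroids and the maturity
column is reconstructed from length cut-offs, both documented as such in
`?grmr_tags`.
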