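# reeftrace

Do no-take marine reserves benefit reef sharks? Two predictions follow if
they do: individual sharks should show high **site-fidelity** to the
protected reef, and their **relative abundance** should be higher inside
reserves than on comparable fished reefs. `reeftrace` implements the
standard analysis pipeline for testing both predictions with the two field
assays used in reef-shark reserve studies:

* **Passive acoustic telemetry.** Tagged sharks carry coded transmitters;
  an array of fixed receivers logs every detection for years. The package
  filters raw logs into quality-controlled *detection strings* (runs of ≥ 2
  closely spaced detections, screening out signal collisions and noise),
  reduces them to daily presence with a per-shark eligibility mask (tag
  battery life ∩ array uptime), and computes the standard fidelity metrics:

  - residency index `RI = detected eligible days / eligible days` ∈ [0, 1],
  - minimum linear dispersal `MLD` = the greatest distance between two
    receivers with detections (a lower bound on range extent),
  - monitoring duration, monthly occurrence bins, and OLS regressions of
    RI and MLD on body size.

* **The delta-lognormal detection model.** Whether a shark was ever
  detected at a receiver is a logit-link binomial GLM/GLMM in log distance
  from the tagging site, habitat, sampling effort and shark type; the
  fraction of days detected *given* any detection is lognormal; the
  expected fraction is the product `E[frac] = π̂ · exp(μ̂ + σ̂²/2)`.
  Sequential analysis-of-deviance tables, a three-clause term-inclusion
  rule, AIC/BIC candidate selection (`lme4` mixed variants included), and
  observed-vs-predicted confusion matrices.

* **Month-scale retention.** A logistic GLM of any-detection per 30-day
  month since tagging, with an inverse-logit retention curve ± 2 SE.

* **BRUV reserve analysis.** Baited remote underwater video deployments
  scored for shark presence across reserve and fished reefs: per-site
  summaries, a nested-location logistic GLM of the reserve effect, one-way
  ANOVA/Tukey environmental screening, a reserve-subset environmental GLM,
  and an **area-proportional bootstrap** — resample each site down to an
  area-proportional count, refit `presence ~ reserve`, and report the
  fraction of 2000 replicates in which the reserve term stays significant
  by likelihood-ratio χ², correcting for unequal sampling density across
  sites of unequal area.

* **Synthetic data.** Seeded generators (`simulate_telemetry()`,
  `simulate_bruv()`) emulate both assays — home-centred sharks with
  logit-linear distance decay, lognormal day fractions, 180–360 s pulse
  trains, battery expiry, per-site presence rates — so the whole pipeline
  is testable end-to-end and `recovery_report()` verifies parameter
  recovery by simulation.

The package ships the published summary tables of a reference study — 33
acoustically monitored Caribbean reef sharks at Glover's Reef Marine
Reserve, Belize, and 200 BRUV deployments across four Mesoamerican Barrier
Reef sites — as plain-text fixtures (`grmr_tags()`, `grmr_monitoring()`,
`grmr_bruv_counts()`, `grmr_reference_table()`).

## Worked example

```r
library(reeftrace)

## Site-fidelity of the 33 reference sharks
mon <- grmr_monitoring()
subset(fidelity_summary(mon), metric == "ri")
#>   group metric  n  mean    sd  min  max
#> 1   all     ri 33 0.435 0.305 0.01 0.99
#> 5   V16     ri 19 0.361 0.295 0.01 0.98
#> 9    V9     ri 14 0.536 0.300 0.05 0.99
```

The average shark was detected on 44% of the days its transmitter was live
and the array was listening. Body size explains essentially none of the
variation:

```r
size_regression(mon, "ri")[c("slope", "r_squared")]
#> slope = -0.00076, r^2 = 0.010
```

The reserve effect on BRUV presence, and its density-corrected bootstrap:

```r
d <- bruv_from_counts(grmr_bruv_counts())
fit_reserve_glm(d)
#> Sequential analysis of deviance (binomial_logit): presence ~ reserve + reserve:site
#> NULL deviance 191.6 on 199 df
#>          term df deviance resid_df resid_dev statistic   p_value percent_deviance
#>       reserve  1   15.372      198     176.2    15.372 8.828e-05          0.08025
#>  reserve:site  2    2.705      196     173.5     2.705 2.586e-01          0.01412

bootstrap_density(d, c(TU = 50, SWC = 30, GRMR = 25, CCMR = 25),
                  n_reps = 2000, seed = 1)
#> Area-proportional bootstrap: 2000 replicates, with replacement
#>   per-site draws: TU=50, SWC=30, GRMR=25, CCMR=25
#>   reserve term significant (LRT p < 0.05) in 84.6% of replicates
```

Reserve status is a strong predictor of shark presence (χ²₁ = 15.4,
p < 0.001), there is no detectable difference between sites within a
stratum, and the effect survives equalising sampling density in ~85% of
area-proportional resamples.

End-to-end on synthetic telemetry:

```r
sim  <- simulate_telemetry(telemetry_sim_config(n_sharks = 12, seed = 42))
pres <- daily_presence(build_strings(sim$detections), sim$tags, sim$receivers)
fit_detection_glm(build_summary(pres), "presence", c("days", "ldist", "habitat"))
#> Sequential analysis of deviance (binomial_logit): detected ~ days + ldist + habitat
#> NULL deviance 126.4 on 230 df
#>     term df deviance resid_df resid_dev statistic   p_value percent_deviance
#>     days  1  0.06532      229    126.37   0.06532 7.983e-01        0.0005167
#>    ldist  1 62.63673      228     63.73  62.63673 2.486e-15        0.4954139
#>  habitat  2  1.33685      226     62.39   1.33685 5.125e-01        0.0105736
```

Log distance from the tagging site dominates, as the generator's
home-ranging structure dictates.

## Documentation

See the methods vignette (`vignettes/reeftrace-methods.Rmd`) for the models,
their assumptions, every tunable threshold and default, what the synthetic
generator does and does not emulate, and known limitations.
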