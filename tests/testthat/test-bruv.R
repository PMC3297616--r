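ref_deployments <- function() bruv_from_counts(grmr_bruv_counts())

test_that("site summaries reproduce the per-site and stratum percentages", {
  s <- summarize_sites(ref_deployments())
  expect_equal(s$percent_present[s$site == "GRMR"], 32)
  expect_equal(s$percent_present[s$site == "SWC"], 4)
  expect_equal(s$n_multi[s$site == "CCMR"], 6)
  expect_equal(s$n_present[s$site == "reserve"], 29)
  expect_equal(s$n_present[s$site == "fished"], 8)
  # site percentages recompose to the stratum totals
  expect_equal(sum(s$n_present[s$stratum == "site" & s$reserve]),
               s$n_present[s$site == "reserve"])

  empty <- summarize_sites(ref_deployments(), sites = c("GRMR", "NOWHERE"))
  expect_true(empty$undefined_percent[empty$site == "NOWHERE"])
  expect_equal(empty$percent_present[empty$site == "NOWHERE"], 0)
})

test_that("the reserve GLM finds the reserve effect and decomposes cleanly", {
  fit <- fit_reserve_glm(ref_deployments())
  a <- fit$anodev
  expect_equal(a$term, c("reserve", "reserve:site"))
  expect_lt(a$p_value[a$term == "reserve"], 0.05)
  expect_gt(a$deviance[a$term == "reserve"], 3.84) # chi-sq_1 at 0.05
  expect_equal(sum(a$deviance) + fit$resid_deviance, fit$null_deviance,
               tolerance = 1e-8)
  # no between-site difference within strata in the reference counts beyond noise
  expect_gt(a$p_value[a$term == "reserve:site"], 0.05)

  # identical rates in both strata: reserve deviance collapses to zero
  flat <- bruv_from_counts(data.frame(
    site = c("A", "B", "C", "D"), reserve = c(TRUE, TRUE, FALSE, FALSE),
    n_deployments = 50L, n_present = 10L))
  flat_fit <- fit_reserve_glm(flat)
  expect_lt(flat_fit$anodev$deviance[1], 1e-8)

  # a single-site stratum drops the nested term with a warning
  lop <- bruv_from_counts(data.frame(
    site = c("A", "B", "C"), reserve = c(TRUE, TRUE, FALSE),
    n_deployments = 50L, n_present = c(15L, 12L, 3L)))
  expect_warning(lfit <- fit_reserve_glm(lop), "single site")
  expect_equal(lfit$anodev$term, "reserve")
})

test_that("the bootstrap is seed-reproducible and honours its edge cases", {
  d <- ref_deployments()
  site_n <- c(TU = 50, SWC = 30, GRMR = 25, CCMR = 25)
  b1 <- bootstrap_density(d, site_n, n_reps = 50, seed = 99)
  b2 <- bootstrap_density(d, site_n, n_reps = 50, seed = 99)
  expect_identical(b1$p_values, b2$p_values)
  expect_identical(b1$fraction_significant, b2$fraction_significant)

  # full-sample subsampling has no resampling variance
  full_n <- c(TU = 50, SWC = 50, GRMR = 50, CCMR = 50)
  bf <- bootstrap_density(d, full_n, n_reps = 10, seed = 1, replace = FALSE)
  expect_true(bf$fraction_significant %in% c(0, 1))
  expect_equal(max(bf$p_values) - min(bf$p_values), 0, tolerance = 1e-10)

  # all-absent data can never reject
  none <- bruv_from_counts(data.frame(
    site = c("A", "B"), reserve = c(TRUE, FALSE),
    n_deployments = 30L, n_present = 0L))
  b0 <- bootstrap_density(none, c(A = 20, B = 20), n_reps = 20, seed = 4)
  expect_equal(b0$fraction_significant, 0)

  expect_error(
    bootstrap_density(d, c(TU = 51, SWC = 30, GRMR = 25, CCMR = 25),
                      n_reps = 5, seed = 1, replace = FALSE),
    "exceeds available"
  )
  expect_error(bootstrap_density(d, c(XX = 10), n_reps = 5, seed = 1),
               "not in deployments")
})

test_that("bootstrap power is monotone in the true reserve odds ratio", {
  site_n <- c(A = 30, B = 30)
  frac_at <- function(p_reserve) {
    k <- round(p_reserve * 50)
    d <- bruv_from_counts(data.frame(
      site = c("A", "B"), reserve = c(TRUE, FALSE),
      n_deployments = 50L, n_present = c(k, 5L)))
    bootstrap_density(d, site_n, n_reps = 150, seed = 12)$fraction_significant
  }
  # presence 5/50 fished vs {5, 15, 30}/50 reserve: OR 1, ~3.6, ~13.5
  fr <- vapply(c(0.10, 0.30, 0.60), frac_at, numeric(1))
  expect_true(all(diff(fr) >= -0.02))
  expect_lt(fr[1], 0.2)
  expect_gt(fr[3], 0.8)
})

test_that("environmental comparisons: ANOVA/Tukey detect a shifted site only", {
  cfg <- bruv_sim_config(seed = 31)
  d <- simulate_bruv(cfg)
  # SWC is generated warmer: its pairwise temperature contrasts must show
  cmp <- compare_environments(d, "temp_start")
  expect_lt(cmp$p_value, 0.001)
  swc_rows <- grepl("SWC", rownames(cmp$tukey))
  expect_true(all(cmp$tukey[swc_rows, "p adj"] < 0.001))

  # salinity has no configured site differences
  cmp2 <- compare_environments(d, "salinity")
  expect_gt(cmp2$p_value, 0.01)

  single <- d[d$site == "GRMR", ]
  expect_error(compare_environments(single, "temp_start"), "at least 2 sites")

  d$visibility_m[1:5] <- NA
  cmp3 <- compare_environments(d, "visibility_m")
  expect_equal(cmp3$n_missing, 5)
  expect_equal(cmp3$n_used, nrow(d) - 5)
})

test_that("ANOVA across identical sites rejects at the nominal rate", {
  set.seed(88)
  reject <- replicate(200, {
    d <- data.frame(site = rep(c("A", "B", "C", "D"), each = 15),
                    temp_start = rnorm(60, 28, 0.7))
    compare_environments(d, "temp_start")$p_value < 0.05
  })
  expect_lt(abs(mean(reject) - 0.05), 0.05) # 3+ MC SEs of headroom
})

test_that("the reserve-subset environmental GLM has the expected structure", {
  d <- simulate_bruv(bruv_sim_config(seed = 7))
  fit <- fit_env_glm_reserve_subset(d)
  expect_equal(nrow(fit$anodev), 6)
  expect_equal(fit$null_df, sum(d$reserve) - 1)
  expect_equal(sum(fit$anodev$deviance) + fit$resid_deviance,
               fit$null_deviance, tolerance = 1e-8)

  d$flow_velocity[d$reserve] <- 0.2 # constant covariate: aliased interaction
  expect_error(fit_env_glm_reserve_subset(d), "aliased")
})
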