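sim_rows <- function(seed = 5, ...) {
  sim <- simulate_telemetry(small_telemetry_cfg(seed = seed, ...))
  pres <- daily_presence(build_strings(sim$detections), sim$tags, sim$receivers)
  build_summary(pres)
}

test_that("the model substrate applies the distance floor and frac rules", {
  tags <- mk_tags() # tagged exactly at R01's coordinates
  rec <- mk_receivers(lat = c(16.75, 16.80))
  pres <- daily_presence(
    mk_strings(seq(as.Date("2005-06-10"), by = "day", length.out = 5)),
    tags, rec)
  rows <- build_summary(pres, distance_floor_km = 0.05)
  r1 <- rows[rows$receiver_id == "R01", ]
  expect_equal(r1$ldist, log(0.05)) # floored at the tagging receiver
  expect_equal(r1$detected, 1L)
  # operational days clipped to the battery window
  expect_equal(r1$days,
               as.integer(as.Date("2006-05-01") - as.Date("2005-06-01")) + 1L)
  expect_equal(r1$frac_days, 5 / r1$days)
  r2 <- rows[rows$receiver_id == "R02", ]
  expect_equal(r2$detected, 0L)
  expect_true(is.na(r2$frac_days))
  expect_error(build_summary(pres, distance_floor_km = 0), "positive")
})

test_that("intercept-only binomial deviance equals the closed form", {
  k <- 7L; n <- 25L
  rows <- data.frame(detected = rep(c(1L, 0L), c(k, n - k)), ldist = 0)
  fit <- fit_detection_glm(rows, "presence", "1")
  phat <- k / n
  expect_equal(fit$null_deviance,
               -2 * (k * log(phat) + (n - k) * log(1 - phat)),
               tolerance = 1e-10)
})

test_that("glm fits match a brute-force likelihood optimizer on small data", {
  set.seed(61)
  n <- 45
  rows <- data.frame(ldist = rnorm(n), days = runif(n, 100, 500))
  eta <- 0.4 - 1.1 * rows$ldist + 0.004 * rows$days
  rows$detected <- rbinom(n, 1, plogis(eta))
  fit <- fit_detection_glm(rows, "presence", c("ldist", "days"))
  X <- cbind(1, rows$ldist, rows$days)
  oracle <- logit_mle(X, rows$detected)
  expect_equal(unname(coef(fit$model)), oracle, tolerance = 1e-5)

  # gaussian stage against the normal equations
  rows$frac_days <- exp(rnorm(n, -2 - 0.5 * rows$ldist, 0.4))
  rows$frac_days <- pmin(rows$frac_days, 1)
  rows$detected <- 1L
  gfit <- fit_detection_glm(rows, "fraction", "ldist")
  Xg <- cbind(1, rows$ldist)
  beta_ls <- solve(crossprod(Xg), crossprod(Xg, log(rows$frac_days)))
  expect_equal(unname(coef(gfit$model)), drop(beta_ls), tolerance = 1e-8)
})

test_that("sequential deviances always add up to the null deviance", {
  rows <- sim_rows(seed = 21)
  for (terms in list("ldist", c("ldist", "habitat"),
                     c("days", "ldist", "habitat"))) {
    fit <- suppressWarnings(fit_detection_glm(rows, "presence", terms))
    expect_equal(sum(fit$anodev$deviance) + fit$resid_deviance,
                 fit$null_deviance, tolerance = 1e-8)
    expect_equal(fit$anodev$resid_dev[nrow(fit$anodev)], fit$resid_deviance,
                 tolerance = 1e-8)
  }
  gfit <- fit_detection_glm(rows, "fraction", c("ldist", "habitat"))
  expect_equal(sum(gfit$anodev$deviance) + gfit$resid_deviance,
               gfit$null_deviance, tolerance = 1e-8)
})

test_that("rank deficiency errors name the aliased column, separation warns", {
  rows <- sim_rows(seed = 22)
  rows$ldist2 <- 2 * rows$ldist
  expect_error(fit_detection_glm(rows, "presence", c("ldist", "ldist2")),
               "aliased.*ldist2")

  # perfectly separated response
  sep <- data.frame(ldist = c(-3, -2, -1, 1, 2, 3),
                    detected = c(1L, 1L, 1L, 0L, 0L, 0L))
  expect_warning(fit <- fit_detection_glm(sep, "presence", "ldist"),
                 "separation")
  expect_true(all(is.finite(fit$coefficients_regularised)))
})

test_that("percent deviance reproduces the reference shares", {
  expect_equal(percent_deviance(grmr_reference_table("presence"), "ldist"),
               158.43 / 700.62, tolerance = 1e-10)
  expect_equal(percent_deviance(grmr_reference_table("fraction"), "ldist"),
               211.33 / 582.06, tolerance = 1e-10)
  # a null model explains nothing
  rows <- data.frame(detected = rep(c(0L, 1L), 10), ldist = 0)
  null_fit <- fit_detection_glm(rows, "presence", "1")
  expect_equal(percent_deviance(null_fit, "anything"), 0)
})

test_that("the three-clause inclusion rule follows its truth table", {
  # non-significant term still enters when AIC improves
  d <- inclusion_decision(p_value = 0.11, percent_dev = 0.01,
                          delta_aic = -2.5, delta_bic = 1.0)
  expect_true(d$include)
  expect_match(d$rationale, "AIC")
  # significant but weak term with worse AIC and BIC stays out
  d2 <- inclusion_decision(p_value = 0.01, percent_dev = 0.01,
                           delta_aic = 0.5, delta_bic = 2.0)
  expect_false(d2$include)
  # significant and substantial term enters even when AIC/BIC worsen
  d3 <- inclusion_decision(p_value = 0.01, percent_dev = 0.05,
                           delta_aic = 0.5, delta_bic = 2.0)
  expect_true(d3$include)
  expect_match(d3$rationale, "significant")
})

test_that("sequential selection keeps the signal term and drops pure noise", {
  set.seed(8)
  rows <- sim_rows(seed = 23)
  rows$noise <- rnorm(nrow(rows))
  sel <- suppressWarnings(
    select_terms(rows, "presence", c("ldist", "noise"))
  )
  expect_true("ldist" %in% sel$terms)
  expect_false("noise" %in% sel$terms)
  expect_equal(nrow(sel$decisions), 2)
})

test_that("AIC selection breaks ties by declaration order and skips failed fits", {
  f1 <- structure(list(aic = 10, bic = 12), class = "shark_glm")
  f2 <- structure(list(aic = 10, bic = 11), class = "shark_glm")
  f3 <- structure(list(aic = 9, bic = 15, converged = FALSE),
                  class = "shark_glmm")
  expect_message(sel <- select_aic(list(a = f1, b = f2, bad = f3)),
                 "non-converged")
  expect_equal(sel$name, "a")
  expect_equal(sel$table$delta_aic, c(0, 0))
})

test_that("mixed fits collapse to the fixed-effects fit without group structure", {
  set.seed(91)
  n_shark <- 12; n_rec <- 10
  rows <- expand.grid(shark_id = sprintf("S%02d", 1:n_shark),
                      receiver_id = sprintf("R%02d", 1:n_rec),
                      stringsAsFactors = FALSE)
  rows$ldist <- rep(runif(n_rec, -3, 3), each = n_shark)
  rows$detected <- rbinom(nrow(rows), 1, plogis(0.5 - 0.9 * rows$ldist))
  glmm <- fit_detection_glmm(rows, "presence", "ldist", "shark")
  glm_fit <- fit_detection_glm(rows, "presence", "ldist")
  expect_lt(glmm$ranef_sd[[grep("Intercept", names(glmm$ranef_sd))]], 0.2)
  expect_equal(unname(glmm$fixef), unname(coef(glm_fit$model)),
               tolerance = 1e-2)
})

test_that("mixed fits recover a known shark random-intercept SD", {
  set.seed(14)
  ests <- replicate(6, {
    n_shark <- 30; n_rec <- 20
    re <- rnorm(n_shark, 0, 1)
    rows <- expand.grid(shark = 1:n_shark, rec = 1:n_rec)
    rows$shark_id <- sprintf("S%02d", rows$shark)
    rows$ldist <- runif(n_rec, -3, 3)[rows$rec]
    rows$detected <- rbinom(nrow(rows), 1,
                            plogis(0.3 - 0.8 * rows$ldist + re[rows$shark]))
    fit <- fit_detection_glmm(rows, "presence", "ldist", "shark")
    fit$ranef_sd[[grep("Intercept", names(fit$ranef_sd))[1]]]
  })
  expect_gt(mean(ests), 0.7)
  expect_lt(mean(ests), 1.3)
})

test_that("random ldist slopes by shark are expressible", {
  rows <- sim_rows(seed = 24)
  fit <- suppressWarnings(
    fit_detection_glmm(rows, "presence", c("ldist", "habitat"), "ldist|shark"))
  expect_s3_class(fit, "shark_glmm")
  expect_true("ldist" %in% names(fit$ranef_sd) ||
                any(grepl("ldist", names(fit$ranef_sd))))
})

test_that("the delta combination multiplies the two stages with bias correction", {
  # pi = 1 and a degenerate lognormal at log(0.5) combine to 0.5
  rows <- data.frame(detected = rep(1L, 20), ldist = rnorm(20))
  rows$frac_days <- 0.5
  pfit <- suppressWarnings(fit_detection_glm(rows, "presence", "1"))
  ffit <- suppressWarnings(fit_detection_glm(rows, "fraction", "1"))
  ef <- suppressWarnings(combine_delta(pfit, ffit, rows))
  expect_equal(as.numeric(ef), rep(0.5, 20), tolerance = 1e-6)

  # pi = 0 forces a zero expectation
  rows0 <- rows
  rows0$detected <- 0L
  pfit0 <- suppressWarnings(fit_detection_glm(rows0, "presence", "1"))
  expect_equal(max(suppressWarnings(combine_delta(pfit0, ffit, rows0))), 0,
               tolerance = 1e-6)

  # bias correction inflates by exp(sigma^2 / 2); clipping is counted
  set.seed(6)
  rows$frac_days <- pmin(exp(rnorm(20, -0.1, 0.8)), 1)
  ffit2 <- fit_detection_glm(rows, "fraction", "1")
  ef_bc <- combine_delta(pfit, ffit2, rows)
  ef_raw <- combine_delta(pfit, ffit2, rows, bias_correct = FALSE)
  expect_true(all(ef_bc >= ef_raw - 1e-12))
  expect_gte(attr(ef_bc, "n_clipped"), 0)
})

test_that("fitted detection probability declines with distance and the expected
           fraction beyond 1 km is small on generator-default-like data", {
  sim <- simulate_telemetry(telemetry_sim_config(
    n_sharks = 25, study_start = "2005-05-01", study_end = "2006-11-01",
    seed = 42))
  pres <- daily_presence(build_strings(sim$detections), sim$tags, sim$receivers)
  rows <- build_summary(pres)
  pfit <- fit_detection_glm(rows, "presence", "ldist")
  ffit <- fit_detection_glm(rows, "fraction", "ldist")
  expect_lt(coef(pfit$model)[["ldist"]], 0)
  grid <- data.frame(ldist = log(c(1, 2, 5, 10, 20)))
  probs <- predict(pfit$model, newdata = grid, type = "response")
  expect_true(all(diff(probs) < 0)) # strictly decreasing in distance
  expect_true(all(combine_delta(pfit, ffit, grid) < 0.10))
})

test_that("presence prediction rounds at 0.5 with ties counted present", {
  rows <- data.frame(detected = rep(0L, 10), ldist = rnorm(10))
  pfit <- suppressWarnings(fit_detection_glm(rows, "presence", "1"))
  pred <- predict_presence(pfit, rows)
  expect_equal(pred$accuracy, 1) # all-absent data, near-zero probabilities
  expect_equal(sum(pred$confusion), 10)

  m <- matrix(c(3, 0, 0, 7), 2, 2)
  expect_equal(confusion_accuracy(m), 1)
  # a fitted probability exactly at threshold counts as present
  even <- data.frame(detected = rep(c(0L, 1L), 8), ldist = 0)
  efit <- fit_detection_glm(even, "presence", "1")
  expect_equal(unname(predict_presence(efit, even)$confusion["present", ]),
               c(8L, 8L))
})
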