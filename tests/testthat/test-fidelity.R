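test_that("residency index is detected eligible days over eligible days", {
  tags <- mk_tags(tag_date = as.Date("2005-06-01"))
  rec <- mk_receivers() # operational 2005-05-01 .. 2006-05-01
  elig_span <- seq(as.Date("2005-06-01"), as.Date("2006-05-01"), by = "day")

  pres_all <- daily_presence(mk_strings(elig_span), tags, rec)
  expect_equal(residency_index(pres_all, "S01"), 1)

  pres_none <- daily_presence(mk_strings(as.Date(character())), tags, rec)
  expect_equal(residency_index(pres_none, "S01"), 0)

  # detections after battery expiry don't enter the numerator
  pres_px <- daily_presence(
    mk_strings(c(elig_span[1:10], as.Date("2006-07-01"))),
    tags, mk_receivers(op_end = as.Date("2006-12-31"))
  )
  expect_equal(residency_index(pres_px, "S01"), 10 / 365)

  # zero eligible days is an error, not a zero
  tags_late <- mk_tags(tag_date = as.Date("2007-01-01"))
  pres_late <- daily_presence(mk_strings(as.Date(character())), tags_late, rec)
  expect_error(residency_index(pres_late, "S01"), "zero eligible days")
})

test_that("residency index is invariant to duplicated within-day detections", {
  tags <- mk_tags()
  rec <- mk_receivers(lat = c(16.75, 16.76))
  day <- as.Date("2005-06-10")
  one <- daily_presence(mk_strings(day), tags, rec)
  many <- daily_presence(rbind(mk_strings(day), mk_strings(day, at = "15:00:00"),
                               mk_strings(day, receiver = "R02")),
                         tags, rec)
  expect_equal(residency_index(one, "S01"), residency_index(many, "S01"))
})

test_that("minimum linear dispersal is the brute-force pairwise maximum", {
  tags <- mk_tags()
  rec3 <- mk_receivers(lat = c(0, 0, 0), lon = c(0, 0.01, 0.02))
  tags$tag_lat <- 0
  tags$tag_lon <- 0
  pres <- daily_presence(rbind(mk_strings(as.Date("2005-06-01"), "R01"),
                               mk_strings(as.Date("2005-06-02"), "R02"),
                               mk_strings(as.Date("2005-06-03"), "R03")),
                         tags, rec3)
  expect_equal(minimum_linear_dispersal(pres, "S01"),
               haversine_km(0, 0, 0, 0.02), tolerance = 1e-9)
  expect_equal(minimum_linear_dispersal(pres, "S01"), 2.224, tolerance = 1e-3)

  # single receiver: zero by definition
  pres1 <- daily_presence(mk_strings(as.Date("2005-06-01")), tags, rec3)
  expect_equal(minimum_linear_dispersal(pres1, "S01"), 0)

  # oracle: exhaustive pair loop over random arrays
  set.seed(77)
  for (rep in 1:5) {
    n <- sample(3:8, 1)
    rec <- mk_receivers(lat = 16.7 + runif(n, 0, 0.3),
                        lon = -87.9 + runif(n, 0, 0.3))
    visited <- sample(rec$receiver_id, sample(2:n, 1))
    strings <- do.call(rbind, lapply(seq_along(visited), function(i) {
      mk_strings(as.Date("2005-06-01") + i, receiver = visited[i])
    }))
    pres_r <- daily_presence(strings, tags, rec)
    oracle <- 0
    sub <- rec[rec$receiver_id %in% visited, ]
    for (i in seq_len(nrow(sub))) {
      for (j in seq_len(nrow(sub))) {
        oracle <- max(oracle, haversine_km(sub$lat[i], sub$lon[i],
                                           sub$lat[j], sub$lon[j]))
      }
    }
    expect_equal(minimum_linear_dispersal(pres_r, "S01"), oracle)
    # invariant to visit frequency: revisit every receiver
    pres_2x <- daily_presence(rbind(strings, transform(strings,
                                                       start = start + 86400 * 30,
                                                       end = end + 86400 * 30)),
                              tags, rec)
    expect_equal(minimum_linear_dispersal(pres_2x, "S01"), oracle)
  }
})

test_that("an undetected receiver changes no fidelity metric", {
  tags <- mk_tags()
  rec <- mk_receivers(lat = c(16.75, 16.80))
  strings <- mk_strings(seq(as.Date("2005-06-01"), by = "day", length.out = 20))
  pres <- daily_presence(strings, tags, rec)
  rec_plus <- rbind(rec, mk_receivers(lat = 16.9)[1, ])
  rec_plus$receiver_id[3] <- "R99"
  pres_plus <- daily_presence(strings, tags, rec_plus)
  expect_equal(fidelity_table(pres)[, -(1:6)], fidelity_table(pres_plus)[, -(1:6)],
               ignore_attr = TRUE)
})

test_that("monitoring duration runs from tagging to the last string, expiry or not", {
  tags <- mk_tags(tag_date = as.Date("2005-05-24"))
  rec <- mk_receivers(op_end = as.Date("2007-05-01"))
  pres <- daily_presence(mk_strings(as.Date(c("2005-05-24", "2006-12-29"))),
                         tags, rec)
  expect_equal(monitoring_duration(pres, "S01"), 584) # ~19 months, post-expiry

  pres0 <- daily_presence(mk_strings(as.Date("2005-05-24")), tags, rec)
  expect_equal(monitoring_duration(pres0, "S01"), 0)

  pres_none <- daily_presence(mk_strings(as.Date(character())), tags, rec)
  expect_error(monitoring_duration(pres_none, "S01"), "never detected")
})

test_that("monthly occurrence bins use the reported class boundaries", {
  expect_equal(as.character(occurrence_bin(c(0, 1, 7, 8, 14, 15, 30))),
               c("none", "1-7", "1-7", "8-14", "8-14", ">14", ">14"))
  tags <- mk_tags()
  rec <- mk_receivers()
  days <- c(seq(as.Date("2005-06-01"), by = "day", length.out = 7),
            seq(as.Date("2005-07-01"), by = "day", length.out = 20))
  mo <- monthly_occurrence(daily_presence(mk_strings(days), tags, rec))
  expect_equal(mo$days[mo$month == "2005-06"], 7L)
  expect_equal(as.character(mo$bin[mo$month == "2005-06"]), "1-7")
  expect_equal(as.character(mo$bin[mo$month == "2005-07"]), ">14")
})

test_that("mean residency recovers the generating daily detection rate", {
  # with per-day detection probability p over E eligible days, E[RI] = p
  tags <- mk_tags(tag_date = as.Date("2005-05-01"))
  rec <- mk_receivers(op_end = as.Date("2006-06-01")) # covers full battery
  elig <- seq(as.Date("2005-05-01"), by = "day", length.out = 365)
  p <- 0.3
  set.seed(123)
  ris <- replicate(200, {
    hit <- elig[runif(365) < p]
    pres <- daily_presence(mk_strings(hit), tags, rec)
    residency_index(pres, "S01")
  })
  se <- sqrt(p * (1 - p) / 365) / sqrt(200)
  expect_lt(abs(mean(ris) - p), 3 * se)
  expect_true(all(ris >= 0 & ris <= 1))
})

test_that("group summaries and size regressions behave on trivial input", {
  one <- data.frame(tag_type = "V9", ri = 0.4, mld_km = 3, n_days = 10,
                    dur_days = 50, total_length_cm = 120)
  s <- fidelity_summary(one)
  expect_equal(s$mean[s$group == "all" & s$metric == "ri"], 0.4)
  expect_equal(s$mean[s$group == "V9" & s$metric == "mld_km"], 3)

  # exactly linear response: r^2 = 1
  lin <- data.frame(total_length_cm = c(100, 120, 140, 160),
                    ri = 0.1 + 0.002 * c(100, 120, 140, 160))
  expect_equal(suppressWarnings(size_regression(lin, "ri")$r_squared), 1)

  flat <- data.frame(total_length_cm = rep(100, 5), ri = runif(5))
  expect_error(size_regression(flat, "ri"), "zero variance")
  expect_error(size_regression(lin[1:2, ], "ri"), "at least 3")
})
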