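# Builders for minimal in-memory fixtures; all test data is generated in code.

mk_tags <- function(n = 1, tag_date = as.Date("2005-06-01"), tag_type = "V9",
                    attachment = "internal", lat = 16.75, lon = -87.80) {
  data.frame(
    shark_id = sprintf("S%02d", seq_len(n)),
    transmitter_id = sprintf("T%02d", seq_len(n)),
    tag_type = tag_type,
    battery_days = ifelse(tag_type == "V9", 365L, 540L),
    attachment = attachment,
    tag_date = tag_date, sex = "F", total_length_cm = 100,
    maturity = "juvenile", tagging_site_label = "X",
    tag_lat = lat, tag_lon = lon, stringsAsFactors = FALSE
  )
}

mk_receivers <- function(lat = 16.75, lon = -87.80, habitat = "ocean_reef",
                         op_start = as.Date("2005-05-01"),
                         op_end = as.Date("2006-05-01")) {
  n <- max(length(lat), length(lon))
  data.frame(
    receiver_id = sprintf("R%02d", seq_len(n)),
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    habitat = rep_len(habitat, n), depth_m = 20,
    op_start = op_start, op_end = op_end, stringsAsFactors = FALSE
  )
}

# a detection log from offsets (seconds) relative to an origin instant
mk_detections <- function(times_s, receiver = "R01", transmitter = "T01",
                          origin = as.POSIXct("2005-06-01 00:00:00", tz = "UTC")) {
  data.frame(timestamp = origin + times_s,
             receiver_id = rep_len(receiver, length(times_s)),
             transmitter_id = rep_len(transmitter, length(times_s)),
             stringsAsFactors = FALSE)
}

# one two-detection string per date, so daily presence is exactly `dates`
mk_strings <- function(dates, receiver = "R01", transmitter = "T01",
                       at = "12:00:00") {
  if (length(dates) == 0) {
    return(data.frame(receiver_id = character(), transmitter_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_detections = integer(), max_gap_s = numeric(),
                      stringsAsFactors = FALSE))
  }
  start <- as.POSIXct(paste(dates, at), tz = "UTC")
  data.frame(receiver_id = rep_len(receiver, length(dates)),
             transmitter_id = transmitter,
             start = start, end = start + 300, n_detections = 2L,
             max_gap_s = 300, stringsAsFactors = FALSE)
}

small_telemetry_cfg <- function(...) {
  telemetry_sim_config(
    n_sharks = 8, habitat_mix = c(ocean_reef = 8, deep_lagoon = 2,
                                  shallow_lagoon = 2),
    study_start = "2005-05-01", study_end = "2006-05-01", ...
  )
}

# independent maximum-likelihood oracle: BFGS on the hand-coded
# log-likelihood, nothing shared with glm's IRLS path
logit_mle <- function(X, y) {
  nll <- function(b) {
    eta <- drop(X %*% b)
    sum(log1p(exp(eta))) - sum(y * eta)
  }
  grad <- function(b) drop(crossprod(X, plogis(drop(X %*% b)) - y))
  optim(rep(0, ncol(X)), nll, grad, method = "BFGS",
        control = list(maxit = 500, reltol = 1e-15))$par
}
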