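# Detection-string QC and daily presence. Single isolated pings are the
# classic acoustic-telemetry false positive (signal collisions, background
# noise), so only runs of >= 2 closely spaced detections of one transmitter at
# one receiver are carried downstream.

#' Group raw detections into detection strings
#'
#' Sorts the log by receiver, transmitter and time, then groups consecutive
#' detections of the same (receiver, transmitter) pair whose inter-detection
#' gap is at most `string_gap_s` seconds. Groups of size one (isolated pings)
#' are discarded and counted.
#'
#' The default gap of 720 s is twice the 360 s maximum nominal transmitter
#' delay, so a string survives one missed pulse.
#'
#' @param detections Detection `data.frame` ([read_detections()]); any order.
#' @param string_gap_s Maximum within-string inter-detection gap, seconds (> 0).
#' @return A `data.frame` with one row per string: `receiver_id`,
#'   `transmitter_id`, `start`, `end`, `n_detections` (>= 2), `max_gap_s`
#'   (largest internal gap; 0 s never occurs since n >= 2 implies >= 1 gap).
#'   Attribute `n_singletons` counts discarded isolated detections.
#' @export
build_strings <- function(detections, string_gap_s = 720) {
  stopifnot(is.numeric(string_gap_s), string_gap_s > 0)
  empty <- data.frame(receiver_id = character(), transmitter_id = character(),
                      start = as.POSIXct(character(), tz = "UTC"),
                      end = as.POSIXct(character(), tz = "UTC"),
                      n_detections = integer(), max_gap_s = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(detections) == 0) return(structure(empty, n_singletons = 0L))
  d <- detections[order(detections$receiver_id, detections$transmitter_id,
                        detections$timestamp), , drop = FALSE]
  pair <- paste(d$receiver_id, d$transmitter_id, sep = "\r")
  gap <- c(Inf, as.numeric(difftime(d$timestamp[-1],
                                    d$timestamp[-nrow(d)], units = "secs")))
  new_string <- pair != c("", pair[-length(pair)]) | gap > string_gap_s
  sid <- cumsum(new_string)
  idx <- split(seq_len(nrow(d)), sid)
  sizes <- lengths(idx)
  keep <- idx[sizes >= 2]
  n_singletons <- sum(sizes == 1)
  if (length(keep) == 0) return(structure(empty, n_singletons = n_singletons))
  first <- vapply(keep, `[`, integer(1), 1L)
  last <- vapply(keep, function(i) i[length(i)], integer(1))
  out <- data.frame(
    receiver_id = d$receiver_id[first],
    transmitter_id = d$transmitter_id[first],
    start = d$timestamp[first],
    end = d$timestamp[last],
    n_detections = as.integer(last - first + 1L),
    max_gap_s = vapply(keep, function(i) max(gap[i[-1]]), numeric(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, n_singletons = n_singletons)
}

#' Flag candidate signal-collision artifacts
#'
#' When three or more transmitters are heard at one receiver within a short
#' window, overlapping pulse trains can fabricate detections of a third
#' transmitter. The screening logic: examine only receiver-time neighbourhoods
#' with at least three simultaneous transmitters, and flag any string there
#' whose largest internal gap exceeds `collision_lag_factor` times the nominal
#' maximum transmitter delay — an unusually long lag given the transmission
#' rate. A clean dataset yields an empty report.
#'
#' @param strings String table from [build_strings()].
#' @param simultaneity_window_s Padding (seconds) around a string within which
#'   other transmitters count as simultaneous.
#' @param collision_lag_factor Multiplier on `nominal_max_delay_s` above which
#'   an internal gap is deemed suspicious.
#' @param nominal_max_delay_s Maximum nominal transmitter delay, seconds.
#' @return A `data.frame` of flagged strings (possibly zero rows) with the
#'   [build_strings()] columns plus `n_transmitters` (distinct transmitters in
#'   the examined window). Attribute `n_examined` counts strings that were in
#'   >= 3-transmitter windows.
#' @export
flag_collisions <- function(strings, simultaneity_window_s = 600,
                            collision_lag_factor = 2,
                            nominal_max_delay_s = 360) {
  stopifnot(simultaneity_window_s > 0, collision_lag_factor > 0,
            nominal_max_delay_s > 0)
  out <- cbind(strings[0, , drop = FALSE], n_transmitters = integer())
  n_examined <- 0L
  for (rid in unique(strings$receiver_id)) {
    s <- strings[strings$receiver_id == rid, , drop = FALSE]
    if (length(unique(s$transmitter_id)) < 3) next
    lo <- as.numeric(s$start) - simultaneity_window_s
    hi <- as.numeric(s$end) + simultaneity_window_s
    for (i in seq_len(nrow(s))) {
      ov <- as.numeric(s$start) <= hi[i] & as.numeric(s$end) >= lo[i]
      n_trans <- length(unique(s$transmitter_id[ov]))
      if (n_trans < 3) next
      n_examined <- n_examined + 1L
      if (s$max_gap_s[i] > collision_lag_factor * nominal_max_delay_s) {
        out <- rbind(out, cbind(s[i, , drop = FALSE],
                                n_transmitters = n_trans))
      }
    }
  }
  rownames(out) <- NULL
  structure(out, n_examined = n_examined)
}

#' Reduce detection strings to daily presence with eligibility
#'
#' The day-scale substrate every downstream analysis consumes: which sharks
#' were detected at which receivers on which dates, plus a per-shark
#' eligibility mask. A date is *eligible* for a shark when its transmitter is
#' within battery life (`tag_date` through `tag_date + battery_days - 1`) and
#' at least one receiver in the array is operational. Detections outside the
#' eligibility window (e.g. after nominal battery expiry) are retained —
#' monitoring duration uses them — but are excluded from the residency index.
#'
#' @param strings String table from [build_strings()].
#' @param tags Tag table ([read_tags()]); transmitter ids in `strings` must
#'   resolve here.
#' @param receivers Receiver table ([read_receivers()]).
#' @return An object of class `daily_presence`: a list with `days` (distinct
#'   detected shark x receiver x date rows), `tags`, `receivers` and
#'   `array_dates` (dates with >= 1 operational receiver). Sharks with no
#'   strings are still representable (all-zero rows are implicit).
#' @export
daily_presence <- function(strings, tags, receivers) {
  unknown <- setdiff(strings$transmitter_id, tags$transmitter_id)
  if (length(unknown) > 0) {
    stop("strings reference unknown transmitter id(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unknown_r <- setdiff(strings$receiver_id, receivers$receiver_id)
  if (length(unknown_r) > 0) {
    stop("strings reference unknown receiver id(s): ",
         paste(unknown_r, collapse = ", "), call. = FALSE)
  }
  shark_of <- setNames(tags$shark_id, tags$transmitter_id)
  if (nrow(strings) > 0) {
    d0 <- as.Date(strings$start, tz = "UTC")
    d1 <- as.Date(strings$end, tz = "UTC")
    span <- as.integer(d1 - d0)
    # strings overlapping midnight contribute presence to every date spanned
    reps <- span + 1L
    days <- data.frame(
      shark_id = rep(shark_of[strings$transmitter_id], reps),
      receiver_id = rep(strings$receiver_id, reps),
      date = rep(d0, reps) + sequence(reps) - 1L,
      stringsAsFactors = FALSE
    )
    days <- unique(days)
    rownames(days) <- NULL
  } else {
    days <- data.frame(shark_id = character(), receiver_id = character(),
                       date = as.Date(character()), stringsAsFactors = FALSE)
  }
  span_lo <- min(receivers$op_start)
  span_hi <- max(receivers$op_end)
  all_dates <- seq(span_lo, span_hi, by = "day")
  covered <- rep(FALSE, length(all_dates))
  for (i in seq_len(nrow(receivers))) {
    covered <- covered | (all_dates >= receivers$op_start[i] &
                            all_dates <= receivers$op_end[i])
  }
  structure(
    list(days = days, tags = tags, receivers = receivers,
         array_dates = all_dates[covered]),
    class = "daily_presence"
  )
}

#' @export
print.daily_presence <- function(x, ...) {
  cat("daily_presence:", length(unique(x$days$shark_id)), "shark(s) detected,",
      nrow(x$days), "shark x receiver x day record(s),",
      length(x$array_dates), "array-operational day(s)\n")
  invisible(x)
}

tag_row <- function(presence, shark_id) {
  row <- presence$tags[presence$tags$shark_id == shark_id, , drop = FALSE]
  if (nrow(row) == 0) stop("unknown shark_id '", shark_id, "'", call. = FALSE)
  row
}

#' Eligible dates for one shark
#'
#' Dates on which the shark could have been detected: transmitter within
#' battery life and at least one receiver operational.
#'
#' @param presence A [daily_presence()] object.
#' @param shark_id Single shark id.
#' @return A `Date` vector (possibly empty).
#' @export
eligible_dates <- function(presence, shark_id) {
  row <- tag_row(presence, shark_id)
  window <- seq(row$tag_date, by = "day", length.out = row$battery_days)
  window[window %in% presence$array_dates]
}

#' Dates with a detection anywhere in the array for one shark
#'
#' @inheritParams eligible_dates
#' @param eligible_only If `TRUE`, restrict to eligible dates (battery window
#'   and array uptime); post-expiry detections are retained when `FALSE`.
#' @return A sorted `Date` vector.
#' @export
detected_dates <- function(presence, shark_id, eligible_only = FALSE) {
  det <- sort(unique(presence$days$date[presence$days$shark_id == shark_id]))
  if (eligible_only) det <- det[det %in% eligible_dates(presence, shark_id)]
  det
}
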