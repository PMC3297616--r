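# Per-shark site-fidelity metrics and their body-size regressions.

#' Residency index for one shark
#'
#' RI = (eligible days with a detection anywhere in the array) / (eligible
#' days), where an eligible day has the transmitter within battery life and at
#' least one receiver operational. Detections after nominal battery expiry are
#' excluded from the numerator. A shark detected every eligible day scores 1;
#' a never-detected shark scores 0.
#'
#' @param presence A [daily_presence()] object.
#' @param shark_id Single shark id.
#' @return RI in `[0, 1]`.
#' @export
residency_index <- function(presence, shark_id) {
  elig <- eligible_dates(presence, shark_id)
  if (length(elig) == 0) {
    stop("residency index undefined for shark '", shark_id,
         "': zero eligible days", call. = FALSE)
  }
  det <- detected_dates(presence, shark_id, eligible_only = TRUE)
  length(det) / length(elig)
}

#' Minimum linear dispersal for one shark
#'
#' The greatest great-circle distance between any two receivers at which the
#' shark was ever detected — a lower bound on linear range extent. Zero when
#' the shark was detected at one receiver or none; invariant to visit order
#' and frequency (set semantics over visited receivers).
#'
#' @inheritParams residency_index
#' @param receivers Optional receiver table; defaults to the one embedded in
#'   `presence`.
#' @return Distance in kilometres.
#' @export
minimum_linear_dispersal <- function(presence, shark_id, receivers = NULL) {
  if (is.null(receivers)) receivers <- presence$receivers
  visited <- unique(presence$days$receiver_id[presence$days$shark_id == shark_id])
  if (length(visited) <= 1) return(0)
  coords <- unique(receivers[receivers$receiver_id %in% visited,
                             c("receiver_id", "lat", "lon")])
  pairs <- utils::combn(nrow(coords), 2)
  max(haversine_km(coords$lat[pairs[1, ]], coords$lon[pairs[1, ]],
                   coords$lat[pairs[2, ]], coords$lon[pairs[2, ]]))
}

#' Monitoring duration for one shark
#'
#' Whole days elapsed between the tagging date and the date of the last
#' detection string, post-expiry detections included (transmitters often
#' outlive their nominal battery life).
#'
#' @inheritParams residency_index
#' @return Integer days (0 if the last detection fell on the tag date).
#' @export
monitoring_duration <- function(presence, shark_id) {
  det <- detected_dates(presence, shark_id)
  if (length(det) == 0) {
    stop("monitoring duration undefined for shark '", shark_id,
         "': never detected", call. = FALSE)
  }
  row <- tag_row(presence, shark_id)
  as.integer(max(det) - row$tag_date)
}

#' Per-shark fidelity metrics table
#'
#' One row per detected shark: days detected anywhere (`n_days`, all detected
#' days including post-expiry), monitoring duration (`dur_days`), minimum
#' linear dispersal (`mld_km`), residency index (`ri`) and the eligible-day
#' denominator. Never-detected sharks are excluded (their RI is 0 but MLD and
#' duration are undefined); their count is kept in attribute `n_undetected`.
#'
#' @param presence A [daily_presence()] object.
#' @return A `data.frame` of metrics joined to tag biology columns.
#' @export
fidelity_table <- function(presence) {
  detected_ids <- unique(presence$days$shark_id)
  sharks <- presence$tags[presence$tags$shark_id %in% detected_ids, ,
                          drop = FALSE]
  metrics <- lapply(sharks$shark_id, function(id) {
    data.frame(
      shark_id = id,
      n_days = length(detected_dates(presence, id)),
      dur_days = monitoring_duration(presence, id),
      mld_km = minimum_linear_dispersal(presence, id),
      ri = residency_index(presence, id),
      eligible_days = length(eligible_dates(presence, id)),
      stringsAsFactors = FALSE
    )
  })
  out <- merge(
    sharks[, c("shark_id", "tag_type", "attachment", "sex",
               "total_length_cm", "tag_date")],
    do.call(rbind, metrics), by = "shark_id"
  )
  rownames(out) <- NULL
  structure(out,
            n_undetected = sum(!presence$tags$shark_id %in% detected_ids))
}

#' Group summaries of fidelity metrics
#'
#' Mean, standard deviation and range of each metric over detected sharks,
#' overall and by group (transmitter type by default). Works on
#' [fidelity_table()] output or on the packaged reference summaries
#' ([grmr_monitoring()]); any of the metric columns may be absent.
#'
#' @param metrics A `data.frame` with some of `ri`, `mld_km`, `n_days`,
#'   `dur_days`, plus the grouping column.
#' @param group Grouping column name (`NULL` for overall only).
#' @return A long `data.frame`: `group`, `metric`, `n`, `mean`, `sd`, `min`,
#'   `max`. The overall rollup uses group label `"all"`.
#' @export
fidelity_summary <- function(metrics, group = "tag_type") {
  metric_cols <- intersect(c("ri", "mld_km", "n_days", "dur_days"),
                           names(metrics))
  if (length(metric_cols) == 0) stop("no metric columns found", call. = FALSE)
  groups <- list(all = rep(TRUE, nrow(metrics)))
  if (!is.null(group)) {
    for (g in sort(unique(metrics[[group]]))) {
      groups[[as.character(g)]] <- metrics[[group]] == g
    }
  }
  rows <- list()
  for (gname in names(groups)) {
    sub <- metrics[groups[[gname]], , drop = FALSE]
    for (m in metric_cols) {
      v <- sub[[m]]
      rows[[length(rows) + 1L]] <- data.frame(
        group = gname, metric = m, n = length(v), mean = mean(v),
        sd = if (length(v) > 1) sd(v) else NA_real_,
        min = min(v), max = max(v), stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Monthly occurrence bins
#'
#' Days detected per shark per calendar month, binned into the standard
#' occurrence-plot classes: `none`, `1-7`, `8-14`, `>14` days. Counts are
#' total days per month, not consecutive days.
#'
#' @param presence A [daily_presence()] object.
#' @param eligible_only Restrict to eligible detection days?
#' @return A `data.frame`: `shark_id`, `month` (`"YYYY-MM"`), `days`, `bin`
#'   (ordered factor). Months without detections are omitted except through
#'   [occurrence_bin()], which maps 0 to `"none"`.
#' @export
monthly_occurrence <- function(presence, eligible_only = FALSE) {
  ids <- unique(presence$days$shark_id)
  rows <- lapply(ids, function(id) {
    det <- detected_dates(presence, id, eligible_only = eligible_only)
    if (length(det) == 0) return(NULL)
    tab <- table(format(det, "%Y-%m"))
    data.frame(shark_id = id, month = names(tab),
               days = as.integer(tab), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(shark_id = character(), month = character(),
                      days = integer(), stringsAsFactors = FALSE)
  }
  out$bin <- occurrence_bin(out$days)
  rownames(out) <- NULL
  out
}

#' Bin a days-per-month count into occurrence classes
#' @param days Integer vector of days detected in a month.
#' @return Ordered factor with levels `none`, `1-7`, `8-14`, `>14`.
#' @export
occurrence_bin <- function(days) {
  cut(days, breaks = c(-Inf, 0, 7, 14, Inf),
      labels = c("none", "1-7", "8-14", ">14"), ordered_result = TRUE)
}

#' Linear regression of a fidelity metric on body size
#'
#' Ordinary least squares of RI or MLD on total length, the standard test for
#' an ontogenetic shift in residency or range extent.
#'
#' @param metrics A `data.frame` containing the response column and
#'   `total_length_cm` (e.g. [fidelity_table()] or [grmr_monitoring()]).
#' @param response `"ri"` or `"mld_km"`.
#' @return A list: `slope`, `intercept`, `r_squared`, `n`, and the underlying
#'   `lm` fit (`model`).
#' @export
size_regression <- function(metrics, response = c("ri", "mld_km")) {
  response <- match.arg(response)
  d <- metrics[is.finite(metrics[[response]]) &
                 is.finite(metrics$total_length_cm), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 sharks with a defined metric",
                        call. = FALSE)
  if (var(d$total_length_cm) == 0) {
    stop("degenerate design: zero variance in total_length_cm", call. = FALSE)
  }
  fit <- lm(as.formula(paste(response, "~ total_length_cm")), data = d)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = nrow(d), model = fit)
}
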