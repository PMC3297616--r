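# Packaged reference data from the GRMR Caribbean reef shark monitoring study
# (Glover's Reef Marine Reserve, Belize, 2004-2008) and the four-site BRUV
# survey of the Mesoamerican Barrier Reef. Only quantities printed in the
# study's summary tables are carried; the raw detection logs were never made
# public, so pipeline-level tests run on synthetic logs instead (see
# simulate_telemetry()).

rt_extdata <- function(file) {
  system.file("extdata", file, package = "reeftrace", mustWork = TRUE)
}

#' Reference tag deployments: 33 Caribbean reef sharks at Glover's Reef
#'
#' The tag-deployment table for the 33 sharks (of 34 tagged; one was never
#' detected and has no published record) acoustically monitored at Glover's
#' Reef Marine Reserve, Belize, 2004-2008. Transmitter type, battery life,
#' attachment mode, tagging date, sex and total length are as published.
#' Two columns are reconstructions, not published values: `tag_lat`/`tag_lon`
#' are approximate centroids of the labelled tagging sites (the study reported
#' site labels only), and `maturity` is assigned from the length cut-offs in
#' [assign_maturity()] chosen to reproduce the reported maturity counts
#' (2 mature females, 6 mature males).
#'
#' @return A validated tag `data.frame` (see [read_tags()]).
#' @export
grmr_tags <- function() {
  read_tags(rt_extdata("grmr_tags.csv"))
}

#' Reference monitoring summaries for the Glover's Reef sharks
#'
#' Per-shark monitoring metrics as published for the 33 detected sharks:
#' `n_days` (days with a detection anywhere in the array), `dur_days`
#' (monitoring duration, tagging to last detection), `mld_km` (minimum linear
#' dispersal) and `ri` (residency index, printed to two decimals), joined to
#' the biology columns of [grmr_tags()]. This is the substrate for the
#' fidelity summary statistics and the body-size regressions.
#'
#' @return A `data.frame` with one row per detected shark.
#' @export
grmr_monitoring <- function() {
  metrics <- read.csv(rt_extdata("grmr_monitoring.csv"), stringsAsFactors = FALSE)
  tags <- grmr_tags()
  out <- merge(tags[, c("shark_id", "tag_type", "attachment", "tag_date", "sex",
                        "total_length_cm", "tagging_site_label")],
               metrics, by = "shark_id")
  out[order(match(out$shark_id, metrics$shark_id)), , drop = FALSE]
}

#' Reference analysis-of-deviance and confusion tables
#'
#' The published sequential analysis-of-deviance tables from the GRMR
#' detection study, in the layout produced by [fit_detection_glm()] (a `NULL`
#' row carrying the null deviance followed by one row per term):
#' `"presence"` (binomial any-detection model: days, ldist, shark type,
#' habitat), `"fraction"` (lognormal fraction-of-days model: ldist, habitat,
#' interaction) and `"monthly"` (month-scale retention model: sharkmonth,
#' taglife). `"confusion_best"` and `"confusion_reduced"` are the published
#' observed-vs-predicted confusion matrices for the best and the
#' days+ldist-only presence models, as 2x2 matrices.
#'
#' @param table One of `"presence"`, `"fraction"`, `"monthly"`,
#'   `"confusion_best"`, `"confusion_reduced"`.
#' @return A `data.frame` (deviance tables) or 2x2 `matrix` (confusion tables).
#' @export
grmr_reference_table <- function(table = c("presence", "fraction", "monthly",
                                           "confusion_best", "confusion_reduced")) {
  table <- match.arg(table)
  if (startsWith(table, "confusion")) {
    df <- read.csv(rt_extdata(paste0("grmr_", table, ".csv")),
                   stringsAsFactors = FALSE)
    m <- as.matrix(df[, c("observed_absent", "observed_present")])
    dimnames(m) <- list(predicted = df$predicted,
                        observed = c("absent", "present"))
    return(m)
  }
  file <- switch(table,
                 presence = "grmr_presence_anodev.csv",
                 fraction = "grmr_fraction_anodev.csv",
                 monthly = "grmr_monthly_anodev.csv")
  read.csv(rt_extdata(file), stringsAsFactors = FALSE)
}

#' Reference per-site BRUV presence counts
#'
#' Per-site deployment, presence and multi-individual counts for the 200
#' baited-video deployments across the four Mesoamerican Barrier Reef sites:
#' two marine reserves (GRMR, CCMR) and two fished reefs (TU, SWC), 50
#' deployments each. Expand to deployment level with [bruv_from_counts()].
#'
#' @return A `data.frame` with columns `site`, `reserve`, `n_deployments`,
#'   `n_present`, `n_multi`.
#' @export
grmr_bruv_counts <- function() {
  df <- read.csv(rt_extdata("grmr_bruv_counts.csv"), stringsAsFactors = FALSE)
  df$reserve <- as.logical(toupper(df$reserve))
  df
}

#' Expand per-site presence counts to deployment-level records
#'
#' Reconstructs a minimal deployment table from per-site totals: each site
#' contributes `n_present` present rows (`nmax = 1`, or 2 for the first
#' `n_multi` of them) and `n_deployments - n_present` absent rows.
#' Environmental covariates are not reconstructable from counts and are `NA`.
#' Sufficient for presence/absence modelling and the area-proportional
#' bootstrap, which use only `site`, `reserve` and `presence`.
#'
#' @param counts A `data.frame` like [grmr_bruv_counts()] (columns `site`,
#'   `reserve`, `n_deployments`, `n_present`, optional `n_multi`).
#' @return A deployment-level `data.frame` with the [read_bruv()] columns.
#' @export
bruv_from_counts <- function(counts) {
  stopifnot(all(c("site", "reserve", "n_deployments", "n_present") %in%
                  names(counts)))
  if (any(counts$n_present > counts$n_deployments)) {
    stop("n_present exceeds n_deployments", call. = FALSE)
  }
  n_multi <- if ("n_multi" %in% names(counts)) counts$n_multi else
    rep(0L, nrow(counts))
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- counts$n_deployments[i]
    k <- counts$n_present[i]
    m <- min(n_multi[i], k)
    nmax <- c(rep(2L, m), rep(1L, k - m), rep(0L, n - k))
    data.frame(
      site = counts$site[i], reserve = counts$reserve[i],
      date = as.Date(NA), lat = NA_real_, lon = NA_real_, depth_m = NA_real_,
      flow_velocity = NA_real_, temp_start = NA_real_, temp_end = NA_real_,
      salinity = NA_real_, ph = NA_real_, dissolved_oxygen = NA_real_,
      visibility_m = NA_real_,
      presence = as.integer(nmax >= 1), nmax = nmax, nmax_a = nmax,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out$env_complete <- FALSE
  rownames(out) <- NULL
  out
}
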