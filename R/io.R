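# CSV ingest/egress for the four interchange schemas, plus the geodesic
# distance primitive used everywhere downstream. All files are comma-separated
# UTF-8 with a mandatory header row; dates are ISO-8601; timestamps are
# interpreted in a single configured zone with no DST arithmetic.

.TAG_COLUMNS <- c(
  "shark_id", "transmitter_id", "tag_type", "battery_days", "attachment",
  "tag_date", "sex", "total_length_cm", "maturity", "tagging_site_label",
  "tag_lat", "tag_lon"
)
.RECEIVER_COLUMNS <- c(
  "receiver_id", "lat", "lon", "habitat", "depth_m", "op_start", "op_end"
)
.DETECTION_COLUMNS <- c("timestamp", "receiver_id", "transmitter_id")
.BRUV_COLUMNS <- c(
  "site", "reserve", "date", "lat", "lon", "depth_m", "flow_velocity",
  "temp_start", "temp_end", "salinity", "ph", "dissolved_oxygen",
  "visibility_m", "presence", "nmax", "nmax_a"
)

.HABITATS <- c("ocean_reef", "deep_lagoon", "shallow_lagoon")
.BATTERY_DAYS <- c(V9 = 365L, V16 = 540L)

check_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in '", path, "': missing column(s) ",
         paste(sQuote(missing), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}

parse_date_col <- function(x, col, path) {
  out <- as.Date(x, format = "%Y-%m-%d")
  bad <- which(is.na(out) & !is.na(x) & nzchar(x))
  if (length(bad) > 0) {
    stop("unparseable date in '", path, "', column '", col, "', row(s) ",
         paste(bad, collapse = ", "), " (expected ISO-8601 YYYY-MM-DD)",
         call. = FALSE)
  }
  out
}

report_rows <- function(bad, what, path) {
  if (length(bad) > 0) {
    stop("invariant violation in '", path, "': ", what, " at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
}

check_coords <- function(df, lat_col, lon_col, path) {
  report_rows(which(abs(df[[lat_col]]) > 90 | is.na(df[[lat_col]])),
              paste0("'", lat_col, "' outside [-90, 90]"), path)
  report_rows(which(abs(df[[lon_col]]) > 180 | is.na(df[[lon_col]])),
              paste0("'", lon_col, "' outside [-180, 180]"), path)
}

#' Great-circle distance between coordinate pairs
#'
#' Haversine distance on a sphere of radius 6371.0088 km (the IUGG mean Earth
#' radius), the package's standard surrogate for GIS map distance between
#' tagging sites and receiver moorings. At atoll scale (tens of km) the
#' spherical approximation error is far below 1%.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#'   Vectorised; vectors are recycled.
#' @return Distance(s) in kilometres. Zero if and only if the points coincide.
#' @examples
#' haversine_km(0, 0, 0, 1) # one equatorial degree, ~111.195 km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE)) {
    stop("latitude outside [-90, 90]", call. = FALSE)
  }
  if (any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("longitude outside [-180, 180]", call. = FALSE)
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371008.8) / 1000
}

#' Assign maturity class from length cut-offs
#'
#' Field studies typically judge maturity from size (females) or clasper
#' calcification (males); when only lengths are available a per-sex length
#' cut-off is the standard proxy. Defaults (female 190 cm, male 166 cm total
#' length) follow published size-at-maturity for the Caribbean reef shark.
#'
#' @param total_length_cm Numeric vector of total lengths (cm).
#' @param sex Character vector, `"F"` or `"M"`.
#' @param cutoffs_cm Named numeric vector with elements `F` and `M`.
#' @return Character vector, `"adult"` or `"juvenile"`.
#' @export
assign_maturity <- function(total_length_cm, sex, cutoffs_cm = c(F = 190, M = 166)) {
  stopifnot(all(sex %in% c("F", "M")), all(c("F", "M") %in% names(cutoffs_cm)))
  unname(ifelse(total_length_cm >= cutoffs_cm[sex], "adult", "juvenile"))
}

#' Read a tag-deployment table
#'
#' One row per tagged shark: biology (sex, total length, maturity), transmitter
#' specification (type, battery life, attachment mode) and the tagging event
#' (date, site label, coordinates). Rows violating schema invariants are
#' reported with their row numbers; nothing is silently coerced or dropped.
#'
#' @param path Path to a `tags.csv` file with columns
#'   `shark_id, transmitter_id, tag_type, battery_days, attachment, tag_date,
#'   sex, total_length_cm, maturity, tagging_site_label, tag_lat, tag_lon`.
#' @return A `data.frame` with one validated row per deployment; `tag_date`
#'   is a `Date`, `battery_days` an integer.
#' @seealso [grmr_tags()] for the packaged reference fixture.
#' @export
read_tags <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, .TAG_COLUMNS, path)
  df <- df[, .TAG_COLUMNS]
  if (nrow(df) == 0) return(df)
  df$tag_date <- parse_date_col(df$tag_date, "tag_date", path)
  df$battery_days <- as.integer(df$battery_days)
  report_rows(which(!df$tag_type %in% names(.BATTERY_DAYS)),
              "tag_type not one of V9/V16", path)
  report_rows(which(df$battery_days != .BATTERY_DAYS[df$tag_type]),
              "battery_days inconsistent with tag_type (V9 = 365, V16 = 540)",
              path)
  report_rows(which(!df$attachment %in% c("internal", "external")),
              "attachment not one of internal/external", path)
  report_rows(which(!df$sex %in% c("F", "M")), "sex not one of F/M", path)
  report_rows(which(!is.finite(df$total_length_cm) | df$total_length_cm <= 0),
              "total_length_cm not a positive number", path)
  report_rows(which(!df$maturity %in% c("adult", "juvenile")),
              "maturity not one of adult/juvenile", path)
  report_rows(which(duplicated(df$shark_id)), "duplicated shark_id", path)
  check_coords(df, "tag_lat", "tag_lon", path)
  df
}

#' Read a receiver-station table
#'
#' One row per receiver per operational interval; receivers that were pulled
#' for refurbishment and redeployed appear as multiple rows with disjoint
#' `[op_start, op_end]` date ranges. Habitat must be one of exactly three
#' classes: `ocean_reef`, `deep_lagoon`, `shallow_lagoon`.
#'
#' @param path Path to a `receivers.csv` file with columns
#'   `receiver_id, lat, lon, habitat, depth_m, op_start, op_end`.
#' @return A validated `data.frame`; `op_start`/`op_end` are `Date`s.
#' @export
read_receivers <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, .RECEIVER_COLUMNS, path)
  df <- df[, .RECEIVER_COLUMNS]
  if (nrow(df) == 0) return(df)
  df$op_start <- parse_date_col(df$op_start, "op_start", path)
  df$op_end <- parse_date_col(df$op_end, "op_end", path)
  report_rows(which(!df$habitat %in% .HABITATS),
              paste("habitat not one of", paste(.HABITATS, collapse = "/")),
              path)
  report_rows(which(!is.finite(df$depth_m) | df$depth_m <= 0),
              "depth_m not a positive number", path)
  report_rows(which(df$op_start > df$op_end), "op_start after op_end", path)
  check_coords(df, "lat", "lon", path)
  # per-receiver intervals must be pairwise non-overlapping
  for (id in unique(df$receiver_id)) {
    iv <- df[df$receiver_id == id, , drop = FALSE]
    iv <- iv[order(iv$op_start), ]
    if (nrow(iv) > 1 && any(iv$op_start[-1] <= iv$op_end[-nrow(iv)])) {
      stop("invariant violation in '", path, "': overlapping operational ",
           "intervals for receiver '", id, "'", call. = FALSE)
    }
    meta <- iv[, c("lat", "lon", "habitat", "depth_m")]
    if (nrow(unique(meta)) > 1) {
      stop("invariant violation in '", path, "': inconsistent metadata ",
           "across intervals for receiver '", id, "'", call. = FALSE)
    }
  }
  df
}

#' Count operational days for one receiver
#'
#' Sums the lengths (in days, endpoints inclusive) of a receiver's operational
#' intervals, so multi-interval records exclude refurbishment gaps.
#'
#' @param receivers A receiver table from [read_receivers()].
#' @param receiver_id Single receiver id.
#' @return Integer number of operational days.
#' @export
operational_days <- function(receivers, receiver_id) {
  iv <- receivers[receivers$receiver_id == receiver_id, , drop = FALSE]
  if (nrow(iv) == 0) stop("unknown receiver_id '", receiver_id, "'", call. = FALSE)
  sum(as.integer(iv$op_end - iv$op_start) + 1L)
}

#' Read a raw detection log
#'
#' VR2-export-like CSV of `(timestamp, receiver_id, transmitter_id)` triples.
#' Timestamps are parsed in a single zone (default UTC, standing in for the
#' logger's local clock; no DST arithmetic) and the log is returned in
#' chronological order. Exact duplicate triples are collapsed and counted;
#' rows whose ids do not resolve against the supplied tag/receiver tables are
#' quarantined with a warning rather than silently dropped.
#'
#' @param path Path to a `detections.csv` file.
#' @param tags Optional tag table ([read_tags()]); detections of unknown
#'   transmitters are quarantined.
#' @param receivers Optional receiver table ([read_receivers()]); detections at
#'   unknown receivers are quarantined.
#' @param tz Time zone for timestamp interpretation.
#' @return A `data.frame` of detections sorted by time, with attributes
#'   `n_duplicates` (collapsed duplicate count) and `quarantine` (the
#'   unresolvable rows, possibly empty).
#' @export
read_detections <- function(path, tags = NULL, receivers = NULL, tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, .DETECTION_COLUMNS, path)
  df <- df[, .DETECTION_COLUMNS]
  ts <- as.POSIXct(df$timestamp, format = "%Y-%m-%d %H:%M:%S", tz = tz)
  bad <- which(is.na(ts) & !is.na(df$timestamp))
  report_rows(bad, "unparseable timestamp (expected YYYY-MM-DD HH:MM:SS)", path)
  df$timestamp <- ts
  dup <- duplicated(df)
  n_dup <- sum(dup)
  if (n_dup > 0) {
    message(n_dup, " duplicate detection(s) collapsed")
    df <- df[!dup, , drop = FALSE]
  }
  quarantine <- df[0, , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  if (!is.null(tags)) keep <- keep & df$transmitter_id %in% tags$transmitter_id
  if (!is.null(receivers)) keep <- keep & df$receiver_id %in% receivers$receiver_id
  if (any(!keep)) {
    quarantine <- df[!keep, , drop = FALSE]
    warning(sum(!keep), " detection(s) with unresolvable ids quarantined",
            call. = FALSE)
    df <- df[keep, , drop = FALSE]
  }
  df <- df[order(df$timestamp, df$receiver_id, df$transmitter_id), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, n_duplicates = n_dup, quarantine = quarantine)
}

#' Write a detection log
#'
#' Inverse of [read_detections()]: timestamps are serialised as
#' `YYYY-MM-DD HH:MM:SS` in the zone they carry, so a write/read round trip is
#' lossless at one-second resolution.
#'
#' @param detections Detection `data.frame` (columns `timestamp`,
#'   `receiver_id`, `transmitter_id`).
#' @param path Output file path.
#' @export
write_detections <- function(detections, path) {
  out <- data.frame(
    timestamp = format(detections$timestamp, "%Y-%m-%d %H:%M:%S"),
    receiver_id = detections$receiver_id,
    transmitter_id = detections$transmitter_id,
    stringsAsFactors = FALSE
  )
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a BRUV deployment table
#'
#' One row per baited-video drop: site label, reserve flag, deployment date and
#' position, environmental covariates, the presence score and the two count
#' summaries (`nmax`, the most sharks in any single frame; `nmax_a`, the most
#' distinguishable individuals across the whole video). Environmental fields
#' may be missing; incomplete rows are flagged in the logical `env_complete`
#' column, never dropped.
#'
#' @param path Path to a `bruv.csv` file.
#' @return A validated `data.frame` with an added `env_complete` column;
#'   `reserve` is logical, `date` a `Date`.
#' @export
read_bruv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  check_columns(df, .BRUV_COLUMNS, path)
  df <- df[, .BRUV_COLUMNS]
  if (nrow(df) == 0) {
    df$env_complete <- logical(0)
    return(df)
  }
  df$date <- parse_date_col(df$date, "date", path)
  df$reserve <- as.logical(df$reserve)
  report_rows(which(is.na(df$reserve)), "reserve not interpretable as logical",
              path)
  report_rows(which(!df$presence %in% c(0L, 1L)), "presence not 0/1", path)
  report_rows(which(df$nmax < 0 | df$nmax != round(df$nmax)),
              "nmax not a non-negative integer", path)
  report_rows(which((df$presence == 1) != (df$nmax >= 1)),
              "presence inconsistent with nmax (presence = 1 iff nmax >= 1)",
              path)
  report_rows(which(df$nmax_a < df$nmax),
              "nmax_a smaller than nmax", path)
  check_coords(df, "lat", "lon", path)
  env_cols <- c("flow_velocity", "temp_start", "temp_end", "salinity", "ph",
                "dissolved_oxygen", "visibility_m")
  df$env_complete <- complete.cases(df[, env_cols])
  df
}

#' Write a BRUV deployment table
#' @param bruv BRUV `data.frame` (the `env_complete` flag column is not written).
#' @param path Output file path.
#' @export
write_bruv <- function(bruv, path) {
  out <- bruv[, .BRUV_COLUMNS]
  out$reserve <- tolower(as.character(out$reserve))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write tag and receiver tables
#' @param tags,receivers Validated tables as returned by [read_tags()] /
#'   [read_receivers()].
#' @param path Output file path.
#' @rdname write_tables
#' @export
write_tags <- function(tags, path) {
  write.csv(tags[, .TAG_COLUMNS], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tables
#' @export
write_receivers <- function(receivers, path) {
  out <- receivers[, .RECEIVER_COLUMNS]
  out$op_start <- format(out$op_start)
  out$op_end <- format(out$op_end)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
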