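# Month-scale retention: a logistic model of any-detection per month since
# tagging, over the first 12 months so every shark contributes the same span.

#' Build per-shark monthly presence records
#'
#' Month *i* is the 30-day block `[30(i-1), 30i)` days after the tagging date
#' (the `"calendar"` alignment instead advances by calendar months from the
#' tag date). `detected` is 1 when the shark had an eligible-day detection
#' anywhere in the array during the block. Only months 1..12 are kept so 12-
#' and 18-month tags are comparable; externally tagged sharks are omitted
#' (their attachment mode confounds retention); months in which the array was
#' entirely down are dropped, not scored 0.
#'
#' @param presence A [daily_presence()] object.
#' @param align `"tag"` (30-day blocks, default) or `"calendar"`.
#' @return A `data.frame`: `shark_id`, `sharkmonth` (1..12), `detected` (0/1),
#'   `taglife` (factor `12mo`/`18mo`).
#' @export
build_monthly_records <- function(presence, align = c("tag", "calendar")) {
  align <- match.arg(align)
  tags <- presence$tags
  internal <- tags[tags$attachment == "internal", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(internal))) {
    sh <- internal[i, ]
    det <- detected_dates(presence, sh$shark_id, eligible_only = TRUE)
    for (m in 1:12) {
      if (align == "tag") {
        lo <- sh$tag_date + 30L * (m - 1L)
        hi <- sh$tag_date + 30L * m - 1L
      } else {
        lo <- seq(sh$tag_date, by = "month", length.out = m)[m]
        hi <- seq(sh$tag_date, by = "month", length.out = m + 1L)[m + 1L] - 1L
      }
      block <- seq(lo, hi, by = "day")
      elig <- block[block %in% presence$array_dates &
                      block < sh$tag_date + sh$battery_days]
      if (length(elig) == 0) next # array fully down (or battery over): drop
      rows[[length(rows) + 1L]] <- data.frame(
        shark_id = sh$shark_id, sharkmonth = m,
        detected = as.integer(any(det >= lo & det <= hi)),
        taglife = if (sh$battery_days <= 365) "12mo" else "18mo",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(shark_id = character(), sharkmonth = integer(),
                      detected = integer(), taglife = character(),
                      stringsAsFactors = FALSE)
  }
  out$taglife <- factor(out$taglife, levels = c("12mo", "18mo"))
  rownames(out) <- NULL
  out
}

#' Fit the month-scale retention model
#'
#' Logistic GLM of monthly any-detection on months-since-tagging (numeric) and
#' transmitter battery class, with the sequential deviance decomposition.
#'
#' @param records Records from [build_monthly_records()].
#' @param terms Model terms, by default `c("sharkmonth", "taglife")`; a term
#'   is dropped automatically when it has a single level in `records`.
#' @return A `shark_glm` object.
#' @export
fit_month_model <- function(records, terms = c("sharkmonth", "taglife")) {
  if ("taglife" %in% terms && length(unique(records$taglife)) < 2) {
    terms <- setdiff(terms, "taglife")
  }
  form <- as.formula(paste("detected ~", paste(terms, collapse = " + ")))
  fit <- glm(form, family = binomial("logit"), data = records)
  new_shark_glm(fit, "detected", "binomial_logit", terms)
}

#' Predicted monthly retention curve with a 2-SE band
#'
#' Inverse-logit of the linear predictor at months 1..12 for each battery
#' class, with the band computed as plus/minus two standard errors on the
#' linear-predictor scale (delta method) and then back-transformed, so the
#' band always contains the point estimate and stays inside (0, 1).
#'
#' @param fit A `shark_glm` from [fit_month_model()].
#' @param months Months to predict at.
#' @return A `data.frame`: `taglife`, `sharkmonth`, `prob`, `lower`, `upper`.
#' @export
predict_retention_curve <- function(fit, months = 1:12) {
  stopifnot(inherits(fit, "shark_glm"))
  model <- fit$model
  has_taglife <- "taglife" %in% fit$terms
  lifes <- if (has_taglife) levels(model$model$taglife) else "all"
  grid <- expand.grid(sharkmonth = months, taglife = lifes,
                      stringsAsFactors = FALSE)
  if (has_taglife) {
    grid$taglife <- factor(grid$taglife, levels = lifes)
  }
  pr <- predict(model, newdata = grid, type = "link", se.fit = TRUE)
  grid$prob <- plogis(pr$fit)
  grid$lower <- plogis(pr$fit - 2 * pr$se.fit)
  grid$upper <- plogis(pr$fit + 2 * pr$se.fit)
  grid
}
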