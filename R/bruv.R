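# Reserve-effect analysis of BRUV deployments: site summaries, nested-location
# logistic GLMs, the area-proportional bootstrap that equalises sample density
# across sites of unequal area, and environmental comparisons.

#' Per-site BRUV summaries
#'
#' Deployments, presences, percent presence and multi-individual deployments
#' (`nmax_a >= 2`) per site, with reserve/fished stratum rollups appended. An
#' empty site reports 0 deployments and a 0 percentage flagged in the
#' `undefined_percent` column rather than NaN.
#'
#' @param deployments BRUV table ([read_bruv()] or [bruv_from_counts()]).
#' @param sites Optional site labels to force into the output (so empty sites
#'   appear).
#' @return A `data.frame`: `site`, `reserve`, `n_deployments`, `n_present`,
#'   `percent_present`, `n_multi`, `undefined_percent`; stratum rollups carry
#'   site labels `"reserve"`/`"fished"` and `NA` reserve flag semantics via
#'   the `stratum` column.
#' @export
summarize_sites <- function(deployments, sites = NULL) {
  if (is.null(sites)) sites <- unique(deployments$site)
  one <- function(rows, label, reserve, stratum) {
    n <- nrow(rows)
    k <- sum(rows$presence)
    data.frame(
      site = label, reserve = reserve, n_deployments = n, n_present = k,
      percent_present = if (n > 0) 100 * k / n else 0,
      n_multi = sum(rows$nmax_a >= 2, na.rm = TRUE),
      undefined_percent = n == 0, stratum = stratum,
      stringsAsFactors = FALSE
    )
  }
  rows <- lapply(sites, function(s) {
    d <- deployments[deployments$site == s, , drop = FALSE]
    one(d, s, if (nrow(d) > 0) d$reserve[1] else NA, "site")
  })
  rows <- c(rows, list(
    one(deployments[deployments$reserve, , drop = FALSE], "reserve", TRUE,
        "rollup"),
    one(deployments[!deployments$reserve, , drop = FALSE], "fished", FALSE,
        "rollup")
  ))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Logistic GLM of presence on reserve status with nested location
#'
#' Fits `presence ~ reserve + reserve:location` (location nested within the
#' reserve/fished stratum) with sequential analysis of deviance, so the
#' reserve contrast is tested first and the between-site variation within
#' each stratum second. If any stratum contains a single site the nested term
#' is dropped with a warning.
#'
#' @param deployments BRUV table.
#' @param nested Include the location-within-stratum term?
#' @return A `shark_glm` object.
#' @export
fit_reserve_glm <- function(deployments, nested = TRUE) {
  d <- deployments
  d$reserve <- factor(ifelse(d$reserve, "reserve", "fished"),
                      levels = c("fished", "reserve"))
  d$site <- factor(d$site)
  if (nested) {
    per_stratum <- tapply(as.character(d$site), d$reserve,
                          function(s) length(unique(s)))
    if (any(per_stratum < 2)) {
      warning("a stratum has a single site; nested location term dropped",
              call. = FALSE)
      nested <- FALSE
    }
  }
  terms <- if (nested) c("reserve", "reserve:site") else "reserve"
  form <- as.formula(paste("presence ~", paste(terms, collapse = " + ")))
  fit <- glm(form, family = binomial("logit"), data = d)
  new_shark_glm(fit, "presence", "binomial_logit", terms)
}

#' Area-proportional bootstrap of the reserve effect
#'
#' Sites of unequal area sampled with equal deployment counts have unequal
#' sample density; this resamples each site down to an area-proportional
#' count and re-tests the reserve term, reporting the fraction of replicates
#' in which it stays significant. Per replicate: draw `site_n[s]` deployments
#' from each site (with replacement by default — a stratified bootstrap;
#' `replace = FALSE` gives plain subsampling, in which case `site_n` may not
#' exceed a site's deployments), fit the logistic GLM `presence ~ reserve`
#' (optionally with the nested location term), and record the likelihood-ratio
#' chi-square p-value for the reserve term.
#'
#' Fully reproducible: the same `seed` gives a bit-identical result.
#'
#' @param deployments BRUV table.
#' @param site_n Named integer vector of per-site draw counts.
#' @param n_reps Number of replicates.
#' @param alpha Significance level.
#' @param seed Integer seed (`NULL` leaves the RNG state alone).
#' @param replace Resample with replacement?
#' @param nested Include the nested location term in each replicate model?
#'   Off by default: subsamples can empty a site's presence cells.
#' @return An object of class `bruv_bootstrap`: `n_reps`, `site_n`, `alpha`,
#'   `fraction_significant`, `p_values` (retained for audit), `seed`,
#'   `replace`.
#' @export
bootstrap_density <- function(deployments, site_n, n_reps = 2000,
                              alpha = 0.05, seed = NULL, replace = TRUE,
                              nested = FALSE) {
  stopifnot(is.numeric(site_n), !is.null(names(site_n)), n_reps >= 1,
            alpha > 0, alpha < 1)
  unknown <- setdiff(names(site_n), unique(deployments$site))
  if (length(unknown) > 0) {
    stop("site_n names not in deployments: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  avail <- table(deployments$site)
  if (!replace) {
    over <- names(site_n)[site_n > avail[names(site_n)]]
    if (length(over) > 0) {
      stop("site_n exceeds available deployments at: ",
           paste(over, collapse = ", "), call. = FALSE)
    }
  }
  if (!is.null(seed)) set.seed(seed)
  site_idx <- lapply(names(site_n), function(s) which(deployments$site == s))
  names(site_idx) <- names(site_n)
  p_values <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    idx <- unlist(lapply(names(site_n), function(s) {
      sample(site_idx[[s]], site_n[[s]], replace = replace)
    }), use.names = FALSE)
    d <- deployments[idx, , drop = FALSE]
    p_values[r] <- reserve_lrt_p(d, nested = nested)
  }
  structure(
    list(n_reps = n_reps, site_n = site_n, alpha = alpha,
         fraction_significant = mean(p_values < alpha),
         p_values = p_values, seed = seed, replace = replace),
    class = "bruv_bootstrap"
  )
}

# LRT chi-square p for the reserve term of presence ~ reserve (+ nested site).
reserve_lrt_p <- function(d, nested = FALSE) {
  if (length(unique(d$reserve)) < 2) return(1)
  form <- if (nested) presence ~ reserve + reserve:site else presence ~ reserve
  fit <- glm(form, family = binomial("logit"), data = d, model = FALSE)
  a <- anova(fit)
  pchisq(a["reserve", "Deviance"], a["reserve", "Df"], lower.tail = FALSE)
}

#' @export
print.bruv_bootstrap <- function(x, ...) {
  cat("Area-proportional bootstrap:", x$n_reps, "replicates,",
      if (x$replace) "with" else "without", "replacement\n")
  cat("  per-site draws:", paste(names(x$site_n), x$site_n, sep = "=",
                                 collapse = ", "), "\n")
  cat(sprintf("  reserve term significant (LRT p < %.2g) in %.1f%% of replicates\n",
              x$alpha, 100 * x$fraction_significant))
  invisible(x)
}

#' One-way ANOVA and Tukey HSD of an environmental variable across sites
#'
#' Screens for environmental confounding of the reserve effect: a one-way
#' ANOVA of the variable by site, followed by Tukey honest significant
#' difference pairwise comparisons with family-wise adjusted p-values.
#' Rows with a missing value of the variable are excluded (and counted).
#'
#' @param deployments BRUV table.
#' @param variable Environmental column name, e.g. `"temp_start"`.
#' @return A list: `anova` (the `summary.aov` table as a `data.frame`),
#'   `tukey` (pairwise matrix from [TukeyHSD()]), `p_value` (ANOVA p),
#'   `n_used`, `n_missing`.
#' @export
compare_environments <- function(deployments, variable) {
  stopifnot(variable %in% names(deployments))
  d <- deployments[, c("site", variable)]
  n_missing <- sum(!complete.cases(d))
  d <- d[complete.cases(d), , drop = FALSE]
  d$site <- factor(d$site)
  if (nlevels(d$site) < 2) {
    stop("ANOVA needs at least 2 sites with data for '", variable, "'",
         call. = FALSE)
  }
  names(d)[2] <- "y"
  fit <- aov(y ~ site, data = d)
  tab <- as.data.frame(summary(fit)[[1]])
  list(anova = tab, tukey = TukeyHSD(fit)$site,
       p_value = tab[["Pr(>F)"]][1], n_used = nrow(d), n_missing = n_missing)
}

#' Environmental GLM on the reserve subset
#'
#' Within reserve deployments only (fished sites are too presence-sparse to
#' model environment and reserve status jointly), a logistic GLM of presence
#' on location, flow velocity, start temperature and their pairwise
#' interactions, with sequential analysis of deviance. Only rows with
#' complete flow and temperature are used (count logged in attribute
#' `n_dropped`); a constant covariate is a rank-deficiency error.
#'
#' @param deployments BRUV table.
#' @return A `shark_glm` with attribute `n_dropped`.
#' @export
fit_env_glm_reserve_subset <- function(deployments) {
  d <- deployments[deployments$reserve, , drop = FALSE]
  ok <- complete.cases(d[, c("flow_velocity", "temp_start")])
  n_dropped <- sum(!ok)
  d <- d[ok, , drop = FALSE]
  if (nrow(d) == 0) stop("no reserve deployments with complete covariates",
                         call. = FALSE)
  d$location <- factor(d$site)
  if (nlevels(d$location) < 2) {
    stop("need at least 2 reserve sites", call. = FALSE)
  }
  terms <- c("location", "flow_velocity", "temp_start",
             "location:flow_velocity", "location:temp_start",
             "flow_velocity:temp_start")
  form <- as.formula(paste("presence ~", paste(terms, collapse = " + ")))
  check_rank(model.matrix(form, d))
  fit <- glm(form, family = binomial("logit"), data = d)
  out <- new_shark_glm(fit, "presence", "binomial_logit", terms)
  attr(out, "n_dropped") <- n_dropped
  out
}
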