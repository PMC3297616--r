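# Delta-lognormal shark x receiver detection model: a binomial model for
# whether a shark was ever detected at a receiver, a lognormal model for the
# fraction of days detected given any detection, sequential analysis of
# deviance, the three-clause term-inclusion rule, and the combined
# (probability x back-transformed mean) prediction.

#' Build the shark-by-receiver model substrate
#'
#' One row per detected shark per receiver that was operational at some point
#' during the shark's battery window: `detected` (ever detected there),
#' `frac_days` (detected days at that receiver divided by the receiver's
#' operational days within the battery window; `NA` when never detected),
#' `ldist` (natural log of the tagging-point-to-receiver distance in km,
#' floored at `distance_floor_km` before logging), `habitat`, `days` (receiver
#' operational days while the tag was live) and `shark_type`
#' (maturity x sex: `adult_F`, `adult_M`, `juv_F`, `juv_M`).
#'
#' @param presence A [daily_presence()] object.
#' @param distance_floor_km Floor applied to distances before logging, so a
#'   shark tagged at a receiver's coordinates has a finite `ldist`. Must be
#'   positive.
#' @return A `data.frame`, one row per shark x receiver pair.
#' @export
build_summary <- function(presence, distance_floor_km = 0.05) {
  if (!is.numeric(distance_floor_km) || distance_floor_km <= 0) {
    stop("distance_floor_km must be positive (log of zero distance is undefined)",
         call. = FALSE)
  }
  tags <- presence$tags
  recs <- unique(presence$receivers[, c("receiver_id", "lat", "lon", "habitat")])
  detected_ids <- unique(presence$days$shark_id)
  sharks <- tags[tags$shark_id %in% detected_ids, , drop = FALSE]
  det_days <- presence$days
  rows <- list()
  for (i in seq_len(nrow(sharks))) {
    sh <- sharks[i, ]
    battery <- seq(sh$tag_date, by = "day", length.out = sh$battery_days)
    sh_days <- det_days[det_days$shark_id == sh$shark_id, , drop = FALSE]
    for (j in seq_len(nrow(recs))) {
      rid <- recs$receiver_id[j]
      iv <- presence$receivers[presence$receivers$receiver_id == rid, ,
                               drop = FALSE]
      op <- 0L
      for (k in seq_len(nrow(iv))) {
        lo <- max(iv$op_start[k], battery[1])
        hi <- min(iv$op_end[k], battery[length(battery)])
        if (lo <= hi) op <- op + as.integer(hi - lo) + 1L
      }
      if (op == 0L) next
      ndet <- length(unique(sh_days$date[sh_days$receiver_id == rid]))
      dist <- haversine_km(sh$tag_lat, sh$tag_lon, recs$lat[j], recs$lon[j])
      rows[[length(rows) + 1L]] <- data.frame(
        shark_id = sh$shark_id, receiver_id = rid,
        detected = as.integer(ndet > 0),
        frac_days = if (ndet > 0) min(ndet / op, 1) else NA_real_,
        dist_km = dist,
        ldist = log(max(dist, distance_floor_km)),
        habitat = recs$habitat[j], days = op,
        shark_type = paste(substr(sh$maturity, 1, ifelse(sh$maturity == "adult", 5L, 3L)),
                           sh$sex, sep = "_"),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$habitat <- factor(out$habitat, levels = .HABITATS)
  out$shark_type <- factor(out$shark_type)
  rownames(out) <- NULL
  out
}

# ---- sequential analysis of deviance wrappers -------------------------------

anodev_standardise <- function(atab, null_dev, stat_col, p_col) {
  terms <- rownames(atab)
  keep <- terms != "Residuals"
  if (sum(keep) == 0) {
    return(data.frame(term = character(), df = numeric(),
                      deviance = numeric(), resid_df = numeric(),
                      resid_dev = numeric(), statistic = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE))
  }
  resid_dev <- if ("Resid. Dev" %in% colnames(atab)) {
    atab[keep, "Resid. Dev"]
  } else {
    null_dev - cumsum(ifelse(is.na(atab[keep, "Sum Sq"]), 0,
                             atab[keep, "Sum Sq"]))
  }
  resid_df <- if ("Resid. Df" %in% colnames(atab)) atab[keep, "Resid. Df"] else {
    NA
  }
  data.frame(
    term = terms[keep],
    df = atab[keep, "Df"],
    deviance = if ("Deviance" %in% colnames(atab)) atab[keep, "Deviance"] else
      atab[keep, "Sum Sq"],
    resid_df = resid_df,
    resid_dev = resid_dev,
    statistic = if (stat_col %in% colnames(atab)) atab[keep, stat_col] else NA,
    p_value = if (p_col %in% colnames(atab)) atab[keep, p_col] else NA,
    stringsAsFactors = FALSE
  )
}

new_shark_glm <- function(model, response, family_label, terms) {
  if (inherits(model, "glm")) {
    atab <- anova(model, test = "Chisq")
    null_dev <- model$null.deviance
    std <- anodev_standardise(as.data.frame(atab), null_dev,
                              stat_col = "Deviance", p_col = "Pr(>Chi)")
    if (nrow(std) > 0 && std$term[1] == "NULL") {
      null_row <- std[1, , drop = FALSE]
      std <- std[-1, , drop = FALSE]
    }
  } else {
    atab <- as.data.frame(anova(model))
    y <- model$model[[1]]
    null_dev <- sum((y - mean(y))^2)
    std <- anodev_standardise(atab, null_dev, stat_col = "F value",
                              p_col = "Pr(>F)")
    std$resid_df <- (length(y) - 1L) - cumsum(std$df)
  }
  std$percent_deviance <- std$deviance / null_dev
  resid_df0 <- if (inherits(model, "glm")) model$df.null else
    model$df.residual + sum(std$df)
  structure(
    list(model = model, response = response, family_label = family_label,
         terms = terms, anodev = std, null_deviance = null_dev,
         resid_deviance = if (inherits(model, "glm")) model$deviance else
           sum(model$residuals^2),
         null_df = resid_df0,
         aic = AIC(model), bic = BIC(model),
         loglik = as.numeric(logLik(model))),
    class = "shark_glm"
  )
}

#' @export
print.shark_glm <- function(x, digits = 4, ...) {
  cat("Sequential analysis of deviance (", x$family_label, "): ",
      x$response, " ~ ", paste(x$terms, collapse = " + "), "\n", sep = "")
  cat("NULL deviance ", format(x$null_deviance, digits = digits),
      " on ", x$null_df, " df\n", sep = "")
  print(format(x$anodev, digits = digits), row.names = FALSE)
  cat("AIC ", format(x$aic, digits = digits), ", BIC ",
      format(x$bic, digits = digits), "\n", sep = "")
  invisible(x)
}

check_rank <- function(X) {
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    aliased <- colnames(X)[qr_X$pivot[(qr_X$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased column(s): ",
         paste(aliased, collapse = ", "), call. = FALSE)
  }
}

# Finite-coefficient fallback under complete separation: logistic Newton
# iterations with a small L2 penalty on the non-intercept coefficients.
ridge_logit <- function(X, y, lambda = 1e-4, maxit = 100, tol = 1e-10) {
  beta <- rep(0, ncol(X))
  pen <- diag(c(0, rep(lambda, ncol(X) - 1L)), ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    grad <- drop(crossprod(X, y - mu)) - pen %*% beta
    hess <- crossprod(X * w, X) + pen
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  drop(beta)
}

#' Fit a fixed-effects stage of the delta-lognormal model
#'
#' `response = "presence"` fits a logit-link binomial GLM (IRLS) of
#' ever-detected on the given terms over all shark x receiver rows;
#' `response = "fraction"` fits a Gaussian least-squares model of
#' `log(frac_days)` over the detected rows only. Terms enter the sequential
#' (type-I) analysis of deviance in the order given; p-values are chi-square
#' (binomial) or F (Gaussian).
#'
#' Complete separation in the binomial stage triggers a warning and a
#' finite-coefficient ridge fallback (stored as `coefficients_regularised`;
#' the deviance decomposition still comes from the unpenalised fit). A
#' rank-deficient design is an error naming the aliased columns.
#'
#' @param rows Model substrate from [build_summary()].
#' @param response `"presence"` or `"fraction"`.
#' @param terms Character vector of model terms, e.g.
#'   `c("days", "ldist", "habitat")`; interactions as `"ldist:habitat"`.
#' @return A `shark_glm` object: the underlying fit plus the standardised
#'   sequential deviance table (`anodev`), `null_deviance`, `aic`, `bic`.
#' @export
fit_detection_glm <- function(rows, response = c("presence", "fraction"),
                              terms = c("days", "ldist", "habitat")) {
  response <- match.arg(response)
  if (response == "presence") {
    form <- as.formula(paste("detected ~", paste(terms, collapse = " + ")))
    check_rank(model.matrix(form, rows))
    fit <- withCallingHandlers(
      glm(form, family = binomial("logit"), data = rows),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
    out <- new_shark_glm(fit, "detected", "binomial_logit", terms)
    if (any(abs(coef(fit)) > 15, na.rm = TRUE)) {
      warning("possible complete separation; ridge fallback coefficients ",
              "stored in $coefficients_regularised", call. = FALSE)
      X <- model.matrix(form, rows)
      out$coefficients_regularised <-
        setNames(ridge_logit(X, rows$detected), colnames(X))
    }
    out
  } else {
    d <- droplevels(rows[rows$detected == 1 & is.finite(rows$frac_days), ,
                         drop = FALSE])
    d$log_frac <- log(d$frac_days)
    form <- as.formula(paste("log_frac ~", paste(terms, collapse = " + ")))
    check_rank(model.matrix(form, d))
    fit <- lm(form, data = d)
    new_shark_glm(fit, "log(frac_days)", "gaussian_log", terms)
  }
}

#' Fit a mixed-effects stage of the delta-lognormal model
#'
#' Mixed-model variants with receivers and/or sharks as random intercepts, or
#' a random slope of `ldist` by shark or receiver. Binomial models use the
#' Laplace approximation ([lme4::glmer()]); Gaussian log-fraction models use
#' [lme4::lmer()] with REML off so AIC/BIC are comparable within a candidate
#' set. Non-convergence flags the fit (`$converged = FALSE`) rather than
#' erroring, so selection can skip it with a log entry.
#'
#' @inheritParams fit_detection_glm
#' @param random_terms Character vector drawn from `"shark"`, `"monitor"`
#'   (random intercepts for shark / receiver) and `"ldist|shark"`,
#'   `"ldist|monitor"` (random `ldist` slopes).
#' @return A `shark_glmm` object: `model`, `fixef`, `fixef_se`, `ranef_sd`,
#'   `aic`, `bic`, `converged`.
#' @export
fit_detection_glmm <- function(rows, response = c("presence", "fraction"),
                               terms = c("days", "ldist", "habitat"),
                               random_terms = "shark") {
  response <- match.arg(response)
  re_map <- c(shark = "(1 | shark_id)", monitor = "(1 | receiver_id)",
              `ldist|shark` = "(ldist | shark_id)",
              `ldist|monitor` = "(ldist | receiver_id)")
  unknown <- setdiff(random_terms, names(re_map))
  if (length(unknown) > 0) {
    stop("unknown random term(s): ", paste(unknown, collapse = ", "),
         "; use ", paste(names(re_map), collapse = ", "), call. = FALSE)
  }
  rhs <- paste(c(terms, re_map[random_terms]), collapse = " + ")
  converged <- TRUE
  note_nonconv <- function(w) {
    if (grepl("converge|Hessian|singular", conditionMessage(w),
              ignore.case = TRUE)) {
      converged <<- FALSE
      invokeRestart("muffleWarning")
    }
  }
  if (response == "presence") {
    form <- as.formula(paste("detected ~", rhs))
    fit <- withCallingHandlers(
      lme4::glmer(form, family = binomial("logit"), data = rows),
      warning = note_nonconv, message = function(m) invokeRestart("muffleMessage")
    )
  } else {
    d <- rows[rows$detected == 1 & is.finite(rows$frac_days), , drop = FALSE]
    d$log_frac <- log(d$frac_days)
    form <- as.formula(paste("log_frac ~", rhs))
    fit <- withCallingHandlers(
      lme4::lmer(form, data = d, REML = FALSE),
      warning = note_nonconv, message = function(m) invokeRestart("muffleMessage")
    )
  }
  vc <- lme4::VarCorr(fit)
  ranef_sd <- unlist(lapply(vc, function(v) attr(v, "stddev")))
  structure(
    list(model = fit, response = response, terms = terms,
         random_terms = random_terms,
         fixef = lme4::fixef(fit),
         fixef_se = sqrt(diag(as.matrix(vcov(fit)))),
         ranef_sd = ranef_sd,
         aic = AIC(fit), bic = BIC(fit), converged = converged),
    class = "shark_glmm"
  )
}

#' @export
print.shark_glmm <- function(x, digits = 4, ...) {
  cat("Mixed model (", x$response, "): fixed ",
      paste(x$terms, collapse = " + "), "; random ",
      paste(x$random_terms, collapse = " + "), "\n", sep = "")
  print(round(x$fixef, digits))
  cat("Random-effect SD(s):", paste(round(x$ranef_sd, digits), collapse = ", "),
      "\nAIC", round(x$aic, 2), "BIC", round(x$bic, 2),
      if (!x$converged) "(NOT CONVERGED)" else "", "\n")
  invisible(x)
}

#' Percent of null deviance explained by a term
#'
#' A term's sequential deviance contribution divided by the null deviance.
#' Accepts a fitted `shark_glm` or a standardised deviance table that carries
#' a `NULL` row (as the packaged reference tables do).
#'
#' @param fit A `shark_glm` object or a `data.frame` with columns `term`,
#'   `deviance`, `resid_dev` including a `NULL` row.
#' @param term Term name.
#' @return Fraction of the null deviance (0 for any term of a null model).
#' @export
percent_deviance <- function(fit, term) {
  if (inherits(fit, "shark_glm")) {
    tab <- fit$anodev
    null_dev <- fit$null_deviance
  } else {
    stopifnot(is.data.frame(fit), all(c("term", "deviance", "resid_dev") %in%
                                        names(fit)))
    null_dev <- fit$resid_dev[fit$term == "NULL"]
    if (length(null_dev) != 1) stop("deviance table lacks a NULL row",
                                    call. = FALSE)
    tab <- fit[fit$term != "NULL", , drop = FALSE]
  }
  if (!term %in% tab$term) {
    if (nrow(tab) == 0) return(0) # null model explains nothing
    stop("term '", term, "' not in the deviance table", call. = FALSE)
  }
  unname(tab$deviance[tab$term == term] / null_dev)
}

# ---- term selection ---------------------------------------------------------

#' Decide whether a candidate term enters the model
#'
#' The three-clause inclusion rule: a term is admitted when it improves the
#' AIC or the BIC, or when it is both significant at `alpha` and explains more
#' than `min_percent` of the null deviance. The pure decision function is
#' exposed so the rule's truth table can be examined directly.
#'
#' @param p_value Sequential-deviance p-value for the term.
#' @param percent_dev Fraction of null deviance the term explains.
#' @param delta_aic,delta_bic Change in AIC/BIC from adding the term
#'   (negative = improvement).
#' @param alpha Significance level.
#' @param min_percent Minimum fraction of null deviance.
#' @return A list: `include` (logical) and `rationale` (string naming the
#'   clause(s) that passed, or why it failed).
#' @export
inclusion_decision <- function(p_value, percent_dev, delta_aic, delta_bic,
                               alpha = 0.05, min_percent = 0.02) {
  clauses <- character()
  if (delta_aic < 0) clauses <- c(clauses, "improves AIC")
  if (delta_bic < 0) clauses <- c(clauses, "improves BIC")
  if (p_value < alpha && percent_dev > min_percent) {
    clauses <- c(clauses, sprintf("significant (p=%.3g) and explains %.1f%% deviance",
                                  p_value, 100 * percent_dev))
  }
  if (length(clauses) > 0) {
    list(include = TRUE, rationale = paste(clauses, collapse = "; "))
  } else {
    list(include = FALSE,
         rationale = sprintf(
           "p=%.3g, %.1f%% deviance, dAIC=%+.2f, dBIC=%+.2f: no clause passed",
           p_value, 100 * percent_dev, delta_aic, delta_bic))
  }
}

#' Sequential term selection for a delta-lognormal stage
#'
#' Walks the candidate terms in the declared order, refitting with each term
#' appended and applying [inclusion_decision()] against the current model.
#' Ties in any criterion keep the earlier model (first by declaration order).
#'
#' @inheritParams fit_detection_glm
#' @param candidate_terms Terms to consider, in order.
#' @param alpha,min_percent Passed to [inclusion_decision()].
#' @return A list: `terms` (those retained), `fit` (final `shark_glm`),
#'   `decisions` (per-term `data.frame` with the statistics and rationale).
#' @export
select_terms <- function(rows, response = c("presence", "fraction"),
                         candidate_terms = c("days", "ldist", "habitat"),
                         alpha = 0.05, min_percent = 0.02) {
  response <- match.arg(response)
  kept <- character()
  decisions <- list()
  current_aic <- current_bic <- NULL
  for (term in candidate_terms) {
    fit <- fit_detection_glm(rows, response, c(kept, term))
    row <- fit$anodev[fit$anodev$term == term, ]
    if (is.null(current_aic)) {
      # baseline: intercept-only model
      null_fit <- if (response == "presence") {
        glm(detected ~ 1, binomial, rows)
      } else {
        d <- rows[rows$detected == 1 & is.finite(rows$frac_days), ]
        lm(log(frac_days) ~ 1, d)
      }
      current_aic <- AIC(null_fit)
      current_bic <- BIC(null_fit)
    }
    dec <- inclusion_decision(row$p_value, row$percent_deviance,
                              fit$aic - current_aic, fit$bic - current_bic,
                              alpha, min_percent)
    decisions[[term]] <- data.frame(
      term = term, p_value = row$p_value,
      percent_deviance = row$percent_deviance,
      delta_aic = fit$aic - current_aic, delta_bic = fit$bic - current_bic,
      include = dec$include, rationale = dec$rationale,
      stringsAsFactors = FALSE
    )
    if (dec$include) {
      kept <- c(kept, term)
      current_aic <- fit$aic
      current_bic <- fit$bic
    }
  }
  final <- fit_detection_glm(rows, response,
                             if (length(kept) > 0) kept else "1")
  list(terms = kept, fit = final,
       decisions = do.call(rbind, c(decisions, list(make.row.names = FALSE))))
}

#' Pick the AIC-best fit from a candidate set
#'
#' Argmin of AIC over fitted models (`shark_glm` or `shark_glmm`), skipping
#' flagged non-converged mixed fits (with a message). Exact ties go to the
#' earliest candidate in declaration order. Also reports each candidate's
#' `delta_aic`/`delta_bic` relative to the best.
#'
#' @param fits A named list of fitted models.
#' @return A list: `best` (the winning fit), `name`, `table` (AIC/BIC ladder).
#' @export
select_aic <- function(fits) {
  stopifnot(length(fits) > 0)
  if (is.null(names(fits))) names(fits) <- paste0("model", seq_along(fits))
  ok <- vapply(fits, function(f) !identical(f$converged, FALSE), logical(1))
  if (any(!ok)) {
    message(sum(!ok), " non-converged fit(s) excluded from selection: ",
            paste(names(fits)[!ok], collapse = ", "))
  }
  usable <- fits[ok]
  if (length(usable) == 0) stop("no converged candidate fits", call. = FALSE)
  aics <- vapply(usable, `[[`, numeric(1), "aic")
  bics <- vapply(usable, `[[`, numeric(1), "bic")
  best_i <- which(aics == min(aics))[1] # tie -> first declared
  tab <- data.frame(model = names(usable), aic = aics, bic = bics,
                    delta_aic = aics - min(aics), delta_bic = bics - min(bics),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(best = usable[[best_i]], name = names(usable)[best_i], table = tab)
}

# ---- combined prediction ----------------------------------------------------

#' Expected fraction of days detected (delta-lognormal combination)
#'
#' For each shark x receiver row, the probability of any detection from the
#' binomial stage times the back-transformed mean of the lognormal stage:
#' `E[frac] = pi * exp(mu + sigma^2 / 2)` with the lognormal bias correction
#' on by default (`bias_correct = FALSE` drops the `sigma^2/2` term for
#' sensitivity analysis). Values above 1 are clipped, with the clip count kept
#' in attribute `n_clipped`.
#'
#' @param presence_fit `shark_glm` from `fit_detection_glm(, "presence", )`.
#' @param fraction_fit `shark_glm` from `fit_detection_glm(, "fraction", )`.
#' @param rows Rows to predict for (same columns as [build_summary()]).
#' @param bias_correct Apply the `exp(sigma^2/2)` lognormal mean correction?
#' @return Numeric vector in `[0, 1]`, one value per row.
#' @export
combine_delta <- function(presence_fit, fraction_fit, rows,
                          bias_correct = TRUE) {
  stopifnot(inherits(presence_fit, "shark_glm"),
            inherits(fraction_fit, "shark_glm"))
  pi_hat <- predict(presence_fit$model, newdata = rows, type = "response")
  mu_hat <- predict(fraction_fit$model, newdata = rows)
  sigma2 <- summary(fraction_fit$model)$sigma^2
  ef <- pi_hat * exp(mu_hat + if (bias_correct) sigma2 / 2 else 0)
  n_clipped <- sum(ef > 1)
  ef <- pmin(pmax(ef, 0), 1)
  structure(unname(ef), n_clipped = n_clipped)
}

#' Predicted-vs-observed confusion matrix for the presence stage
#'
#' Rounds each fitted detection probability to 0/1 at `threshold` (ties count
#' as present) and cross-tabulates against the observed indicator.
#'
#' @param presence_fit `shark_glm` binomial fit.
#' @param rows Rows with observed `detected`; defaults to the training rows.
#' @param threshold Rounding threshold.
#' @return A list: `confusion` (2x2 matrix, predicted x observed) and
#'   `accuracy`.
#' @export
predict_presence <- function(presence_fit, rows = NULL, threshold = 0.5) {
  if (is.null(rows)) {
    p <- predict(presence_fit$model, type = "response")
    obs <- presence_fit$model$y
  } else {
    p <- predict(presence_fit$model, newdata = rows, type = "response")
    obs <- rows$detected
  }
  pred <- as.integer(round(p, 12) >= threshold) # ties (to rounding) -> present
  m <- table(factor(pred, levels = 0:1), factor(obs, levels = 0:1))
  m <- matrix(as.integer(m), 2, 2,
              dimnames = list(predicted = c("absent", "present"),
                              observed = c("absent", "present")))
  list(confusion = m, accuracy = confusion_accuracy(m))
}

#' Accuracy of a 2x2 confusion matrix
#' @param confusion 2x2 matrix, predicted x observed, absent/present order.
#' @return Fraction of rows on the diagonal.
#' @export
confusion_accuracy <- function(confusion) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == c(2, 2)),
            all(confusion >= 0))
  sum(diag(confusion)) / sum(confusion)
}
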