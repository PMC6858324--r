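.OUTCOME_TYPES <- c("fulfillment", "ideal_mv", "partner_mv")

#' Reshape mate-value records to the long outcome table
#'
#' One row per individual per observed outcome: fully partnered individuals
#' contribute three rows (fulfillment, ideal_mv, partner_mv); unpartnered
#' individuals contribute only the ideal_mv row. Rows with missing outcome
#' values are dropped listwise per row.
#'
#' @param records output of [mate_value_suite()].
#' @return data frame with columns `id`, `group`, `mate_value`,
#'   `outcome_type` (factor, fulfillment as reference level), and
#'   `outcome_value`.
#' @export
to_long <- function(records) {
  long <- do.call(rbind, lapply(.OUTCOME_TYPES, function(ot) {
    data.frame(id = records$id, group = records$group,
               mate_value = records$mate_value,
               outcome_type = ot, outcome_value = records[[ot]],
               stringsAsFactors = FALSE)
  }))
  long <- long[!is.na(long$outcome_value) & !is.na(long$mate_value), ]
  long$outcome_type <- factor(long$outcome_type, levels = .OUTCOME_TYPES)
  rownames(long) <- NULL
  long
}

#' Train the outcome predictor on a long table
#'
#' Fits the multilevel regression used for model comparison: outcome value
#' predicted from the interaction of mate value and outcome type (treatment
#' coding, fulfillment as reference), with a random intercept per individual
#' — three observations nested within each individual cannot support random
#' slopes. If the mixed fit fails or is singular, the fixed-effects-only
#' linear model is used instead and flagged. Since prediction targets
#' individuals never seen in training, predictions use fixed effects only
#' either way.
#'
#' @param table long table from [to_long()] (at least 2 outcome types and 10
#'   individuals).
#' @return an `mm_predictor`: list with `coefficients` (fixed effects),
#'   `std_slopes` (per-type standardized mate-value slopes), `fallback`
#'   (logical: fixed-effects-only fit used), `types` seen in training.
#' @export
train_predictor <- function(table) {
  table <- table[!is.na(table$outcome_value), ]
  types <- intersect(.OUTCOME_TYPES, unique(as.character(table$outcome_type)))
  if (length(types) < 2) stop("need at least 2 outcome types to train")
  if (length(unique(table$id)) < 10) stop("need at least 10 individuals")
  table$outcome_type <- factor(as.character(table$outcome_type),
                               levels = .OUTCOME_TYPES)

  fallback <- FALSE
  coefs <- NULL
  # convergence gripes on degenerate (e.g. noiseless) inputs are expected;
  # the singularity check below decides whether the fit is kept
  fit <- tryCatch(
    suppressWarnings(suppressMessages(lme4::lmer(
      outcome_value ~ mate_value * outcome_type + (1 | id), data = table,
      control = lme4::lmerControl(check.conv.singular = "ignore")))),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    coefs <- lme4::fixef(fit)
  } else {
    fallback <- TRUE
    lmfit <- stats::lm(outcome_value ~ mate_value * outcome_type,
                       data = table)
    coefs <- stats::coef(lmfit)
    coefs[is.na(coefs)] <- 0
  }

  # Standardized mate-value slope per outcome type, from the training data.
  std_slopes <- vapply(types, function(ot) {
    r <- table[table$outcome_type == ot, ]
    b <- coefs[["mate_value"]] +
      if (ot == "fulfillment") 0 else
        .coef_or_zero(coefs, paste0("mate_value:outcome_type", ot))
    sdo <- stats::sd(r$outcome_value)
    if (sdo > 0) b * stats::sd(r$mate_value) / sdo else NA_real_
  }, numeric(1))

  structure(list(coefficients = coefs, std_slopes = std_slopes,
                 fallback = fallback, types = types),
            class = "mm_predictor")
}

.coef_or_zero <- function(coefs, name) {
  if (name %in% names(coefs)) coefs[[name]] else 0
}

#' Predict outcomes from fixed effects only
#'
#' @param object an `mm_predictor`.
#' @param newdata data frame with `mate_value` and `outcome_type`.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.mm_predictor <- function(object, newdata, ...) {
  ot <- as.character(newdata$outcome_type)
  bad <- setdiff(unique(ot), object$types)
  if (length(bad))
    stop("outcome type(s) not seen in training: ", paste(bad, collapse = ", "))
  cf <- object$coefficients
  pred <- cf[["(Intercept)"]] + cf[["mate_value"]] * newdata$mate_value
  for (t in setdiff(object$types, "fulfillment")) {
    sel <- ot == t
    pred[sel] <- pred[sel] + .coef_or_zero(cf, paste0("outcome_type", t)) +
      .coef_or_zero(cf, paste0("mate_value:outcome_type", t)) *
        newdata$mate_value[sel]
  }
  unname(pred)
}

#' Score a trained predictor against a cohort, sight-unseen
#'
#' Predicts every row of the cohort's long table from fixed effects only and
#' returns the two fit indices: root mean squared error and the Pearson
#' correlation between predicted and observed values. Constant predictions
#' give a missing correlation.
#'
#' @param model an `mm_predictor`.
#' @param cohort_long long table of the held-out cohort (see [to_long()]).
#' @return list with `rmse` and `correlation`.
#' @export
score_out_of_sample <- function(model, cohort_long) {
  cohort_long <- cohort_long[!is.na(cohort_long$outcome_value) &
                               !is.na(cohort_long$mate_value), ]
  if (nrow(cohort_long) == 0) stop("cohort long table is empty")
  pred <- predict(model, cohort_long)
  obs <- cohort_long$outcome_value
  rmse <- sqrt(mean((pred - obs)^2))
  correlation <- if (stats::sd(pred) == 0) NA_real_ else stats::cor(pred, obs)
  list(rmse = rmse, correlation = correlation)
}

.t_ci <- function(v, conf = 0.95) {
  v <- v[!is.na(v)]
  n <- length(v)
  if (n < 2) return(c(mean = mean(v), lo = NA_real_, hi = NA_real_))
  half <- stats::qt(1 - (1 - conf) / 2, n - 1) * stats::sd(v) / sqrt(n)
  c(mean = mean(v), lo = mean(v) - half, hi = mean(v) + half)
}

#' Compare simulated markets against a cohort
#'
#' For every model, trains one predictor per run on that run's mate-value
#' records, scores it sight-unseen on the cohort, and aggregates RMSE and
#' predicted-observed correlation across runs with t-based 95% confidence
#' intervals. A cohort-trained baseline (`"cohort_baseline"`), fitted and
#' scored in-sample on the cohort itself, marks the best fit attainable by a
#' regression of this form.
#'
#' @param runs_by_model named list; each element is either a list of
#'   per-run [mate_value_suite()] record tables or a single table whose
#'   `group` column separates runs.
#' @param cohort_records [mate_value_suite()] records of the cohort.
#' @param conf confidence level.
#' @param include_baseline add the cohort-trained row (default TRUE).
#' @return an `mm_fitreport` data frame, one row per model sorted by
#'   descending mean correlation: `model`, `n_runs`, `rmse_mean`, `rmse_lo`,
#'   `rmse_hi`, `cor_mean`, `cor_lo`, `cor_hi`, `baseline`.
#' @export
compare_models <- function(runs_by_model, cohort_records, conf = 0.95,
                           include_baseline = TRUE) {
  cohort_long <- to_long(cohort_records)
  rows <- lapply(names(runs_by_model), function(m) {
    runs <- runs_by_model[[m]]
    if (is.data.frame(runs)) runs <- split(runs, runs$group)
    scores <- lapply(runs, function(rec) {
      score_out_of_sample(train_predictor(to_long(rec)), cohort_long)
    })
    rmse <- .t_ci(vapply(scores, `[[`, numeric(1), "rmse"), conf)
    corr <- .t_ci(vapply(scores, `[[`, numeric(1), "correlation"), conf)
    data.frame(model = m, n_runs = length(scores),
               rmse_mean = rmse[["mean"]], rmse_lo = rmse[["lo"]],
               rmse_hi = rmse[["hi"]], cor_mean = corr[["mean"]],
               cor_lo = corr[["lo"]], cor_hi = corr[["hi"]],
               baseline = FALSE, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (include_baseline) {
    base <- score_out_of_sample(train_predictor(cohort_long), cohort_long)
    out <- rbind(out, data.frame(
      model = "cohort_baseline", n_runs = 1L, rmse_mean = base$rmse,
      rmse_lo = NA_real_, rmse_hi = NA_real_, cor_mean = base$correlation,
      cor_lo = NA_real_, cor_hi = NA_real_, baseline = TRUE,
      stringsAsFactors = FALSE))
  }
  out <- out[order(-out$cor_mean), ]
  rownames(out) <- NULL
  class(out) <- c("mm_fitreport", "data.frame")
  out
}

#' Plot a fit report (RMSE vs predicted-observed correlation)
#'
#' Scatter of the two fit indices with confidence-interval bars in both
#' directions; points toward the top-left fit the cohort best. Requires
#' ggplot2.
#'
#' @param report an `mm_fitreport`.
#' @return a ggplot object.
#' @export
plot_fit_report <- function(report) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_fit_report() requires the ggplot2 package")
  ggplot2::ggplot(report,
                  ggplot2::aes(x = rmse_mean, y = cor_mean, label = model)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = cor_lo, ymax = cor_hi),
                           width = 0) +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = rmse_lo, xmax = rmse_hi),
                            height = 0) +
    ggplot2::geom_point(ggplot2::aes(shape = baseline), size = 2) +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::labs(x = "RMSE (lower is better)",
                  y = "Predicted-observed correlation (higher is better)",
                  shape = "Cohort-trained baseline") +
    ggplot2::theme_minimal()
}

utils::globalVariables(c("rmse_mean", "cor_mean", "model", "cor_lo", "cor_hi",
                         "rmse_lo", "rmse_hi", "baseline"))
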