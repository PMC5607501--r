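## Diagnostic modelling layer: logistic models compared by AIC, ROC/AUC by
## the rank (Mann-Whitney) construction, classification-tree cut-off
## discovery by exhaustive Gini scan, combined k-of-k rules, and
## confusion-matrix metrics.

#' Fit a logistic classification model for patient status
#'
#' Multiple logistic regression of patient status (patient = 1) on the
#' given predictor columns, by maximum likelihood (IRLS via
#' `stats::glm`). Records the log-likelihood, AIC = 2(k+1) - 2 lnL, and
#' flags (quasi-)complete separation and strong predictor collinearity.
#'
#' @param cohort A `cohort_table` with a `group` column.
#' @param predictors Character vector of predictor column names; empty for
#'   the intercept-only baseline.
#' @return Object of class `logistic_model`: list with `fit` (the glm),
#'   `predictors`, `coefficients`, `log_likelihood`, `aic`, `converged`,
#'   `separation`, `condition_number`.
#' @export
fit_logistic <- function(cohort, predictors = character()) {
  stopifnot("group" %in% names(cohort))
  y <- as.integer(cohort$group == "patient")
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("need at least 2 subjects per group")
  missing_p <- setdiff(predictors, names(cohort))
  if (length(missing_p))
    stop("predictors not in cohort: ", paste(missing_p, collapse = ", "))
  dat <- data.frame(.y = y, cohort[predictors], check.names = FALSE)
  form <- if (length(predictors))
    stats::reformulate(sprintf("`%s`", predictors), response = ".y")
  else .y ~ 1
  fit <- suppressWarnings(glm(form, family = binomial(), data = dat))
  ll <- as.numeric(stats::logLik(fit))
  k <- length(coef(fit))
  sep <- any(abs(coef(fit)[-1]) > 15) ||
    (length(predictors) > 0 &&
       all(fit$fitted.values[y == 1] > 0.999) &&
       all(fit$fitted.values[y == 0] < 0.001))
  cond <- NA_real_
  if (length(predictors) >= 2) {
    X <- scale(as.matrix(cohort[predictors]))
    sv <- svd(X, nu = 0, nv = 0)$d
    cond <- sv[1] / sv[length(sv)]
    if (is.finite(cond) && cond > 30)
      warning("predictors are strongly collinear (condition number ",
              round(cond, 1), ")")
  }
  structure(list(fit = fit, predictors = predictors,
                 coefficients = coef(fit), log_likelihood = ll,
                 aic = 2 * k - 2 * ll, converged = fit$converged,
                 separation = isTRUE(sep), condition_number = cond),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat("Logistic model:",
      if (length(x$predictors)) paste(x$predictors, collapse = " + ")
      else "(intercept only)", "\n")
  cat(sprintf("  logLik %.3f, AIC %.2f%s\n", x$log_likelihood, x$aic,
              if (x$separation) " [separation]" else ""))
  invisible(x)
}

#' @export
coef.logistic_model <- function(object, ...) object$coefficients

#' @export
predict.logistic_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) object$fit$fitted.values
  else predict(object$fit, newdata = newdata, type = "response")
}

#' ROC curve and AUC by the rank construction
#'
#' AUC is the Mann-Whitney probability that a randomly chosen patient
#' scores above a randomly chosen control, ties counting one half:
#' `AUC = (sum over pairs [s_p > s_c] + 0.5 [s_p = s_c]) / (n_p * n_c)`,
#' computed from midranks. ROC points are returned at every distinct
#' threshold.
#'
#' @param scores Numeric scores.
#' @param labels Group labels (`"control"`/`"patient"`, logical, or 0/1
#'   with 1 = patient).
#' @param larger_is_abnormal Direction: if FALSE the scores are negated
#'   before ranking (e.g. strain, where less-negative is abnormal, uses
#'   TRUE as well; set per parameter).
#' @return Object of class `roc_curve`: list with `auc` and `points`
#'   (data.frame threshold, tpr, fpr).
#' @export
roc_auc <- function(scores, labels, larger_is_abnormal = TRUE) {
  y <- normalize_labels(labels)
  stopifnot(length(scores) == length(y))
  if (!any(y == 1) || !any(y == 0))
    stop("both classes must be present")
  s <- if (larger_is_abnormal) scores else -scores
  n_p <- sum(y == 1); n_c <- sum(y == 0)
  r <- rank(s, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_p * (n_p + 1) / 2) / (n_p * n_c)
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  pts <- data.frame(
    threshold = thr,
    tpr = vapply(thr, function(t) mean(s[y == 1] >= t), numeric(1)),
    fpr = vapply(thr, function(t) mean(s[y == 0] >= t), numeric(1)))
  structure(list(auc = auc, points = pts), class = "roc_curve")
}

normalize_labels <- function(labels) {
  if (is.factor(labels) || is.character(labels)) {
    lv <- as.character(labels)
    stopifnot(all(lv %in% c("control", "patient")))
    as.integer(lv == "patient")
  } else as.integer(as.logical(labels))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d thresholds\n", x$auc,
              nrow(x$points)))
  invisible(x)
}

#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "s", xlab = "1 - specificity",
       ylab = "sensitivity", main = sprintf("AUC = %.3f", x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

## Gini impurity of a node holding n_p patients and n_c controls
gini <- function(n_p, n_c) {
  n <- n_p + n_c
  if (n == 0) return(0)
  p <- n_p / n
  2 * p * (1 - p)
}

#' Single-parameter cut-off by exhaustive classification-tree split
#'
#' Scans every candidate split point (midpoints between consecutive
#' distinct sorted values) and selects the one maximizing the decrease in
#' Gini impurity — the root split of a classification tree — subject to a
#' minimum leaf size. The abnormal direction is set so that the
#' patient-majority side of the split is called abnormal; score ties are
#' broken toward the smaller threshold.
#'
#' @param values Numeric parameter values.
#' @param labels Group labels (control/patient).
#' @param min_leaf Minimum subjects on each side of the split (default 7).
#' @return Object of class `cutoff_rule`: list with `parameter` (NA here;
#'   filled by callers), `threshold`, `direction` (`">="` abnormal-high or
#'   `"<="` abnormal-low), `gini_decrease`.
#' @export
tree_cutoff <- function(values, labels, min_leaf = 7L) {
  y <- normalize_labels(labels)
  stopifnot(length(values) == length(y))
  ok <- is.finite(values)
  values <- values[ok]; y <- y[ok]
  n <- length(y)
  if (n < 2L * min_leaf)
    stop("need at least 2 * min_leaf subjects")
  if (length(unique(y)) < 2L) stop("all labels identical: no split")
  u <- sort(unique(values))
  if (length(u) < 2L) stop("single unique value: no split")
  cand <- (head(u, -1) + tail(u, -1)) / 2
  root <- gini(sum(y), n - sum(y))
  best <- NULL
  for (thr in cand) {
    hi <- values >= thr
    n_hi <- sum(hi); n_lo <- n - n_hi
    if (n_hi < min_leaf || n_lo < min_leaf) next
    dec <- root - (n_hi / n) * gini(sum(y[hi]), n_hi - sum(y[hi])) -
      (n_lo / n) * gini(sum(y[!hi]), n_lo - sum(y[!hi]))
    if (is.null(best) || dec > best$dec + 1e-12)
      best <- list(thr = thr, dec = dec, n_hi = n_hi,
                   p_hi = mean(y[hi]), p_lo = mean(y[!hi]))
  }
  if (is.null(best)) stop("no admissible split under min_leaf = ", min_leaf)
  direction <- if (best$p_hi >= best$p_lo) ">=" else "<="
  structure(list(parameter = NA_character_, threshold = best$thr,
                 direction = direction, gini_decrease = best$dec),
            class = "cutoff_rule")
}

#' Build a named cut-off rule
#'
#' @param parameter Column name the rule applies to.
#' @param threshold Numeric threshold.
#' @param direction `">="` (values at or above threshold are abnormal) or
#'   `"<="`.
#' @return A `cutoff_rule`.
#' @export
cutoff_rule <- function(parameter, threshold, direction = ">=") {
  stopifnot(direction %in% c(">=", "<="))
  structure(list(parameter = parameter, threshold = threshold,
                 direction = direction, gini_decrease = NA_real_),
            class = "cutoff_rule")
}

#' @export
print.cutoff_rule <- function(x, ...) {
  cat(sprintf("Cut-off: %s %s %g\n",
              if (is.na(x$parameter)) "value" else x$parameter,
              x$direction, x$threshold))
  invisible(x)
}

rule_met <- function(rule, values) {
  if (rule$direction == ">=") values >= rule$threshold
  else values <= rule$threshold
}

#' Confusion-matrix diagnostic metrics
#'
#' Sensitivity, specificity, PPV, NPV and accuracy (percent) from the four
#' confusion counts. Exact fractions are kept in the `_frac` fields; the
#' percent fields are conventionally displayed rounded to integers by
#' `print`. Undefined ratios (zero denominators) are NA, never 0.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts.
#' @return Object of class `rule_metrics`: counts plus sensitivity,
#'   specificity, ppv, npv, accuracy in percent (and `*_frac` exact
#'   fractions); `auc` slot NA until set by the caller.
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  frac <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- frac(tp, tp + fn)
  spec <- frac(tn, tn + fp)
  ppv <- frac(tp, tp + fp)
  npv <- frac(tn, tn + fn)
  acc <- frac(tp + tn, tp + fp + tn + fn)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity_frac = sens, specificity_frac = spec,
                 ppv_frac = ppv, npv_frac = npv, accuracy_frac = acc,
                 sensitivity = 100 * sens, specificity = 100 * spec,
                 ppv = 100 * ppv, npv = 100 * npv, accuracy = 100 * acc,
                 auc = NA_real_),
            class = "rule_metrics")
}

#' @export
print.rule_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "n/a" else sprintf("%d%%", round(v))
  cat(sprintf("TP %d  FP %d  TN %d  FN %d\n", x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("sens %s  spec %s  PPV %s  NPV %s  acc %s",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$ppv),
              fmt(x$npv), fmt(x$accuracy)))
  if (!is.na(x$auc)) cat(sprintf("  AUC %.2f", x$auc))
  cat("\n")
  invisible(x)
}

#' Combined k-of-k rule metrics
#'
#' A subject is test-positive only if every listed criterion is met
#' (k-of-k positivity): sensitivity is the proportion of patients meeting
#' all k cut-offs, specificity the proportion of controls failing at least
#' one. Subjects with a missing parameter value are excluded (their count
#' is reported). Two AUCs accompany the counts: `auc` from the
#' logistic-model predicted probabilities over the same predictors, and
#' `auc_binary` from the binary rule output itself.
#'
#' @param cohort A `cohort_table`.
#' @param rules List of `cutoff_rule`s; a rule on column `LGE` with
#'   threshold 1 and `">="` expresses "LGE positive".
#' @param auc_from `"logistic"` (default) computes `auc` from logistic
#'   predicted probabilities; `"none"` leaves it NA.
#' @return A `rule_metrics` with extra fields `n_excluded`, `auc_binary`,
#'   `positive` (the per-subject rule output, NA for excluded subjects).
#' @export
combined_rule_metrics <- function(cohort, rules,
                                  auc_from = c("logistic", "none")) {
  auc_from <- match.arg(auc_from)
  stopifnot(length(rules) >= 1)
  pars <- vapply(rules, function(r) r$parameter, character(1))
  if (anyNA(pars)) stop("every rule needs a parameter name")
  missing_p <- setdiff(pars, names(cohort))
  if (length(missing_p))
    stop("rule parameters not in cohort: ",
         paste(missing_p, collapse = ", "))
  y <- normalize_labels(cohort$group)
  met <- sapply(rules, function(r) rule_met(r, cohort[[r$parameter]]))
  met <- matrix(met, nrow = nrow(cohort))
  complete <- rowSums(is.na(met)) == 0
  pos <- rep(NA, nrow(cohort))
  pos[complete] <- rowSums(met[complete, , drop = FALSE]) == length(rules)
  yc <- y[complete]; pc <- pos[complete]
  m <- confusion_metrics(tp = sum(pc & yc == 1), fp = sum(pc & yc == 0),
                         tn = sum(!pc & yc == 0), fn = sum(!pc & yc == 1))
  m$n_excluded <- sum(!complete)
  m$auc_binary <- roc_auc(as.numeric(pc), yc)$auc
  if (auc_from == "logistic") {
    mod <- fit_logistic(cohort[complete, , drop = FALSE], unique(pars))
    m$auc <- roc_auc(predict(mod), yc)$auc
  }
  m$positive <- pos
  m
}

#' Fit and rank candidate logistic models
#'
#' Fits a logistic model per predictor set, ranks by AIC (lower is
#' better), and attaches the AUC of each model's predicted probabilities —
#' the model-comparison workflow of the diagnostic analysis.
#'
#' @param cohort A `cohort_table`.
#' @param model_specs Named list of character vectors of predictor names
#'   (an empty vector gives the intercept-only baseline).
#' @return Data.frame sorted by AIC: model, predictors, n_predictors,
#'   log_likelihood, aic, auc, separation.
#' @export
model_comparison_report <- function(cohort, model_specs) {
  stopifnot(is.list(model_specs), length(model_specs) >= 1)
  nm <- names(model_specs)
  if (is.null(nm))
    nm <- vapply(model_specs, function(p)
      if (length(p)) paste(p, collapse = " + ") else "(intercept)",
      character(1))
  y <- normalize_labels(cohort$group)
  rows <- lapply(seq_along(model_specs), function(i) {
    mod <- fit_logistic(cohort, model_specs[[i]])
    auc <- if (length(model_specs[[i]]))
      roc_auc(predict(mod), y)$auc else 0.5
    data.frame(model = nm[i],
               predictors = paste(model_specs[[i]], collapse = "+"),
               n_predictors = length(model_specs[[i]]),
               log_likelihood = mod$log_likelihood, aic = mod$aic,
               auc = auc, separation = mod$separation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$aic), , drop = FALSE]
}
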