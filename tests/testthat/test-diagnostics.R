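two_group <- function(xc, xp, extra = NULL) {
  co <- data.frame(
    group = factor(rep(c("control", "patient"), c(length(xc), length(xp))),
                   levels = c("control", "patient")),
    x = c(xc, xp))
  if (!is.null(extra)) co <- cbind(co, extra)
  class(co) <- c("cohort_table", "data.frame")
  co
}

test_that("intercept-only logistic model has the closed-form AIC", {
  co <- two_group(c(0, 0), c(0, 0))   # 2 controls, 2 patients
  m <- fit_logistic(co, character())
  expect_equal(m$log_likelihood, 4 * log(0.5), tolerance = 1e-8)
  expect_equal(m$aic, 2 + 8 * log(2), tolerance = 1e-6)   # 7.545...
})

test_that("binary-predictor slope equals the log odds ratio", {
  ## 2x2 table a,b,c,d: slope = ln(ad/bc)
  set.seed(1)
  for (i in 1:10) {
    a <- sample(3:20, 1); b <- sample(3:20, 1)
    cc <- sample(3:20, 1); d <- sample(3:20, 1)
    ## predictor 1: a patients, b controls; predictor 0: c patients, d controls
    co <- two_group(rep(0, b + d), rep(0, a + cc))
    co$z <- c(rep(1, b), rep(0, d), rep(1, a), rep(0, cc))
    m <- fit_logistic(co, "z")
    expect_equal(unname(coef(m)["z"]), log(a * d / (b * cc)),
                 tolerance = 1e-6)
  }
})

test_that("perfect separation is flagged", {
  co <- two_group(rnorm(10, 0, 0.1), rnorm(10, 10, 0.1))
  m <- fit_logistic(co, "x")
  expect_true(m$separation)
})

test_that("collinear predictors trigger a condition-number warning", {
  set.seed(2)
  x <- rnorm(40)
  co <- two_group(x[1:20], x[21:40] + 2)
  co$x2 <- co$x * 3 + rnorm(40, sd = 1e-4)
  expect_warning(fit_logistic(co, c("x", "x2")), "collinear")
})

test_that("AUC reproduces the forced pairwise example", {
  ## patients {3,1,2}, controls {2,0}: 4 wins + 1 tie of 6 pairs = 0.75
  r <- roc_auc(c(2, 0, 3, 1, 2), c(0, 0, 1, 1, 1))
  expect_equal(r$auc, 4.5 / 6)
  ## perfectly separated scores
  expect_equal(roc_auc(c(1, 2, 9, 10), c(0, 0, 1, 1))$auc, 1.0)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank AUC equals the pairwise oracle on random instances", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(8:40, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(round(rnorm(n), sample(0:2, 1)))   # induce ties
    expect_identical(roc_auc(s, y)$auc, pairwise_auc_oracle(s, y))
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(8)
  y <- rbinom(60, 1, 0.4)
  s <- rnorm(60)
  a0 <- roc_auc(s, y)$auc
  expect_equal(roc_auc(exp(s), y)$auc, a0)
  expect_equal(roc_auc(s^3 + 2 * s, y)$auc, a0)
  expect_equal(roc_auc(-s, y, larger_is_abnormal = FALSE)$auc, a0)
})

test_that("AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  y <- c(rep(0, 25), rep(1, 40))
  s <- rnorm(65) + y
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(s, y)$auc, ref, tolerance = 1e-12)
})

test_that("single-rule sensitivity/specificity sit on the ROC curve", {
  set.seed(44)
  co <- two_group(rnorm(30, 1.7, 1), rnorm(40, 2.9, 1.4))
  r <- roc_auc(co$x, co$group)
  thr <- 2.1
  m <- combined_rule_metrics(co, list(cutoff_rule("x", thr)),
                             auc_from = "none")
  i <- which(r$points$threshold == max(r$points$threshold[
    r$points$threshold <= thr]))
  ## the rule x >= 2.1 corresponds to the ROC point at the smallest
  ## observed score >= 2.1
  pt_tpr <- mean(co$x[co$group == "patient"] >= thr)
  pt_fpr <- mean(co$x[co$group == "control"] >= thr)
  expect_equal(m$sensitivity_frac, pt_tpr)
  expect_equal(1 - m$specificity_frac, pt_fpr)
  expect_true(any(abs(r$points$tpr - pt_tpr) < 1e-12 &
                    abs(r$points$fpr - pt_fpr) < 1e-12))
})

test_that("tree cut-off finds the clean separation midpoint", {
  r <- tree_cutoff(c(1, 1, 1, 3, 3, 3), c(0, 0, 0, 1, 1, 1), min_leaf = 1)
  expect_equal(r$threshold, 2.0)
  expect_equal(r$direction, ">=")
  expect_error(tree_cutoff(c(1, 2, 3, 4), c(1, 1, 1, 1), min_leaf = 1),
               "labels identical")
  expect_error(tree_cutoff(rep(2, 6), c(0, 0, 0, 1, 1, 1), min_leaf = 1),
               "single unique")
})

test_that("direction flips when patients sit below the threshold", {
  r <- tree_cutoff(c(5, 6, 7, 1, 2, 3), c(0, 0, 0, 1, 1, 1), min_leaf = 1)
  expect_equal(r$threshold, 4)
  expect_equal(r$direction, "<=")
})

test_that("tree cut-off equals the independent exhaustive scan", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(20:60, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    v <- round(rnorm(n, mean = y), sample(1:2, 1))
    r <- tryCatch(tree_cutoff(v, y, min_leaf = 5), error = function(e) NULL)
    o <- gini_scan_oracle(v, y, min_leaf = 5)
    if (is.null(r)) {
      expect_true(!is.finite(o$dec) || is.na(o$thr))
    } else {
      expect_equal(r$threshold, o$thr)
      expect_equal(r$gini_decrease, o$dec, tolerance = 1e-12)
    }
  }
})

test_that("planted cut-off at 1.8 is recovered on noisy cohorts", {
  set.seed(66)
  for (rep in 1:5) {
    n <- 100
    y <- rbinom(n, 1, 0.6)
    v <- ifelse(y == 1, runif(n, 1.9, 4.5), runif(n, 0.2, 1.7))
    flip <- sample(n, round(0.1 * n))      # 10% label noise
    y[flip] <- 1 - y[flip]
    r <- tree_cutoff(v, y, min_leaf = 7)
    ## recovered threshold lies in the gap between the generative bands
    expect_gt(r$threshold, 1.6)
    expect_lt(r$threshold, 2.0)
    expect_equal(r$direction, ">=")
  }
})

test_that("tree cut-off matches the root split of rpart", {
  skip_if_not_installed("rpart")
  set.seed(91)
  for (i in 1:10) {
    n <- 80
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    v <- rnorm(n, mean = 1.5 * y)
    fit <- rpart::rpart(factor(y) ~ v, data = data.frame(y = y, v = v),
                        method = "class",
                        control = rpart::rpart.control(
                          minsplit = 2, minbucket = 7, cp = 0,
                          maxdepth = 1, xval = 0))
    if (is.null(fit$splits)) next
    r <- tree_cutoff(v, y, min_leaf = 7)
    expect_equal(r$threshold, unname(fit$splits[1, "index"]),
                 tolerance = 1e-8)
  }
})

test_that("confusion metrics reproduce the worked 67/17 example", {
  ## 39 of 67 patients detected, all 17 controls negative
  m <- confusion_metrics(tp = 39, fp = 0, tn = 17, fn = 28)
  expect_equal(round(m$sensitivity), 58)
  expect_equal(round(m$specificity), 100)
  expect_equal(round(m$ppv), 100)
  expect_equal(round(m$npv), 38)
  expect_equal(round(m$accuracy), 67)
  ## exact fractions are retained
  expect_equal(m$sensitivity_frac, 39 / 67)
  expect_equal(m$accuracy_frac, 56 / 84)
})

test_that("undefined ratios are NA, never zero", {
  m <- confusion_metrics(tp = 0, fp = 3, tn = 5, fn = 0)
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$npv) == FALSE)      # tn + fn = 5 > 0
  m2 <- confusion_metrics(tp = 5, fp = 0, tn = 7, fn = 0)
  expect_equal(m2$sensitivity, 100)
  expect_equal(m2$specificity, 100)
  expect_equal(m2$accuracy, 100)
})

test_that("k-of-k positivity requires every criterion", {
  rules <- list(cutoff_rule("madSD_ms", 1.8, ">="),
                cutoff_rule("GCS_LV_pct", -25, ">="),
                cutoff_rule("LGE", 1, ">="))
  co <- data.frame(
    group = factor(c("patient", "patient", "control"),
                   levels = c("control", "patient")),
    madSD_ms = c(2.0, 2.0, 1.0),
    GCS_LV_pct = c(-20, -30, -28),
    LGE = c(1, 1, 0))
  class(co) <- c("cohort_table", "data.frame")
  m <- combined_rule_metrics(co, rules, auc_from = "none")
  ## patient 1 meets all three; patient 2 fails GCS (-30 < -25)
  expect_equal(m$positive[1], TRUE)
  expect_equal(m$positive[2], FALSE)
  expect_equal(m$tp, 1); expect_equal(m$fn, 1); expect_equal(m$tn, 1)
})

test_that("degenerate rules saturate sensitivity and specificity", {
  co <- two_group(rnorm(10), rnorm(12))
  m <- combined_rule_metrics(co, list(cutoff_rule("x", -Inf)),
                             auc_from = "none")
  expect_equal(m$sensitivity, 100)
  expect_equal(m$specificity, 0)
})

test_that("adding a criterion never raises sensitivity or lowers specificity", {
  set.seed(14)
  for (i in 1:10) {
    co <- simulate_cohort(cohort_spec(n_controls = 30, n_patients = 50,
                                      seed = 1000 + i))
    r1 <- list(cutoff_rule("madSD_ms", 1.8))
    r2 <- c(r1, list(cutoff_rule("GCS_LV_pct", -25)))
    r3 <- c(r2, list(cutoff_rule("LGE", 1)))
    m1 <- combined_rule_metrics(co, r1, auc_from = "none")
    m2 <- combined_rule_metrics(co, r2, auc_from = "none")
    m3 <- combined_rule_metrics(co, r3, auc_from = "none")
    expect_true(m2$sensitivity_frac <= m1$sensitivity_frac + 1e-12)
    expect_true(m3$sensitivity_frac <= m2$sensitivity_frac + 1e-12)
    expect_true(m2$specificity_frac >= m1$specificity_frac - 1e-12)
    expect_true(m3$specificity_frac >= m2$specificity_frac - 1e-12)
  }
})

test_that("model comparison prefers the true sparse model by AIC", {
  ## data generated with only predictor A informative: {A} should beat
  ## {A, B} in most seeded cohorts (AIC penalty on the useless predictor)
  set.seed(70)
  wins <- 0L
  n_rep <- 40L
  for (i in seq_len(n_rep)) {
    n <- 90
    a <- rnorm(n)
    b <- rnorm(n)
    y <- rbinom(n, 1, plogis(-0.3 + 1.2 * a))
    if (length(unique(y)) < 2) next
    co <- data.frame(group = factor(ifelse(y == 1, "patient", "control"),
                                    levels = c("control", "patient")),
                     A = a, B = b)
    class(co) <- c("cohort_table", "data.frame")
    rep_tab <- model_comparison_report(co, list(A = "A", AB = c("A", "B")))
    if (rep_tab$model[1] == "A") wins <- wins + 1L
  }
  expect_gt(wins / n_rep, 0.7)
})

test_that("model comparison report is deterministic and ranked", {
  co <- simulate_cohort(cohort_spec(seed = 3))
  specs <- list(madSD = "madSD_ms", twice = "madSD_ms",
                base = character())
  tab <- model_comparison_report(co, specs)
  expect_equal(tab$aic, sort(tab$aic))
  ## identical model listed twice gives identical rows
  expect_equal(tab$aic[tab$model == "madSD"],
               tab$aic[tab$model == "twice"])
  ## intercept-only baseline present with AUC 0.5
  expect_equal(tab$auc[tab$model == "base"], 0.5)
})
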