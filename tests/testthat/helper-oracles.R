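## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: brute-force enumeration, grid search, direct
## double loops.

## Ring contour fixture: n points on a circle.
ring_contour <- function(n = 32, r = 30, center = c(48, 48)) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

## Brute-force Rician maximum-likelihood (s0, t2) by grid search over t2
## (fixed step) with profile optimization of s0 at each candidate.
grid_mle_oracle <- function(m, te, sigma, t2_grid = seq(1, 300, by = 0.5)) {
  best_t2 <- NA_real_
  best_ll <- -Inf
  for (t2 in t2_grid) {
    shape <- exp(-te / t2)
    op <- stats::optimize(
      function(s0) myomapr::rician_loglik(m, s0 * shape, sigma),
      lower = 1e-6, upper = max(m) * 5 + 10 * sigma, maximum = TRUE)
    if (op$objective > best_ll) {
      best_ll <- op$objective
      best_t2 <- t2
    }
  }
  list(t2 = best_t2, loglik = best_ll)
}

## O(n^2) pairwise AUC: patients vs controls, ties count one half.
pairwise_auc_oracle <- function(scores, labels) {
  y <- if (is.factor(labels) || is.character(labels))
    as.integer(as.character(labels) == "patient") else as.integer(labels)
  sp <- scores[y == 1]
  sc <- scores[y == 0]
  tot <- 0
  for (a in sp) for (b in sc)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sc))
}

## Exhaustive Gini root-split scan, written independently of the package:
## iterates candidate thresholds as midpoints, computes impurity decrease
## directly from counts, first (smallest) maximizer wins.
gini_scan_oracle <- function(values, labels, min_leaf = 7L) {
  y <- if (is.factor(labels) || is.character(labels))
    as.integer(as.character(labels) == "patient") else as.integer(labels)
  ok <- is.finite(values)
  values <- values[ok]; y <- y[ok]
  n <- length(y)
  g <- function(np, nc) {
    tot <- np + nc
    if (tot == 0) 0 else 2 * (np / tot) * (nc / tot)
  }
  u <- sort(unique(values))
  cands <- (u[-length(u)] + u[-1]) / 2
  root <- g(sum(y), n - sum(y))
  best <- list(dec = -Inf, thr = NA_real_)
  for (thr in cands) {
    above <- values >= thr
    na <- sum(above); nb <- n - na
    if (na < min_leaf || nb < min_leaf) next
    dec <- root - (na / n) * g(sum(y[above]), na - sum(y[above])) -
      (nb / n) * g(sum(y[!above]), nb - sum(y[!above]))
    if (dec > best$dec + 1e-12) best <- list(dec = dec, thr = thr)
  }
  best
}

## Exact one-sided Wilcoxon p-value by exhaustive enumeration of group
## assignments (small n only).
wilcoxon_exact_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  k <- length(x)
  idx <- utils::combn(n, k)
  obs <- sum(rank(pooled)[seq_len(k)])
  stat <- apply(idx, 2, function(ii) sum(rank(pooled)[ii]))
  mean(stat <= obs)
}
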