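#' Standardize a numeric series (z-scoring)
#'
#' Centers to mean 0 and scales to sample SD 1. Used before distribution
#' comparisons so that automated and manual noise measurements are compared
#' irrespective of their absolute scales.
#'
#' @param values Numeric vector, `n >= 2`, non-constant.
#' @return Standardized vector.
#' @export
zscore <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("zero variance: need n >= 2", call. = FALSE)
  s <- sd(values)
  if (!is.finite(s) || s == 0) stop("zero variance", call. = FALSE)
  (values - mean(values)) / s
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# two-sample KS D with tie handling, given pooled sorted structure
ks_d_from_sorted <- function(w_sorted, keep) {
  max(abs(cumsum(w_sorted)[keep]))
}

#' Paired two-sample Kolmogorov-Smirnov test
#'
#' Compares the distributions of two paired series with the two-sample KS
#' statistic `D = sup |ECDF_x - ECDF_y|`, with a null distribution that
#' respects the pairing: each permutation randomly swaps `x_i` and `y_i`
#' within pair `i` (a within-pair label flip), and the p-value is the
#' add-one permutation estimate `p = (1 + #\{D_perm >= D_obs\}) / (1 +
#' n_permutations)`. The asymptotic unpaired two-sample KS p-value is also
#' reported for transparency.
#'
#' @param x,y Paired numeric series of equal length `n >= 3`.
#' @param n_permutations Number of within-pair swap permutations (default
#'   9999).
#' @param seed Integer seed making the permutation p-value reproducible.
#' @return Object of class `ks_result`: `d_statistic`, `p_value`,
#'   `p_asymptotic`, `n_pairs`, `n_permutations`, `seed`.
#' @export
paired_ks_test <- function(x, y, n_permutations = 9999L, seed = 1L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("unpaired input: lengths differ", call. = FALSE)
  if (n < 3L) stop("need at least 3 pairs", call. = FALSE)

  z <- c(x, y)
  w <- c(rep(1 / n, n), rep(-1 / n, n))
  o <- order(z)
  zs <- z[o]
  keep <- c(diff(zs) != 0, TRUE)
  wo <- w[o]
  po <- c(seq_len(n), seq_len(n))[o]   # pair id of each pooled point
  d_obs <- ks_d_from_sorted(wo, keep)

  eps <- 1e-12
  n_ge <- with_seed(seed, {
    count <- 0L
    for (b in seq_len(n_permutations)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      d_b <- ks_d_from_sorted(wo * s[po], keep)
      if (d_b >= d_obs - eps) count <- count + 1L
    }
    count
  })
  p_perm <- (1 + n_ge) / (1 + n_permutations)
  p_asym <- suppressWarnings(stats::ks.test(x, y, exact = FALSE)$p.value)

  structure(
    list(d_statistic = d_obs, p_value = p_perm, p_asymptotic = p_asym,
         n_pairs = n, n_permutations = as.integer(n_permutations),
         seed = as.integer(seed)),
    class = "ks_result"
  )
}

#' Spearman rank correlation with verbal interpretation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value from
#' the t approximation; the coefficient is labeled on the verbal scale of
#' [interpret_correlation()].
#'
#' @param x,y Numeric series of equal length `n >= 3`.
#' @return Object of class `correlation_result`: `rho`, `p_value`, `n`,
#'   `chan_label`.
#' @export
spearman_cor <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop("unpaired input: lengths differ", call. = FALSE)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop("undefined correlation: constant series", call. = FALSE)
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(
    list(rho = rho, p_value = p, n = n, chan_label = interpret_correlation(rho)),
    class = "correlation_result"
  )
}

#' Verbal interpretation of a correlation coefficient
#'
#' Maps `|rho|` to a verbal strength label: at least 0.8 "very strong", 0.6
#' up to 0.8 "moderately strong", 0.3 to 0.5 "fair", less than 0.3 "poor".
#' The scale as stated leaves (0.5, 0.6) unmapped; such values are flagged
#' `"unclassified"` rather than silently binned.
#'
#' @param rho Correlation coefficient in `[-1, 1]`.
#' @return One of `"very strong"`, `"moderately strong"`, `"fair"`,
#'   `"poor"`, `"unclassified"`.
#' @export
interpret_correlation <- function(rho) {
  if (!is.finite(rho) || abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  a <- abs(rho)
  if (a >= 0.8) "very strong"
  else if (a >= 0.6) "moderately strong"
  else if (a > 0.5) "unclassified"
  else if (a >= 0.3) "fair"
  else "poor"
}

#' ROC analysis of a noise score against binary quality labels
#'
#' Builds the empirical ROC of a score (e.g. the GNI) for discriminating
#' insufficient from sufficient image quality. Higher scores are treated as
#' evidence of insufficient quality: the positive class is "insufficient"
#' and a case is called positive when `score >= cutoff`. The AUC is the
#' trapezoidal area (equal to the normalized Mann-Whitney U statistic, ties
#' counted 1/2), with a DeLong 95% confidence interval, and the reported
#' operating point maximizes Youden's index `sensitivity + specificity - 1`
#' over the empirical thresholds.
#'
#' @param scores Numeric scores (higher = noisier).
#' @param labels Character/factor with values `"sufficient"` /
#'   `"insufficient"` (or a logical vector, `TRUE` = insufficient).
#' @return Object of class `roc_result`.
#' @export
roc_analysis <- function(scores, labels) {
  scores <- as.numeric(scores)
  if (is.logical(labels)) {
    labels <- ifelse(labels, "insufficient", "sufficient")
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("sufficient", "insufficient"))) {
    stop("labels must be 'sufficient' or 'insufficient'", call. = FALSE)
  }
  if (length(labels) != length(scores)) {
    stop("scores and labels must have equal length", call. = FALSE)
  }
  pos <- labels == "insufficient"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("degenerate labels: both classes required", call. = FALSE)

  xp <- scores[pos]; xn <- scores[!pos]

  # AUC by the rank (Mann-Whitney) formula; ties contribute 1/2
  r <- rank(scores)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)

  # DeLong variance from placement values
  v10 <- vapply(xp, function(xi) (sum(xi > xn) + 0.5 * sum(xi == xn)) / n0,
                numeric(1))
  v01 <- vapply(xn, function(yj) (sum(xp > yj) + 0.5 * sum(xp == yj)) / n1,
                numeric(1))
  var_auc <- stats::var(v10) / n1 + stats::var(v01) / n0
  half <- qnorm(0.975) * sqrt(max(var_auc, 0))
  ci <- c(max(0, auc - half), min(1, auc + half))

  # empirical operating points: positive iff score >= threshold
  thr <- sort(unique(scores))
  thresholds <- c(thr, Inf)
  sens <- vapply(thresholds, function(t) mean(xp >= t), numeric(1))
  spec <- vapply(thresholds, function(t) mean(xn < t), numeric(1))
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[1L]                     # ties: lowest cutoff

  structure(
    list(
      thresholds = thresholds,
      sensitivity = sens,
      specificity = spec,
      auc = auc,
      auc_ci95 = ci,
      youden_cutoff = thresholds[best],
      sens_at_cutoff = sens[best],
      spec_at_cutoff = spec[best],
      positive_label_is_insufficient = TRUE,
      n_positive = n1,
      n_negative = n0
    ),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "ROC: AUC %.3f (95%% CI %.3f-%.3f), Youden cutoff %.4g (sens %.0f%%, spec %.0f%%)\n",
    x$auc, x$auc_ci95[1], x$auc_ci95[2], x$youden_cutoff,
    100 * x$sens_at_cutoff, 100 * x$spec_at_cutoff
  ))
  invisible(x)
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf(
    "Paired KS: D = %.4f, permutation p = %.4g (%d pairs, %d permutations, seed %d)\n",
    x$d_statistic, x$p_value, x$n_pairs, x$n_permutations, x$seed
  ))
  invisible(x)
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f (%s), p = %.4g, n = %d\n",
              x$rho, x$chan_label, x$p_value, x$n))
  invisible(x)
}
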