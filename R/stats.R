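# Nonparametric statistics used throughout the pipeline. The exact
# signed-rank test and the Benjamini-Hochberg step-up are implemented here
# (the exact small-sample tail is the quantity of interest at n = 8, where
# the smallest attainable two-sided p is 2/2^8 = 0.0078125); the remaining
# standard tests wrap base R behind a common result container.

test_result <- function(statistic, p, n, method, tails = "two-sided") {
  structure(list(statistic = unname(statistic), p = unname(min(1, max(0, p))),
                 n = n, method = method, tails = tails),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (n = %d, %s)\n",
              x$method, x$statistic, x$p, x$n, x$tails))
  invisible(x)
}

#' Exact Wilcoxon signed-rank test
#'
#' Two-sided one-sample signed-rank test on paired differences. For
#' `n <= exact_limit` the p-value is computed from the exact permutation
#' distribution over all 2^n sign assignments, evaluated by dynamic
#' programming over (doubled, tie-averaged) ranks — so ties are handled
#' exactly rather than by a continuity-corrected approximation. Above the
#' limit, a normal approximation with tie correction is used. Zero
#' differences are dropped (with a message); with n = 8 all-positive
#' differences the exact two-sided p is 2/256 = 0.0078125.
#'
#' @param diffs numeric vector of paired differences.
#' @param exact_limit largest n for the exact distribution (default 25).
#' @return a `test_result` with the signed-rank statistic W (sum of ranks of
#'   positive differences).
#' @export
wilcoxon_signed_rank <- function(diffs, exact_limit = 25) {
  diffs <- diffs[!is.na(diffs)]
  nz <- diffs != 0
  if (sum(!nz) > 0)
    message(sprintf("wilcoxon_signed_rank: dropped %d zero difference(s)",
                    sum(!nz)))
  d <- diffs[nz]
  n <- length(d)
  if (n == 0) stop("all differences are zero: signed-rank test undefined")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= exact_limit) {
    # DP over doubled ranks (integers even with average-rank ties)
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    counts <- c(1, rep(0, total))          # counts[w+1] = #assignments, W2 = w
    for (ri in r2) {
      shifted <- c(rep(0, ri), counts[seq_len(total + 1 - ri)])
      counts <- counts + shifted
    }
    probs <- counts / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(probs[seq_len(w2 + 1)])
    p_ge <- sum(probs[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "Wilcoxon signed-rank (exact)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (W - mu) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "Wilcoxon signed-rank (normal approximation)"
  }
  test_result(W, p, n, method)
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjustment: `q_(i) = min_(j >= i) m p_(j) / j` over the sorted
#' p-values, preserving the input order. NAs propagate (and do not count
#' toward m).
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return vector of q-values, same order as the input.
#' @export
benjamini_hochberg <- function(pvals) {
  q <- rep(NA_real_, length(pvals))
  ok <- which(!is.na(pvals))
  m <- length(ok)
  if (m == 0) return(q)
  p <- pvals[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  o <- order(p, decreasing = TRUE)
  qs <- pmin(1, cummin(m / seq(m, 1) * p[o]))
  q[ok[o]] <- qs
  q
}

#' Kolmogorov-Smirnov normality gate
#'
#' KS statistic of the sample against a normal distribution with the
#' sample's own mean and standard deviation. Because the parameters are
#' estimated from the same sample, the nominal p-value is conservative
#' (Lilliefors caveat); the test is used only as a gate for choosing a
#' nonparametric test over a t-test. With n < 4 the gate defaults to
#' nonparametric (p = 0).
#'
#' @param sample numeric vector.
#' @return a `test_result`; `p > 0.05` is treated as compatible with
#'   normality.
#' @export
ks_normality <- function(sample) {
  sample <- sample[!is.na(sample)]
  n <- length(sample)
  if (n < 4 || stats::sd(sample) == 0)
    return(test_result(NA_real_, 0, n, "Kolmogorov-Smirnov normality (small-sample gate)"))
  kt <- suppressWarnings(stats::ks.test(sample, "pnorm", mean(sample),
                                        stats::sd(sample)))
  test_result(kt$statistic, kt$p.value, n, "Kolmogorov-Smirnov normality")
}

#' Paired t-test
#'
#' @param x,y paired numeric vectors.
#' @return a `test_result`.
#' @export
paired_t_test <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (stats::sd(x - y) == 0 && all(x == y))
    return(test_result(0, 1, length(x), "Paired t-test"))
  tt <- stats::t.test(x, y, paired = TRUE)
  test_result(tt$statistic, tt$p.value, length(x), "Paired t-test")
}

#' Friedman test
#'
#' Nonparametric repeated-measures test across treatments (columns) with
#' subjects as blocks (rows); average ranks for ties. Identical blocks give
#' a statistic of 0.
#'
#' @param blocks numeric matrix, subjects x treatments.
#' @return a `test_result`.
#' @export
friedman <- function(blocks) {
  blocks <- as.matrix(blocks)
  n <- nrow(blocks); k <- ncol(blocks)
  if (n < 2 || k < 2)
    stop(sprintf("degenerate block design: %d subject(s) x %d treatment(s)",
                 n, k))
  R <- t(apply(blocks, 1, rank))
  S <- sum((colSums(R) - n * (k + 1) / 2)^2)
  C <- sum(apply(blocks, 1, function(row) {
    tt <- table(row); sum(tt^3 - tt)
  }))
  denom <- n * k * (k + 1) - C / (k - 1)
  if (denom <= 0)                       # every block fully tied
    return(test_result(0, 1, n, "Friedman test"))
  chisq <- 12 * S / denom
  test_result(chisq, stats::pchisq(chisq, df = k - 1, lower.tail = FALSE),
              n, "Friedman test")
}

#' Kruskal-Wallis test
#'
#' @param groups list of numeric vectors.
#' @return a `test_result`.
#' @export
kruskal_wallis <- function(groups) {
  sizes <- vapply(groups, length, integer(1))
  if (any(sizes < 1))
    stop("degenerate group: ",
         paste(names(groups)[sizes < 1], collapse = ", "))
  if (length(unique(unlist(groups))) == 1)
    return(test_result(0, 1, sum(sizes), "Kruskal-Wallis test"))
  kt <- stats::kruskal.test(groups)
  test_result(kt$statistic, kt$p.value, sum(sizes), "Kruskal-Wallis test")
}
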