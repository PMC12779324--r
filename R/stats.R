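#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact p by hypergeometric enumeration with the minimum-likelihood
#' convention: the sum of the probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table.
#'
#' @param tab 2x2 matrix of non-negative counts (rows = group, columns =
#'   outcome), e.g. `matrix(c(15, 3, 0, 6), 2)` for 15/15 vs 3/9 animals.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (any(dim(tab) != 2) || any(tab < 0) || any(tab != round(tab)))
    stop("need a 2x2 matrix of non-negative integer counts")
  if (sum(tab) == 0) stop("all-zero table")
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  ks <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(ks, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Cohen's kappa from a confusion matrix
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = trace/total` and chance agreement
#' `p_e = sum_k row_k * col_k / total^2`. When `p_e = 1` the statistic is
#' undefined and `NA` is returned with a warning.
#'
#' @param cm square matrix of counts, rows = reference, columns = automated.
#' @return kappa (dimensionless).
#' @export
cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) stop("confusion matrix must be square")
  if (any(cm < 0)) stop("negative counts")
  tot <- sum(cm)
  if (tot <= 0) stop("empty confusion matrix")
  po <- sum(diag(cm)) / tot
  pe <- sum(rowSums(cm) * colSums(cm)) / tot^2
  if (abs(1 - pe) < 1e-12) {
    warning("chance agreement is 1; kappa undefined")
    return(NA_real_)
  }
  (po - pe) / (1 - pe)
}

#' Pearson correlation with t statistic and p-value
#'
#' `r` is the sample correlation; `t = r * sqrt(df) / sqrt(1 - r^2)` with
#' `df = n - 2`; the p-value is two-sided from the t distribution.
#'
#' @param x,y numeric vectors of equal length `n >= 3` with non-zero variance.
#' @return `list(r, t, df, p)`.
#' @export
pearson_r <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need n >= 3")
  xd <- x - mean(x); yd <- y - mean(y)
  sx <- sqrt(sum(xd^2)); sy <- sqrt(sum(yd^2))
  if (sx == 0 || sy == 0) stop("constant input: correlation undefined")
  r <- sum(xd * yd) / (sx * sy)
  df <- n - 2
  t <- if (abs(r) >= 1) sign(r) * Inf else r * sqrt(df) / sqrt(1 - r^2)
  p <- 2 * stats::pt(-abs(t), df)
  list(r = r, t = t, df = df, p = p)
}

#' Two-sample comparison: Welch t or Wilcoxon rank sum
#'
#' `welch_t` delegates to [stats::t.test()] (Welch-Satterthwaite df).
#' `rank_sum` uses midranks for ties; for combined `n <= 20` (or
#' `exact = TRUE`) the two-sided p is exact — the permutation mass of rank
#' sums at least as far from their mean as observed, computed by dynamic
#' programming over the doubled midranks — otherwise a normal approximation
#' with tie correction and continuity correction.
#'
#' @param a,b numeric vectors (each `n >= 2`).
#' @param method `"welch_t"` or `"rank_sum"`.
#' @param exact force exact/approximate rank-sum (`NULL` = auto by size).
#' @return `list(statistic, p, method)`; `statistic` is the t value or the
#'   rank-sum `W` of group `a`.
#' @export
two_sample_test <- function(a, b, method = c("welch_t", "rank_sum"),
                            exact = NULL) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (method == "welch_t") {
    tt <- stats::t.test(a, b)
    return(list(statistic = unname(tt$statistic), p = tt$p.value,
                method = "welch_t", df = unname(tt$parameter)))
  }
  na <- length(a); nb <- length(b); N <- na + nb
  rk <- rank(c(a, b))           # midranks
  W <- sum(rk[seq_len(na)])
  use_exact <- exact %||% (N <= 20)
  if (use_exact) {
    p <- rank_sum_exact_p(rk, na, W)
  } else {
    mu <- na * (N + 1) / 2
    ties <- table(rk)
    sig2 <- na * nb * (N + 1) / 12 -
      na * nb * sum(ties^3 - ties) / (12 * N * (N - 1))
    if (sig2 <= 0) return(list(statistic = W, p = 1, method = "rank_sum"))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  list(statistic = W, p = p, method = "rank_sum")
}

# exact two-sided rank-sum p: DP over doubled midranks (integers) counting,
# for each subset size, how many subsets attain each doubled rank sum
rank_sum_exact_p <- function(rk, na, W) {
  r2 <- as.integer(round(2 * rk))
  N <- length(r2)
  total_max <- sum(sort(r2, decreasing = TRUE)[seq_len(na)])
  # dp[k+1, s+1] = number of k-subsets with doubled rank sum s
  dp <- matrix(0, na + 1, total_max + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    kmax <- na
    for (k in kmax:1) {
      nz <- which(dp[k, ] > 0)
      nz <- nz[nz - 1 + v <= total_max]
      if (length(nz)) dp[k + 1, nz + v] <- dp[k + 1, nz + v] + dp[k, nz]
    }
  }
  counts <- dp[na + 1, ]
  sums2 <- which(counts > 0) - 1
  cnt <- counts[counts > 0]
  mu2 <- na * sum(r2) / N
  dev <- abs(sums2 - mu2)
  obs <- abs(2 * W - mu2)
  sum(cnt[dev >= obs - 1e-9]) / sum(cnt)
}
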