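#' Quantile-normalize the columns of a matrix
#'
#' Forces every sample (column) onto the same distribution: the mean of the
#' per-sample sorted values. Ties within a column receive the mean of the
#' reference values across their rank span, so tied inputs stay tied.
#'
#' @param x Numeric matrix (features x samples) or [count_matrix()].
#' @return Real-valued matrix of the same dimension (a plain matrix; the
#'   design of a `count_matrix` input is carried through unchanged as the
#'   `samples` attribute).
#' @examples
#' quantile_normalize(cbind(a = c(1, 10), b = c(2, 20)))
#' @export
quantile_normalize <- function(x) {
  cm <- NULL
  if (inherits(x, "count_matrix")) {
    cm <- x
    x <- x$counts
  }
  x <- as.matrix(x)
  if (ncol(x) < 2L) stop("quantile normalization needs at least 2 samples")
  ref <- rowMeans(apply(x, 2L, sort))
  out <- x
  for (j in seq_len(ncol(x))) {
    r <- rank(x[, j], ties.method = "min")
    runs <- rank(x[, j], ties.method = "max")
    # mean of reference values over each tie's rank span
    cref <- c(0, cumsum(ref))
    lo <- r
    hi <- runs
    out[, j] <- (cref[hi + 1L] - cref[lo]) / (hi - lo + 1)
  }
  if (!is.null(cm)) attr(out, "samples") <- cm$samples
  out
}

#' Filter features by total raw count
#'
#' Keeps features whose summed raw count across all samples is at least
#' `min_sum` (inclusive boundary, as in edgeR-style `minRowSum` filtering).
#'
#' @param x [count_matrix()] or matrix.
#' @param min_sum Minimum row sum (default 10).
#' @return Filtered object of the same class, with attribute `n_removed`.
#' @export
filter_min_row_sum <- function(x, min_sum = 10) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  keep <- rowSums(m) >= min_sum
  out <- if (inherits(x, "count_matrix")) x[keep, ] else
    m[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Two-group differential count test
#'
#' Self-contained replacement for an edgeR-style windowed differential
#' coverage test: samples are quantile-normalized, a single common dispersion
#' is moment-estimated across all features, and each feature is scored with a
#' two-sided exact negative-binomial test of the treatment group-sum against
#' the control group-sum, conditioning on their total (the classic exact NB
#' test construction). Two-sided p-values double the smaller mid-p tail
#' (half of the observed outcome's probability counts toward each tail),
#' capped at 1; the mid-p convention keeps the discrete test calibrated.
#' p-values are deliberately NOT multiplicity-adjusted; callers threshold
#' raw p exactly as the downstream DMR/DEG/DAI definitions require.
#'
#' @param x A [count_matrix()].
#' @param control,treatment Group labels; default: first unique label is
#'   control, second is treatment.
#' @param normalization `"quantile"` (default) or `"none"`.
#' @param min_row_sum Features with raw row sum below this are dropped before
#'   testing (default 10).
#' @param dispersion Optional fixed NB dispersion phi (variance =
#'   mu + phi * mu^2); when `NULL` it is moment-estimated from the data.
#' @return Data frame of class `diff_result`: `feature_id`, `mean_ctrl`,
#'   `mean_trt` (normalized group means), `log2fc`, `pvalue`, `direction`
#'   (`up`/`down`/`none`; sign of the normalized mean difference, `none` when
#'   exactly zero). Attributes: `dispersion`, `groups`.
#' @export
diff_test <- function(x, control = NULL, treatment = NULL,
                      normalization = c("quantile", "none"),
                      min_row_sum = 10, dispersion = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  normalization <- match.arg(normalization)
  gi <- group_indices(x, control, treatment)
  if (length(gi$control) < 2L || length(gi$treatment) < 2L) {
    stop("insufficient replication: need >= 2 samples per group")
  }
  x <- filter_min_row_sum(x, min_row_sum)
  n_removed <- attr(x, "n_removed")
  m <- x$counts
  norm <- if (normalization == "quantile") quantile_normalize(m) else m
  mt <- rowMeans(norm[, gi$treatment, drop = FALSE])
  mc <- rowMeans(norm[, gi$control, drop = FALSE])
  if (is.null(dispersion)) dispersion <- estimate_common_dispersion(norm, gi)

  k_trt <- round(rowSums(norm[, gi$treatment, drop = FALSE]))
  k_tot <- k_trt + round(rowSums(norm[, gi$control, drop = FALSE]))
  p <- exact_nb_pvalues(k_trt, k_tot, n_trt = length(gi$treatment),
                        n_ctrl = length(gi$control), phi = dispersion)

  log2fc <- log2((mt + 0.5) / (mc + 0.5))
  direction <- ifelse(mt > mc, "up", ifelse(mt < mc, "down", "none"))
  out <- data.frame(feature_id = rownames(m), mean_ctrl = mc, mean_trt = mt,
                    log2fc = log2fc, pvalue = p, direction = direction,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- dispersion
  attr(out, "n_removed") <- n_removed
  attr(out, "groups") <- c(control = gi$control_label,
                           treatment = gi$treatment_label)
  class(out) <- c("diff_result", "data.frame")
  out
}

# Method-of-moments common NB dispersion on normalized counts: per-feature
# phi_i = (pooled within-group variance - mean) / mean^2, averaged across
# features (negative estimates floored at 0 before averaging).
estimate_common_dispersion <- function(norm, gi) {
  grab <- function(idx) {
    sub <- norm[, idx, drop = FALSE]
    list(mean = rowMeans(sub),
         var = apply(sub, 1L, stats::var))
  }
  a <- grab(gi$control)
  b <- grab(gi$treatment)
  na <- length(gi$control); nb <- length(gi$treatment)
  pooled_var <- ((na - 1) * a$var + (nb - 1) * b$var) / (na + nb - 2)
  mu <- (na * a$mean + nb * b$mean) / (na + nb)
  ok <- mu > 0
  phi <- (pooled_var[ok] - mu[ok]) / mu[ok]^2
  est <- mean(pmax(phi, 0))
  max(est, 1e-8)
}

# Exact conditional NB test: with n iid NB(mu, size = 1/phi) samples per
# group, the group sum is NB(n * mu, size = n / phi); conditional on the
# total, the treatment sum has a pmf free of the NB prob parameter. p-values
# are cached on the unique totals since the conditional law depends only on
# (total, group sizes, phi).
exact_nb_pvalues <- function(k_trt, k_tot, n_trt, n_ctrl, phi) {
  p <- rep(NA_real_, length(k_trt))
  for (s in unique(k_tot)) {
    idx <- which(k_tot == s)
    if (s == 0) {
      p[idx] <- 1
      next
    }
    mu <- s / (n_trt + n_ctrl)
    lw <- cond_log_pmf(s, n_trt, n_ctrl, mu, phi)
    pmf <- exp(lw - max(lw))
    pmf <- pmf / sum(pmf)
    cdf <- cumsum(pmf)
    k <- k_trt[idx]
    # mid-p tails: half the observed outcome's mass counts in each tail,
    # which keeps the discrete test calibrated (plain tail doubling is
    # measurably conservative at these counts)
    lower <- c(0, cdf)[k + 1L] + pmf[k + 1L] / 2
    upper <- 1 - c(0, cdf)[k + 1L] - pmf[k + 1L] / 2
    p[idx] <- pmin(1, 2 * pmin(lower, upper))
  }
  p
}

# log of the (unnormalized) conditional pmf of the treatment group sum given
# the total s; support 0..s. Poisson limit when phi ~ 0.
cond_log_pmf <- function(s, n_trt, n_ctrl, mu, phi) {
  k <- 0:s
  if (phi < 1e-10) {
    stats::dbinom(k, s, n_trt / (n_trt + n_ctrl), log = TRUE)
  } else {
    size_t <- n_trt / phi
    size_c <- n_ctrl / phi
    # prob parameter cancels after normalization; any common value works
    stats::dnbinom(k, size = size_t, mu = n_trt * mu, log = TRUE) +
      stats::dnbinom(s - k, size = size_c, mu = n_ctrl * mu, log = TRUE)
  }
}

#' Write a differential test result as TSV
#'
#' @param diff A `diff_result`.
#' @param path Output path.
#' @export
write_diff_result <- function(diff, path) {
  utils::write.table(as.data.frame(diff), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Power of the two-sample t test via the noncentral t distribution
#'
#' @param n Per-group sample size.
#' @param d Cohen's d effect size.
#' @param alpha Type I error rate.
#' @param tails 1 or 2 (default 2). Two-tailed power ignores the negligible
#'   wrong-tail mass.
#' @return Power (probability of rejecting at level `alpha`).
#' @export
power_two_sample_t <- function(n, d, alpha = 0.05, tails = 2) {
  stopifnot(n >= 2, d > 0, alpha > 0, alpha < 1, tails %in% c(1, 2))
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  crit <- stats::qt(1 - alpha / tails, df)
  stats::pt(crit, df, ncp = ncp, lower.tail = FALSE)
}

#' Minimum per-group sample size for a target power
#'
#' A priori power analysis for a two-sample t test: the smallest integer
#' n >= 2 such that the noncentral-t power (df = 2n - 2, noncentrality
#' d * sqrt(n / 2)) reaches the target.
#'
#' @param d Cohen's d (> 0).
#' @param alpha Type I error rate (default 0.05).
#' @param power Target power 1 - beta (default 0.8).
#' @param tails 1 or 2 (default 2).
#' @param n_max Search bound (default 1e6).
#' @return Integer per-group sample size.
#' @examples
#' min_sample_size(d = 3.92, power = 0.95) # 4
#' min_sample_size(d = 3.47, power = 0.80) # 3
#' @export
min_sample_size <- function(d, alpha = 0.05, power = 0.8, tails = 2,
                            n_max = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  n <- 2
  while (n <= n_max) {
    if (power_two_sample_t(n, d, alpha, tails) >= power) return(as.integer(n))
    n <- n + 1
  }
  stop("target power unreachable with n <= ", n_max)
}
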