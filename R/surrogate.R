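# Surrogate-based significance mapping: Fourier phase-randomization null for
# the standardized agreement statistic, empirical p-values, and weak FDR
# control with C(K) = sum_{i<=K} 1/i.

# Accepts an n x M x K array (or an n x M matrix for K = 1) and returns the
# flat n x (M*K) layout used by the compiled block routines.
flatten_voxels <- function(X) {
  if (is.matrix(X)) X <- array(X, dim = c(nrow(X), ncol(X), 1L))
  stopifnot(length(dim(X)) == 3L)
  d <- dim(X)
  list(flat = matrix(X, d[1L], d[2L] * d[3L]), n = d[1L], M = d[2L], K = d[3L])
}

#' Fourier phase randomization of a time series
#'
#' Returns a surrogate series with the same length, mean and amplitude
#' spectrum as \code{x}, but with the phases of all non-DC, non-Nyquist
#' frequency bins replaced by iid uniform draws on \eqn{(0, 2\pi)} (conjugate
#' symmetry enforced so the output is real). For even n the real Nyquist bin
#' is multiplied by a random sign. Phase randomization destroys any alignment
#' between series while preserving each series' autocovariance structure up to
#' the circularity of the discrete Fourier transform, which is what makes it a
#' null for inter-subject synchronization.
#'
#' Uses the current R random number generator state; call \code{set.seed()}
#' first for reproducibility.
#'
#' @param x numeric vector, length >= 4.
#' @return numeric vector of the same length.
#' @examples
#' set.seed(1)
#' x <- as.numeric(arima.sim(list(ar = 0.5), 64))
#' s <- phase_randomize(x)
#' max(abs(Mod(fft(s)) - Mod(fft(x))))  # spectrum preserved
#' @export
phase_randomize <- function(x) {
  n <- length(x)
  if (n < 4L) stop("series must have length >= 4", call. = FALSE)
  f <- stats::fft(x)
  half <- (n - 2L + n %% 2L) %/% 2L
  ph <- runif(half, 0, 2 * pi)
  f[2:(half + 1L)] <- f[2:(half + 1L)] * exp(1i * ph)
  if (n %% 2L == 0L)
    f[n / 2L + 1L] <- f[n / 2L + 1L] * sample(c(-1, 1), 1L)
  f[(n - half + 1L):n] <- Conj(f[(half + 1L):2])
  Re(stats::fft(f, inverse = TRUE)) / n
}

#' Voxelwise agreement statistics
#'
#' Runs the ICC agreement chain over a block of voxels and returns per-voxel
#' \code{A_hat}, \code{var_A}, \code{se_A}, \code{t_A}, \code{C_hat} and
#' \code{Gamma}. The compiled path is numerically identical to [icc_fit()]
#' applied voxel by voxel.
#'
#' @param X numeric array n x M x K (time x subjects x voxels), or an n x M
#'   matrix for a single voxel.
#' @return data.frame with one row per voxel.
#' @export
icc_t_map <- function(X) {
  fx <- flatten_voxels(X)
  if (fx$n < 4L || fx$M < 2L)
    stop("need n >= 4 time points and M >= 2 subjects", call. = FALSE)
  cv <- .colVars(fx$flat)
  if (any(cv <= 0))
    stop("degenerate voxel: constant subject time course present", call. = FALSE)
  st <- cpp_icc_block(fx$flat, fx$M)
  data.frame(voxel = seq_len(fx$K), A_hat = st[, 1], var_A = st[, 2],
             se_A = sqrt(st[, 2]), t_A = st[, 3], C_hat = st[, 4],
             Gamma = st[, 5])
}

#' Pooled phase-randomization null for the agreement statistic
#'
#' For each surrogate replicate, every subject's series at every voxel is
#' independently phase-randomized and the full agreement chain (moments,
#' Gamma, variance, t) is recomputed; the resulting t values are pooled across
#' voxels and replicates into one brain-wide null distribution, from which the
#' upper \code{1 - tail_prob} empirical quantile is taken as the critical
#' value. A single pooled null (rather than a per-voxel null) is used because
#' the per-voxel replicate count is far too small to estimate voxelwise tails.
#'
#' @inheritParams icc_t_map
#' @param n_surrogates number of surrogate replicates (default 50).
#' @param tail_prob upper tail probability for the critical value.
#' @param seed optional integer; if given, sets the RNG seed so the whole
#'   surrogate stream (per replicate, per subject, per voxel) is reproducible.
#' @return An object of class \code{"surrogate_null"}: list with \code{null_t}
#'   (K x n_surrogates matrix), \code{critical_value}, \code{tail_prob},
#'   \code{n_surrogates}, \code{n}, \code{M}, \code{K}.
#' @export
build_surrogate_null <- function(X, n_surrogates = 50L, tail_prob = 0.05,
                                 seed = NULL) {
  if (n_surrogates < 2L) stop("need at least 2 surrogates", call. = FALSE)
  stopifnot(tail_prob > 0, tail_prob < 1)
  fx <- flatten_voxels(X)
  if (!is.null(seed)) set.seed(seed)
  null_t <- cpp_surrogate_t(fx$flat, fx$M, as.integer(n_surrogates))
  structure(list(null_t = null_t,
                 critical_value = as.numeric(
                   quantile(null_t, 1 - tail_prob, names = FALSE)),
                 tail_prob = tail_prob,
                 n_surrogates = as.integer(n_surrogates),
                 n = fx$n, M = fx$M, K = fx$K),
            class = "surrogate_null")
}

#' @export
print.surrogate_null <- function(x, ...) {
  cat("Pooled phase-randomization null:", x$n_surrogates, "surrogates x",
      x$K, "voxels =", length(x$null_t), "t values\n")
  cat(sprintf("  critical value (tail %.3g): %.4f\n",
              x$tail_prob, x$critical_value))
  invisible(x)
}

#' Empirical p-values against a surrogate null
#'
#' \eqn{p = (1 + \#\{t_{null} \ge t_{obs}\}) / (1 + N)} over the pooled null of
#' size N: the proportion of surrogate t values greater than or equal to the
#' observed one, with an add-one correction so that p is always strictly
#' positive for a finite pool.
#'
#' @param t_obs numeric vector of observed t values.
#' @param null a \code{"surrogate_null"} object or a numeric vector pool.
#' @return numeric vector of p-values in \eqn{(0, 1]}.
#' @export
empirical_pvalues <- function(t_obs, null) {
  pool <- if (inherits(null, "surrogate_null")) as.numeric(null$null_t)
          else as.numeric(null)
  N <- length(pool)
  if (N == 0L) stop("empty null pool", call. = FALSE)
  srt <- sort(pool)
  # #{pool >= t} = N - #{pool < t}
  n_lt <- findInterval(t_obs, srt, left.open = TRUE)
  (1 + (N - n_lt)) / (1 + N)
}

#' Weak FDR control with C(K) = sum of reciprocals
#'
#' Step-up false discovery rate control valid under arbitrary dependence among
#' tests: the i-th smallest p-value is compared with
#' \eqn{(i/K)\,\alpha/C(K)} where \eqn{C(K) = \sum_{i=1}^{K} 1/i}; the largest
#' rank whose p-value passes determines the rejection set (all hypotheses with
#' the i* smallest p-values; ties at the boundary are all rejected).
#'
#' @param p numeric vector of p-values in (0, 1].
#' @param alpha family-wise control level.
#' @return list with \code{reject} (logical vector), \code{n_reject},
#'   \code{K}, \code{C_K}, \code{critical_values} (sorted-rank critical
#'   values), \code{p_threshold} (largest rejected p-value or NA).
#' @export
fdr_weak <- function(p, alpha = 0.05) {
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  K <- length(p)
  C_K <- sum(1 / seq_len(K))
  crit <- seq_len(K) / K * alpha / C_K
  o <- order(p)
  ps <- p[o]
  pass <- which(ps <= crit)
  if (length(pass) == 0L) {
    reject <- rep(FALSE, K)
    thr <- NA_real_
  } else {
    istar <- max(pass)
    thr <- ps[istar]
    reject <- p <= thr
  }
  list(reject = reject, n_reject = sum(reject), K = K, C_K = C_K,
       critical_values = crit, p_threshold = thr)
}

#' Voxelwise agreement map with surrogate-null thresholding
#'
#' The full significance-mapping chain: observed voxelwise agreement
#' statistics, a pooled phase-randomization null, empirical p-values and
#' weak-FDR supra-threshold selection.
#'
#' @inheritParams build_surrogate_null
#' @param alpha FDR control level.
#' @return An object of class \code{"icc_map"}: list with \code{stats} (the
#'   [icc_t_map()] data.frame plus \code{p} and \code{supra}), \code{null},
#'   \code{fdr}, \code{alpha}.
#' @export
icc_map <- function(X, n_surrogates = 50L, alpha = 0.05, tail_prob = 0.05,
                    seed = NULL) {
  stats_df <- icc_t_map(X)
  null <- build_surrogate_null(X, n_surrogates = n_surrogates,
                               tail_prob = tail_prob, seed = seed)
  stats_df$p <- empirical_pvalues(stats_df$t_A, null)
  fdr <- fdr_weak(stats_df$p, alpha = alpha)
  stats_df$supra <- fdr$reject
  structure(list(stats = stats_df, null = null, fdr = fdr, alpha = alpha),
            class = "icc_map")
}

#' @export
print.icc_map <- function(x, ...) {
  cat("ICC agreement map:", nrow(x$stats), "voxels,",
      x$null$n_surrogates, "surrogates\n")
  cat(sprintf("  critical value %.4f; %d supra-threshold voxels at FDR alpha = %.3g\n",
              x$null$critical_value, x$fdr$n_reject, x$alpha))
  invisible(x)
}
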