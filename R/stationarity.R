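# Stationarity screening of per-subject voxel time courses: KPSS
# trend-stationarity test, ADF unit-root test, lagged-correlation mixing
# diagnostic, and the across-subject consistency aggregation.
#
# Implemented in-package: the regressions are ordinary least squares, the
# KPSS long-run variance uses a Bartlett window, and p-values are linearly
# interpolated within the published critical-value tables (and clamped to the
# table range, as is conventional for these tests).

.kpss_crit <- list(p = c(0.10, 0.05, 0.025, 0.01),
                   stat = c(0.119, 0.146, 0.176, 0.216))
.adf_crit <- list(p = c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99),
                  stat = c(-3.96, -3.66, -3.41, -3.12, -1.25, -0.94, -0.66,
                           -0.33))

.interp_p <- function(stat, table) {
  # table$stat monotone in table$p; clamp outside the table
  stats::approx(table$stat, table$p, xout = stat, rule = 2)$y
}

#' KPSS test for trend stationarity
#'
#' Tests the null hypothesis that the series is stationary around a
#' deterministic linear trend against the alternative of a unit root. The
#' statistic is \eqn{\sum_t S_t^2 / (n^2 \hat{\sigma}^2_{lr})} where
#' \eqn{S_t} are partial sums of the detrending residuals and the long-run
#' variance uses a Bartlett kernel with \code{trunc(4 (n/100)^{1/4})} lags.
#' The p-value is interpolated in the published critical-value table and
#' clamped to [0.01, 0.10].
#'
#' @param x numeric series, length >= 20, nonconstant.
#' @param lags Bartlett window width; default is the data-driven rule above.
#' @return list with \code{statistic}, \code{p_value}, \code{lags}.
#' @export
kpss_test <- function(x, lags = NULL) {
  n <- length(x)
  if (n < 20L) stop("series too short for the KPSS test (need n >= 20)",
                    call. = FALSE)
  if (var(x) == 0) stop("constant series", call. = FALSE)
  if (is.null(lags)) lags <- trunc(4 * (n / 100)^0.25)
  tt <- seq_len(n)
  e <- stats::lm.fit(cbind(1, tt), x)$residuals
  S <- cumsum(e)
  lrv <- sum(e^2) / n
  if (lags > 0) {
    for (l in seq_len(lags)) {
      w <- 1 - l / (lags + 1)
      lrv <- lrv + 2 * w * sum(e[(l + 1):n] * e[1:(n - l)]) / n
    }
  }
  stat <- sum(S^2) / (n^2 * lrv)
  list(statistic = stat, p_value = .interp_p(stat, .kpss_crit), lags = lags)
}

#' Augmented Dickey-Fuller test for a unit root
#'
#' Tests the null hypothesis of a unit root (non-stationarity) against the
#' alternative of stationarity, using the regression of the first difference
#' on the lagged level, a constant, a linear trend, and \code{lags} lagged
#' differences (the trend term keeps the test's alternative aligned with the
#' trend-stationarity null of the KPSS test). The statistic is the t-ratio
#' of the lagged-level coefficient; the p-value is interpolated in the
#' Dickey-Fuller table for the constant-plus-trend case and clamped to
#' [0.01, 0.99].
#'
#' @param x numeric series, length >= 20, nonconstant.
#' @param lags number of lagged differences; default
#'   \code{trunc((n - 1)^(1/3))}.
#' @return list with \code{statistic}, \code{p_value}, \code{lags}.
#' @export
adf_test <- function(x, lags = NULL) {
  n <- length(x)
  if (n < 20L) stop("series too short for the ADF test (need n >= 20)",
                    call. = FALSE)
  if (var(x) == 0) stop("constant series", call. = FALSE)
  if (is.null(lags)) lags <- trunc((n - 1)^(1/3))
  dx <- diff(x)
  k <- lags
  yt <- dx[(k + 1):(n - 1)]
  xlag <- x[(k + 1):(n - 1)]
  Z <- cbind(1, xlag, seq_along(yt))
  if (k > 0)
    for (j in seq_len(k)) Z <- cbind(Z, dx[(k + 1 - j):(n - 1 - j)])
  fit <- stats::lm.fit(Z, yt)
  res <- fit$residuals
  df <- length(yt) - ncol(Z)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(Z)))
  se <- sqrt(sigma2 * XtXinv[2, 2])
  stat <- fit$coefficients[2] / se
  list(statistic = unname(stat),
       p_value = .interp_p(unname(stat), .adf_crit), lags = k)
}

#' Both stationarity tests for one series
#'
#' A series is treated as stationary when the KPSS test fails to reject
#' trend-stationarity and the ADF test rejects the unit root.
#'
#' @inheritParams kpss_test
#' @return list with \code{kpss_stat}, \code{kpss_p}, \code{adf_stat},
#'   \code{adf_p}.
#' @export
stationarity_tests <- function(x) {
  k <- kpss_test(x)
  a <- adf_test(x)
  list(kpss_stat = k$statistic, kpss_p = k$p_value,
       adf_stat = a$statistic, adf_p = a$p_value)
}

#' Maximal lagged-correlation profile (rho-mixing diagnostic)
#'
#' For each lag \eqn{\upsilon} in \code{lag_grid}, the maximum over all voxels
#' and subjects of the absolute lag-\eqn{\upsilon} autocorrelation
#' \eqn{|\rho(X_k, X_{k+\upsilon})|}. Weak dependence (rho-mixing) requires
#' this profile to decay toward zero with increasing lag; it underwrites the
#' asymptotic variance formulas.
#'
#' @param X n x M x K array (or n x M matrix) of time courses.
#' @param lag_grid strictly increasing positive integer lags, all < n - 3.
#' @return data.frame with columns \code{lag} and \code{max_abs_corr}.
#' @export
lagged_corr_profile <- function(X, lag_grid = seq(10L, 230L, by = 20L)) {
  fx <- flatten_voxels(X)
  n <- fx$n
  if (length(lag_grid) == 0L) stop("empty lag grid", call. = FALSE)
  if (is.unsorted(lag_grid, strictly = TRUE))
    stop("lag grid must be strictly increasing", call. = FALSE)
  if (max(lag_grid) >= n - 3L)
    stop("maximum lag must be < n - 3", call. = FALSE)
  prof <- vapply(lag_grid, function(v) {
    a <- fx$flat[1:(n - v), , drop = FALSE]
    b <- fx$flat[(1 + v):n, , drop = FALSE]
    na <- nrow(a)
    am <- a - rep(colMeans(a), each = na)
    bm <- b - rep(colMeans(b), each = na)
    num <- colSums(am * bm)
    den <- sqrt(colSums(am^2) * colSums(bm^2))
    ok <- den > 0
    if (!any(ok)) return(0)
    max(abs(num[ok] / den[ok]))
  }, numeric(1))
  data.frame(lag = as.integer(lag_grid), max_abs_corr = prof)
}

#' Across-subject consistency aggregation of rejections
#'
#' Fraction of voxels whose per-subject rejection indicator is true for at
#' least \code{ceil(subject_fraction * M)} subjects.
#'
#' @param reject_matrix logical matrix, voxels x subjects.
#' @param subject_fraction fraction of subjects in (0, 1].
#' @return scalar proportion of voxels.
#' @export
consistency_aggregate <- function(reject_matrix, subject_fraction) {
  stopifnot(is.matrix(reject_matrix),
            subject_fraction > 0, subject_fraction <= 1)
  M <- ncol(reject_matrix)
  need <- ceiling(subject_fraction * M)
  mean(rowSums(reject_matrix) >= need)
}

#' Stationarity screen over a voxel block
#'
#' Runs KPSS and ADF on every (voxel, subject) series, optionally applies
#' weak FDR control to each subject's voxelwise KPSS p-values, and aggregates
#' KPSS rejections across subjects at the requested subject fractions. The
#' ADF side is reported descriptively (counts of subjects accepting the unit
#' root). Screening is reported, never used to exclude voxels from the maps.
#'
#' @param X n x M x K array of time courses.
#' @param alpha per-test level.
#' @param fractions subject fractions at which to aggregate.
#' @param apply_fdr also compute the aggregation after per-subject weak FDR
#'   correction across voxels.
#' @return An object of class \code{"stationarity_report"}: list with
#'   \code{kpss_p}, \code{adf_p} (K x M matrices), \code{reject_kpss},
#'   \code{reject_kpss_fdr}, \code{proportions} (data.frame over fractions,
#'   raw and FDR-corrected), \code{adf_accept_counts}.
#' @export
stationarity_screen <- function(X, alpha = 0.05,
                                fractions = c(0.5, 0.6, 0.7),
                                apply_fdr = TRUE) {
  fx <- flatten_voxels(X)
  K <- fx$K; M <- fx$M
  kp <- ap <- matrix(NA_real_, K, M)
  for (i in seq_len(M)) {
    cols <- (seq_len(K) - 1L) * M + i
    for (k in seq_len(K)) {
      x <- fx$flat[, cols[k]]
      kp[k, i] <- kpss_test(x)$p_value
      ap[k, i] <- adf_test(x)$p_value
    }
  }
  reject <- kp <= alpha
  prop <- data.frame(fraction = fractions,
                     proportion = vapply(fractions, function(f)
                       consistency_aggregate(reject, f), numeric(1)))
  reject_fdr <- NULL
  if (apply_fdr) {
    reject_fdr <- reject
    for (i in seq_len(M))
      reject_fdr[, i] <- fdr_weak(kp[, i], alpha = alpha)$reject
    prop$proportion_fdr <- vapply(fractions, function(f)
      consistency_aggregate(reject_fdr, f), numeric(1))
  }
  structure(list(kpss_p = kp, adf_p = ap,
                 reject_kpss = reject, reject_kpss_fdr = reject_fdr,
                 proportions = prop,
                 adf_accept_counts = rowSums(ap > alpha),
                 alpha = alpha),
            class = "stationarity_report")
}

#' @export
print.stationarity_report <- function(x, ...) {
  cat("Stationarity screen:", nrow(x$kpss_p), "voxels x",
      ncol(x$kpss_p), "subjects (alpha =", x$alpha, ")\n")
  print(x$proportions, row.names = FALSE)
  invisible(x)
}

#' Write a stationarity report as TSV
#'
#' @param report a \code{"stationarity_report"}.
#' @param path output file.
#' @param fractions subject fractions for the per-voxel flags.
#' @return the path, invisibly.
#' @export
write_stationarity_tsv <- function(report, path,
                                   fractions = c(0.5, 0.6, 0.7)) {
  M <- ncol(report$kpss_p)
  df <- data.frame(voxel_id = seq_len(nrow(report$kpss_p)),
                   n_subjects_rejected_kpss = rowSums(report$reject_kpss),
                   n_subjects_accepted_adf = report$adf_accept_counts)
  for (f in fractions)
    df[[sprintf("flag_%d", round(100 * f))]] <-
      rowSums(report$reject_kpss) >= ceiling(f * M)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
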