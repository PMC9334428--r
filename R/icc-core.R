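#' @useDynLib iscagree, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats var cor sd pt qnorm quantile rnorm runif kmeans p.adjust
#'   complete.cases lm.fit
NULL

# Validate an n x M subject-time matrix (time points in rows, subjects in
# columns). Constant columns are degenerate: the column-wise covariance S
# would have a zero diagonal element and every downstream ratio is undefined.
validate_stm <- function(X) {
  if (!is.matrix(X) || !is.numeric(X))
    stop("`X` must be a numeric matrix (time points x subjects)", call. = FALSE)
  if (anyNA(X)) stop("`X` contains missing values", call. = FALSE)
  n <- nrow(X); M <- ncol(X)
  if (n < 4L) stop("need at least 4 time points, got ", n, call. = FALSE)
  if (M < 2L) stop("need at least 2 subjects, got ", M, call. = FALSE)
  cv <- .colVars(X)
  if (any(cv <= 0))
    stop("degenerate voxel: subject column(s) ",
         paste(which(cv <= 0), collapse = ", "),
         " have zero temporal variance", call. = FALSE)
  invisible(list(n = n, M = M))
}

.colVars <- function(X) {
  n <- nrow(X)
  colMeans(X^2) - colMeans(X)^2 + 0 * n
}

#' Column- and row-wise moment matrices of a subject-time matrix
#'
#' Computes the M-by-M column-wise (between-subject) cross-covariance matrix
#' \code{S} at zero lag and the n-by-n row-wise (between-time-point) covariance
#' matrix \code{V} of an n-by-M matrix of per-subject time courses. Both use
#' divide-by-count (population-style) divisors, n for \code{S} and M for
#' \code{V}; with these divisors the agreement index built from them is exactly
#' the two-way random-effects ICC(2,M) of Shrout and Fleiss.
#'
#' @param X numeric matrix, n time points (rows) by M subjects (columns);
#'   n >= 4, M >= 2, no constant column.
#' @return An object of class \code{"icc_moments"}: a list with \code{S},
#'   \code{V}, \code{trace_S}, \code{quad_S} (\code{1'S1}), \code{quad_V}
#'   (\code{1'V1}), \code{n} and \code{M}.
#' @examples
#' X <- matrix(rnorm(120), 30, 4)
#' m <- moment_matrices(X)
#' all.equal(m$quad_S, sum(m$S))
#' @export
moment_matrices <- function(X) {
  d <- validate_stm(X)
  n <- d$n; M <- d$M
  Xc <- X - rep(colMeans(X), each = n)
  S <- crossprod(Xc) / n
  Xr <- X - rowMeans(X)
  V <- tcrossprod(Xr) / M
  structure(list(S = S, V = V,
                 trace_S = sum(diag(S)),
                 quad_S = sum(S), quad_V = sum(V),
                 n = n, M = M),
            class = "icc_moments")
}

#' Gamma ratio of row to column covariance mass
#'
#' The sample ratio \eqn{\Gamma = (1'V1/n^2) / (1'S1/M^2)}, a consistent
#' estimate of \eqn{\gamma = \sigma_r^2/\sigma_c^2}, the ratio of the mean
#' element of the row-wise covariance matrix to the mean element of the
#' column-wise covariance matrix. \eqn{\Gamma} grows with between-subject
#' differences in mean intensity and drives the gap between the agreement and
#' consistency indices.
#'
#' @param m an \code{"icc_moments"} object from [moment_matrices()].
#' @return An object of class \code{"icc_gamma"}: list with \code{Gamma},
#'   \code{sigma_r2} (\code{1'V1/n^2}), \code{sigma_c2} (\code{1'S1/M^2}).
#' @export
gamma_ratio <- function(m) {
  stopifnot(inherits(m, "icc_moments"))
  if (m$quad_S <= 0)
    stop("degenerate voxel: 1'S1 <= 0", call. = FALSE)
  sigma_r2 <- m$quad_V / m$n^2
  sigma_c2 <- m$quad_S / m$M^2
  structure(list(Gamma = sigma_r2 / sigma_c2,
                 sigma_r2 = sigma_r2, sigma_c2 = sigma_c2),
            class = "icc_gamma")
}

#' Consistency index ICC(C,M)
#'
#' The average-measures consistency intraclass correlation,
#' \eqn{\hat{C} = (M/(M-1)) (1'S1 - tr S) / 1'S1}, identical to the
#' Shrout-Fleiss ICC(3,M) from a two-way mixed-effects ANOVA. It is invariant
#' to per-subject mean shifts.
#'
#' @inheritParams gamma_ratio
#' @return scalar \code{C_hat} in \eqn{(-\infty, 1]}.
#' @export
icc_consistency <- function(m) {
  stopifnot(inherits(m, "icc_moments"))
  if (m$quad_S <= 0) stop("degenerate voxel: 1'S1 <= 0", call. = FALSE)
  (m$M / (m$M - 1)) * (m$quad_S - m$trace_S) / m$quad_S
}

#' Agreement index ICC(A,M) with its large-sample approximation
#'
#' The agreement intraclass correlation
#' \deqn{\hat{A} = \frac{(M/(M-1)) [1'S1 - tr(S)]}{1'S1 \left[1 +
#'   \frac{(n-1)\Gamma}{n(M-1)} - \frac{M}{n(M-1)}\frac{tr(S)}{1'S1} +
#'   \frac{1}{n(M-1)}\right]},}
#' identical to Shrout-Fleiss ICC(2,M), together with its large-sample
#' approximation \eqn{\hat{C}(M-1)/((M-1)+\Gamma)}; the two differ by a
#' remainder of order \eqn{1/(nM)}. Negative values are reported as-is (the
#' index ranges over \eqn{(-\infty, 1]}).
#'
#' @param m an \code{"icc_moments"} object.
#' @param g an \code{"icc_gamma"} object for the same matrix.
#' @return list with \code{A_hat}, \code{A_approx} and \code{remainder_bound}
#'   (\code{|A_hat - A_approx|}).
#' @export
icc_agreement <- function(m, g) {
  stopifnot(inherits(m, "icc_moments"), inherits(g, "icc_gamma"))
  n <- m$n; M <- m$M; s <- m$quad_S; tS <- m$trace_S; G <- g$Gamma
  denom <- s * (1 + (n - 1) * G / (n * (M - 1)) -
                  (M / (n * (M - 1))) * (tS / s) + 1 / (n * (M - 1)))
  A_hat <- (M / (M - 1)) * (s - tS) / denom
  A_approx <- icc_consistency(m) * (M - 1) / ((M - 1) + G)
  list(A_hat = A_hat, A_approx = A_approx,
       remainder_bound = abs(A_hat - A_approx))
}

#' Duplication and elimination transforms for symmetric matrices
#'
#' \code{duplication_matrix(M)} returns \eqn{G_M} of order
#' \eqn{M^2 \times M(M+1)/2} with \eqn{vec \Sigma = G_M vech \Sigma};
#' \code{elimination_matrix(M)} returns \eqn{K_M = (G'G)^{-1} G'} of order
#' \eqn{M(M+1)/2 \times M^2} with \eqn{vech \Sigma = K_M vec \Sigma} and
#' \eqn{K_M G_M = I}. \eqn{K_M} is the Moore-Penrose left inverse of
#' \eqn{G_M}, the choice under which the delta-method variance of the
#' consistency index matches the Gaussian sampling variance of \eqn{vech S}.
#' Half-vectorization stacks the lower triangle (including the diagonal)
#' column by column.
#'
#' @param M order of the symmetric matrix, M >= 2.
#' @return a dense numeric matrix.
#' @export
duplication_matrix <- function(M) {
  stopifnot(M >= 2)
  p <- M * (M + 1) / 2
  G <- matrix(0, M * M, p)
  k <- 0L
  for (j in seq_len(M)) for (i in j:M) {
    k <- k + 1L
    G[(j - 1L) * M + i, k] <- 1
    G[(i - 1L) * M + j, k] <- 1
  }
  G
}

#' @rdname duplication_matrix
#' @export
elimination_matrix <- function(M) {
  G <- duplication_matrix(M)
  solve(crossprod(G), t(G))
}

#' Delta-method variances of the consistency and agreement indices
#'
#' The asymptotic variance of the consistency index is
#' \eqn{Var(\hat{C}) = 2 n^{-1} \eta' K_M (\Sigma \otimes \Sigma) K_M' \eta}
#' with \eqn{\Sigma} evaluated at \eqn{S} and
#' \eqn{\eta' = \frac{M}{(M-1)(1'\Sigma 1)^2}[-(1'\Sigma 1) vec'(I_M) +
#' tr(\Sigma)(1' \otimes 1')] G_M}, the derivative of ICC(C,M) with respect to
#' \eqn{vech'\Sigma}. The variance of the agreement index follows as
#' \eqn{Var(\hat{A}) = Var(\hat{C}) ((M-1)/((M-1)+\gamma))^2} with
#' \eqn{\gamma} evaluated at \eqn{\Gamma}.
#'
#' The quadratic form is evaluated in closed form,
#' \eqn{2 n^{-1} c^2 (t^2 s^2 - 2 t s u + s^2 v)} with \eqn{t = tr S},
#' \eqn{s = 1'S1}, \eqn{u = 1'S^2 1}, \eqn{v = tr(S^2)} and
#' \eqn{c = M/((M-1) s^2)}, so the \eqn{M^2 \times M^2} Kronecker product is
#' never materialized; the identity with the explicit transform-matrix route
#' holds exactly.
#'
#' @inheritParams icc_agreement
#' @param tol negative computed variances beyond \code{-tol} raise an error
#'   (numerical failure is reported, never silently clamped); values within
#'   \code{[-tol, 0]} are clipped to 0.
#' @return list with \code{eta} (length \eqn{M(M+1)/2}), \code{var_C},
#'   \code{var_A}.
#' @export
icc_variances <- function(m, g, tol = 1e-12) {
  stopifnot(inherits(m, "icc_moments"), inherits(g, "icc_gamma"))
  S <- m$S; n <- m$n; M <- m$M
  s <- m$quad_S; tS <- m$trace_S
  cc <- M / ((M - 1) * s^2)
  # eta = c * G'vec(A), A = tr(S) J - (1'S1) I  => diag A_ii, off-diag 2 A_ij
  A <- matrix(tS, M, M); diag(A) <- tS - s
  eta <- numeric(M * (M + 1) / 2)
  k <- 0L
  for (j in seq_len(M)) for (i in j:M) {
    k <- k + 1L
    eta[k] <- cc * (if (i == j) A[i, j] else 2 * A[i, j])
  }
  rs <- rowSums(S)
  u <- sum(rs^2); v <- sum(S * S)
  q <- tS^2 * s^2 - 2 * tS * s * u + s^2 * v
  var_C <- 2 / n * cc^2 * q
  if (var_C < -tol)
    stop("numerical failure: negative variance ", var_C, call. = FALSE)
  var_C <- max(var_C, 0)
  var_A <- var_C * ((M - 1) / ((M - 1) + g$Gamma))^2
  list(eta = eta, var_C = var_C, var_A = var_A)
}

#' Standardized agreement statistic
#'
#' \eqn{t_{\hat{A}} = \hat{A} / \sqrt{Var(\hat{A})}}, the standardized value
#' used for significance evaluation of the empirical agreement index.
#'
#' @param A_hat agreement index.
#' @param var_A its estimated variance, must be strictly positive.
#' @return scalar t value.
#' @export
t_statistic <- function(A_hat, var_A) {
  if (!is.finite(var_A) || var_A <= 0)
    stop("var_A must be strictly positive", call. = FALSE)
  A_hat / sqrt(var_A)
}

#' Full ICC fit for one voxel
#'
#' Runs the complete single-voxel chain: moment matrices, Gamma ratio,
#' agreement and consistency indices, delta-method variances and the
#' standardized statistic.
#'
#' @inheritParams moment_matrices
#' @return An object of class \code{"icc_estimate"} with fields \code{A_hat},
#'   \code{A_approx}, \code{remainder_bound}, \code{C_hat}, \code{Gamma},
#'   \code{sigma_r2}, \code{sigma_c2}, \code{eta}, \code{var_C}, \code{var_A},
#'   \code{se_A}, \code{t_A}, \code{n}, \code{M}.
#' @examples
#' set.seed(1)
#' x <- rnorm(60)
#' X <- sapply(1:5, function(i) x + rnorm(60, sd = 0.8))
#' icc_fit(X)
#' @export
icc_fit <- function(X) {
  m <- moment_matrices(X)
  g <- gamma_ratio(m)
  a <- icc_agreement(m, g)
  v <- icc_variances(m, g)
  structure(list(A_hat = a$A_hat, A_approx = a$A_approx,
                 remainder_bound = a$remainder_bound,
                 C_hat = icc_consistency(m),
                 Gamma = g$Gamma, sigma_r2 = g$sigma_r2,
                 sigma_c2 = g$sigma_c2,
                 eta = v$eta, var_C = v$var_C, var_A = v$var_A,
                 se_A = sqrt(v$var_A),
                 t_A = if (v$var_A > 0) a$A_hat / sqrt(v$var_A) else NA_real_,
                 n = m$n, M = m$M),
            class = "icc_estimate")
}

#' @export
print.icc_estimate <- function(x, ...) {
  cat("ICC agreement fit (n =", x$n, "time points, M =", x$M, "subjects)\n")
  cat(sprintf("  A_hat = %.4f (SE %.4f), C_hat = %.4f, Gamma = %.4f\n",
              x$A_hat, x$se_A, x$C_hat, x$Gamma))
  cat(sprintf("  t_A = %.3f, |A_hat - A_approx| = %.2e\n",
              x$t_A, x$remainder_bound))
  invisible(x)
}
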