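# Pairwise Fisher-Z connectivity from subject-level ROI series, group-level
# t-tests with weak FDR, hemispheric summaries, and partial correlation with
# cortisol controlling demographics.

#' Pairwise connectivity rows
#'
#' Pearson correlation between each pair of entries' subject-level mean time
#' courses over the requested window, per subject, with the Fisher transform
#' \code{z = atanh(r)} and the standardized value \code{z_std = z * sqrt(n)}
#' where n is the actual window length (the printed convention standardizes
#' by the reciprocal root of the series length, 1/sqrt(240) for a full
#' session). Pairs whose correlation is numerically 1 in magnitude (infinite
#' Fisher Z) are skipped with a warning, as are constant-in-window series.
#'
#' @param roi_set a \code{"roi_series_set"}.
#' @param window integer vector of volume indices (default: all volumes).
#' @param window_name label stored with the rows ("full", "EC", "EO", ...).
#' @return data.frame: subject, roi_a, roi_b (entry indices), name_a, name_b,
#'   r, z, z_std, window, n_window.
#' @export
pairwise_connectivity <- function(roi_set, window = NULL,
                                  window_name = "full") {
  R <- ncol(roi_set$group_tc)
  if (R < 2L) stop("need at least 2 entries", call. = FALSE)
  n <- nrow(roi_set$group_tc)
  if (is.null(window)) window <- seq_len(n)
  if (min(window) < 1L || max(window) > n)
    stop("window outside [1, n]", call. = FALSE)
  M <- ncol(roi_set$subject_tcs[[1]])
  nw <- length(window)
  out <- vector("list", R * (R - 1) / 2 * M)
  kk <- 0L
  skipped <- 0L
  for (a in 1:(R - 1)) for (b in (a + 1):R) {
    ta <- roi_set$subject_tcs[[a]][window, , drop = FALSE]
    tb <- roi_set$subject_tcs[[b]][window, , drop = FALSE]
    for (i in seq_len(M)) {
      if (sd(ta[, i]) == 0 || sd(tb[, i]) == 0) { skipped <- skipped + 1L; next }
      r <- cor(ta[, i], tb[, i])
      if (abs(r) >= 1 - 1e-12) { skipped <- skipped + 1L; next }
      kk <- kk + 1L
      out[[kk]] <- data.frame(
        subject = i, roi_a = a, roi_b = b,
        name_a = roi_set$meta$roi_name[a], name_b = roi_set$meta$roi_name[b],
        r = r, z = atanh(r), z_std = atanh(r) * sqrt(nw),
        window = window_name, n_window = nw)
    }
  }
  if (skipped > 0L)
    warning(skipped, " (pair, subject) entries skipped (constant or ",
            "perfectly correlated series)", call. = FALSE)
  if (kk == 0L) stop("no valid connectivity rows", call. = FALSE)
  do.call(rbind, out[seq_len(kk)])
}

#' Group-level test of pairwise connectivity
#'
#' One-sample Student's t-test of the per-subject Fisher-Z values against
#' zero for every ROI pair, two-sided, with weak-FDR flags over the joint
#' family of all pairs. Pairs with fewer than 3 subjects are skipped.
#'
#' @param conn data.frame from [pairwise_connectivity()].
#' @param alpha FDR level.
#' @return data.frame: roi_a, roi_b, name_a, name_b, n_subjects, mean_z_std,
#'   sd_z_std, t, p, reject.
#' @export
group_connectivity_test <- function(conn, alpha = 0.05) {
  key <- interaction(conn$roi_a, conn$roi_b, drop = TRUE)
  rows <- lapply(split(conn, key), function(d) {
    N <- nrow(d)
    if (N < 3L) return(NULL)
    m <- mean(d$z_std); s <- sd(d$z_std)
    tstat <- if (s > 0) m / (s / sqrt(N)) else if (m == 0) 0 else Inf * sign(m)
    p <- if (is.finite(tstat)) 2 * pt(-abs(tstat), df = N - 1)
         else .Machine$double.eps
    data.frame(roi_a = d$roi_a[1], roi_b = d$roi_b[1],
               name_a = d$name_a[1], name_b = d$name_b[1],
               n_subjects = N, mean_z_std = m, sd_z_std = s,
               t = tstat, p = p)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    stop("no pair has >= 3 subjects", call. = FALSE)
  rownames(out) <- NULL
  out$reject <- fdr_weak(out$p, alpha = alpha)$reject
  out
}

#' Hemispheric connectivity summaries
#'
#' Per subject, averages the standardized Fisher-Z values over the pairs
#' whose endpoints are both left-hemisphere ("left"), both right-hemisphere
#' ("right"), or one of each ("inter"), within each network and between each
#' pair of networks. Entries with a hemisphere label other than "L"/"R" are
#' excluded from the left/right scopes and from inter.
#'
#' @param conn data.frame from [pairwise_connectivity()].
#' @param meta the \code{meta} data.frame of the series set (must carry
#'   \code{hemisphere}) with one row per entry.
#' @param network integer or character vector, one network label per entry.
#' @return data.frame: subject, net_a, net_b (net_a == net_b for
#'   within-network scopes), scope, mean_z_std, n_pairs.
#' @export
hemispheric_summaries <- function(conn, meta, network) {
  stopifnot(nrow(meta) >= max(conn$roi_a, conn$roi_b),
            length(network) == nrow(meta))
  hemi <- as.character(meta$hemisphere)
  ha <- hemi[conn$roi_a]; hb <- hemi[conn$roi_b]
  ok <- ha %in% c("L", "R") & hb %in% c("L", "R")
  cc <- conn[ok, ]
  ha <- ha[ok]; hb <- hb[ok]
  scope <- ifelse(ha == hb, ifelse(ha == "L", "left", "right"), "inter")
  na <- as.character(network)[cc$roi_a]
  nb <- as.character(network)[cc$roi_b]
  net_a <- pmin(na, nb); net_b <- pmax(na, nb)
  key <- paste(cc$subject, net_a, net_b, scope, sep = "\r")
  agg <- tapply(cc$z_std, key, mean)
  cnt <- tapply(cc$z_std, key, length)
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(subject = as.integer(parts[, 1]),
                    net_a = parts[, 2], net_b = parts[, 3],
                    scope = parts[, 4],
                    mean_z_std = as.numeric(agg),
                    n_pairs = as.integer(cnt))
  out[order(out$net_a, out$net_b, out$scope, out$subject), ]
}

#' Partial correlation controlling covariates
#'
#' Pearson correlation of the residuals of \code{y} and \code{x} after linear
#' projection on an intercept and the covariates; the p-value uses the t
#' reference with \code{N - 2 - c} degrees of freedom where c is the number
#' of covariates. With no covariates this is the plain Pearson correlation.
#'
#' @param y,x numeric vectors of equal length.
#' @param covariates numeric matrix or data.frame with one row per
#'   observation, or NULL.
#' @return list with \code{estimate}, \code{statistic}, \code{df},
#'   \code{p_value}, \code{n}, \code{n_covariates}.
#' @export
partial_correlation <- function(y, x, covariates = NULL) {
  N <- length(y)
  stopifnot(length(x) == N)
  if (is.null(covariates)) {
    Z <- matrix(1, N, 1)
    ncov <- 0L
  } else {
    covariates <- as.matrix(covariates)
    stopifnot(nrow(covariates) == N)
    Z <- cbind(1, covariates)
    ncov <- ncol(covariates)
  }
  if (N <= ncov + 2L)
    stop("need N > number of covariates + 2", call. = FALSE)
  if (qr(Z)$rank < ncol(Z))
    stop("covariate matrix is rank deficient", call. = FALSE)
  ry <- stats::lm.fit(Z, y)$residuals
  rx <- stats::lm.fit(Z, x)$residuals
  r <- cor(ry, rx)
  df <- N - 2L - ncov
  tstat <- r * sqrt(df / (1 - r^2))
  list(estimate = r, statistic = tstat, df = df,
       p_value = 2 * pt(-abs(tstat), df = df),
       n = N, n_covariates = ncov)
}

#' Cortisol association table
#'
#' For every (network scope, hemisphere scope) summary in \code{summaries},
#' the mean and standard deviation of the per-subject connectivity values and
#' the partial correlations (with p-values) against pre- and post-scan
#' cortisol, controlling for the demographic covariates (by default age,
#' sex, trait anxiety and the stress questionnaire score; state anxiety is
#' excluded).
#'
#' @param summaries data.frame from [hemispheric_summaries()].
#' @param subjects subjects table with columns \code{subject_id},
#'   \code{pre_cortisol}, \code{post_cortisol} and the covariates.
#' @param covariates character vector of covariate column names.
#' @return data.frame: net_a, net_b, scope, n, mean, sd, r_pre, p_pre,
#'   r_post, p_post.
#' @export
cortisol_association <- function(summaries, subjects,
                                 covariates = c("age", "sex", "STAI_trait",
                                                "SQ_ISMA")) {
  stopifnot(all(c("pre_cortisol", "post_cortisol", "subject_id", covariates)
                %in% names(subjects)))
  key <- interaction(summaries$net_a, summaries$net_b, summaries$scope,
                     drop = TRUE)
  rows <- lapply(split(summaries, key), function(d) {
    idx <- match(d$subject, subjects$subject_id)
    keep <- !is.na(idx)
    d <- d[keep, ]; idx <- idx[keep]
    if (nrow(d) <= length(covariates) + 2L) return(NULL)
    Z <- as.matrix(subjects[idx, covariates])
    pre <- partial_correlation(subjects$pre_cortisol[idx], d$mean_z_std, Z)
    post <- partial_correlation(subjects$post_cortisol[idx], d$mean_z_std, Z)
    data.frame(net_a = d$net_a[1], net_b = d$net_b[1], scope = d$scope[1],
               n = nrow(d), mean = mean(d$mean_z_std), sd = sd(d$mean_z_std),
               r_pre = pre$estimate, p_pre = pre$p_value,
               r_post = post$estimate, p_post = post$p_value)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
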