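make_roi_set <- function(tcs, names_ = NULL, hemi = NULL) {
  R <- length(tcs)
  meta <- data.frame(
    roi_id = seq_len(R),
    roi_name = if (is.null(names_)) paste0("roi", seq_len(R)) else names_,
    hemisphere = if (is.null(hemi)) rep(c("L", "R"), length.out = R) else hemi,
    network_hint = "x", n_supra_voxels = 1L, n_voxels = 1L,
    supra_fraction = 1)
  structure(list(meta = meta, subject_tcs = tcs,
                 group_tc = sapply(tcs, rowMeans),
                 voxel_members = as.list(seq_len(R))),
            class = "roi_series_set")
}

test_that("pairwise connectivity recovers a planted correlation", {
  set.seed(401)
  n <- 240; M <- 20; rho <- 0.6
  base <- matrix(rnorm(n * M), n, M)
  ta <- base
  tb <- rho * base + sqrt(1 - rho^2) * matrix(rnorm(n * M), n, M)
  conn <- pairwise_connectivity(make_roi_set(list(ta, tb)))
  expect_equal(nrow(conn), M)
  expect_equal(mean(conn$r), rho, tolerance = 0.05)
  expect_equal(conn$z, atanh(conn$r), tolerance = 1e-12)
  expect_equal(mean(conn$z_std), atanh(rho) * sqrt(240), tolerance = 1)

  # orthogonal sinusoids: r ~ 0
  s1 <- matrix(sin(2 * pi * seq_len(n) / 40), n, 2)
  s2 <- matrix(cos(2 * pi * seq_len(n) / 40), n, 2)
  c0 <- pairwise_connectivity(make_roi_set(list(s1, s2)))
  expect_lt(max(abs(c0$r)), 1e-8)

  # identical series: infinite Fisher Z, skipped explicitly
  expect_warning(
    expect_error(pairwise_connectivity(make_roi_set(list(ta, ta))),
                 "no valid"),
    "skipped")
  expect_error(pairwise_connectivity(make_roi_set(list(ta, tb)),
                                     window = 0:10), "window")
})

test_that("standardized Fisher Z scales exactly with the root window length", {
  set.seed(411)
  n <- 240
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  rs <- make_roi_set(list(cbind(x, x), cbind(y, y)))
  full <- pairwise_connectivity(rs, window = 1:240)
  half <- pairwise_connectivity(rs, window = 1:120)
  expect_equal(full$z_std[1] / full$z[1], sqrt(240), tolerance = 1e-12)
  expect_equal(half$z_std[1] / half$z[1], sqrt(120), tolerance = 1e-12)
  # at fixed r the ratio of standardizations is exactly sqrt(2)
  expect_equal((full$z[1] * sqrt(240)) / (full$z[1] * sqrt(120)), sqrt(2),
               tolerance = 1e-12)
})

test_that("group test matches hand arithmetic and degenerate cases", {
  zz <- c(0.1, 0.2, 0.3, 0.2, 0.2)
  conn <- data.frame(subject = 1:5, roi_a = 1L, roi_b = 2L,
                     name_a = "a", name_b = "b", r = tanh(zz), z = zz,
                     z_std = zz, window = "full", n_window = 1)
  g <- group_connectivity_test(conn)
  expect_equal(g$t, mean(zz) / (sd(zz) / sqrt(5)), tolerance = 1e-12)
  expect_equal(g$p, 2 * pt(-abs(g$t), df = 4), tolerance = 1e-12)
  # all-zero connectivity: t = 0, p = 1
  conn0 <- conn; conn0$z_std <- 0
  g0 <- group_connectivity_test(conn0)
  expect_equal(g0$t, 0)
  expect_equal(g0$p, 1)
})

test_that("group test has power at the planted cohort effect", {
  set.seed(421)
  hits <- 0L
  for (s in 1:20) {
    z <- rnorm(25, mean = 0.3, sd = 0.1)
    conn <- data.frame(subject = 1:25, roi_a = 1L, roi_b = 2L,
                       name_a = "a", name_b = "b", r = tanh(z), z = z,
                       z_std = z, window = "full", n_window = 1)
    hits <- hits + (group_connectivity_test(conn, alpha = 0.05)$reject)
  }
  expect_gte(hits, 19L)  # >= 95 percent of seeds
})

test_that("hemispheric scopes have the right pair combinatorics", {
  set.seed(431)
  n <- 60
  tcs <- lapply(1:4, function(i) matrix(rnorm(n * 3), n, 3))
  rs <- make_roi_set(tcs, hemi = c("L", "L", "R", "R"))
  conn <- pairwise_connectivity(rs)
  summ <- hemispheric_summaries(conn, rs$meta, rep(1L, 4))
  cnt <- summ[summ$subject == 1, c("scope", "n_pairs")]
  expect_equal(cnt$n_pairs[cnt$scope == "left"], 1L)
  expect_equal(cnt$n_pairs[cnt$scope == "right"], 1L)
  expect_equal(cnt$n_pairs[cnt$scope == "inter"], 4L)

  # all pairs equal z: every scope mean equals that z
  conn2 <- conn; conn2$z_std <- 0.7
  s2 <- hemispheric_summaries(conn2, rs$meta, rep(1L, 4))
  expect_true(all(abs(s2$mean_z_std - 0.7) < 1e-12))
})

test_that("planted left-hemisphere strengthening shows in the summaries", {
  set.seed(441)
  n <- 240; M <- 12
  shared_L <- matrix(rnorm(n * M), n, M)
  shared_R <- matrix(rnorm(n * M), n, M)
  mk <- function(shared, lam)
    lam * shared + sqrt(1 - lam^2) * matrix(rnorm(n * M), n, M)
  tcs <- list(mk(shared_L, 0.8), mk(shared_L, 0.8),   # strong left pair
              mk(shared_R, 0.4), mk(shared_R, 0.4))   # weaker right pair
  rs <- make_roi_set(tcs, hemi = c("L", "L", "R", "R"))
  conn <- pairwise_connectivity(rs)
  summ <- hemispheric_summaries(conn, rs$meta, rep(1L, 4))
  left <- mean(summ$mean_z_std[summ$scope == "left"])
  right <- mean(summ$mean_z_std[summ$scope == "right"])
  expect_gt(left, right)
})

test_that("partial correlation residualizes exactly", {
  set.seed(451)
  N <- 40
  x <- rnorm(N)
  # no covariates: plain Pearson correlation
  y <- 0.5 * x + rnorm(N)
  pc <- partial_correlation(y, x)
  expect_equal(pc$estimate, cor(y, x), tolerance = 1e-12)
  expect_equal(pc$df, N - 2L)

  # y = x + covariate exactly; controlling the covariate leaves the
  # noise-free residual relationship (r = 1 up to rounding)
  cv <- rnorm(N)
  y2 <- x + 3 * cv
  pc2 <- partial_correlation(y2, x, cbind(cv))
  ry <- lm.fit(cbind(1, cv), y2)$residuals
  rx <- lm.fit(cbind(1, cv), x)$residuals
  expect_equal(pc2$estimate, cor(ry, rx), tolerance = 1e-12)
  expect_equal(pc2$estimate, 1, tolerance = 1e-8)
  expect_equal(pc2$df, N - 3L)

  # affine invariance
  Z <- cbind(rnorm(N), rnorm(N))
  y3 <- rnorm(N); x3 <- rnorm(N)
  a <- partial_correlation(y3, x3, Z)
  b <- partial_correlation(5 * y3 - 2, -3 * x3 + 1,
                           sweep(Z * 2.5, 2, c(1, -4), "+"))
  expect_equal(abs(a$estimate), abs(b$estimate), tolerance = 1e-10)

  expect_error(partial_correlation(y3, x3, cbind(Z, Z[, 1])), "rank")
  expect_error(partial_correlation(rnorm(5), rnorm(5), matrix(rnorm(20), 5)),
               "N >")
})

test_that("cortisol association table covers scopes with both hormones", {
  set.seed(461)
  N <- 25
  subj <- simulate_cortisol(rnorm(N), target_partial_r = 0.5, seed = 462)
  summ <- expand.grid(subject = 1:N, net_a = c("1", "2"), net_b = c("1", "2"),
                      scope = c("left", "right", "inter"),
                      stringsAsFactors = FALSE)
  summ <- summ[summ$net_a <= summ$net_b, ]
  summ$mean_z_std <- rnorm(nrow(summ))
  summ$n_pairs <- 1L
  tab <- cortisol_association(summ, subj)
  expect_true(all(c("r_pre", "p_pre", "r_post", "p_post") %in% names(tab)))
  expect_true(all(abs(tab$r_pre) <= 1 & abs(tab$r_post) <= 1))
  expect_equal(nrow(tab), 9L)
})
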