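test_that("ROI means reproduce single- and two-voxel averages exactly", {
  set.seed(301)
  d <- synthetic_design(n_volumes = 40, eo_onset = 21, n_subjects = 3,
                        grid = c(4L, 4L, 4L))
  ds <- simulate_dataset(d)
  supra <- rep(TRUE, dim(ds$bold)[3])
  roi <- roi_mean_timecourses(ds, supra)
  # single-voxel region: restrict supra to one voxel of region 1
  vox1 <- which(as.integer(ds$atlas) == 1L)
  supra1 <- rep(FALSE, dim(ds$bold)[3]); supra1[vox1[1]] <- TRUE
  r1 <- suppressWarnings(roi_mean_timecourses(ds, supra1))
  expect_equal(r1$subject_tcs[[1]], ds$bold[, , vox1[1]], tolerance = 1e-12)
  # two-voxel region: mean is (a + b) / 2 (coarser grid so regions span
  # several voxels)
  d8 <- synthetic_design(n_volumes = 40, eo_onset = 21, n_subjects = 3,
                         grid = c(8L, 8L, 4L))
  ds8 <- simulate_dataset(d8)
  vox8 <- which(as.integer(ds8$atlas) == 1L)
  supra2 <- rep(FALSE, dim(ds8$bold)[3]); supra2[vox8[1:2]] <- TRUE
  r2 <- suppressWarnings(roi_mean_timecourses(ds8, supra2))
  expect_equal(r2$subject_tcs[[1]],
               (ds8$bold[, , vox8[1]] + ds8$bold[, , vox8[2]]) / 2,
               tolerance = 1e-12)
  # group tc is the elementwise mean of subject tcs
  expect_equal(roi$group_tc[, 1], rowMeans(roi$subject_tcs[[1]]),
               tolerance = 1e-10)
  expect_error(roi_mean_timecourses(ds, TRUE), "grid mismatch")
})

test_that("regions without supra-threshold voxels are dropped with warning", {
  set.seed(302)
  d <- synthetic_design(n_volumes = 24, eo_onset = 13, n_subjects = 2,
                        grid = c(4L, 4L, 4L))
  ds <- simulate_dataset(d)
  supra <- as.integer(ds$atlas) == 1L
  w <- capture_warnings(roi <- roi_mean_timecourses(ds, supra))
  expect_true(any(grepl("dropped", w)))
  expect_equal(nrow(roi$meta), 1L)
  expect_equal(roi$meta$supra_fraction, 1)
})

test_that("homogeneity split fires only on genuinely mixed regions", {
  set.seed(311)
  n <- 120
  tmpl <- sin(2 * pi * seq_len(n) / 40)
  # homogeneous region: one template + noise, no split
  hom <- sapply(1:10, function(i) tmpl + rnorm(n, sd = 1))
  expect_false(homogeneity_split(hom)$split)
  # mixed region: half positive, half negative transients -> split
  mix <- cbind(sapply(1:5, function(i) 3 * tmpl + rnorm(n, sd = 0.5)),
               sapply(1:5, function(i) -3 * tmpl + rnorm(n, sd = 0.5)))
  hs <- homogeneity_split(mix)
  expect_true(hs$split)
  expect_equal(length(unique(hs$assignment[1:5])), 1L)
  expect_true(all(hs$assignment[1:5] != hs$assignment[6:10]))
  # too few voxels: returned unsplit
  expect_false(homogeneity_split(mix[, 1:3])$split)
})

test_that("split of a planted mixed region yields opposite-signed groups", {
  set.seed(321)
  d <- synthetic_design(n_volumes = 120, eo_onset = 61, n_subjects = 6,
                        grid = c(8L, 8L, 4L), amplitude = 1)
  ds <- simulate_dataset(d)
  # overwrite region 1 voxels: half get the negated template
  vox1 <- which(as.integer(ds$atlas) == 1L)
  half <- vox1[seq(1, length(vox1), by = 2)]
  tmpl <- response_template("positive-transient", d)
  tmpl <- 2 * tmpl / sd(tmpl)
  for (v in half) ds$bold[, , v] <- ds$bold[, , v] - rep(tmpl, 6) * 2
  supra <- rep(TRUE, dim(ds$bold)[3])
  roi <- roi_mean_timecourses(ds, supra)
  roi2 <- split_heterogeneous_rois(ds, roi)
  sub1 <- grep("^pos_L1", roi2$meta$roi_name)
  expect_equal(length(sub1), 2L)
  g <- roi2$group_tc[, sub1]
  expect_lt(cor(g[, 1], g[, 2]), 0)
})

test_that("network partition selects the planted number of clusters", {
  set.seed(331)
  n <- 120
  t1 <- sin(2 * pi * seq_len(n) / 60)
  t2 <- cos(2 * pi * seq_len(n) / 30)
  two <- cbind(sapply(1:4, function(i) t1 + rnorm(n, sd = 0.2)),
               sapply(1:4, function(i) t2 + rnorm(n, sd = 0.2)))
  p2 <- network_partition(two, K_range = 2:4, seed = 332)
  expect_equal(p2$K, 2L)
  expect_equal(length(unique(p2$labels[1:4])), 1L)
  expect_true(all(p2$labels[1:4] != p2$labels[5:8]))
  expect_equal(unname(p2$silhouette_mean), max(p2$silhouette_per_K))
  # degenerate: identical series
  same <- matrix(rep(t1, 5), n, 5)
  expect_error(network_partition(same), "identical")
})

test_that("partition is invariant to entry order and affine rescaling", {
  set.seed(341)
  n <- 100
  t1 <- sin(2 * pi * seq_len(n) / 50)
  t2 <- c(rep(-1, 50), rep(1, 50))
  G <- cbind(sapply(1:3, function(i) t1 + rnorm(n, sd = 0.2)),
             sapply(1:3, function(i) t2 + rnorm(n, sd = 0.2)))
  p0 <- network_partition(G, K_range = 2:3, seed = 342)
  # permuted columns
  perm <- c(4, 1, 5, 2, 6, 3)
  p1 <- network_partition(G[, perm], K_range = 2:3, seed = 342)
  expect_equal(p1$K, p0$K)
  agree <- table(p0$labels[perm], p1$labels)
  expect_equal(sum(apply(agree, 1, max)), 6)
  # per-series affine rescaling: z-scoring removes it
  Ga <- sweep(sweep(G, 2, c(2, 5, 1, 9, 3, 4), "*"), 2, rnorm(6), "+")
  p2 <- network_partition(Ga, K_range = 2:3, seed = 342)
  agree2 <- table(p0$labels, p2$labels)
  expect_equal(sum(apply(agree2, 1, max)), 6)
})

test_that("K range shrinks with a warning when entries are scarce", {
  set.seed(351)
  n <- 60
  G <- cbind(sapply(1:2, function(i) sin(seq_len(n) / 5) + rnorm(n, sd = .3)),
             sapply(1:2, function(i) cos(seq_len(n) / 9) + rnorm(n, sd = .3)))
  expect_warning(p <- network_partition(G, K_range = 2:6), "shrunk")
  expect_lte(p$K, 3L)
})
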