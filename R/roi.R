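# Supra-threshold ROI mean time courses, homogeneity splitting of mixed
# regions, and network identification by multi-restart K-means with
# Silhouette model selection.

#' ROI mean time courses over supra-threshold voxels
#'
#' For every region in the atlas, averages the time courses of the voxels
#' that are both inside the region and supra-threshold, per subject; the
#' group time course is the mean of the subject-level means. Regions with an
#' empty intersection are dropped with a warning.
#'
#' @param dataset an \code{"isc_dataset"} (or any list with \code{bold}
#'   n x M x K, \code{atlas}, \code{labels}).
#' @param supra logical vector of length K flagging supra-threshold voxels.
#' @return An object of class \code{"roi_series_set"}: list with \code{meta}
#'   (data.frame: roi_id, roi_name, hemisphere, network_hint,
#'   n_supra_voxels, n_voxels, supra_fraction), \code{subject_tcs} (list of
#'   n x M matrices), \code{group_tc} (n x R matrix), \code{voxel_members}
#'   (list of supra voxel indices per region).
#' @export
roi_mean_timecourses <- function(dataset, supra) {
  K <- dim(dataset$bold)[3]
  if (length(supra) != K)
    stop("`supra` must have one entry per voxel (grid mismatch)",
         call. = FALSE)
  lab_vec <- as.integer(dataset$atlas)
  if (length(lab_vec) != K)
    stop("atlas/data grid mismatch", call. = FALSE)
  meta <- list(); subject_tcs <- list(); members <- list()
  group <- list()
  kept <- 0L
  for (r in seq_len(nrow(dataset$labels))) {
    row <- dataset$labels[r, ]
    vox_all <- which(lab_vec == row$label_id)
    vox_sup <- vox_all[supra[vox_all]]
    if (length(vox_sup) == 0L) {
      warning("ROI ", row$roi_name, " has no supra-threshold voxels; dropped",
              call. = FALSE)
      next
    }
    kept <- kept + 1L
    stc <- apply(dataset$bold[, , vox_sup, drop = FALSE], c(1, 2), mean)
    meta[[kept]] <- data.frame(
      roi_id = row$label_id, roi_name = row$roi_name,
      hemisphere = row$hemisphere, network_hint = row$network_hint,
      n_supra_voxels = length(vox_sup), n_voxels = length(vox_all),
      supra_fraction = length(vox_sup) / length(vox_all))
    subject_tcs[[kept]] <- stc
    group[[kept]] <- rowMeans(stc)
    members[[kept]] <- vox_sup
  }
  if (kept == 0L) stop("no ROI has supra-threshold voxels", call. = FALSE)
  meta <- do.call(rbind, meta)
  structure(list(meta = meta, subject_tcs = subject_tcs,
                 group_tc = do.call(cbind, group),
                 voxel_members = members),
            class = "roi_series_set")
}

#' @export
print.roi_series_set <- function(x, ...) {
  cat("ROI series set:", nrow(x$meta), "entries,",
      nrow(x$group_tc), "time points\n")
  print(x$meta[, c("roi_name", "hemisphere", "n_supra_voxels",
                   "supra_fraction")], row.names = FALSE)
  invisible(x)
}

# mean silhouette width of a flat clustering (Euclidean distance)
.mean_silhouette <- function(labels, X) {
  sil <- cluster::silhouette(labels, stats::dist(X))
  mean(sil[, "sil_width"])
}

#' Split a heterogeneous ROI into two sub-ROIs
#'
#' K-means with K = 2 on the z-scored voxelwise mean-across-subjects series
#' of a region; the split is accepted only when the mean Silhouette width is
#' at least \code{sil_threshold} (0.5, the conventional lower edge of
#' "reasonable structure"). Regions with fewer than 4 supra-threshold voxels
#' are returned unsplit.
#'
#' @param voxel_tcs n x V matrix, one column per supra-threshold voxel in the
#'   region (mean across subjects).
#' @param sil_threshold minimum mean Silhouette width to accept the split.
#' @param nstart K-means restarts.
#' @return list with \code{split} (logical), \code{assignment} (integer
#'   vector of length V, all 1 when unsplit), \code{silhouette}.
#' @export
homogeneity_split <- function(voxel_tcs, sil_threshold = 0.5, nstart = 25L) {
  V <- ncol(voxel_tcs)
  if (V < 4L)
    return(list(split = FALSE, assignment = rep(1L, V),
                silhouette = NA_real_))
  Z <- scale(voxel_tcs)
  km <- kmeans(t(Z), centers = 2L, nstart = nstart)
  sil <- .mean_silhouette(km$cluster, t(Z))
  if (is.finite(sil) && sil >= sil_threshold)
    list(split = TRUE, assignment = as.integer(km$cluster), silhouette = sil)
  else
    list(split = FALSE, assignment = rep(1L, V), silhouette = sil)
}

#' Apply homogeneity splitting to every region of a series set
#'
#' Re-derives the per-region voxel mean series from the dataset, tests each
#' region with [homogeneity_split()], and rebuilds the series set with
#' accepted splits as sub-regions (suffixes "a"/"b" on the region name).
#'
#' @inheritParams roi_mean_timecourses
#' @param roi_set a \code{"roi_series_set"} from [roi_mean_timecourses()].
#' @param sil_threshold passed to [homogeneity_split()].
#' @return a new \code{"roi_series_set"}.
#' @export
split_heterogeneous_rois <- function(dataset, roi_set, sil_threshold = 0.5) {
  meta <- list(); subject_tcs <- list(); group <- list(); members <- list()
  kept <- 0L
  for (r in seq_len(nrow(roi_set$meta))) {
    vox <- roi_set$voxel_members[[r]]
    vox_mean <- apply(dataset$bold[, , vox, drop = FALSE], c(1, 3), mean)
    hs <- homogeneity_split(vox_mean, sil_threshold = sil_threshold)
    parts <- if (hs$split) split(seq_along(vox), hs$assignment)
             else list(seq_along(vox))
    for (pi in seq_along(parts)) {
      kept <- kept + 1L
      vx <- vox[parts[[pi]]]
      stc <- apply(dataset$bold[, , vx, drop = FALSE], c(1, 2), mean)
      m <- roi_set$meta[r, ]
      if (hs$split)
        m$roi_name <- paste0(m$roi_name, c("a", "b")[pi])
      m$n_supra_voxels <- length(vx)
      m$supra_fraction <- length(vx) / m$n_voxels
      meta[[kept]] <- m
      subject_tcs[[kept]] <- stc
      group[[kept]] <- rowMeans(stc)
      members[[kept]] <- vx
    }
  }
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  structure(list(meta = meta, subject_tcs = subject_tcs,
                 group_tc = do.call(cbind, group), voxel_members = members),
            class = "roi_series_set")
}

#' Network identification by iterative K-means with Silhouette selection
#'
#' Clusters the group-level mean time courses (z-scored per series, so that
#' response shape rather than amplitude drives the grouping) with
#' multi-restart K-means for every candidate K, and selects the K with the
#' largest mean Silhouette width.
#'
#' @param group_tc n x R matrix of group-level series (one column per ROI or
#'   sub-ROI entry).
#' @param K_range candidate cluster counts (default 2:6); shrunk with a
#'   warning if there are too few series.
#' @param nstart K-means restarts per candidate K.
#' @param seed optional RNG seed for the restarts.
#' @return An object of class \code{"network_partition"}: list with \code{K},
#'   \code{labels}, \code{silhouette_mean}, \code{silhouette_per_K},
#'   \code{centers}.
#' @export
network_partition <- function(group_tc, K_range = 2:6, nstart = 100L,
                              seed = NULL) {
  R <- ncol(group_tc)
  if (R < 3L) stop("need at least 3 series to partition", call. = FALSE)
  Z <- scale(group_tc)
  if (max(stats::dist(t(Z))) < 1e-10)
    stop("degenerate input: all series are identical after z-scoring",
         call. = FALSE)
  if (max(K_range) + 1L > R) {
    K_range <- K_range[K_range + 1L <= R]
    warning("K range shrunk to ", paste(range(K_range), collapse = ".."),
            " (only ", R, " series)", call. = FALSE)
    if (length(K_range) == 0L)
      stop("too few series for any candidate K", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  sil_per_K <- stats::setNames(numeric(length(K_range)),
                               as.character(K_range))
  fits <- vector("list", length(K_range))
  for (i in seq_along(K_range)) {
    km <- kmeans(t(Z), centers = K_range[i], nstart = nstart)
    fits[[i]] <- km
    sil_per_K[i] <- .mean_silhouette(km$cluster, t(Z))
  }
  best <- which.max(sil_per_K)
  structure(list(K = K_range[best],
                 labels = as.integer(fits[[best]]$cluster),
                 silhouette_mean = sil_per_K[best],
                 silhouette_per_K = sil_per_K,
                 centers = fits[[best]]$centers),
            class = "network_partition")
}

#' @export
print.network_partition <- function(x, ...) {
  cat("Network partition: K =", x$K,
      sprintf("(mean silhouette %.3f)\n", x$silhouette_mean))
  cat("  silhouette by K:",
      paste(names(x$silhouette_per_K),
            sprintf("%.3f", x$silhouette_per_K), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}
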