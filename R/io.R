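# NIfTI-1 and TSV input/output. Volumes are written with RNifti; the voxel
# block layout used in memory (n x M x K over in-mask voxels) is
# reconstructed from the mask on read.

#' Write a dataset as NIfTI volumes and TSV tables
#'
#' Writes one 4D BOLD volume per subject, the brain mask, the integer atlas,
#' the label and truth tables (TSV), and a JSON design record.
#'
#' @param dataset an \code{"isc_dataset"}.
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  d <- dataset$design
  n <- d$n_volumes; M <- d$n_subjects; g <- d$grid
  idx <- which(dataset$mask)
  for (i in seq_len(M)) {
    vol <- array(0, dim = c(g, n))
    flat <- matrix(vol, prod(g), n)
    flat[idx, ] <- t(dataset$bold[, i, ])
    vol <- array(flat, dim = c(g, n))
    img <- RNifti::asNifti(vol, reference = NULL)
    RNifti::pixdim(img) <- c(1, 1, 1, d$tr)
    RNifti::writeNifti(img, file.path(dir, sprintf("sub-%02d_bold.nii.gz", i)))
  }
  RNifti::writeNifti(RNifti::asNifti(array(as.integer(dataset$mask), g)),
                     file.path(dir, "mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(dataset$atlas),
                     file.path(dir, "atlas.nii.gz"))
  utils::write.table(dataset$labels, file.path(dir, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(d), file.path(dir, "design.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir directory holding \code{sub-*_bold.nii.gz}, \code{mask.nii.gz},
#'   \code{atlas.nii.gz}, \code{labels.tsv} and (optionally)
#'   \code{truth.tsv}, \code{design.json}.
#' @return an \code{"isc_dataset"}.
#' @export
read_dataset <- function(dir) {
  bold_files <- sort(list.files(dir, pattern = "^sub-.*_bold\\.nii(\\.gz)?$",
                                full.names = TRUE))
  if (length(bold_files) == 0L)
    stop("no subject BOLD volumes found in ", dir, call. = FALSE)
  mask <- RNifti::readNifti(file.path(dir, "mask.nii.gz"))
  mask <- array(mask > 0, dim = dim(mask))
  atlas <- RNifti::readNifti(file.path(dir, "atlas.nii.gz"))
  atlas <- array(as.integer(atlas), dim = dim(atlas))
  idx <- which(mask)
  g <- dim(mask)
  M <- length(bold_files)
  bold <- NULL
  for (i in seq_len(M)) {
    vol <- RNifti::readNifti(bold_files[i])
    if (!all(dim(vol)[1:3] == g))
      stop("grid mismatch between mask and ", bold_files[i], call. = FALSE)
    n <- dim(vol)[4]
    flat <- matrix(vol, prod(g), n)
    if (is.null(bold)) bold <- array(0, dim = c(n, M, length(idx)))
    bold[, i, ] <- t(flat[idx, , drop = FALSE])
  }
  labels <- utils::read.delim(file.path(dir, "labels.tsv"))
  truth_f <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_f)) utils::read.delim(truth_f) else NULL
  design_f <- file.path(dir, "design.json")
  design <- if (file.exists(design_f)) {
    dl <- jsonlite::read_json(design_f, simplifyVector = TRUE)
    structure(dl, class = "synthetic_design")
  } else NULL
  vox <- which(mask, arr.ind = TRUE)
  structure(list(bold = bold, mask = mask, atlas = atlas, vox = vox,
                 labels = labels, truth = truth, design = design),
            class = "isc_dataset")
}

#' Write agreement stat maps as NIfTI volumes
#'
#' Writes brain-shaped A, SE, t, p and supra-threshold mask volumes sharing
#' the mask's grid, plus a TSV summary of the supra-threshold voxels.
#'
#' @param map an \code{"icc_map"}.
#' @param mask logical 3D array (in-mask voxels in the map's voxel order).
#' @param dir output directory.
#' @param prefix file name prefix.
#' @return the directory, invisibly.
#' @export
write_stat_maps <- function(map, mask, dir, prefix = "icc") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  idx <- which(mask)
  g <- dim(mask)
  stopifnot(length(idx) == nrow(map$stats))
  put <- function(values, file) {
    vol <- array(NA_real_, g)
    vol[idx] <- values
    RNifti::writeNifti(RNifti::asNifti(vol), file.path(dir, file))
  }
  put(map$stats$A_hat, paste0(prefix, "_A.nii.gz"))
  put(map$stats$se_A, paste0(prefix, "_SE.nii.gz"))
  put(map$stats$t_A, paste0(prefix, "_t.nii.gz"))
  put(map$stats$p, paste0(prefix, "_p.nii.gz"))
  put(as.numeric(map$stats$supra), paste0(prefix, "_supra.nii.gz"))
  vox <- which(mask, arr.ind = TRUE)
  sup <- map$stats$supra
  summ <- data.frame(voxel = map$stats$voxel[sup],
                     x = vox[sup, 1], y = vox[sup, 2], z = vox[sup, 3],
                     A_hat = map$stats$A_hat[sup],
                     t_A = map$stats$t_A[sup], p = map$stats$p[sup])
  utils::write.table(summ, file.path(dir, paste0(prefix, "_supra.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
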