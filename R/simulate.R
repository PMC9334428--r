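# Synthetic multi-subject BOLD generator with known ground truth.
#
# The generator emulates a single eyes-closed -> eyes-open resting-state
# cycle: n = 240 volumes at TR = 2 s, the EC condition starting at volume 1
# and the EO condition at volume 121, with network-shaped transient responses
# shared across subjects, AR(1) temporal noise, between-subject mean offsets
# (which drive the Gamma > 0 regime separating agreement from consistency),
# and subject-specific response amplitudes.

#' Synthetic study design
#'
#' Parameters of the synthetic EC/EO dataset. Defaults follow the acquisition
#' being emulated (240 volumes, TR 2 s, EC onset at volume 1, EO onset at
#' volume 121, transient responses lasting about 60 s) on a small
#' 12 x 12 x 8 voxel grid with three planted response networks of four
#' regions each (two per hemisphere), four signal-free control regions, and
#' unlabeled null background voxels.
#'
#' @param n_volumes number of time points.
#' @param tr repetition time in seconds.
#' @param n_subjects number of subjects M (up to 49).
#' @param grid 3-vector of grid dimensions; each must be divisible by the
#'   block layout (4, 4, 4).
#' @param ec_onset,eo_onset condition onset volumes.
#' @param amplitude shared network response amplitude, expressed as the
#'   standard deviation of the response time course (each network shape is
#'   normalized to unit time-course SD at simulation time) in units of the
#'   noise innovation standard deviation.
#' @param transient_duration response decay time constant support in seconds;
#'   the positive/negative transients return to within 10 percent of baseline
#'   by 90 s after onset.
#' @param subject_amp_sd between-subject relative amplitude spread.
#' @param ar_coef AR(1) coefficient of the temporal noise, in (-1, 1).
#' @param innovation_sd AR(1) innovation standard deviation.
#' @param offset_sd standard deviation of per-subject, per-voxel mean offsets.
#' @param seed master seed recorded with the design.
#' @return An object of class \code{"synthetic_design"}.
#' @export
synthetic_design <- function(n_volumes = 240L, tr = 2, n_subjects = 10L,
                             grid = c(12L, 12L, 8L),
                             ec_onset = 1L, eo_onset = 121L,
                             amplitude = 0.5, transient_duration = 60,
                             subject_amp_sd = 0.25,
                             ar_coef = 0.3, innovation_sd = 1,
                             offset_sd = 1, seed = 1L) {
  stopifnot(n_volumes >= 8, n_subjects >= 2, length(grid) == 3,
            ec_onset >= 1, eo_onset > ec_onset, eo_onset <= n_volumes,
            abs(ar_coef) < 1, innovation_sd > 0)
  if (any(grid %% c(4L, 4L, 4L) != 0))
    stop("grid dimensions must be divisible by 4", call. = FALSE)
  structure(list(n_volumes = as.integer(n_volumes), tr = tr,
                 n_subjects = as.integer(n_subjects),
                 grid = as.integer(grid),
                 ec_onset = as.integer(ec_onset),
                 eo_onset = as.integer(eo_onset),
                 amplitude = amplitude,
                 transient_duration = transient_duration,
                 subject_amp_sd = subject_amp_sd,
                 ar_coef = ar_coef, innovation_sd = innovation_sd,
                 offset_sd = offset_sd, seed = as.integer(seed)),
            class = "synthetic_design")
}

.network_types <- c("positive-transient", "negative-transient",
                    "limbic-biphasic", "null")

#' Network response templates
#'
#' Deterministic response shapes, one value per volume, peak magnitude 1
#' (scaled by the design amplitude at simulation time):
#' \itemize{
#'   \item \code{positive-transient}: a gamma-like bump
#'     (difference of exponentials) after each onset, with the EO response
#'     twice the EC amplitude, decaying to baseline within the configured
#'     duration;
#'   \item \code{negative-transient}: its negation;
#'   \item \code{limbic-biphasic}: a slow prolonged decrease during EC, then
#'     a short dip followed by a sustained rise after EO;
#'   \item \code{null}: zeros.
#' }
#'
#' @param type one of \code{"positive-transient"}, \code{"negative-transient"},
#'   \code{"limbic-biphasic"}, \code{"null"}.
#' @param design a \code{"synthetic_design"}.
#' @return numeric vector of length \code{design$n_volumes}.
#' @export
response_template <- function(type, design) {
  type <- match.arg(type, .network_types)
  n <- design$n_volumes
  t_sec <- (seq_len(n) - 1) * design$tr
  t_ec <- (design$ec_onset - 1) * design$tr
  t_eo <- (design$eo_onset - 1) * design$tr
  tau1 <- design$transient_duration / 5   # decay; ~exp(-90/12) at 90 s
  tau2 <- tau1 / 4                         # rise
  bump <- function(s, d1 = tau1, d2 = d1 / 4) {
    h <- ifelse(s >= 0, exp(-s / d1) - exp(-s / d2), 0)
    pk <- max(h)
    if (pk > 0) h / pk else h
  }
  if (type == "null") return(rep(0, n))
  if (type %in% c("positive-transient", "negative-transient")) {
    tmpl <- 0.5 * bump(t_sec - t_ec) + 1.0 * bump(t_sec - t_eo)
    if (type == "negative-transient") tmpl <- -tmpl
    return(tmpl)
  }
  # limbic-biphasic
  ec_part <- ifelse(t_sec < t_eo, -(1 - exp(-(t_sec - t_ec) / 60)), 0)
  s <- t_sec - t_eo
  eo_part <- ifelse(s >= 0,
                    -exp(-s / 30) - 0.6 * bump(s, 10, 2.5) +
                      0.9 * (1 - exp(-s / 45)),
                    0)
  ec_part + eo_part
}

# Block layout: the grid is cut into 4 x 4 x 4 equal blocks. Networks occupy
# row by = 1..3 of blocks (two left, two right each); by = 4, bz = 3 holds
# four signal-free control regions; all remaining blocks are unlabeled
# background.
.atlas_layout <- function(design) {
  g <- design$grid
  bs <- g %/% c(4L, 4L, 4L)
  lab <- array(0L, g)
  rois <- list()
  id <- 0L
  net_short <- c("pos", "neg", "bip")
  place <- function(bx, by, bz, name, hemi, net) {
    id <<- id + 1L
    xr <- ((bx - 1L) * bs[1] + 1L):(bx * bs[1])
    yr <- ((by - 1L) * bs[2] + 1L):(by * bs[2])
    zr <- ((bz - 1L) * bs[3] + 1L):(bz * bs[3])
    lab[xr, yr, zr] <<- id
    rois[[id]] <<- data.frame(label_id = id, roi_name = name,
                              hemisphere = hemi, network_hint = net)
  }
  for (i in 1:3) {
    nm <- net_short[i]; net <- .network_types[i]
    place(1L, i, 1L, paste0(nm, "_L1"), "L", net)
    place(2L, i, 2L, paste0(nm, "_L2"), "L", net)
    place(3L, i, 1L, paste0(nm, "_R1"), "R", net)
    place(4L, i, 2L, paste0(nm, "_R2"), "R", net)
  }
  for (bx in 1:4)
    place(bx, 4L, 3L, paste0("ctl_", c("L1", "L2", "R1", "R2")[bx]),
          c("L", "L", "R", "R")[bx], "null")
  list(atlas = lab, labels = do.call(rbind, rois))
}

# AR(1) noise, stationary start, via the recursive filter.
.ar1_noise <- function(n, n_series, phi, innov_sd) {
  e <- matrix(rnorm(n * n_series, sd = innov_sd), n, n_series)
  if (phi == 0) return(e)
  x <- stats::filter(e, phi, method = "recursive",
                     init = matrix(rnorm(n_series,
                                         sd = innov_sd / sqrt(1 - phi^2)),
                                   1))
  matrix(as.numeric(x), n, n_series)
}

#' Simulate a multi-subject EC/EO dataset
#'
#' Each voxel time course is
#' \code{offset + subject_amplitude * network_template + AR(1) noise}, with
#' the offset drawn per subject and voxel (N(0, offset_sd)), the subject
#' amplitude \code{amplitude * (1 + N(0, subject_amp_sd))} shared across the
#' subject's voxels, and AR(1) noise independent across subjects and voxels.
#' Ground truth sufficient to score every downstream stage is returned
#' alongside the data.
#'
#' @param design a \code{"synthetic_design"}.
#' @param seed integer; overrides \code{design$seed} when given.
#' @param global_null if TRUE, all network amplitudes are forced to zero
#'   (pure noise everywhere) while the atlas and truth tables are kept.
#' @return An object of class \code{"isc_dataset"}: list with \code{bold}
#'   (n x M x K array over in-mask voxels), \code{mask} (logical 3D array),
#'   \code{atlas} (integer 3D array), \code{vox} (K x 3 voxel grid
#'   coordinates), \code{labels} (label table), \code{truth} (per-voxel
#'   data.frame: voxel, label_id, network), \code{subject_amps},
#'   \code{design}.
#' @export
simulate_dataset <- function(design, seed = NULL, global_null = FALSE) {
  stopifnot(inherits(design, "synthetic_design"))
  if (is.null(seed)) seed <- design$seed
  set.seed(seed)
  n <- design$n_volumes; M <- design$n_subjects
  lay <- .atlas_layout(design)
  K <- prod(design$grid)
  vox <- as.matrix(expand.grid(x = seq_len(design$grid[1]),
                               y = seq_len(design$grid[2]),
                               z = seq_len(design$grid[3])))
  lab_vec <- as.integer(lay$atlas)
  net_of_label <- c("none", lay$labels$network_hint)[lab_vec + 1L]
  templates <- vapply(.network_types, function(ty) {
    tm <- response_template(ty, design)
    s <- sqrt(mean((tm - mean(tm))^2))
    if (s > 0) tm / s else tm       # unit time-course SD per network shape
  }, numeric(n))
  amp <- if (global_null) 0 else design$amplitude
  subject_amps <- amp * (1 + rnorm(M, sd = design$subject_amp_sd))
  bold <- array(0, dim = c(n, M, K))
  tmpl_vox <- matrix(0, n, K)
  planted <- net_of_label %in% .network_types[1:3]
  if (any(planted))
    tmpl_vox[, planted] <- templates[, net_of_label[planted]]
  for (i in seq_len(M)) {
    noise <- .ar1_noise(n, K, design$ar_coef, design$innovation_sd)
    offs <- rnorm(K, sd = design$offset_sd)
    bold[, i, ] <- noise + rep(offs, each = n) + subject_amps[i] * tmpl_vox
  }
  truth <- data.frame(voxel = seq_len(K), label_id = lab_vec,
                      network = ifelse(planted & !global_null,
                                       net_of_label, "null"))
  structure(list(bold = bold,
                 mask = array(TRUE, design$grid),
                 atlas = lay$atlas, vox = vox,
                 labels = lay$labels, truth = truth,
                 subject_amps = subject_amps,
                 design = design, seed = seed),
            class = "isc_dataset")
}

#' @export
print.isc_dataset <- function(x, ...) {
  d <- x$design
  cat("Synthetic EC/EO dataset:", d$n_volumes, "volumes x",
      d$n_subjects, "subjects x", dim(x$bold)[3], "voxels\n")
  cat("  grid", paste(d$grid, collapse = " x "),
      "| EO onset at volume", d$eo_onset,
      "| AR(1)", d$ar_coef, "| amplitude", d$amplitude, "\n")
  invisible(x)
}

#' Simulate a flat block of global-null voxels
#'
#' Pure-noise voxel time courses with no inter-subject synchronization:
#' per-subject, per-voxel AR(1) noise plus per-subject, per-voxel mean
#' offsets. Used for false-positive calibration of the mapping pipeline,
#' where a flat voxel block (no grid or atlas) is all that is needed.
#'
#' @param n,M,K time points, subjects, voxels.
#' @param ar_coef AR(1) coefficient.
#' @param innovation_sd AR(1) innovation standard deviation.
#' @param offset_sd standard deviation of the mean offsets.
#' @param seed optional RNG seed.
#' @return n x M x K array.
#' @export
simulate_null_voxels <- function(n, M, K, ar_coef = 0.3, innovation_sd = 1,
                                 offset_sd = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- array(0, dim = c(n, M, K))
  for (i in seq_len(M)) {
    X[, i, ] <- .ar1_noise(n, K, ar_coef, innovation_sd) +
      rep(rnorm(K, sd = offset_sd), each = n)
  }
  X
}

#' Simulate a subjects table with cortisol calibrated to a target partial
#' correlation
#'
#' Draws demographics (age, sex, anxiety and stress scale scores) with the
#' cohort moments of the saliva subsample being emulated, then generates
#' pre-scan cortisol as a linear combination of the covariates and the
#' supplied per-subject connectivity summary plus noise, calibrated so that
#' the population partial correlation between pre-cortisol and connectivity
#' given the covariates equals \code{target_partial_r}. Post-scan cortisol is
#' correlated with pre-scan cortisol at \code{post_pre_r}.
#'
#' @param connectivity numeric vector, one connectivity summary per subject
#'   (N >= 8).
#' @param target_partial_r target partial correlation, in (-1, 1).
#' @param post_pre_r correlation between pre- and post-scan cortisol.
#' @param seed optional RNG seed.
#' @return data.frame with subject_id, age, sex, STAI_state, STAI_trait,
#'   SQ_ISMA, pre_cortisol, post_cortisol.
#' @export
simulate_cortisol <- function(connectivity, target_partial_r = 0.5,
                              post_pre_r = 0.417, seed = NULL) {
  N <- length(connectivity)
  if (N < 8L) stop("need at least 8 subjects", call. = FALSE)
  if (abs(target_partial_r) >= 1)
    stop("target partial correlation must lie in (-1, 1)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  age <- rnorm(N, 23.44, 2.52)
  sex <- rbinom(N, 1L, 12 / 25)          # 1 = male
  stai_state <- rnorm(N, 35.28, 11.37)
  stai_trait <- rnorm(N, 41.52, 8.17)
  sq_isma <- rnorm(N, 9.92, 3.79)
  Z <- cbind(age, sex, stai_trait, sq_isma)
  # covariate loadings on cortisol (pg/ml per covariate SD)
  load_sd <- c(age = 200, sex = 500, stai_trait = 150, sq_isma = 150)
  Zsd <- c(2.52, 0.5, 8.17, 3.79)
  lin <- sweep(sweep(Z, 2, colMeans(Z)), 2, Zsd, "/") %*% load_sd
  s_res <- stats::lm.fit(cbind(1, Z), connectivity)$residuals
  sd_s <- sd(s_res)
  r <- target_partial_r
  if (r == 0 || sd_s == 0) {
    b <- 0; sd_eps <- 800
  } else {
    b <- sign(r) * 800 / sd_s
    sd_eps <- 800 * sqrt(1 / r^2 - 1)
  }
  pre <- 3617.39 + drop(lin) + b * s_res + rnorm(N, sd = sd_eps)
  sd_pre <- sd(pre)
  post <- 5273.96 + post_pre_r * (4204.41 / sd_pre) * (pre - mean(pre)) +
    rnorm(N, sd = 4204.41 * sqrt(1 - post_pre_r^2))
  data.frame(subject_id = seq_len(N), age = age, sex = sex,
             STAI_state = stai_state, STAI_trait = stai_trait,
             SQ_ISMA = sq_isma, pre_cortisol = pre, post_cortisol = post)
}
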