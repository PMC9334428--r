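# Pipeline orchestration: validated configuration, staged execution, and
# deterministic, self-describing outputs.

#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Either
#' \code{input_dir} points at an existing dataset (as written by
#' [write_dataset()]) or \code{simulate = TRUE} generates one from
#' \code{design}.
#'
#' @param out_dir output directory.
#' @param input_dir dataset directory, or NULL when simulating.
#' @param simulate generate a synthetic dataset first.
#' @param design a \code{"synthetic_design"} used when simulating.
#' @param subjects_table optional TSV path with subject covariates and
#'   cortisol; when NULL and simulating, a table is generated.
#' @param n_surrogates,alpha,tail_prob surrogate/FDR parameters.
#' @param K_range candidate network counts.
#' @param lag_grid lags for the mixing diagnostic.
#' @param windows named list of volume windows for connectivity (default
#'   full session plus the EC and EO halves).
#' @param covariates covariate names for the cortisol partial correlations.
#' @param seed master seed.
#' @return a validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            simulate = is.null(input_dir),
                            design = synthetic_design(),
                            subjects_table = NULL,
                            n_surrogates = 50L, alpha = 0.05,
                            tail_prob = 0.05,
                            K_range = 2:6,
                            lag_grid = seq(10L, 230L, by = 20L),
                            windows = NULL,
                            covariates = c("age", "sex", "STAI_trait",
                                           "SQ_ISMA"),
                            seed = 1L) {
  if (!simulate) {
    if (is.null(input_dir) || !dir.exists(input_dir))
      stop("config field `input_dir`: directory not found: ",
           if (is.null(input_dir)) "NULL" else input_dir, call. = FALSE)
  }
  if (!is.null(subjects_table) && !file.exists(subjects_table))
    stop("config field `subjects_table`: file not found: ", subjects_table,
         call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("config field `alpha` must lie in (0, 1)", call. = FALSE)
  structure(list(out_dir = out_dir, input_dir = input_dir,
                 simulate = simulate, design = design,
                 subjects_table = subjects_table,
                 n_surrogates = as.integer(n_surrogates), alpha = alpha,
                 tail_prob = tail_prob, K_range = K_range,
                 lag_grid = lag_grid, windows = windows,
                 covariates = covariates, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Scalar fields of the YAML document override the defaults of
#' [pipeline_config()]; design parameters are given under a \code{design}
#' mapping.
#'
#' @param path YAML file.
#' @return a \code{"pipeline_config"}.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  design <- if (!is.null(y$design)) do.call(synthetic_design, y$design)
            else synthetic_design()
  args <- y[setdiff(names(y), "design")]
  args$design <- design
  do.call(pipeline_config, args)
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) simulation, voxelwise agreement maps with the
#' surrogate null and weak FDR, the stationarity screen, ROI extraction with
#' homogeneity splitting and network partitioning, pairwise connectivity
#' with group tests and hemispheric summaries, and cortisol partial
#' correlations. All outputs are TSV/NIfTI/JSON files in \code{out_dir};
#' identical configuration and seed give identical outputs.
#'
#' @param config a \code{"pipeline_config"} (or YAML path).
#' @return invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  if (config$simulate) {
    ds <- simulate_dataset(config$design, seed = config$seed)
    write_dataset(ds, file.path(config$out_dir, "dataset"))
  } else {
    ds <- read_dataset(config$input_dir)
  }
  n <- dim(ds$bold)[1]

  # stage 1: agreement maps
  map <- icc_map(ds$bold, n_surrogates = config$n_surrogates,
                 alpha = config$alpha, tail_prob = config$tail_prob,
                 seed = config$seed + 1L)
  write_stat_maps(map, ds$mask, config$out_dir)

  # stage 2: stationarity screen
  stat_rep <- stationarity_screen(ds$bold, alpha = config$alpha)
  write_stationarity_tsv(stat_rep, file.path(config$out_dir,
                                             "stationarity.tsv"))
  mix <- lagged_corr_profile(ds$bold,
                             config$lag_grid[config$lag_grid < n - 3L])
  utils::write.table(mix, file.path(config$out_dir, "mixing_profile.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 3: ROI series + networks
  roi <- roi_mean_timecourses(ds, map$stats$supra)
  roi <- split_heterogeneous_rois(ds, roi)
  part <- network_partition(roi$group_tc, K_range = config$K_range,
                            seed = config$seed + 2L)
  net_tab <- cbind(roi$meta, network_label = part$labels)
  utils::write.table(net_tab, file.path(config$out_dir, "networks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  gtc <- as.data.frame(roi$group_tc)
  names(gtc) <- roi$meta$roi_name
  utils::write.table(cbind(volume = seq_len(n), gtc),
                     file.path(config$out_dir, "group_timecourses.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  # stage 4: connectivity
  windows <- config$windows
  if (is.null(windows)) {
    eo <- if (!is.null(ds$design)) ds$design$eo_onset else (n %/% 2 + 1L)
    windows <- list(full = seq_len(n), EC = seq_len(eo - 1L), EO = eo:n)
  }
  conn <- do.call(rbind, lapply(names(windows), function(w)
    pairwise_connectivity(roi, windows[[w]], window_name = w)))
  gct <- group_connectivity_test(conn[conn$window == "full", ],
                                 alpha = config$alpha)
  utils::write.table(gct, file.path(config$out_dir, "connectivity.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summ <- hemispheric_summaries(conn[conn$window == "full", ], roi$meta,
                                part$labels)

  # stage 5: cortisol association
  if (!is.null(config$subjects_table)) {
    subjects <- utils::read.delim(config$subjects_table)
  } else {
    M <- dim(ds$bold)[2]
    base <- summ[summ$scope == "inter" & summ$net_a == summ$net_b, ]
    sm <- tapply(base$mean_z_std, base$subject, mean)
    conn_summary <- as.numeric(sm)[order(as.integer(names(sm)))]
    if (length(conn_summary) < M)
      conn_summary <- rep_len(conn_summary, M)
    subjects <- simulate_cortisol(conn_summary, seed = config$seed + 3L)
  }
  cort <- cortisol_association(summ, subjects,
                               covariates = config$covariates)
  utils::write.table(cort, file.path(config$out_dir, "cortisol.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cfg_out <- unclass(config)
  cfg_out$design <- unclass(cfg_out$design)
  jsonlite::write_json(cfg_out, file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(dataset = ds, map = map, stationarity = stat_rep,
                 roi = roi, partition = part, connectivity = conn,
                 group_test = gct, summaries = summ, cortisol = cort))
}
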