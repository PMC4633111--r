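# End-to-end orchestration: from gray-matter volumes (real NIfTI inputs
# or the synthetic generator) through similarity matrices, thresholded
# graphs and metrics, to cohort summaries, reliability and covariate
# analysis, with a manifest that makes the run reproducible.

#' Build a pipeline run configuration
#'
#' Either `synthetic` (arguments for [synthetic_spec()] plus `n_subjects`,
#' `sessions`) or file inputs (`volumes`, optionally `volumes_session2`,
#' `atlas`, `region_table`) must be supplied.
#'
#' @param synthetic Optional list: arguments to [synthetic_spec()] plus
#'   `n_subjects` and `sessions`.
#' @param volumes Character vector of per-subject NIfTI paths (session 1).
#' @param volumes_session2 Optional second-session paths, same order.
#' @param atlas Path to the label image (file inputs only).
#' @param region_table Path to the TSV mapping label id to name.
#' @param covariate Optional numeric per-subject covariate (e.g. age).
#' @param sparsities Sparsity sweep (default 10%..40% step 1%).
#' @param spotlight Highlighted threshold (default 0.23); must be in
#'   `sparsities`.
#' @param n_random Null networks per graph (default 100).
#' @param n_grid KDE grid resolution (default 256).
#' @param gm_threshold Gray-matter threshold for atlas refinement.
#' @param seed Master seed for null-model reproducibility.
#' @param out_dir Output directory (default a tempdir subdirectory).
#' @return A `run_config` list.
#' @export
run_config <- function(synthetic = NULL, volumes = NULL,
                       volumes_session2 = NULL, atlas = NULL,
                       region_table = NULL, covariate = NULL,
                       sparsities = seq(0.10, 0.40, by = 0.01),
                       spotlight = 0.23, n_random = 100L, n_grid = 256L,
                       gm_threshold = 0, seed = 1L, out_dir = NULL) {
  sparsities <- sort(unique(sparsities))
  if (any(sparsities <= 0 | sparsities >= 1))
    stop("sparsities must lie in (0, 1)")
  if (!any(abs(sparsities - spotlight) < 1e-9))
    stop("spotlight threshold must be one of the sparsities")
  if (is.null(synthetic) && is.null(volumes))
    stop("either a synthetic spec or input volumes are required")
  if (is.null(out_dir))
    out_dir <- file.path(tempdir(), paste0("morphnet_run_",
                                           format(Sys.time(), "%Y%m%d%H%M%S")))
  structure(list(synthetic = synthetic, volumes = volumes,
                 volumes_session2 = volumes_session2, atlas = atlas,
                 region_table = region_table, covariate = covariate,
                 sparsities = sparsities, spotlight = spotlight,
                 n_random = as.integer(n_random), n_grid = as.integer(n_grid),
                 gm_threshold = gm_threshold, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

.stage <- function(name, verbose) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
}

.metric_table_for_session <- function(sims, config, verbose = TRUE) {
  rows <- list()
  profiles_spot <- NULL
  for (m in seq_along(sims)) {
    for (S in config$sparsities) {
      adj <- binarize_by_sparsity(sims[[m]], S)
      gm <- withCallingHandlers(
        small_world_metrics(adj, n_random = config$n_random,
                            seed = .derive_seed(config$seed, m,
                                                round(S * 1000))),
        morphnet_disconnected = function(w) invokeRestart("muffleWarning"))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = m, S = S,
        metric = c("Cp", "Lp", "gamma", "lambda", "sigma", "Eg", "Eloc",
                   "meanBet"),
        value = c(gm$Cp, gm$Lp, gm$gamma, gm$lambda, gm$sigma, gm$Eg,
                  gm$Eloc, gm$meanBet), stringsAsFactors = FALSE)
      if (abs(S - config$spotlight) < 1e-9) {
        b <- betweenness_normalized(adj)$b
        profiles_spot <- rbind(profiles_spot, b)
      }
    }
    .stage(sprintf("  subject %d/%d metrics done", m, length(sims)), verbose)
  }
  rownames(profiles_spot) <- names(sims)
  list(table = do.call(rbind, rows), profiles = profiles_spot)
}

#' Run the full morphological-network pipeline
#'
#' Stages: (1) acquire per-subject gray-matter volumes and the refined
#' atlas (from files or the synthetic generator); (2) estimate regional
#' densities and build each subject's KLS similarity matrix; (3) binarize
#' at every sparsity threshold and compute global metrics against Maslov
#' null ensembles; (4) cohort summaries — mean and CV connection maps,
#' hubs, betweenness-profile similarity/uniqueness at the spotlight
#' threshold; (5) if a second session exists, edge-wise and metric-wise
#' ICC reliability; (6) if a covariate is supplied, the correlation sweep
#' with FDR at the spotlight. Results are written as TSV plus a JSON
#' manifest under `config$out_dir`.
#'
#' @param config A `run_config`.
#' @param verbose Log stage progress (default TRUE).
#' @return Invisibly, a list with all in-memory results and `out_dir`.
#' @export
run_full_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  covariate <- config$covariate

  .stage("stage 1: inputs", verbose)
  if (!is.null(config$synthetic)) {
    syn <- config$synthetic
    n_subjects <- syn$n_subjects %||% 21L
    sessions <- syn$sessions %||% 1L
    syn$n_subjects <- NULL; syn$sessions <- NULL
    spec <- do.call(synthetic_spec, syn)
    cohort <- generate_cohort(spec, n_subjects, covariates = covariate,
                              sessions = sessions)
    atlas <- cohort$atlas
    vols1 <- lapply(cohort$volumes, `[[`, 1L)
    vols2 <- if (sessions >= 2L) lapply(cohort$volumes, `[[`, 2L) else NULL
  } else {
    ref <- load_gm_volume(config$volumes[[1L]])
    atlas <- load_atlas(config$atlas, config$region_table, reference = ref)
    vols1 <- lapply(config$volumes, load_gm_volume)
    vols2 <- if (!is.null(config$volumes_session2))
      lapply(config$volumes_session2, load_gm_volume) else NULL
    atlas <- refine_atlas(atlas, ref, gm_threshold = config$gm_threshold)
    n_subjects <- length(vols1)
  }
  subj_ids <- sprintf("sub%03d", seq_len(n_subjects))

  .stage("stage 2: similarity matrices", verbose)
  sim1 <- lapply(seq_along(vols1), function(m)
    subject_similarity_matrix(vols1[[m]], atlas, n_grid = config$n_grid,
                              subject_id = subj_ids[m]))
  names(sim1) <- subj_ids
  sim2 <- NULL
  if (!is.null(vols2)) {
    sim2 <- lapply(seq_along(vols2), function(m)
      subject_similarity_matrix(vols2[[m]], atlas, n_grid = config$n_grid,
                                subject_id = subj_ids[m]))
    names(sim2) <- subj_ids
  }
  for (m in seq_along(sim1))
    write_matrix_tsv(sim1[[m]], file.path(config$out_dir,
                                          paste0("similarity_", subj_ids[m],
                                                 "_ses1.tsv")))

  .stage("stage 3: graph metrics across thresholds", verbose)
  mt1 <- .metric_table_for_session(sim1, config, verbose)
  utils::write.table(mt1$table, file.path(config$out_dir, "metrics_ses1.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  .stage("stage 4: cohort summaries", verbose)
  mean_mat <- cohort_mean_matrix(sim1)
  write_matrix_tsv(mean_mat, file.path(config$out_dir, "mean_matrix.tsv"))
  cv_mat <- NULL
  if (length(sim1) >= 2L) {
    cv_mat <- cohort_cv_matrix(sim1)
    write_matrix_tsv(cv_mat, file.path(config$out_dir, "cv_matrix.tsv"))
  }
  hubs <- identify_hubs(mt1$profiles)
  utils::write.table(
    data.frame(region = names(hubs$mean_b) %||% seq_along(hubs$mean_b),
               mean_b = hubs$mean_b,
               hub = seq_along(hubs$mean_b) %in%
                 match(hubs$hubs, names(hubs$mean_b) %||% seq_along(hubs$mean_b))),
    file.path(config$out_dir, "hubs.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  profile_scores <- if (nrow(mt1$profiles) >= 2L)
    profile_similarity_uniqueness(mt1$profiles) else NULL
  if (!is.null(profile_scores))
    utils::write.table(profile_scores,
                       file.path(config$out_dir, "profile_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  reliability <- NULL
  mt2 <- NULL
  if (!is.null(sim2)) {
    .stage("stage 5: test-retest reliability", verbose)
    mt2 <- .metric_table_for_session(sim2, config, verbose)
    edge_icc <- edge_icc_map(sim1, sim2)
    write_matrix_tsv(edge_icc$icc, file.path(config$out_dir, "edge_icc.tsv"))
    metric_icc <- metric_icc_curve(mt1$table, mt2$table)
    utils::write.table(metric_icc$curve,
                       file.path(config$out_dir, "metric_icc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    reliability <- list(edge = edge_icc, metric = metric_icc)
  }

  covariate_results <- NULL
  if (!is.null(covariate)) {
    .stage("stage 6: covariate analysis", verbose)
    covariate_results <- sweep_covariate_analysis(
      mt1$table, stats::setNames(covariate, seq_len(n_subjects)),
      spotlight = config$spotlight)
    utils::write.table(covariate_results,
                       file.path(config$out_dir, "covariate_analysis.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(package = "morphnet",
                   version = as.character(utils::packageVersion("morphnet")),
                   n_subjects = n_subjects,
                   sessions = if (is.null(sim2)) 1L else 2L,
                   n_regions = length(atlas$region_ids),
                   sparsities = config$sparsities,
                   spotlight = config$spotlight,
                   n_random = config$n_random, seed = config$seed)
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  .stage("done", verbose)
  invisible(list(atlas = atlas, similarity = sim1, similarity_session2 = sim2,
                 metrics = mt1$table, metrics_session2 = mt2$table,
                 profiles = mt1$profiles, mean_matrix = mean_mat,
                 cv_matrix = cv_mat, hubs = hubs,
                 profile_scores = profile_scores, reliability = reliability,
                 covariate = covariate_results, out_dir = config$out_dir))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
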