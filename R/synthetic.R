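# Synthetic gray-matter cohorts: atlas-labeled volumes whose per-region
# voxel intensities are drawn from truncated-at-0 normal distributions,
# with homotopic region pairs sharing a generator, pair-level subject
# random effects, session-to-session noise, an age-linked scale effect,
# and optional spatial smoothing. Everything is deterministic given the
# master seed, so parameter-recovery tests can assert against the
# manifest.

.derive_seed <- function(master, subject = 0L, session = 0L) {
  (((master %% 1e6) * 1000003 + subject * 10007 + session * 97 + 1) %%
     2147483629)
}

#' Specification of a synthetic cohort
#'
#' Regions come in homotopic pairs that share a generating distribution
#' (truncated-at-0 normal), mirroring the high inter-hemispheric
#' similarity of real gray-matter maps; pair location means are spread
#' over a plausible modulated-GM intensity range. Subject random effects
#' act at the pair level (shared by both hemispheres, as a subject's
#' anatomy is), session noise and voxel sampling act per region and
#' session, and the covariate (age) inflates every region's scale,
#' diluting the separation between generators.
#'
#' @param n_regions Number of regions (default 90, paired).
#' @param voxels_per_region Voxels per region (default 500; keep >= 150
#'   so kernel density estimates are stable).
#' @param voxel_size mm per axis (default 2-mm isotropic).
#' @param grid_dim Volume grid; default the smallest cube holding all
#'   region blocks.
#' @param mu Per-region location means; default pairs spread 0.30..2.94
#'   in steps of 4 within-region SDs, so generator families are cleanly
#'   separated relative to sampling noise.
#' @param sigma Per-region scales (recycled; default 0.015).
#' @param subject_loc_sd SD of the pair-level subject effect on location
#'   (between-subject variation; default 0.015).
#' @param subject_scale_sd SD of the pair-level subject effect on scale
#'   (default 0.003, 20% of the default scale; this is what carries
#'   between-subject signal on edges whose generating means are far
#'   apart).
#' @param session_loc_sd SD of the per-region, per-session location
#'   perturbation (within-subject noise; default 0.0015, i.e. 10% of the
#'   between-subject SD).
#' @param age_scale_slope Multiplicative scale inflation per unit of the
#'   covariate after rescaling to [0, 1] from the youngest subject:
#'   effective scale is `sigma * (1 + slope * covariate)` (default 0.45,
#'   i.e. the oldest subject's within-region spread is 45% larger than
#'   the youngest's).
#' @param smooth_fwhm Gaussian smoothing FWHM in mm (default 0 = none).
#' @param seed Master seed (default 42).
#' @return A `synthetic_spec` list; `pair_of` maps region index to its
#'   generator (pair) id.
#' @export
synthetic_spec <- function(n_regions = 90L, voxels_per_region = 500L,
                           voxel_size = c(2, 2, 2), grid_dim = NULL,
                           mu = NULL, sigma = 0.015,
                           subject_loc_sd = 0.015, subject_scale_sd = 0.003,
                           session_loc_sd = 0.0015, age_scale_slope = 0.45,
                           smooth_fwhm = 0, seed = 42L) {
  if (n_regions < 1L) stop("need at least one region")
  n_pairs <- ceiling(n_regions / 2)
  pair_of <- rep(seq_len(n_pairs), each = 2L)[seq_len(n_regions)]
  if (is.null(mu)) {
    mu_pair <- 0.30 + 0.06 * (seq_len(n_pairs) - 1L)
    mu <- mu_pair[pair_of]
  }
  stopifnot(length(mu) == n_regions)
  sigma <- rep_len(sigma, n_regions)
  if (any(sigma <= 0)) stop("all scales must be > 0")
  nvox <- rep_len(as.integer(voxels_per_region), n_regions)
  if (is.null(grid_dim)) {
    side <- ceiling((sum(nvox) / 0.95)^(1 / 3))
    grid_dim <- rep(as.integer(side), 3L)
  }
  if (sum(nvox) > prod(grid_dim))
    stop("region voxel counts (", sum(nvox), ") overflow the grid (",
         prod(grid_dim), ")")
  structure(list(n_regions = as.integer(n_regions), n_voxels = nvox,
                 pair_of = pair_of, mu = mu, sigma = sigma,
                 voxel_size = voxel_size, grid_dim = as.integer(grid_dim),
                 subject_loc_sd = subject_loc_sd,
                 subject_scale_sd = subject_scale_sd,
                 session_loc_sd = session_loc_sd,
                 age_scale_slope = age_scale_slope,
                 smooth_fwhm = smooth_fwhm, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate the atlas for a synthetic spec
#'
#' Labels are laid out as contiguous blocks in linear voxel order, one
#' block per region with exactly the requested voxel count; the remainder
#' of the grid is background (0).
#'
#' @param spec `synthetic_spec`.
#' @return A `morph_atlas`.
#' @export
generate_atlas <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  labels <- integer(prod(spec$grid_dim))
  idx <- 1L
  for (r in seq_len(spec$n_regions)) {
    labels[idx:(idx + spec$n_voxels[r] - 1L)] <- r
    idx <- idx + spec$n_voxels[r]
  }
  morph_atlas(array(labels, dim = spec$grid_dim),
              region_ids = seq_len(spec$n_regions),
              region_names = sprintf("R%02d%s", spec$pair_of,
                                     c("L", "R")[1L + (seq_len(spec$n_regions) - 1L) %% 2L]),
              voxel_size = spec$voxel_size)
}

# Truncated-at-0 normal draws by inverse-CDF sampling.
.rtruncnorm0 <- function(n, mean, sd) {
  lo <- stats::pnorm(0, mean, sd)
  stats::qnorm(stats::runif(n, lo, 1), mean, sd)
}

.smooth_gaussian3d <- function(x, fwhm, voxel_size) {
  sigma_vox <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size
  for (axis in 1:3) {
    s <- sigma_vox[axis]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    w <- stats::dnorm(seq(-r, r), sd = s)
    w <- w / sum(w)
    out <- x * w[r + 1L]
    for (off in seq_len(r)) {
      out <- out + w[r + 1L + off] * .shift_num(x, axis, off) +
        w[r + 1L - off] * .shift_num(x, axis, -off)
    }
    x <- out
  }
  x
}

.shift_num <- function(x, axis, off) {
  d <- dim(x)
  out <- array(0, dim = d)
  n <- d[axis]
  if (abs(off) >= n) return(out)
  idx_src <- lapply(d, seq_len)
  idx_dst <- idx_src
  idx_src[[axis]] <- if (off > 0) 1:(n - off) else (1 - off):n
  idx_dst[[axis]] <- if (off > 0) (1 + off):n else 1:(n + off)
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    x[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Generate one synthetic subject volume
#'
#' Region r voxels are drawn from a truncated-at-0 normal with location
#' `mu_r + u_(m, pair(r)) + w_(m, s, r)` and scale
#' `(sigma_r + v_(m, pair(r))) * (1 + slope * covariate)`, where u, v are
#' the subject's pair-level random effects (identical across sessions)
#' and w is the per-session location perturbation. All draws are seeded by
#' (master seed, subject, session), so volumes are bit-reproducible.
#'
#' @param spec `synthetic_spec`.
#' @param subject Integer subject id (>= 1).
#' @param covariate Covariate value rescaled to [0, 1] (0 = youngest, 1 =
#'   oldest; default 0, i.e. the baseline geometry).
#' @param session Session number (default 1).
#' @param atlas Optional pre-built atlas (saves rebuilding in loops).
#' @return A `morph_volume`.
#' @export
generate_subject <- function(spec, subject, covariate = 0, session = 1L,
                             atlas = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(atlas)) atlas <- generate_atlas(spec)
  n_pairs <- max(spec$pair_of)
  eff <- .with_seed(.derive_seed(spec$seed, subject, 0L), {
    list(u = stats::rnorm(n_pairs, 0, spec$subject_loc_sd),
         v = if (spec$subject_scale_sd > 0)
           stats::rnorm(n_pairs, 0, spec$subject_scale_sd)
         else numeric(n_pairs))
  })
  scale_mult <- 1 + spec$age_scale_slope * covariate
  # with zero session noise, sessions are exact replicas (same draw seed);
  # otherwise each session redraws voxels on top of its location perturbation
  session_key <- if (spec$session_loc_sd > 0) session else 1L
  vol <- .with_seed(.derive_seed(spec$seed, subject, session_key), {
    w <- if (spec$session_loc_sd > 0)
      stats::rnorm(spec$n_regions, 0, spec$session_loc_sd)
    else numeric(spec$n_regions)
    vals <- numeric(prod(spec$grid_dim))
    labs <- as.integer(atlas$labels)
    for (r in seq_len(spec$n_regions)) {
      p <- spec$pair_of[r]
      s_eff <- (spec$sigma[r] + eff$v[p]) * scale_mult
      if (s_eff <= 0) stop("negative effective scale for region ", r)
      m_eff <- spec$mu[r] + eff$u[p] + w[r]
      here <- which(labs == r)
      vals[here] <- .rtruncnorm0(length(here), m_eff, s_eff)
    }
    array(vals, dim = spec$grid_dim)
  })
  if (spec$smooth_fwhm > 0)
    vol <- .smooth_gaussian3d(vol, spec$smooth_fwhm, spec$voxel_size)
  structure(list(values = vol, voxel_size = spec$voxel_size,
                 dim = spec$grid_dim,
                 path = sprintf("synthetic:sub%03d_ses%d", subject, session)),
            class = "morph_volume")
}

#' Generate a synthetic cohort
#'
#' Builds the atlas and one volume per subject and session. When
#' `out_dir` is given, volumes and atlas are written as NIfTI (gzipped)
#' together with a manifest (subject, session, covariate, seed, file) and
#' the true generating parameters (region, pair, mu, sigma), enabling
#' parameter-recovery tests; otherwise everything is returned in memory.
#'
#' @param spec `synthetic_spec`.
#' @param n_subjects Number of subjects (>= 2).
#' @param covariates Numeric per-subject covariate (e.g. age); rescaled
#'   internally to [0, 1] (min-max) before entering the scale model, so
#'   the youngest subject carries the baseline geometry and inflation
#'   grows monotonically with the covariate. Default all zero.
#' @param sessions Number of sessions (default 1).
#' @param out_dir Optional output directory.
#' @return List with `atlas`, `volumes` (volumes[[subject]][[session]]),
#'   `manifest`, `params`, `covariates`, `spec`.
#' @export
generate_cohort <- function(spec, n_subjects, covariates = NULL,
                            sessions = 1L, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (n_subjects < 2L) stop("need at least 2 subjects")
  if (is.null(covariates)) covariates <- rep(0, n_subjects)
  stopifnot(length(covariates) == n_subjects)
  z <- if (stats::sd(covariates) > 0)
    (covariates - min(covariates)) / diff(range(covariates))
  else rep(0, n_subjects)
  atlas <- generate_atlas(spec)
  volumes <- vector("list", n_subjects)
  rows <- list()
  for (m in seq_len(n_subjects)) {
    volumes[[m]] <- vector("list", sessions)
    for (s in seq_len(sessions)) {
      volumes[[m]][[s]] <- generate_subject(spec, m, covariate = z[m],
                                            session = s, atlas = atlas)
      rows[[length(rows) + 1L]] <-
        data.frame(subject = m, session = s, covariate = covariates[m],
                   covariate_01 = z[m],
                   seed = .derive_seed(spec$seed, m, s),
                   file = sprintf("sub%03d_ses%d.nii.gz", m, s))
    }
  }
  manifest <- do.call(rbind, rows)
  params <- data.frame(region = seq_len(spec$n_regions),
                       name = atlas$region_names,
                       pair = spec$pair_of, mu = spec$mu, sigma = spec$sigma,
                       n_voxels = spec$n_voxels)
  out <- list(atlas = atlas, volumes = volumes, manifest = manifest,
              params = params, covariates = covariates, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_nifti(array(as.double(atlas$labels), dim = spec$grid_dim),
                file.path(out_dir, "atlas.nii.gz"), pixdim = spec$voxel_size)
    utils::write.table(
      data.frame(id = atlas$region_ids, name = atlas$region_names),
      file.path(out_dir, "regions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    for (m in seq_len(n_subjects)) for (s in seq_len(sessions))
      write_nifti(volumes[[m]][[s]]$values,
                  file.path(out_dir, sprintf("sub%03d_ses%d.nii.gz", m, s)),
                  pixdim = spec$voxel_size)
    utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(params, file.path(out_dir, "params.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' True same-generator region pairs of a spec
#'
#' Returns the (i, j) region index pairs that share a generating
#' distribution — the ground-truth strongest connections a recovery test
#' should find at the top of the KLS ranking.
#'
#' @param spec `synthetic_spec`.
#' @return Two-column integer matrix.
#' @export
same_generator_pairs <- function(spec) {
  out <- NULL
  for (p in unique(spec$pair_of)) {
    members <- which(spec$pair_of == p)
    if (length(members) == 2L) out <- rbind(out, members)
  }
  dimnames(out) <- NULL
  out
}
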