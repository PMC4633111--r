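# Edge definition: symmetric Kullback-Leibler divergence between regional
# densities, mapped to a similarity in [0, 1] by KLS = exp(-KL). A
# subject's network is the R x R matrix of KLS values over all region
# pairs; cohort-level mean and coefficient-of-variation maps summarize
# consistency across subjects.

#' Symmetric Kullback-Leibler divergence between two densities
#'
#' Computes the symmetrized divergence
#' `KL(p, q) = integral p log(p/q) + q log(q/p) dx`
#' by trapezoid quadrature over the common grid. Both densities must have
#' been evaluated on the same grid; both are floored away from zero at
#' construction, so the integrand is finite everywhere.
#'
#' @param p,q `density_estimate` objects on identical grids.
#' @return Nonnegative divergence (nats).
#' @export
symmetric_kl <- function(p, q) {
  stopifnot(inherits(p, "density_estimate"), inherits(q, "density_estimate"))
  if (length(p$grid) != length(q$grid) ||
      any(abs(p$grid - q$grid) > 1e-9 * max(1, abs(p$grid))))
    stop("densities must be evaluated on the same grid")
  integrand <- p$density * log(p$density / q$density) +
    q$density * log(q$density / p$density)
  kl <- .trapz(p$grid, integrand)
  if (kl < -1e-9) stop("negative KL divergence (", kl, "): numeric pathology")
  max(kl, 0)
}

#' Kullback-Leibler similarity (KLS)
#'
#' `KLS(p, q) = exp(-KL(p, q))`, a similarity in [0, 1] that equals 1 for
#' two identical distributions and decays toward 0 as the distributions
#' separate.
#'
#' @inheritParams symmetric_kl
#' @export
kls <- function(p, q) {
  exp(-symmetric_kl(p, q))
}

#' KLS between two raw samples
#'
#' Convenience wrapper: builds the pair's common grid from the pooled
#' samples, estimates both densities by Gaussian KDE with Scott's-rule
#' bandwidths, and returns their KLS.
#'
#' @param x,y Numeric vectors of observations.
#' @param n_grid Grid resolution (default 256).
#' @export
kls_from_samples <- function(x, y, n_grid = 256L) {
  grid <- density_grid(list(x, y), n_grid = n_grid)
  kls(estimate_pdf(x, grid), estimate_pdf(y, grid))
}

#' Similarity matrix from regional samples
#'
#' For each unordered pair of regions the two densities are estimated on a
#' common grid built from the pooled pair samples, and the KLS fills both
#' symmetric entries. The diagonal (self-connection) is stored as `NA`: it
#' is undefined and must never enter thresholding.
#'
#' @param samples List of `region_sample` objects (or plain numeric
#'   vectors), one per region.
#' @param region_ids Optional region identifiers; default from samples.
#' @param n_grid Grid resolution per pair.
#' @param subject_id Optional label stored on the result.
#' @param engine `"cpp"` (default) uses the compiled pairwise kernel;
#'   `"r"` runs the pure-R reference path ([estimate_pdf()] + [kls()]).
#'   Both produce the same values to numerical precision; the R path
#'   exists so the compiled one can be verified against it.
#' @return A `similarity_matrix`: R x R numeric matrix with `NA` diagonal,
#'   `region_ids` attribute, dimnames from region names.
#' @export
similarity_matrix_from_samples <- function(samples, region_ids = NULL,
                                           n_grid = 256L, subject_id = NULL,
                                           engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  vals <- lapply(samples, function(s)
    if (inherits(s, "region_sample")) s$values else as.numeric(s))
  R <- length(vals)
  if (is.null(region_ids)) {
    region_ids <- vapply(seq_len(R), function(k) {
      s <- samples[[k]]
      if (inherits(s, "region_sample")) s$region_id else k
    }, numeric(1))
  }
  rnames <- names(samples)
  if (is.null(rnames)) rnames <- paste0("R", region_ids)
  # precompute per-region bandwidth and range once
  h <- vapply(seq_len(R), function(k) {
    tryCatch(scott_bandwidth(vals[[k]]),
             error = function(e) stop("region ", rnames[k], ": ",
                                      conditionMessage(e)))
  }, numeric(1))
  if (engine == "cpp") {
    m <- .kls_matrix_cpp(vals, h, as.integer(n_grid), 1e-12)
    dimnames(m) <- list(rnames, rnames)
  } else {
    lo <- vapply(vals, min, numeric(1))
    hi <- vapply(vals, max, numeric(1))
    m <- matrix(NA_real_, R, R, dimnames = list(rnames, rnames))
    for (i in seq_len(R - 1L)) {
      for (j in (i + 1L):R) {
        hm <- max(h[i], h[j])
        grid <- seq(min(lo[i], lo[j]) - 3 * hm, max(hi[i], hi[j]) + 3 * hm,
                    length.out = n_grid)
        p <- estimate_pdf(vals[[i]], grid, bandwidth = h[i])
        q <- estimate_pdf(vals[[j]], grid, bandwidth = h[j])
        m[i, j] <- m[j, i] <- kls(p, q)
      }
    }
  }
  structure(m, region_ids = region_ids, subject_id = subject_id,
            class = c("similarity_matrix", "matrix"))
}

#' Subject similarity matrix from a volume and atlas
#'
#' Runs sample extraction and pairwise KLS for one subject: the standard
#' route from a preprocessed gray-matter map plus refined atlas to the
#' R x R morphological connection matrix.
#'
#' @param volume `morph_volume`.
#' @param atlas Refined `morph_atlas`.
#' @param n_grid Grid resolution per pair.
#' @param subject_id Optional label.
#' @export
subject_similarity_matrix <- function(volume, atlas, n_grid = 256L,
                                      subject_id = NULL) {
  samples <- extract_region_samples(volume, atlas)
  similarity_matrix_from_samples(samples, region_ids = atlas$region_ids,
                                 n_grid = n_grid, subject_id = subject_id)
}

.check_same_regions <- function(matrices) {
  if (length(matrices) < 1L) stop("need at least one matrix")
  ref <- rownames(matrices[[1L]])
  for (m in matrices) {
    if (!identical(rownames(m), ref))
      stop("region order mismatch across subjects")
  }
  invisible(ref)
}

#' Cohort mean connection matrix
#'
#' Element-wise mean of the subjects' similarity matrices; the diagonal
#' stays excluded (`NA`).
#'
#' @param matrices List of `similarity_matrix` objects, same region order.
#' @export
cohort_mean_matrix <- function(matrices) {
  .check_same_regions(matrices)
  out <- Reduce(`+`, lapply(matrices, unclass)) / length(matrices)
  attributes(out) <- attributes(matrices[[1L]])
  attr(out, "subject_id") <- NULL
  out
}

#' Cohort coefficient-of-variation matrix
#'
#' Element-wise sample standard deviation (n-1 denominator) divided by the
#' element-wise mean, across subjects. Edges with zero mean are returned
#' as `NaN` (undefined) rather than raising an error.
#'
#' @param matrices List of at least 2 `similarity_matrix` objects.
#' @export
cohort_cv_matrix <- function(matrices) {
  if (length(matrices) < 2L) stop("CV needs at least 2 subjects")
  .check_same_regions(matrices)
  arr <- simplify2array(lapply(matrices, unclass))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  out <- sdv / mu
  out[mu == 0] <- NaN
  attributes(out)$dimnames <- dimnames(matrices[[1L]])
  attr(out, "region_ids") <- attr(matrices[[1L]], "region_ids")
  class(out) <- c("similarity_matrix", "matrix")
  out
}

#' Write / read a connection matrix as TSV
#'
#' Tab-separated with region names as header row and first column; `NA`
#' diagonal round-trips.
#'
#' @param m Matrix with dimnames.
#' @param path Output path.
#' @export
write_matrix_tsv <- function(m, path) {
  utils::write.table(as.data.frame(unclass(m)), path, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, row.names = 1L, check.names = FALSE)
  m <- as.matrix(df)
  structure(m, class = c("similarity_matrix", "matrix"))
}
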