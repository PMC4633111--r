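# Volume and atlas input: loading gray-matter maps, atlas refinement
# against gray matter, and extraction of regional voxel samples.

#' Load a gray-matter volume
#'
#' Reads a VBM-style modulated gray-matter map (NIfTI) and validates it:
#' the image must be 3-D with all-finite, non-negative voxel values. No
#' reorientation or resampling is performed; companion images must share
#' the voxel grid exactly.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A `morph_volume` object: list with `values` (3-D array),
#'   `voxel_size` (mm per axis) and `dim`.
#' @export
load_gm_volume <- function(path) {
  img <- read_nifti(path)
  dims <- img$dim
  if (length(dims) == 4L && dims[4L] == 1L) {
    img$data <- array(img$data, dim = dims[1:3])
    dims <- dims[1:3]
  }
  if (length(dims) != 3L)
    stop("expected 3-D volume, got ", length(dims), "-D image: ", path)
  n_bad <- sum(!is.finite(img$data))
  if (n_bad > 0L)
    stop("volume contains ", n_bad, " non-finite voxel(s): ", path)
  if (any(img$data < 0))
    stop("volume contains ", sum(img$data < 0), " negative voxel(s): ", path)
  structure(list(values = img$data, voxel_size = img$pixdim[1:3],
                 dim = dims, path = path),
            class = "morph_volume")
}

#' Load an atlas parcellation
#'
#' Reads an integer-labeled parcellation (0 = background) and a region
#' table mapping labels to names. Every nonzero label in the image must
#' appear in the table; if a reference volume is supplied its grid must
#' match exactly.
#'
#' @param path Path to the label image (NIfTI).
#' @param region_table Either a data.frame with columns `id`, `name`
#'   (optionally `hemisphere`) or a path to a tab-separated file with those
#'   columns.
#' @param reference Optional `morph_volume` whose grid the atlas must match.
#' @return A `morph_atlas` object: `labels` (3-D integer array),
#'   `region_ids` (sorted ascending), `region_names`, `voxel_size`.
#' @export
load_atlas <- function(path, region_table, reference = NULL) {
  img <- read_nifti(path)
  if (length(img$dim) != 3L)
    stop("expected 3-D atlas, got ", length(img$dim), "-D image: ", path)
  labs <- img$data
  if (any(abs(labs - round(labs)) > 1e-6))
    stop("atlas contains non-integer labels: ", path)
  labs <- array(as.integer(round(labs)), dim = img$dim)
  if (is.character(region_table))
    region_table <- utils::read.delim(region_table, stringsAsFactors = FALSE)
  if (!all(c("id", "name") %in% names(region_table)))
    stop("region table must have columns 'id' and 'name'")
  present <- sort(unique(labs[labs != 0L]))
  unknown <- setdiff(present, region_table$id)
  if (length(unknown) > 0L)
    stop("atlas labels absent from region table: ",
         paste(unknown, collapse = ", "))
  if (!is.null(reference) && !all(dim(labs) == reference$dim))
    stop("grid mismatch: atlas ", paste(dim(labs), collapse = "x"),
         " vs volume ", paste(reference$dim, collapse = "x"))
  ord <- order(region_table$id)
  region_table <- region_table[ord, , drop = FALSE]
  keep <- region_table$id %in% present
  empty <- region_table$id[!keep]
  if (length(empty) > 0L)
    message("regions with no voxels in atlas image: ",
            paste(empty, collapse = ", "))
  structure(list(labels = labs,
                 region_ids = as.integer(region_table$id[keep]),
                 region_names = as.character(region_table$name[keep]),
                 voxel_size = img$pixdim[1:3], dim = dim(labs)),
            class = "morph_atlas")
}

#' Construct an atlas object in memory
#'
#' @param labels 3-D integer array (0 = background).
#' @param region_ids Integer region identifiers; defaults to the sorted
#'   nonzero labels present.
#' @param region_names Text names, parallel to `region_ids`.
#' @param voxel_size mm per axis.
#' @export
morph_atlas <- function(labels, region_ids = NULL, region_names = NULL,
                        voxel_size = c(2, 2, 2)) {
  stopifnot(length(dim(labels)) == 3L)
  storage.mode(labels) <- "integer"
  if (is.null(region_ids))
    region_ids <- sort(unique(labels[labels != 0L]))
  if (is.null(region_names)) region_names <- paste0("R", region_ids)
  structure(list(labels = labels, region_ids = as.integer(region_ids),
                 region_names = as.character(region_names),
                 voxel_size = voxel_size, dim = dim(labels)),
            class = "morph_atlas")
}

# Chebyshev (cubic) binary dilation of a logical 3-D mask by r voxels per
# axis, done separably with shifted copies.
.dilate_mask <- function(mask, r) {
  for (axis in 1:3) {
    if (r[axis] == 0L) next
    out <- mask
    for (off in seq_len(r[axis])) {
      out <- out |
        .shift_along(mask, axis, off) |
        .shift_along(mask, axis, -off)
    }
    mask <- out
  }
  mask
}

.shift_along <- function(mask, axis, off) {
  d <- dim(mask)
  out <- array(FALSE, dim = d)
  n <- d[axis]
  if (abs(off) >= n) return(out)
  src <- if (off > 0) 1:(n - off) else (1 - off):n
  dst <- if (off > 0) (1 + off):n else 1:(n + off)
  idx_src <- vector("list", 3)
  idx_dst <- vector("list", 3)
  for (a in 1:3) {
    idx_src[[a]] <- seq_len(d[a]); idx_dst[[a]] <- seq_len(d[a])
  }
  idx_src[[axis]] <- src; idx_dst[[axis]] <- dst
  out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
    mask[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
  out
}

#' Refine an atlas against a gray-matter map
#'
#' A labeled voxel is retained iff at least one voxel with
#' `gm > gm_threshold` lies within its closed cubic (Chebyshev)
#' neighborhood of radius `neighborhood_mm`, converted to voxel offsets as
#' `floor(neighborhood_mm / voxel_size)` per axis (the classical 2-mm
#' cubic neighborhood on a 2-mm grid is the 3x3x3 cube including the voxel
#' itself). Voxels failing the test — typically white-matter voxels of a
#' raw anatomical mask — are removed.
#'
#' @param atlas `morph_atlas`.
#' @param gm_volume `morph_volume` on the same grid.
#' @param gm_threshold Gray-matter threshold; the default 0 treats any
#'   strictly positive modulated value as gray matter.
#' @param neighborhood_mm Neighborhood radius in mm (default 2).
#' @return The refined `morph_atlas`, with attribute `removed` giving the
#'   per-region removed-voxel counts. Errors if refinement empties a region.
#' @export
refine_atlas <- function(atlas, gm_volume, gm_threshold = 0,
                         neighborhood_mm = 2) {
  stopifnot(inherits(atlas, "morph_atlas"), inherits(gm_volume, "morph_volume"))
  if (!all(atlas$dim == gm_volume$dim))
    stop("grid mismatch: atlas ", paste(atlas$dim, collapse = "x"),
         " vs volume ", paste(gm_volume$dim, collapse = "x"))
  r <- as.integer(floor(neighborhood_mm / atlas$voxel_size))
  gm_mask <- gm_volume$values > gm_threshold
  reach <- .dilate_mask(gm_mask, r)
  labels <- atlas$labels
  drop <- labels != 0L & !reach
  removed <- integer(length(atlas$region_ids))
  names(removed) <- atlas$region_ids
  if (any(drop)) {
    tab <- table(labels[drop])
    removed[names(tab)] <- as.integer(tab)
    labels[drop] <- 0L
  }
  left <- table(factor(labels[labels != 0L], levels = atlas$region_ids))
  emptied <- atlas$region_ids[left == 0L]
  if (length(emptied) > 0L)
    stop("refinement emptied region(s): ",
         paste(atlas$region_names[match(emptied, atlas$region_ids)],
               collapse = ", "))
  out <- atlas
  out$labels <- labels
  attr(out, "removed") <- removed
  out
}

#' Extract per-region voxel samples
#'
#' Pulls the gray-matter intensities of all voxels within each atlas
#' region, in `region_ids` order. Regions with 120 or fewer voxels draw a
#' warning (density estimates from small samples are unstable; reliable
#' estimation needs over 120 observations per region); regions with fewer
#' than 2 voxels are an error.
#'
#' @param volume `morph_volume`.
#' @param atlas Refined `morph_atlas` on the same grid.
#' @param exclude_zero Drop voxels valued exactly 0 from the sample
#'   (default FALSE: zeros inside a retained region are data).
#' @return Named list (by region name) of `region_sample` objects: list
#'   with `region_id`, `region_name`, `values`, `n_voxels`.
#' @export
extract_region_samples <- function(volume, atlas, exclude_zero = FALSE) {
  stopifnot(inherits(atlas, "morph_atlas"), inherits(volume, "morph_volume"))
  if (!all(atlas$dim == volume$dim))
    stop("grid mismatch between volume and atlas")
  out <- vector("list", length(atlas$region_ids))
  names(out) <- atlas$region_names
  small <- character(0)
  for (k in seq_along(atlas$region_ids)) {
    vals <- volume$values[atlas$labels == atlas$region_ids[k]]
    if (exclude_zero) vals <- vals[vals != 0]
    if (length(vals) < 2L)
      stop("region ", atlas$region_names[k], " has ", length(vals),
           " voxel(s); at least 2 required")
    if (length(vals) <= 120L) small <- c(small, atlas$region_names[k])
    out[[k]] <- structure(list(region_id = atlas$region_ids[k],
                               region_name = atlas$region_names[k],
                               values = vals, n_voxels = length(vals)),
                          class = "region_sample")
  }
  if (length(small) > 0L)
    warning("region(s) with <= 120 voxels (density estimates may be ",
            "unreliable below ~120 observations): ",
            paste(small, collapse = ", "))
  out
}
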