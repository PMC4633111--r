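# Volume/atlas I/O, atlas refinement, regional sample extraction.

write_tmp_nifti <- function(data, pixdim = c(2, 2, 2), gz = FALSE,
                            datatype = "float64") {
  path <- tempfile(fileext = if (gz) ".nii.gz" else ".nii")
  morphnet:::write_nifti(data, path, pixdim = pixdim, datatype = datatype)
  path
}

test_that("NIfTI round trip preserves values bit-exactly", {
  set.seed(1)
  arr <- array(stats::runif(1000), dim = c(10, 10, 10))
  for (gz in c(FALSE, TRUE)) {
    p <- write_tmp_nifti(arr, gz = gz)
    v <- load_gm_volume(p)
    expect_identical(v$values, arr)
    expect_equal(v$voxel_size, c(2, 2, 2))
    unlink(p)
  }
})

test_that("NIfTI writer agrees with an independent reader (nibabel)", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  arr <- array(seq_len(60) / 10, dim = c(3, 4, 5))
  p <- write_tmp_nifti(arr)
  out <- system2(py, c("-c", shQuote(paste0(
    "import nibabel, numpy; img = nibabel.load('", p, "'); ",
    "d = numpy.asarray(img.dataobj); ",
    "print(d.shape); print(float(d.sum())); print(float(d[1,2,3]))"
  ))), stdout = TRUE)
  expect_equal(out[1], "(3, 4, 5)")
  expect_equal(as.numeric(out[2]), sum(arr), tolerance = 1e-12)
  expect_equal(as.numeric(out[3]), arr[2, 3, 4], tolerance = 1e-12)
  unlink(p)
})

test_that("load_gm_volume validates dimensionality and finiteness", {
  arr <- array(1, dim = c(4, 4, 4))
  arr[2, 2, 2] <- NaN
  p <- write_tmp_nifti(arr)
  expect_error(load_gm_volume(p), "1 non-finite voxel")
  unlink(p)
  expect_error(load_gm_volume(tempfile(fileext = ".nii")), "not found")
  # 4-D volume: craft by writing raw header with ndim 4
  p4 <- tempfile(fileext = ".nii")
  con <- file(p4, "wb")
  hdr <- raw(348)
  wb <- function(off, values, size) {
    b <- writeBin(values, raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  wb(0, 348L, 4)
  wb(40, as.integer(c(4, 2, 2, 2, 2, 1, 1, 1)), 2)
  wb(70, 64L, 2)
  wb(72, 64L, 2)
  wb(76, c(1, 1, 1, 1, 1, 1, 1, 1), 4)
  wb(108, 352, 4)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))
  writeBin(hdr, con)
  writeBin(raw(4), con)
  writeBin(as.double(1:16), con, size = 8, endian = "little")
  close(con)
  expect_error(load_gm_volume(p4), "expected 3-D volume")
  unlink(p4)
})

test_that("load_atlas validates labels and grids", {
  labs <- array(0L, dim = c(5, 5, 5))
  labs[1:10] <- 1L
  labs[11:20] <- 2L
  p <- write_tmp_nifti(array(as.double(labs), dim = dim(labs)))
  tab <- data.frame(id = c(1, 2), name = c("A", "B"))
  at <- load_atlas(p, tab)
  expect_s3_class(at, "morph_atlas")
  expect_equal(at$region_ids, c(1L, 2L))
  expect_equal(at$region_names, c("A", "B"))
  # unknown label
  labs[21] <- 3L
  p2 <- write_tmp_nifti(array(as.double(labs), dim = dim(labs)))
  expect_error(load_atlas(p2, tab), "absent from region table: 3")
  # grid mismatch against reference volume
  pv <- write_tmp_nifti(array(1, dim = c(4, 4, 4)))
  ref <- load_gm_volume(pv)
  expect_error(load_atlas(p, tab, reference = ref), "grid mismatch")
  unlink(c(p, p2, pv))
})

test_that("refine_atlas removes labeled voxels with no GM in reach", {
  # labeled voxel in a zero-GM zone is removed (3x3x3 cube on a 2-mm grid)
  labs <- array(0L, dim = c(7, 7, 7))
  labs[2, 2, 2] <- 1L   # isolated, GM-free corner zone
  labs[6, 6, 6] <- 1L   # inside GM
  labs[6, 6, 5] <- 1L
  gm <- array(0, dim = c(7, 7, 7))
  gm[5:7, 5:7, 5:7] <- 0.8
  at <- morph_atlas(labs, voxel_size = c(2, 2, 2))
  ref <- refine_atlas(at, structure(list(values = gm, voxel_size = c(2, 2, 2),
                                         dim = dim(gm)),
                                    class = "morph_volume"))
  expect_equal(ref$labels[2, 2, 2], 0L)
  expect_equal(ref$labels[6, 6, 6], 1L)
  expect_equal(attr(ref, "removed")[["1"]], 1L)
})

test_that("refine_atlas is the identity on strictly positive GM and idempotent", {
  set.seed(2)
  labs <- array(sample(0:3, 216, replace = TRUE), dim = c(6, 6, 6))
  gm_pos <- structure(list(values = array(0.5, dim = c(6, 6, 6)),
                           voxel_size = c(2, 2, 2), dim = c(6, 6, 6)),
                      class = "morph_volume")
  at <- morph_atlas(labs, voxel_size = c(2, 2, 2))
  ref <- refine_atlas(at, gm_pos)
  expect_identical(ref$labels, at$labels)
  # idempotence under a partial-GM map
  gm_part <- gm_pos
  gm_part$values[1:3, , ] <- 0
  r1 <- tryCatch(refine_atlas(at, gm_part), error = function(e) NULL)
  if (!is.null(r1)) {
    r2 <- refine_atlas(r1, gm_part)
    expect_identical(r2$labels, r1$labels)
  }
})

test_that("neighborhood radius in mm converts to voxel offsets", {
  # 5x5x5, 1-mm grid: labeled corner voxel, GM two steps away:
  # removed at neighborhood 1 mm, kept at 2 mm
  labs <- array(0L, dim = c(5, 5, 5))
  labs[1, 1, 1] <- 1L
  gm <- array(0, dim = c(5, 5, 5))
  gm[3, 1, 1] <- 1
  vol <- structure(list(values = gm, voxel_size = c(1, 1, 1),
                        dim = dim(gm)), class = "morph_volume")
  at <- morph_atlas(labs, voxel_size = c(1, 1, 1))
  expect_error(refine_atlas(at, vol, neighborhood_mm = 1),
               "emptied region")
  ref2 <- refine_atlas(at, vol, neighborhood_mm = 2)
  expect_equal(ref2$labels[1, 1, 1], 1L)
})

test_that("extract_region_samples masks exactly and partitions voxels", {
  labs <- array(0L, dim = c(4, 4, 4))
  labs[1:4] <- 1L
  labs[5:10] <- 2L
  vals <- array(0, dim = c(4, 4, 4))
  vals[1:4] <- c(0.2, 0.4, 0.6, 0.8)
  vals[5:10] <- seq(1, 2, length.out = 6)
  vol <- structure(list(values = vals, voxel_size = c(2, 2, 2),
                        dim = dim(vals)), class = "morph_volume")
  at <- morph_atlas(labs, voxel_size = c(2, 2, 2))
  samp <- suppressWarnings(extract_region_samples(vol, at))
  expect_length(samp, 2)
  expect_equal(sort(samp[[1]]$values), c(0.2, 0.4, 0.6, 0.8))
  expect_equal(samp[[1]]$n_voxels + samp[[2]]$n_voxels, sum(labs != 0))
  # small-region warning cites the 120-voxel guidance
  expect_warning(extract_region_samples(vol, at), "120")
  # a sub-2-voxel region is an error
  labs2 <- labs
  labs2[labs2 == 2L] <- 0L
  labs2[5] <- 2L
  at2 <- morph_atlas(labs2, voxel_size = c(2, 2, 2))
  expect_error(suppressWarnings(extract_region_samples(vol, at2)),
               "at least 2 required")
})

test_that("regional voxel counts partition the labeled voxels on synthetic data", {
  spec <- tiny_spec(n_regions = 6, voxels_per_region = 150)
  at <- generate_atlas(spec)
  vol <- generate_subject(spec, 1, atlas = at)
  samp <- suppressWarnings(extract_region_samples(vol, at))
  expect_equal(sum(vapply(samp, function(s) s$n_voxels, integer(1))),
               sum(at$labels != 0L))
})
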