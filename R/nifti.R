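# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# Only the subset of the format the pipeline needs is supported: 3-D (or
# trivially squeezable) volumes, little- or big-endian, datatypes uint8,
# int16, int32, float32, float64, with scl_slope/scl_inter honoured.
# Orientation metadata (qform/sform) is carried through verbatim as raw
# bytes: no reorientation or resampling is ever performed.

.nifti_datatypes <- data.frame(
  code   = c(2L, 4L, 8L, 16L, 64L),
  what   = c("integer", "integer", "integer", "double", "double"),
  size   = c(1L, 2L, 4L, 4L, 8L),
  signed = c(FALSE, TRUE, TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

.nifti_connection <- function(path, open) {
  if (grepl("\\.gz$", path)) gzfile(path, open) else file(path, open)
}

#' Read a NIfTI-1 volume
#'
#' Parses a single-file NIfTI-1 image (`.nii`, optionally gzipped) and
#' returns the voxel array together with grid metadata. Endianness is
#' detected from the `sizeof_hdr` field; `scl_slope`/`scl_inter` scaling is
#' applied when present.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A list with `data` (numeric array), `dim`, `pixdim` (voxel size in
#'   mm per axis), `datatype` code and the raw 348-byte header.
#' @keywords internal
read_nifti <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- .nifti_connection(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", n = 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header in ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw, "integer", n = 1L, size = 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw, "integer", n = 1L, size = 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  rd <- function(off, what, n, size) {
    readBin(hdr_raw[(off + 1L):(off + n * size)], what,
            n = n, size = size, endian = endian)
  }
  dim_field <- rd(40L, "integer", 8L, 2L)
  ndim <- dim_field[1L]
  if (ndim < 1L || ndim > 7L) stop("invalid ndim ", ndim, " in ", path)
  dims <- dim_field[2L:(1L + ndim)]
  datatype <- rd(70L, "integer", 1L, 2L)
  pixdim <- rd(76L, "double", 8L, 4L)
  vox_offset <- rd(108L, "double", 1L, 4L)
  scl_slope <- rd(112L, "double", 1L, 4L)
  scl_inter <- rd(116L, "double", 1L, 4L)
  spec <- .nifti_datatypes[.nifti_datatypes$code == datatype, ]
  if (nrow(spec) == 0L)
    stop("unsupported NIfTI datatype code ", datatype, " in ", path)
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", n = as.integer(skip))
  nvox <- prod(dims)
  vals <- readBin(con, spec$what, n = nvox, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) < nvox)
    stop("truncated NIfTI data in ", path, ": expected ", nvox,
         " voxels, got ", length(vals))
  vals <- as.double(vals)
  if (is.finite(scl_slope) && scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  list(data = array(vals, dim = dims), dim = dims,
       pixdim = pixdim[2L:(1L + ndim)], datatype = datatype, header = hdr_raw)
}

#' Write a 3-D array as a NIfTI-1 volume
#'
#' @param data Numeric 3-D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param pixdim Voxel size in mm per axis, length 3.
#' @param datatype Either "float64" (lossless for R doubles) or "float32".
#' @keywords internal
write_nifti <- function(data, path, pixdim = c(2, 2, 2),
                        datatype = c("float64", "float32", "int16")) {
  datatype <- match.arg(datatype)
  if (length(dim(data)) != 3L) stop("write_nifti expects a 3-D array")
  code <- switch(datatype, float64 = 64L, float32 = 16L, int16 = 4L)
  size <- switch(datatype, float64 = 8L, float32 = 4L, int16 = 2L)
  hdr <- raw(348L)
  put <- function(hdr, off, values, what, size) {
    b <- writeBin(values, raw(), size = size, endian = "little")
    hdr[(off + 1L):(off + length(b))] <- b
    hdr
  }
  hdr <- put(hdr, 0L, 348L, "integer", 4L)
  hdr <- put(hdr, 40L, as.integer(c(3L, dim(data), 1L, 1L, 1L, 1L)), "integer", 2L)
  hdr <- put(hdr, 70L, code, "integer", 2L)
  hdr <- put(hdr, 72L, size * 8L, "integer", 2L)
  hdr <- put(hdr, 76L, c(1, pixdim, 1, 1, 1, 1), "double", 4L)
  hdr <- put(hdr, 108L, 352, "double", 4L)     # vox_offset
  hdr <- put(hdr, 112L, 1, "double", 4L)       # scl_slope
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0L))
  con <- .nifti_connection(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4L), con)                       # extension flag
  if (datatype == "int16") {
    writeBin(as.integer(round(data)), con, size = 2L, endian = "little")
  } else {
    writeBin(as.double(data), con, size = size, endian = "little")
  }
  invisible(path)
}
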