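#' Labelled or scalar 3-D volume on a reference grid
#'
#' @param data 3-D array (logical, integer or double).
#' @param grid a [reference_grid()] whose shape matches `dim(data)`.
#' @param label_table optional data.frame with columns `id`, `name` mapping
#'   integer labels to region names (parcellations only).
#' @return object of class `wm_volume`.
#' @export
wm_volume <- function(data, grid, label_table = NULL) {
  if (length(dim(data)) != 3L) stop("data must be a 3-D array")
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("data shape does not match grid")
  if (!is.null(label_table)) {
    if (!all(c("id", "name") %in% names(label_table)))
      stop("label_table needs columns id, name")
    if (anyDuplicated(label_table$id) || anyDuplicated(label_table$name))
      stop("label_table ids and names must be unique")
  }
  structure(list(data = data, grid = grid, label_table = label_table),
            class = "wm_volume")
}

#' @export
print.wm_volume <- function(x, ...) {
  cat("<wm_volume>", paste(dim(x$data), collapse = "x"),
      if (!is.null(x$label_table)) sprintf("(%d labels)", nrow(x$label_table)),
      "\n")
  invisible(x)
}

# ---- NIfTI-1 ----------------------------------------------------------------
# Minimal single-file (.nii / .nii.gz) NIfTI-1 support.  3-D only; affine is
# written as an sform (sform_code = 2) and read from sform, then qform, then
# pixdim as fallback.  Integer data round-trips bit-exactly.

nifti_dtypes <- list(
  "2"   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  "4"   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  "8"   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  "16"  = list(what = "double",  size = 4L, signed = TRUE),   # float32
  "64"  = list(what = "double",  size = 8L, signed = TRUE),   # float64
  "256" = list(what = "integer", size = 1L, signed = TRUE),   # int8
  "512" = list(what = "integer", size = 2L, signed = FALSE)   # uint16
)

open_maybe_gz <- function(path, mode) {
  # gzfile transparently reads plain files too
  gzfile(path, mode)
}

#' Read a 3-D NIfTI-1 volume
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param label_table optional label table to attach (see [wm_volume()]).
#' @return a [wm_volume()].
#' @export
read_volume <- function(path, label_table = NULL) {
  con <- open_maybe_gz(path, "rb")
  on.exit(close(con))
  hdr_raw <- readBin(con, "raw", 348L)
  if (length(hdr_raw) < 348L) stop("truncated NIfTI header: ", path)
  endian <- "little"
  sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
  if (sizeof_hdr != 348L) {
    endian <- "big"
    sizeof_hdr <- readBin(hdr_raw[1:4], "integer", 1L, 4L, endian = endian)
    if (sizeof_hdr != 348L) stop("not a NIfTI-1 file (bad sizeof_hdr): ", path)
  }
  magic <- rawToChar(hdr_raw[345:347])
  if (!magic %in% c("n+1", "ni1")) stop("not a NIfTI-1 file (bad magic): ", path)
  rd_i16 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 2 * n)],
                                     "integer", n, 2L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr_raw[(off + 1):(off + 4 * n)],
                                     "double", n, 4L, endian = endian)
  dims <- rd_i16(40L, 8L)
  ndim <- dims[1]
  extra <- if (ndim > 3L) dims[5:(ndim + 1)] else integer(0)
  if (ndim < 3L || any(extra > 1L))
    stop("only 3-D volumes are supported (file is ", ndim, "-D): ", path)
  shape <- dims[2:4]
  datatype <- rd_i16(70L, 1L)
  dt <- nifti_dtypes[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype ", datatype, ": ", path)
  pixdim <- rd_f32(76L, 8L)
  vox_offset <- rd_f32(108L, 1L)
  scl_slope <- rd_f32(112L, 1L)
  scl_inter <- rd_f32(116L, 1L)
  qform_code <- rd_i16(252L, 1L)
  sform_code <- rd_i16(254L, 1L)
  if (sform_code > 0L) {
    affine <- rbind(rd_f32(280L, 4L), rd_f32(296L, 4L), rd_f32(312L, 4L),
                    c(0, 0, 0, 1))
  } else if (qform_code > 0L) {
    q <- rd_f32(256L, 3L)   # quatern b, c, d
    qo <- rd_f32(268L, 3L)  # offsets
    b <- q[1]; c_ <- q[2]; d <- q[3]
    a2 <- 1 - b * b - c_ * c_ - d * d
    a <- if (a2 > 0) sqrt(a2) else 0
    R <- matrix(c(
      a * a + b * b - c_ * c_ - d * d, 2 * (b * c_ - a * d), 2 * (b * d + a * c_),
      2 * (b * c_ + a * d), a * a + c_ * c_ - b * b - d * d, 2 * (c_ * d - a * b),
      2 * (b * d - a * c_), 2 * (c_ * d + a * b), a * a + d * d - b * b - c_ * c_
    ), 3, 3, byrow = TRUE)
    qfac <- if (pixdim[1] < 0) -1 else 1
    zooms <- pixdim[2:4]
    zooms[3] <- zooms[3] * qfac
    affine <- rbind(cbind(R %*% diag(zooms), qo), c(0, 0, 0, 1))
  } else {
    affine <- diag(c(pixdim[2:4], 1))
  }
  # skip to data
  skip <- vox_offset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n_vox <- prod(shape)
  vals <- readBin(con, dt$what, n_vox, dt$size, signed = dt$signed,
                  endian = endian)
  if (length(vals) < n_vox) stop("truncated NIfTI data: ", path)
  if (is.finite(scl_slope) && scl_slope != 0 &&
      !(scl_slope == 1 && scl_inter == 0)) {
    vals <- vals * scl_slope + scl_inter
  }
  data <- array(vals, dim = shape)
  wm_volume(data, reference_grid(shape, affine), label_table = label_table)
}

#' Write a 3-D volume as NIfTI-1
#'
#' Logical data is written as uint8, integer as int32 and double as float64,
#' so integer volumes round-trip bit-exactly.  The affine goes into the sform.
#'
#' @param volume a [wm_volume()] or a [voi_mask()].
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (inherits(volume, "voi_mask"))
    volume <- wm_volume(array(as.integer(volume$data), dim(volume$data)),
                        volume$grid)
  data <- volume$data
  if (is.logical(data)) {
    datatype <- 2L; bitpix <- 8L; size <- 1L
    vals <- as.integer(data); what <- "integer"
  } else if (is.integer(data)) {
    datatype <- 8L; bitpix <- 32L; size <- 4L
    vals <- as.integer(data); what <- "integer"
  } else {
    datatype <- 64L; bitpix <- 64L; size <- 8L
    vals <- as.double(data); what <- "double"
  }
  shape <- dim(data)
  affine <- volume$grid$affine
  hdr <- raw(348)
  wr <- function(off, x, size_) {
    bytes <- writeBin(x, raw(), size_, endian = "little")
    hdr[(off + 1):(off + length(bytes))] <<- bytes
  }
  wr(0L, 348L, 4L)
  wr(40L, as.integer(c(3L, shape, 1L, 1L, 1L, 1L)), 2L)
  wr(70L, datatype, 2L)
  wr(72L, bitpix, 2L)
  wr(76L, c(1, voxel_sizes(volume$grid), 1, 1, 1, 1), 4L)
  wr(108L, 352, 4L)            # vox_offset
  wr(112L, c(1, 0), 4L)        # scl_slope, scl_inter
  wr(252L, 0L, 2L)             # qform_code
  wr(254L, 2L, 2L)             # sform_code (aligned)
  wr(280L, affine[1, ], 4L)
  wr(296L, affine[2, ], 4L)
  wr(312L, affine[3, ], 4L)
  hdr[345:348] <- c(charToRaw("n+1"), as.raw(0))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(raw(4), con)        # pad to vox_offset 352
  writeBin(vals, con, size, endian = "little")
  invisible(path)
}
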