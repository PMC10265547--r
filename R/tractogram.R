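#' Tractogram container
#'
#' Streamlines are stored as a list of n x 3 numeric matrices of world
#' coordinates in millimetres (RAS+), together with the reference voxel grid
#' of the image they were tracked on.  All selection, density and similarity
#' operations consume this container; on-disk format quirks (TRK's
#' corner-origin voxel-mm convention in particular) are confined to the
#' readers and writers.
#'
#' @param streamlines list of n x 3 matrices, each with at least 2 finite
#'   points.
#' @param grid a [reference_grid()] (may be `NULL` for grid-less TCK data;
#'   most operations then require an explicit grid).
#' @return object of class `wm_tractogram`.
#' @export
tractogram <- function(streamlines, grid = NULL) {
  if (!is.list(streamlines)) stop("streamlines must be a list of matrices")
  streamlines <- lapply(streamlines, function(s) {
    s <- as_points_matrix(s)
    if (nrow(s) < 2L) stop("each streamline needs at least 2 points")
    if (any(!is.finite(s))) stop("streamline coordinates must be finite")
    s
  })
  structure(list(streamlines = streamlines, grid = grid),
            class = "wm_tractogram")
}

#' @export
print.wm_tractogram <- function(x, ...) {
  cat("<wm_tractogram>", length(x$streamlines), "streamlines\n")
  invisible(x)
}

#' Number of streamlines
#' @param x a [tractogram()].
#' @export
n_streamlines <- function(x) length(x$streamlines)

#' Arc lengths of all streamlines
#' @param x a [tractogram()].
#' @return numeric vector of polyline lengths in mm.
#' @export
streamline_lengths <- function(x) {
  vapply(x$streamlines, function(s) {
    sum(sqrt(rowSums((s[-1, , drop = FALSE] - s[-nrow(s), , drop = FALSE])^2)))
  }, numeric(1))
}

subset_tractogram <- function(x, keep) {
  structure(list(streamlines = x$streamlines[keep], grid = x$grid),
            class = "wm_tractogram")
}

#' Read a tractogram (TCK or TRK)
#'
#' Streamlines are returned in world RAS+ mm regardless of the on-disk
#' convention.  For TRK the reference grid comes from the header; TCK does
#' not define one, so wmtract stores it in private `wmt_*` header fields on
#' write and falls back to the `grid` argument otherwise.
#'
#' @param path file ending in `.tck` or `.trk`.
#' @param grid optional [reference_grid()] for TCK files lacking one.
#' @return a [tractogram()].
#' @export
read_tractogram <- function(path, grid = NULL) {
  if (grepl("\\.tck$", path, ignore.case = TRUE)) read_tck(path, grid)
  else if (grepl("\\.trk$", path, ignore.case = TRUE)) read_trk(path)
  else stop("unsupported tractogram extension: ", path)
}

#' Write a tractogram (TCK or TRK)
#'
#' @param x a [tractogram()].
#' @param path output file; format follows the extension unless given.
#' @param format `"tck"` or `"trk"` (default: from extension).
#' @return `path`, invisibly.
#' @export
write_tractogram <- function(x, path, format = NULL) {
  if (is.null(format))
    format <- tolower(sub(".*\\.", "", path))
  switch(format,
         tck = write_tck(x, path),
         trk = write_trk(x, path),
         stop("unsupported tractogram format: ", format))
  invisible(path)
}

# ---- TCK (MRtrix) -----------------------------------------------------------
# Text header terminated by "END\n", then float32 triples; streamlines are
# separated by NaN triples and the stream ends with an Inf triple.

read_tck <- function(path, grid = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header: read a generous chunk, locate END
  head_raw <- readBin(con, "raw", 65536L)
  if (length(head_raw) < 14L ||
      !identical(head_raw[1:13], charToRaw("mrtrix tracks")))
    stop("not a TCK file (bad magic): ", path)
  # locate "\nEND\n" in the raw bytes (binary data follows the header)
  pat <- charToRaw("\nEND\n")
  end_at <- -1L
  limit <- length(head_raw) - 4L
  i <- 1L
  while (i <= limit) {
    if (head_raw[i] == pat[1] &&
        identical(head_raw[i:(i + 4L)], pat)) { end_at <- i; break }
    i <- i + 1L
  }
  if (end_at < 0) stop("TCK header END marker not found: ", path)
  header_txt <- rawToChar(head_raw[seq_len(end_at + 4L)])
  lines <- strsplit(header_txt, "\n", fixed = TRUE)[[1]]
  kv <- list()
  for (ln in lines[-1]) {
    m <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  dtype <- kv[["datatype"]]
  if (is.null(dtype)) dtype <- "Float32LE"
  endian <- if (grepl("BE$", dtype)) "big" else "little"
  size <- if (grepl("^Float64", dtype)) 8L else 4L
  if (!grepl("^Float(32|64)(LE|BE)$", dtype))
    stop("unsupported TCK datatype: ", dtype)
  offs <- kv[["file"]]
  if (is.null(offs)) stop("TCK header lacks file offset: ", path)
  offset <- as.numeric(sub("^\\.\\s+", "", offs))
  if (!is.finite(offset)) stop("bad TCK file offset: ", path)
  seek(con, offset)
  vals <- numeric(0)
  repeat {
    chunk <- readBin(con, "double", 3L * 65536L, size, endian = endian)
    vals <- c(vals, chunk)
    if (length(chunk) < 3L * 65536L) break
  }
  if (length(vals) %% 3L != 0L) stop("truncated TCK data: ", path)
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  streamlines <- list()
  start <- 1L
  n_done <- 0L
  i <- 1L
  while (i <= nrow(m)) {
    if (any(is.nan(m[i, ])) || any(is.infinite(m[i, ]))) {
      if (i > start) {
        n_done <- n_done + 1L
        streamlines[[n_done]] <- m[start:(i - 1L), , drop = FALSE]
      }
      if (any(is.infinite(m[i, ]))) break
      start <- i + 1L
    }
    i <- i + 1L
  }
  if (is.null(grid) && !is.null(kv[["wmt_dim"]]) && !is.null(kv[["wmt_affine"]])) {
    shape <- as.integer(strsplit(kv[["wmt_dim"]], ",")[[1]])
    aff <- matrix(as.numeric(strsplit(kv[["wmt_affine"]], ",")[[1]]),
                  4, 4, byrow = TRUE)
    grid <- reference_grid(shape, aff)
  }
  tractogram(streamlines, grid)
}

write_tck <- function(x, path) {
  lines <- c("mrtrix tracks",
             "datatype: Float32LE",
             sprintf("count: %d", length(x$streamlines)))
  if (!is.null(x$grid)) {
    lines <- c(lines,
               sprintf("wmt_dim: %s", paste(x$grid$shape, collapse = ",")),
               sprintf("wmt_affine: %s",
                       paste(format(t(x$grid$affine), digits = 17,
                                    scientific = TRUE, trim = TRUE),
                             collapse = ",")))
  }
  # the offset appears inside the header; iterate to a fixed point
  offset <- 0L
  repeat {
    full <- c(lines, sprintf("file: . %d", offset), "END")
    hdr <- paste0(paste(full, collapse = "\n"), "\n")
    n <- nchar(hdr, type = "bytes")
    if (n == offset) break
    offset <- n
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(hdr, con, eos = NULL)
  for (s in x$streamlines) {
    writeBin(as.numeric(t(s)), con, 4L, endian = "little")
    writeBin(rep(NaN, 3), con, 4L, endian = "little")
  }
  writeBin(rep(Inf, 3), con, 4L, endian = "little")
  invisible(path)
}

# ---- TRK (TrackVis, version 2) ----------------------------------------------
# 1000-byte header; points stored in corner-origin voxel-mm:
#   world = vox_to_ras %*% (p / voxel_size - 0.5)

trk_axcodes <- function(affine) {
  pos <- c("R", "A", "S"); neg <- c("L", "P", "I")
  R <- affine[1:3, 1:3]
  vapply(1:3, function(j) {
    i <- which.max(abs(R[, j]))
    if (R[i, j] >= 0) pos[i] else neg[i]
  }, character(1))
}

read_trk <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 1000L)
  if (length(hdr) < 1000L) stop("truncated TRK header: ", path)
  if (rawToChar(hdr[1:5]) != "TRACK")
    stop("not a TRK file (bad magic): ", path)
  endian <- "little"
  hdr_size <- readBin(hdr[997:1000], "integer", 1L, 4L, endian = endian)
  if (hdr_size != 1000L) {
    endian <- "big"
    hdr_size <- readBin(hdr[997:1000], "integer", 1L, 4L, endian = endian)
    if (hdr_size != 1000L) stop("bad TRK header size: ", path)
  }
  rd_i16 <- function(off, n) readBin(hdr[(off + 1):(off + 2 * n)], "integer",
                                     n, 2L, endian = endian)
  rd_i32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "integer",
                                     n, 4L, endian = endian)
  rd_f32 <- function(off, n) readBin(hdr[(off + 1):(off + 4 * n)], "double",
                                     n, 4L, endian = endian)
  shape <- rd_i16(6L, 3L)
  voxel_size <- rd_f32(12L, 3L)
  n_scalars <- rd_i16(36L, 1L)
  n_properties <- rd_i16(238L, 1L)
  vox_to_ras <- matrix(rd_f32(440L, 16L), 4, 4, byrow = TRUE)
  version <- rd_i32(992L, 1L)
  if (version >= 2L && vox_to_ras[4, 4] == 0)
    stop("TRK vox_to_ras matrix is unset: ", path)
  if (version < 2L || vox_to_ras[4, 4] == 0)
    vox_to_ras <- diag(c(voxel_size, 1))
  if (abs(det(vox_to_ras[1:3, 1:3])) < .Machine$double.eps * 100)
    stop("non-invertible TRK affine: ", path)
  if (any(voxel_size <= 0)) voxel_size <- sqrt(colSums(vox_to_ras[1:3, 1:3]^2))
  streamlines <- list()
  k <- 0L
  repeat {
    np <- readBin(con, "integer", 1L, 4L, endian = endian)
    if (length(np) == 0L) break
    vals <- readBin(con, "double", np * (3L + n_scalars), 4L, endian = endian)
    if (n_properties > 0L) readBin(con, "double", n_properties, 4L,
                                   endian = endian)
    if (length(vals) < np * (3L + n_scalars)) stop("truncated TRK data: ", path)
    pm <- matrix(vals, ncol = 3L + n_scalars, byrow = TRUE)[, 1:3, drop = FALSE]
    vox <- sweep(pm, 2, voxel_size, "/") - 0.5
    world <- cbind(vox, 1) %*% t(vox_to_ras[1:3, , drop = FALSE])
    k <- k + 1L
    streamlines[[k]] <- world
  }
  tractogram(streamlines, reference_grid(shape, vox_to_ras))
}

write_trk <- function(x, path) {
  if (is.null(x$grid)) stop("TRK output requires a reference grid")
  affine <- x$grid$affine
  voxel_size <- voxel_sizes(x$grid)
  hdr <- raw(1000)
  wr <- function(off, bytes) hdr[(off + 1):(off + length(bytes))] <<- bytes
  wr(0L, c(charToRaw("TRACK"), as.raw(0)))
  wr(6L, writeBin(as.integer(x$grid$shape), raw(), 2L, endian = "little"))
  wr(12L, writeBin(as.numeric(voxel_size), raw(), 4L, endian = "little"))
  wr(440L, writeBin(as.numeric(t(affine)), raw(), 4L, endian = "little"))
  ax <- paste(trk_axcodes(affine), collapse = "")
  wr(948L, c(charToRaw(ax), as.raw(0)))
  wr(988L, writeBin(length(x$streamlines), raw(), 4L, endian = "little"))
  wr(992L, writeBin(2L, raw(), 4L, endian = "little"))
  wr(996L, writeBin(1000L, raw(), 4L, endian = "little"))
  inv <- solve(affine)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  for (s in x$streamlines) {
    vox <- cbind(s, 1) %*% t(inv[1:3, , drop = FALSE])
    pm <- sweep(vox + 0.5, 2, voxel_size, "*")
    writeBin(nrow(s), con, 4L, endian = "little")
    writeBin(as.numeric(t(pm)), con, 4L, endian = "little")
  }
  invisible(path)
}
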