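#' Reference voxel grid
#'
#' A reference grid couples a 3-D array shape with a 4x4 affine mapping
#' 0-based voxel indices to world coordinates in millimetres (RAS+
#' orientation).  All streamline and volume operations in wmtract share this
#' single coordinate contract: computation happens in world mm, and voxel
#' membership uses the voxel-center convention (a world point belongs to
#' index `i` iff its voxel coordinate lies in `[i - 0.5, i + 0.5)` per axis).
#'
#' @param shape integer vector of length 3, all positive.
#' @param affine 4x4 numeric matrix, invertible, mapping voxel indices to
#'   world mm.
#' @return An object of class `wm_grid` with elements `shape` and `affine`.
#' @examples
#' g <- reference_grid(c(10, 10, 10), diag(4))
#' voxel_sizes(g)
#' @export
reference_grid <- function(shape, affine) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("shape must be 3 positive integers")
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    stop("affine must be a finite 4x4 matrix")
  det_a <- det(affine[1:3, 1:3])
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps * 100)
    stop("affine must be invertible")
  structure(list(shape = shape, affine = affine), class = "wm_grid")
}

#' @export
print.wm_grid <- function(x, ...) {
  cat("<wm_grid> shape", paste(x$shape, collapse = "x"),
      " voxel sizes", paste(signif(voxel_sizes(x), 4), collapse = "x"), "mm\n")
  invisible(x)
}

#' Voxel edge lengths of a grid
#'
#' @param grid a [reference_grid()].
#' @return numeric vector of 3 voxel sizes in mm (column norms of the
#'   affine's rotation/zoom block).
#' @export
voxel_sizes <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

grids_equal <- function(a, b, tol = 1e-5) {
  identical(a$shape, b$shape) && all(abs(a$affine - b$affine) < tol)
}

stop_if_grid_mismatch <- function(a, b) {
  if (!grids_equal(a, b)) stop("reference grids do not match")
  invisible(TRUE)
}

as_points_matrix <- function(points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  points <- as.matrix(points)
  if (ncol(points) != 3L) stop("points must be an n x 3 matrix")
  storage.mode(points) <- "double"
  points
}

#' Map world-mm points to 0-based voxel indices
#'
#' Uses the voxel-center convention: a point maps to index `i` iff its
#' continuous voxel coordinate lies in `[i - 0.5, i + 0.5)` on each axis.
#' Out-of-grid points are flagged, never clamped.
#'
#' @param points n x 3 matrix of world coordinates (mm).
#' @param grid a [reference_grid()].
#' @return n x 3 integer matrix of voxel indices with a logical attribute
#'   `in_grid` marking rows that fall inside the grid bounds.
#' @export
world_to_voxel <- function(points, grid) {
  points <- as_points_matrix(points)
  if (nrow(points) == 0L) {
    idx <- matrix(integer(0), 0, 3)
    attr(idx, "in_grid") <- logical(0)
    return(idx)
  }
  inv <- solve(grid$affine)
  v <- cbind(points, 1) %*% t(inv[1:3, , drop = FALSE])
  idx <- floor(v + 0.5)
  in_grid <- idx[, 1] >= 0 & idx[, 1] < grid$shape[1] &
    idx[, 2] >= 0 & idx[, 2] < grid$shape[2] &
    idx[, 3] >= 0 & idx[, 3] < grid$shape[3]
  storage.mode(idx) <- "integer"
  attr(idx, "in_grid") <- as.logical(in_grid)
  idx
}

#' Map 0-based voxel indices to world-mm coordinates of voxel centers
#'
#' @param indices n x 3 matrix of voxel indices.
#' @param grid a [reference_grid()].
#' @return n x 3 numeric matrix of world coordinates.
#' @export
voxel_to_world <- function(indices, grid) {
  indices <- as_points_matrix(indices)
  if (nrow(indices) == 0L) return(matrix(numeric(0), 0, 3))
  cbind(indices, 1) %*% t(grid$affine[1:3, , drop = FALSE])
}

# world coordinates of every voxel center, in array (column-major) order
grid_voxel_centers <- function(grid) {
  s <- grid$shape
  idx <- cbind(
    rep.int(seq_len(s[1]) - 1L, s[2] * s[3]),
    rep.int(rep(seq_len(s[2]) - 1L, each = s[1]), s[3]),
    rep(seq_len(s[3]) - 1L, each = s[1] * s[2])
  )
  voxel_to_world(idx, grid)
}
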