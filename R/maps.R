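#' Streamline-density map (track-density image)
#'
#' Counts, per voxel, the number of streamlines traversing it: each
#' streamline contributes exactly 1 to every distinct voxel it visits,
#' with traversal determined by the same arc-length resampling contract as
#' [streamline_intersects()].  Density is a visit count — not a point count
#' and not length-weighted — which keeps the weighted Dice score scale-free.
#'
#' @param tractogram a [tractogram()].
#' @param grid target [reference_grid()]; defaults to the tractogram's.
#' @param step_mm resampling step (default half the smallest voxel size).
#' @return object of class `wm_density`: integer `counts` array, `grid`,
#'   `n_streamlines`.
#' @export
density_map <- function(tractogram, grid = NULL, step_mm = NULL) {
  if (is.null(grid)) grid <- tractogram$grid
  if (is.null(grid)) stop("density_map needs a reference grid")
  if (is.null(step_mm)) step_mm <- default_step_mm(grid)
  counts <- if (n_streamlines(tractogram) == 0L)
    array(0L, grid$shape)
  else
    density_counts_cpp(tractogram$streamlines, solve(grid$affine),
                       grid$shape, step_mm)
  structure(list(counts = counts, grid = grid,
                 n_streamlines = n_streamlines(tractogram)),
            class = "wm_density")
}

#' @export
print.wm_density <- function(x, ...) {
  cat("<wm_density>", x$n_streamlines, "streamlines,",
      sum(x$counts > 0), "occupied voxels\n")
  invisible(x)
}

#' Binarize a density map
#'
#' @param density a [density_map()].
#' @param min_count threshold, >= 1 (default 1).
#' @return a [voi_mask()], true where `counts >= min_count`.
#' @export
binary_mask <- function(density, min_count = 1L) {
  if (min_count < 1) stop("min_count must be >= 1")
  voi_mask(density$counts >= min_count, density$grid)
}

#' Voxel-wise heat map of summed binary masks
#'
#' Sums binary bundle masks across replicates (subjects or sessions); the
#' resulting integer map has its maximum where all inputs agree (bundle
#' core) and low values around the periphery.
#'
#' @param masks non-empty list of [voi_mask()]s on a shared grid.
#' @return object of class `wm_heatmap`: integer `sums` array, `n_inputs`,
#'   `grid`.
#' @export
heat_map <- function(masks) {
  if (length(masks) == 0L) stop("heat_map needs at least one mask")
  grid <- masks[[1]]$grid
  sums <- array(0L, grid$shape)
  for (m in masks) {
    stop_if_grid_mismatch(grid, m$grid)
    sums <- sums + as.integer(m$data)
  }
  structure(list(sums = array(as.integer(sums), grid$shape),
                 n_inputs = length(masks), grid = grid),
            class = "wm_heatmap")
}
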