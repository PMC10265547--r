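# Voxel-based similarity and reproducibility measures for dissected bundles.

mask_array <- function(x) {
  if (inherits(x, "voi_mask")) x$data
  else if (inherits(x, "wm_density")) x$counts > 0L
  else stop("expected a voi_mask or wm_density")
}

#' Dice similarity coefficient of two binary masks
#'
#' `2|A ∩ B| / (|A| + |B|)`.  When both masks are empty the score is
#' defined as 1 and carries attribute `both_empty = TRUE`.
#'
#' @param mask_a,mask_b [voi_mask()]s on a shared grid.
#' @return numeric in `[0, 1]`.
#' @export
dsc <- function(mask_a, mask_b) {
  stop_if_grid_mismatch(mask_a$grid, mask_b$grid)
  a <- mask_array(mask_a); b <- mask_array(mask_b)
  na <- sum(a); nb <- sum(b)
  if (na + nb == 0L) return(structure(1, both_empty = TRUE))
  2 * sum(a & b) / (na + nb)
}

#' Weighted Dice similarity of two density maps
#'
#' Density counts are first normalized to per-voxel proportions
#' `p_X(v) = counts_X(v) / sum(counts_X)`, so bundles with very different
#' streamline totals compare fairly; the score is the total proportion mass
#' lying on the shared support:
#' `sum over v in supp(A) ∩ supp(B) of (p_A(v) + p_B(v)) / 2`.
#' Equals 1 iff the normalized maps have identical support sets covering all
#' mass, and reduces to plain Dice when both maps are uniform over
#' equal-sized supports.
#'
#' @param density_a,density_b [density_map()]s with positive totals on a
#'   shared grid.
#' @return numeric in `[0, 1]`.
#' @export
wdsc <- function(density_a, density_b) {
  stop_if_grid_mismatch(density_a$grid, density_b$grid)
  ta <- sum(density_a$counts); tb <- sum(density_b$counts)
  if (ta == 0 || tb == 0)
    stop("weighted Dice undefined for an empty density map")
  pa <- density_a$counts / ta
  pb <- density_b$counts / tb
  shared <- density_a$counts > 0L & density_b$counts > 0L
  (sum(pa[shared]) + sum(pb[shared])) / 2
}

#' Pearson correlation of streamline densities
#'
#' Correlates raw voxel counts of the two maps over the union of their
#' supports.
#'
#' @param density_a,density_b [density_map()]s on a shared grid.
#' @return correlation coefficient.
#' @export
density_correlation <- function(density_a, density_b) {
  stop_if_grid_mismatch(density_a$grid, density_b$grid)
  union_sup <- density_a$counts > 0L | density_b$counts > 0L
  if (sum(union_sup) < 3L)
    stop("density correlation needs at least 3 voxels of joint support")
  x <- as.numeric(density_a$counts[union_sup])
  y <- as.numeric(density_b$counts[union_sup])
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("density correlation undefined: zero variance over the support union")
  stats::cor(x, y)
}

#' Volume overlap and overreach
#'
#' Overlap `OL = |C ∩ R| / |R|` is the fraction of the reference
#' recovered; overreach `OR = |C \\ R| / |R|` the spurious volume relative
#' to the reference.
#'
#' @param candidate_mask,reference_mask [voi_mask()]s on a shared grid;
#'   the reference must be non-empty.
#' @return named numeric `c(overlap = , overreach = )`.
#' @export
overlap_overreach <- function(candidate_mask, reference_mask) {
  stop_if_grid_mismatch(candidate_mask$grid, reference_mask$grid)
  cm <- mask_array(candidate_mask); rm_ <- mask_array(reference_mask)
  nr <- sum(rm_)
  if (nr == 0L) stop("reference mask is empty")
  c(overlap = sum(cm & rm_) / nr, overreach = sum(cm & !rm_) / nr)
}

#' Bundle adjacency (mm)
#'
#' Symmetric mean nearest-voxel distance between the non-shared parts of two
#' bundle masks: `0.5 * (mean over A\\B of distance to nearest B voxel +
#' mean over B\\A of distance to nearest A voxel)`, in world mm; a term over
#' an empty difference set contributes 0.  Zero iff the masks are equal.
#'
#' @param mask_a,mask_b non-empty [voi_mask()]s on a shared grid.
#' @return distance in mm, >= 0.
#' @export
bundle_adjacency <- function(mask_a, mask_b) {
  stop_if_grid_mismatch(mask_a$grid, mask_b$grid)
  a <- mask_array(mask_a); b <- mask_array(mask_b)
  if (!any(a) || !any(b)) stop("bundle adjacency needs two non-empty masks")
  grid <- mask_a$grid
  coords <- function(m) {
    idx <- which(m, arr.ind = TRUE) - 1L
    voxel_to_world(idx, grid)
  }
  ca <- coords(a); cb <- coords(b)
  mean_nn <- function(from, to) {
    if (nrow(from) == 0L) return(0)
    # chunked nearest-neighbour search keeps memory bounded
    step <- max(1L, floor(2e6 / nrow(to)))
    mins <- numeric(nrow(from))
    for (s in seq(1L, nrow(from), by = step)) {
      e <- min(s + step - 1L, nrow(from))
      blk <- from[s:e, , drop = FALSE]
      d2 <- outer(rowSums(blk^2), rowSums(to^2), "+") -
        2 * blk %*% t(to)
      mins[s:e] <- sqrt(pmax(apply(d2, 1, min), 0))
    }
    mean(mins)
  }
  only_a <- coords(a & !b); only_b <- coords(b & !a)
  0.5 * (mean_nn(only_a, cb) + mean_nn(only_b, ca))
}

#' Descriptive summary of a score vector
#'
#' @param values numeric vector with at least one finite value.
#' @return list with `median`, `stdev` (sample, n-1), `iqr`
#'   (Q3 - Q1, linear-interpolation quantiles), `min`.
#' @export
summary_stats <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) == 0L) stop("summary_stats needs at least 1 finite value")
  q <- stats::quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  list(median = stats::median(values),
       stdev = if (length(values) > 1L) stats::sd(values) else 0,
       iqr = q[2] - q[1],
       min = min(values))
}

#' Maximum absolute inter-session difference
#'
#' For paired test-retest scores, the largest `|session1 - session2|`
#' across subjects.
#'
#' @param score_pairs n x 2 matrix (or data.frame) of paired scores.
#' @return numeric scalar.
#' @export
max_abs_intersession_diff <- function(score_pairs) {
  score_pairs <- as.matrix(score_pairs)
  if (nrow(score_pairs) == 0L || ncol(score_pairs) != 2L)
    stop("score_pairs must be a non-empty n x 2 matrix")
  max(abs(score_pairs[, 1] - score_pairs[, 2]))
}

#' Per-bundle similarity report between two dissection result sets
#'
#' Computes all six measures (Dice, weighted Dice, density correlation,
#' overlap, overreach, adjacency) per shared bundle name, from the density
#' maps of the selected streamlines.  Measures that are undefined for a
#' pair (empty bundle, zero variance) are reported as `NA`.
#'
#' @param results_a,results_b named lists of `dissection_result`s (see
#'   [dissect_all()]).
#' @param grid reference grid for the density maps.
#' @param step_mm density resampling step.
#' @return data.frame, one row per bundle, long-friendly wide format.
#' @export
similarity_report <- function(results_a, results_b, grid, step_mm = NULL) {
  shared <- intersect(names(results_a), names(results_b))
  rows <- lapply(shared, function(nm) {
    da <- density_map(results_a[[nm]]$selected, grid, step_mm)
    db <- density_map(results_b[[nm]]$selected, grid, step_mm)
    ma <- binary_mask_safe(da); mb <- binary_mask_safe(db)
    safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)
    olor <- tryCatch(overlap_overreach(ma, mb),
                     error = function(e) c(overlap = NA_real_,
                                           overreach = NA_real_))
    data.frame(bundle = nm,
               failed_a = results_a[[nm]]$failed,
               failed_b = results_b[[nm]]$failed,
               dsc = safe(as.numeric(dsc(ma, mb))),
               wdsc = safe(wdsc(da, db)),
               density_r = safe(density_correlation(da, db)),
               overlap = unname(olor["overlap"]),
               overreach = unname(olor["overreach"]),
               adjacency_mm = safe(bundle_adjacency(ma, mb)),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

binary_mask_safe <- function(density) {
  voi_mask(density$counts >= 1L, density$grid)
}
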