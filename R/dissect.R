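# Streamline selection against include/exclude masks, the post-selection
# filters, and the failure rule.  Intersection testing resamples every
# polyline by arc length at a spacing no larger than half the smallest voxel
# dimension by default, which prevents segments from tunneling through
# one-voxel masks at typical (1.25-2.5 mm) voxel sizes.

default_step_mm <- function(grid) min(voxel_sizes(grid)) / 2

#' Does a streamline intersect a mask?
#'
#' The polyline is resampled by arc length at spacing `<= step_mm` with both
#' endpoints always included; the test is true iff any sample falls in a
#' true voxel.
#'
#' @param streamline n x 3 matrix of world-mm points.
#' @param mask a [voi_mask()].
#' @param step_mm sampling step; default half the smallest voxel dimension.
#' @return logical scalar.
#' @export
streamline_intersects <- function(streamline, mask, step_mm = NULL) {
  if (is.null(step_mm)) step_mm <- default_step_mm(mask$grid)
  if (step_mm <= 0) stop("step_mm must be > 0")
  hits_mask_cpp(list(as_points_matrix(streamline)), mask$data,
                mask$grid$shape, solve(mask$grid$affine), step_mm)[1]
}

tractogram_hits <- function(x, mask, step_mm) {
  if (n_streamlines(x) == 0L) return(logical(0))
  hits_mask_cpp(x$streamlines, mask$data, mask$grid$shape,
                solve(mask$grid$affine), step_mm)
}

# at least one of the two terminal points lies inside the mask
terminal_in_mask <- function(x, mask) {
  if (n_streamlines(x) == 0L) return(logical(0))
  ends <- do.call(rbind, lapply(x$streamlines, function(s)
    rbind(s[1, ], s[nrow(s), ])))
  idx <- world_to_voxel(ends, mask$grid)
  ok <- attr(idx, "in_grid")
  inside <- logical(nrow(idx))
  if (any(ok))
    inside[ok] <- mask$data[idx[ok, , drop = FALSE] + 1L]
  inside[c(TRUE, FALSE)] | inside[c(FALSE, TRUE)]
}

#' Failure rule for a dissected bundle
#'
#' A dissection fails if fewer than `min_streamlines` streamlines exist
#' initially, or fewer than `min_streamlines` remain after the first
#' filtering step.
#'
#' @param initial_count streamlines initially in the bundle.
#' @param post_filter_count streamlines after the first filtering step.
#' @param min_streamlines threshold (default 10).
#' @return logical scalar.
#' @examples
#' flag_failure(9, 9, 10)    # TRUE
#' flag_failure(10, 10, 10)  # FALSE
#' @export
flag_failure <- function(initial_count, post_filter_count,
                         min_streamlines = 10L) {
  if (initial_count < 0 || post_filter_count < 0)
    stop("counts must be non-negative")
  initial_count < min_streamlines || post_filter_count < min_streamlines
}

#' Filter streamlines by arc length
#'
#' @param bundle a [tractogram()].
#' @param min_mm,max_mm closed length bounds, `0 <= min < max`.
#' @return filtered [tractogram()].
#' @export
filter_length <- function(bundle, min_mm, max_mm) {
  if (min_mm < 0 || min_mm >= max_mm)
    stop("length bounds must satisfy 0 <= min < max")
  if (n_streamlines(bundle) == 0L) return(bundle)
  len <- streamline_lengths(bundle)
  subset_tractogram(bundle, len >= min_mm & len <= max_mm)
}

#' Remove outlier streamlines by distance to the bundle medoid
#'
#' Each streamline is resampled to `n_points` equidistant points; pairwise
#' symmetric mean-closest-point (MCP) distances are computed (this distance
#' is invariant to streamline orientation, so flipped orderings need no
#' special handling); the medoid is the streamline minimizing the summed
#' distance to all others; streamlines whose distance to the medoid exceeds
#' `mean + z_threshold * sd` of all medoid distances are removed.  Bundles
#' with fewer than 3 streamlines are returned unchanged.
#'
#' @param bundle a [tractogram()].
#' @param z_threshold z-score rejection threshold (> 0).
#' @param n_points resampling resolution (default 32).
#' @return filtered [tractogram()].
#' @export
filter_outliers <- function(bundle, z_threshold, n_points = 32L) {
  subset_tractogram(bundle, outlier_keep(bundle, z_threshold, n_points))
}

outlier_keep <- function(bundle, z_threshold, n_points = 32L) {
  if (z_threshold <= 0) stop("z_threshold must be > 0")
  n <- n_streamlines(bundle)
  if (n < 3L) return(rep(TRUE, n))
  rs <- lapply(bundle$streamlines, resample_fixed_cpp, n_out = n_points)
  dmat <- mcp_matrix_cpp(rs)
  medoid <- which.min(rowSums(dmat))
  d <- dmat[, medoid]
  sdd <- stats::sd(d)
  if (!is.finite(sdd) || sdd == 0) return(rep(TRUE, n))
  d <= mean(d) + z_threshold * sdd
}

#' Smooth streamlines with a centered moving average
#'
#' Each coordinate sequence is smoothed with a centered moving average of
#' odd width `window` (shrunk near the ends); the two endpoints are kept
#' fixed.
#'
#' @param bundle a [tractogram()].
#' @param window odd window size >= 1; `1` is the identity.
#' @return smoothed [tractogram()].
#' @export
smooth_streamlines <- function(bundle, window = 3L) {
  window <- as.integer(window)
  if (is.na(window) || window < 1L || window %% 2L == 0L)
    stop("window must be an odd integer >= 1")
  if (window == 1L) return(bundle)
  half <- window %/% 2L
  sm <- lapply(bundle$streamlines, function(s) {
    n <- nrow(s)
    if (n <= 2L) return(s)
    out <- s
    for (i in 2:(n - 1L)) {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      out[i, ] <- colMeans(s[lo:hi, , drop = FALSE])
    }
    out
  })
  structure(list(streamlines = sm, grid = bundle$grid),
            class = "wm_tractogram")
}

#' Dissect one bundle from a whole-brain tractogram
#'
#' Retains the streamlines that intersect every include mask, no exclude
#' mask and (if endpoint VOIs are declared) terminate in each endpoint mask;
#' then applies the arc-length filter (the "first filtering step" of the
#' failure rule), the medoid-distance outlier filter, and moving-average
#' smoothing.  Stage counts are recorded and the failure rule evaluated on
#' the post-selection and post-length-filter counts.
#'
#' @param tractogram a [tractogram()].
#' @param bundle_def a [bundle_definition()].
#' @param parcellation a [wm_volume()] resolving the definition's labels.
#' @param step_mm intersection sampling step (default half the smallest
#'   voxel dimension).
#' @param smooth_window smoothing window (odd, default 3; 1 disables).
#' @return object of class `dissection_result`: `bundle_name`, `selected`
#'   (a [tractogram()]), `indices` (positions of the retained streamlines in
#'   the input tractogram), `counts` (`initial_candidates`,
#'   `after_selection`, `after_filtering`), `failed`, `failure_reason`.
#' @export
select_bundle <- function(tractogram, bundle_def, parcellation,
                          step_mm = NULL, smooth_window = 3L) {
  grid <- parcellation$grid
  if (is.null(step_mm)) step_mm <- default_step_mm(grid)
  masks <- materialize(bundle_def, parcellation)
  n0 <- n_streamlines(tractogram)
  keep <- rep(TRUE, n0)
  for (m in masks$include) keep <- keep & tractogram_hits(tractogram, m, step_mm)
  for (m in masks$exclude) keep <- keep & !tractogram_hits(tractogram, m, step_mm)
  for (m in masks$endpoint) keep <- keep & terminal_in_mask(tractogram, m)
  idx <- which(keep)
  sel <- subset_tractogram(tractogram, keep)
  n_sel <- n_streamlines(sel)
  if (!is.null(bundle_def$length_bounds_mm)) {
    len <- streamline_lengths(sel)
    ok <- len >= bundle_def$length_bounds_mm[1] &
      len <= bundle_def$length_bounds_mm[2]
    sel <- subset_tractogram(sel, ok)
    idx <- idx[ok]
  }
  n_first_filter <- n_streamlines(sel)
  failed <- flag_failure(n_sel, n_first_filter, bundle_def$min_streamlines)
  if (!is.null(bundle_def$outlier_z)) {
    kept <- outlier_keep(sel, bundle_def$outlier_z)
    sel <- subset_tractogram(sel, kept)
    idx <- idx[kept]
  }
  n_filt <- n_streamlines(sel)
  if (smooth_window > 1L) sel <- smooth_streamlines(sel, smooth_window)
  reason <- if (!failed) NULL
  else if (n_sel < bundle_def$min_streamlines)
    sprintf("only %d streamlines selected (< %d)", n_sel,
            bundle_def$min_streamlines)
  else
    sprintf("only %d streamlines after first filtering step (< %d)",
            n_first_filter, bundle_def$min_streamlines)
  structure(list(bundle_name = bundle_def$name, selected = sel,
                 indices = idx,
                 counts = list(initial_candidates = n0,
                               after_selection = n_sel,
                               after_filtering = n_filt),
                 failed = failed, failure_reason = reason),
            class = "dissection_result")
}

#' @export
print.dissection_result <- function(x, ...) {
  cat(sprintf("<dissection_result> %s: %d -> %d -> %d%s\n", x$bundle_name,
              x$counts$initial_candidates, x$counts$after_selection,
              x$counts$after_filtering,
              if (x$failed) paste0(" FAILED (", x$failure_reason, ")") else ""))
  invisible(x)
}

#' Dissect every bundle of a registry
#'
#' Applies [select_bundle()] per definition.  Per-bundle errors (e.g.
#' unresolvable labels on a parcellation lacking a region) are collected as
#' failed results, not raised, so a run over the full protocol always
#' completes.
#'
#' @inheritParams select_bundle
#' @param registry a [bundle_registry()].
#' @return named list of `dissection_result`s, one per definition.
#' @export
dissect_all <- function(tractogram, registry, parcellation, step_mm = NULL,
                        smooth_window = 3L) {
  res <- lapply(registry$definitions, function(def) {
    tryCatch(
      select_bundle(tractogram, def, parcellation, step_mm = step_mm,
                    smooth_window = smooth_window),
      error = function(e) structure(
        list(bundle_name = def$name,
             selected = structure(list(streamlines = list(),
                                       grid = parcellation$grid),
                                  class = "wm_tractogram"),
             counts = list(initial_candidates = n_streamlines(tractogram),
                           after_selection = 0L, after_filtering = 0L),
             failed = TRUE, failure_reason = conditionMessage(e)),
        class = "dissection_result"))
  })
  names(res) <- names(registry$definitions)
  res
}
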