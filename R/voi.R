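#' Binary volume of interest on a reference grid
#'
#' @param data logical 3-D array.
#' @param grid a [reference_grid()].
#' @param provenance the originating [voi_spec()] (optional).
#' @return object of class `voi_mask`.
#' @export
voi_mask <- function(data, grid, provenance = NULL) {
  if (!is.logical(data)) storage.mode(data) <- "logical"
  if (!identical(as.integer(dim(data)), grid$shape))
    stop("mask shape does not match grid")
  structure(list(data = data, grid = grid, provenance = provenance),
            class = "voi_mask")
}

#' @export
print.voi_mask <- function(x, ...) {
  cat("<voi_mask>", sum(x$data), "of", length(x$data), "voxels\n")
  invisible(x)
}

resolve_label_ids <- function(parcellation, labels, context = NULL) {
  if (is.character(labels)) {
    tab <- parcellation$label_table
    if (is.null(tab))
      stop("symbolic labels need a parcellation with a label table",
           if (!is.null(context)) paste0(" (", context, ")"))
    miss <- setdiff(labels, tab$name)
    if (length(miss))
      stop("unresolvable label name(s) ", paste(miss, collapse = ", "),
           if (!is.null(context)) paste0(" in ", context))
    tab$id[match(labels, tab$name)]
  } else {
    as.integer(labels)
  }
}

#' Mask of a set of parcellation labels
#'
#' True exactly where the parcellation value is one of `label_ids`.  Integer
#' ids absent from the volume contribute nothing and raise a warning;
#' symbolic names that do not resolve against the label table are an error.
#'
#' @param parcellation a [wm_volume()] with integer labels.
#' @param label_ids non-empty integer ids or character region names.
#' @return a [voi_mask()].
#' @export
labels_to_mask <- function(parcellation, label_ids) {
  if (length(label_ids) == 0L) stop("label_ids must be non-empty")
  ids <- resolve_label_ids(parcellation, label_ids)
  present <- unique(as.vector(parcellation$data))
  absent <- setdiff(ids, present)
  if (length(absent))
    warning("label id(s) ", paste(absent, collapse = ", "),
            " absent from parcellation; empty contribution")
  data <- array(parcellation$data %in% ids, dim(parcellation$data))
  voi_mask(data, parcellation$grid,
           provenance = voi_spec("labels", labels = label_ids))
}

#' Axis-aligned world-space box mask
#'
#' True for voxels whose centers fall inside the closed box spanned by two
#' opposite corners (world mm).
#'
#' @param grid a [reference_grid()].
#' @param corners_mm 2 x 3 matrix of opposite corners.
#' @return a [voi_mask()].
#' @export
box_mask <- function(grid, corners_mm) {
  spec <- voi_spec("box", corners_mm = corners_mm)   # validates degeneracy
  corners_mm <- spec$corners_mm
  lo <- pmin(corners_mm[1, ], corners_mm[2, ])
  hi <- pmax(corners_mm[1, ], corners_mm[2, ])
  ctr <- grid_voxel_centers(grid)
  inside <- ctr[, 1] >= lo[1] & ctr[, 1] <= hi[1] &
    ctr[, 2] >= lo[2] & ctr[, 2] <= hi[2] &
    ctr[, 3] >= lo[3] & ctr[, 3] <= hi[3]
  voi_mask(array(inside, grid$shape), grid, provenance = spec)
}

#' Midsagittal slab mask
#'
#' True for voxels whose center's world x-coordinate lies within
#' `thickness_mm / 2` of the grid center's x.  The band is half-open
#' (`[-t/2, t/2)`) so that on even-sized grids a slab exactly one voxel
#' thick resolves toward the lower index.
#'
#' @param grid a [reference_grid()].
#' @param thickness_mm slab thickness, > 0.
#' @return a [voi_mask()].
#' @export
midsagittal_mask <- function(grid, thickness_mm) {
  if (thickness_mm <= 0) stop("thickness_mm must be > 0")
  ctr_vox <- matrix((grid$shape - 1) / 2, 1)
  x_mid <- voxel_to_world(ctr_vox, grid)[1, 1]
  x <- grid_voxel_centers(grid)[, 1]
  inside <- (x - x_mid) >= -thickness_mm / 2 & (x - x_mid) < thickness_mm / 2
  voi_mask(array(inside, grid$shape), grid,
           provenance = voi_spec("midsagittal", thickness_mm = thickness_mm))
}

#' 6-connected binary dilation
#'
#' @param mask a [voi_mask()].
#' @param iterations number of dilation passes, >= 0.
#' @return a [voi_mask()].
#' @export
dilate_mask <- function(mask, iterations) {
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L) stop("iterations must be >= 0")
  d <- mask$data
  s <- dim(d)
  for (it in seq_len(iterations)) {
    out <- d
    out[-1, , ] <- out[-1, , ] | d[-s[1], , ]
    out[-s[1], , ] <- out[-s[1], , ] | d[-1, , ]
    out[, -1, ] <- out[, -1, ] | d[, -s[2], ]
    out[, -s[2], ] <- out[, -s[2], ] | d[, -1, ]
    out[, , -1] <- out[, , -1] | d[, , -s[3]]
    out[, , -s[3]] <- out[, , -s[3]] | d[, , -1]
    d <- out
  }
  voi_mask(d, mask$grid, provenance = mask$provenance)
}

materialize_spec <- function(spec, parcellation, context = NULL) {
  switch(spec$kind,
    labels = {
      ids <- resolve_label_ids(parcellation, spec$labels, context = context)
      labels_to_mask(parcellation, ids)
    },
    box = box_mask(parcellation$grid, spec$corners_mm),
    midsagittal = midsagittal_mask(parcellation$grid, spec$thickness_mm),
    dilated = dilate_mask(materialize_spec(spec$base, parcellation,
                                           context = context),
                          spec$iterations))
}

#' Materialize a bundle definition's VOIs
#'
#' Turns every [voi_spec()] of a [bundle_definition()] into a [voi_mask()]
#' on the parcellation's grid.
#'
#' @param bundle_def a [bundle_definition()].
#' @param parcellation a [wm_volume()] with a label table covering the
#'   definition's symbolic labels.
#' @return list with elements `include`, `exclude`, `endpoint`, each a list
#'   of [voi_mask()]s.
#' @export
materialize <- function(bundle_def, parcellation) {
  mk <- function(specs, what) {
    lapply(seq_along(specs), function(i) {
      tryCatch(
        materialize_spec(specs[[i]], parcellation,
                         context = sprintf("bundle '%s' %s VOI #%d",
                                           bundle_def$name, what, i)),
        error = function(e) stop("bundle '", bundle_def$name, "', ", what,
                                 " VOI #", i, ": ", conditionMessage(e),
                                 call. = FALSE))
    })
  }
  list(include = mk(bundle_def$includes, "include"),
       exclude = mk(bundle_def$excludes, "exclude"),
       endpoint = mk(bundle_def$endpoint_includes, "endpoint"))
}
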