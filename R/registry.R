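#' Volume-of-interest specification
#'
#' A `voi_spec` declares, without reference to any particular grid, how to
#' build one binary volume of interest.  Four kinds exist:
#'
#' * `labels` — union of parcellation labels, given as integer ids or as
#'   symbolic region names resolved against a parcellation's label table;
#' * `box` — axis-aligned world-space box given by two opposite corners (mm);
#' * `midsagittal` — a slab of given thickness (mm) around the grid's
#'   midline x-coordinate (used for commissural bundles);
#' * `dilated` — another `voi_spec` dilated by a number of 6-connected
#'   binary dilation iterations (label-propagation style VOIs).
#'
#' @param kind one of `"labels"`, `"box"`, `"midsagittal"`, `"dilated"`.
#' @param labels integer ids or character names (`kind = "labels"`).
#' @param corners_mm 2 x 3 matrix of opposite box corners (`kind = "box"`).
#' @param thickness_mm slab thickness (`kind = "midsagittal"`).
#' @param base nested `voi_spec` (`kind = "dilated"`).
#' @param iterations dilation count (`kind = "dilated"`).
#' @return object of class `voi_spec`.
#' @export
voi_spec <- function(kind, labels = NULL, corners_mm = NULL,
                     thickness_mm = NULL, base = NULL, iterations = NULL) {
  if (!kind %in% c("labels", "box", "midsagittal", "dilated"))
    stop("unknown VOI kind: ", kind)
  out <- switch(kind,
    labels = {
      if (is.null(labels) || length(labels) == 0L)
        stop("labels VOI needs a non-empty label list")
      if (!is.null(corners_mm) || !is.null(thickness_mm) || !is.null(base))
        stop("labels VOI takes only a label list")
      list(kind = kind, labels = labels)
    },
    box = {
      if (is.null(corners_mm)) stop("box VOI needs corners_mm")
      corners_mm <- as_points_matrix(corners_mm)
      if (nrow(corners_mm) != 2L) stop("corners_mm must be 2 x 3")
      if (any(corners_mm[1, ] == corners_mm[2, ]))
        stop("degenerate box: corners coincide on an axis")
      list(kind = kind, corners_mm = corners_mm)
    },
    midsagittal = {
      if (is.null(thickness_mm) || thickness_mm <= 0)
        stop("midsagittal VOI needs thickness_mm > 0")
      list(kind = kind, thickness_mm = as.numeric(thickness_mm))
    },
    dilated = {
      if (is.null(base) || !inherits(base, "voi_spec"))
        stop("dilated VOI needs a base voi_spec")
      if (is.null(iterations) || iterations < 0)
        stop("dilated VOI needs iterations >= 0")
      list(kind = kind, base = base, iterations = as.integer(iterations))
    })
  structure(out, class = "voi_spec")
}

bundle_groups <- c("association", "commissural", "projection", "cerebellar")
bundle_hemis <- c("left", "right", "midline")

#' Bundle dissection rule
#'
#' A declarative description of how one white-matter bundle is carved out of
#' a whole-brain tractogram: which VOIs every streamline must traverse
#' (`includes`, logical AND), which none may touch (`excludes`, logical OR),
#' optional termination constraints, and the filter parameters applied after
#' selection.
#'
#' @param name unique bundle identifier (e.g. `"AF_L"`).
#' @param group `"association"`, `"commissural"`, `"projection"` or
#'   `"cerebellar"`.
#' @param hemisphere `"left"`, `"right"`, or `"midline"` (commissural only).
#' @param includes non-empty list of [voi_spec()]s; a streamline must
#'   intersect every one.
#' @param excludes list of [voi_spec()]s; intersecting any one rejects the
#'   streamline.
#' @param endpoint_includes list of [voi_spec()]s each of which must contain
#'   a terminal point of the streamline.
#' @param min_streamlines failure threshold; a dissection with fewer
#'   streamlines (initially or after the first filtering step) is flagged as
#'   failed.  Default 10.
#' @param length_bounds_mm optional `c(min, max)` arc-length filter.
#' @param outlier_z optional z-score threshold for the streamline outlier
#'   filter.
#' @return object of class `bundle_definition`.
#' @export
bundle_definition <- function(name, group, hemisphere, includes,
                              excludes = list(), endpoint_includes = list(),
                              min_streamlines = 10L, length_bounds_mm = NULL,
                              outlier_z = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    stop("bundle name must be a non-empty string")
  if (!group %in% bundle_groups)
    stop("bundle '", name, "': unknown group '", group, "'")
  if (!hemisphere %in% bundle_hemis)
    stop("bundle '", name, "': unknown hemisphere '", hemisphere, "'")
  if (hemisphere == "midline" && group != "commissural")
    stop("bundle '", name, "': hemisphere 'midline' is reserved for ",
         "commissural bundles")
  if (!is.list(includes) || length(includes) == 0L)
    stop("bundle '", name, "': includes must be a non-empty list")
  chk <- function(lst, what) {
    for (v in lst) if (!inherits(v, "voi_spec"))
      stop("bundle '", name, "': ", what, " entries must be voi_spec objects")
  }
  chk(includes, "includes"); chk(excludes, "excludes")
  chk(endpoint_includes, "endpoint_includes")
  min_streamlines <- as.integer(min_streamlines)
  if (is.na(min_streamlines) || min_streamlines < 1L)
    stop("bundle '", name, "': min_streamlines must be >= 1")
  if (!is.null(length_bounds_mm)) {
    length_bounds_mm <- as.numeric(length_bounds_mm)
    if (length(length_bounds_mm) != 2L || length_bounds_mm[1] < 0 ||
        length_bounds_mm[1] >= length_bounds_mm[2])
      stop("bundle '", name, "': length_bounds_mm must satisfy 0 <= min < max")
  }
  if (!is.null(outlier_z) && (!is.numeric(outlier_z) || outlier_z <= 0))
    stop("bundle '", name, "': outlier_z must be positive")
  structure(list(name = name, group = group, hemisphere = hemisphere,
                 includes = includes, excludes = excludes,
                 endpoint_includes = endpoint_includes,
                 min_streamlines = min_streamlines,
                 length_bounds_mm = length_bounds_mm,
                 outlier_z = outlier_z),
            class = "bundle_definition")
}

#' Bundle registry
#'
#' An ordered, validated collection of [bundle_definition()]s plus a version
#' tag.  The default registry ([load_registry()] with no argument) holds the
#' full 68-bundle dissection protocol.
#'
#' @param definitions list of [bundle_definition()]s with unique names.
#' @param version free-text version tag.
#' @return object of class `bundle_registry`.
#' @export
bundle_registry <- function(definitions, version = "wmtract-protocol-1") {
  for (d in definitions) if (!inherits(d, "bundle_definition"))
    stop("registry entries must be bundle_definition objects")
  nms <- vapply(definitions, `[[`, character(1), "name")
  dup <- nms[duplicated(nms)]
  if (length(dup)) stop("duplicate bundle names in registry: ",
                        paste(unique(dup), collapse = ", "))
  names(definitions) <- nms
  structure(list(definitions = definitions, version = version),
            class = "bundle_registry")
}

#' @export
print.bundle_registry <- function(x, ...) {
  cat("<bundle_registry>", length(x$definitions), "bundles, version",
      x$version, "\n")
  invisible(x)
}

#' @export
length.bundle_registry <- function(x) length(x$definitions)

#' Group/hemisphere census of a registry
#'
#' Bilateral bundles are counted as families: `AF_L`/`AF_R` is one
#' association family.  Commissural bundles are midline and counted
#' individually.
#'
#' @param registry a [bundle_registry()].
#' @return list with `association_families`, `commissural`,
#'   `projection_families`, `cerebellar_families` and `total`.
#' @export
census <- function(registry) {
  defs <- registry$definitions
  grp <- vapply(defs, `[[`, character(1), "group")
  fam <- function(g) {
    nms <- vapply(defs[grp == g], `[[`, character(1), "name")
    length(unique(sub("_(L|R)$", "", nms)))
  }
  list(association_families = if (any(grp == "association")) fam("association") else 0L,
       commissural = sum(grp == "commissural"),
       projection_families = if (any(grp == "projection")) fam("projection") else 0L,
       cerebellar_families = if (any(grp == "cerebellar")) fam("cerebellar") else 0L,
       total = length(defs))
}

# ---- JSON (de)serialization -------------------------------------------------

voi_spec_to_list <- function(v) {
  switch(v$kind,
         labels = list(kind = "labels", labels = as.list(v$labels)),
         box = list(kind = "box",
                    corners_mm = lapply(1:2, function(i) v$corners_mm[i, ])),
         midsagittal = list(kind = "midsagittal",
                            thickness_mm = v$thickness_mm),
         dilated = list(kind = "dilated", base = voi_spec_to_list(v$base),
                        iterations = v$iterations))
}

voi_spec_from_list <- function(l, where) {
  if (is.null(l$kind)) stop("VOI without kind in ", where)
  switch(as.character(l$kind),
    labels = {
      labels <- unlist(l$labels, use.names = FALSE)
      voi_spec("labels", labels = labels)
    },
    box = voi_spec("box",
                   corners_mm = do.call(rbind, lapply(l$corners_mm, unlist))),
    midsagittal = voi_spec("midsagittal", thickness_mm = l$thickness_mm),
    dilated = voi_spec("dilated", base = voi_spec_from_list(l$base, where),
                       iterations = l$iterations),
    stop("unknown VOI kind '", l$kind, "' in ", where))
}

definition_to_list <- function(d) {
  list(name = d$name, group = d$group, hemisphere = d$hemisphere,
       includes = lapply(d$includes, voi_spec_to_list),
       excludes = lapply(d$excludes, voi_spec_to_list),
       endpoint_includes = lapply(d$endpoint_includes, voi_spec_to_list),
       min_streamlines = d$min_streamlines,
       length_bounds_mm = d$length_bounds_mm,
       outlier_z = d$outlier_z)
}

definition_from_list <- function(l) {
  where <- if (is.null(l$name)) "<unnamed bundle>" else l$name
  if (is.null(l$name)) stop("bundle entry without a name")
  take <- function(x) if (is.null(x)) list() else lapply(x, voi_spec_from_list,
                                                         where = where)
  bundle_definition(
    name = l$name, group = l$group, hemisphere = l$hemisphere,
    includes = take(l$includes), excludes = take(l$excludes),
    endpoint_includes = take(l$endpoint_includes),
    min_streamlines = if (is.null(l$min_streamlines)) 10L else l$min_streamlines,
    length_bounds_mm = if (is.null(l$length_bounds_mm)) NULL
                       else unlist(l$length_bounds_mm),
    outlier_z = l$outlier_z)
}

#' Load a bundle registry
#'
#' With no argument, returns the built-in 68-bundle dissection protocol
#' (see [default_registry()]).  With a path, parses and validates a JSON
#' registry file; schema violations raise errors naming the offending entry.
#'
#' @param path optional path to a registry JSON file.
#' @return a [bundle_registry()].
#' @examples
#' reg <- load_registry()
#' length(reg)          # 68
#' census(reg)
#' @export
load_registry <- function(path = NULL) {
  if (is.null(path)) return(default_registry())
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$bundles)) stop("registry file lacks a 'bundles' array: ", path)
  defs <- lapply(obj$bundles, definition_from_list)
  bundle_registry(defs, version = if (is.null(obj$version)) "unversioned"
                                  else obj$version)
}

#' Write a bundle registry to JSON
#'
#' @param registry a [bundle_registry()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(registry, path) {
  obj <- list(version = registry$version,
              bundles = lapply(unname(registry$definitions),
                               definition_to_list))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
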