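# Synthetic streamline phantoms: a miniature parcellation plus geometric
# bundles with Gaussian radial jitter, standing in for real test-retest
# acquisitions.  Everything is deterministic under a fixed seed.

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

#' Phantom scene specification
#'
#' Declares the stated world of a synthetic scene: the grid, the planted
#' bundles (each a geometric centerline between two named endpoint regions,
#' replicated with Gaussian radial jitter), and free-floating distractor
#' streamlines.
#'
#' @param shape grid shape (3 integers).
#' @param voxel_mm isotropic voxel size in mm.
#' @param bundles list of bundle declarations; each is a list with `name`,
#'   `kind` (`"straight"`, `"arc"`, `"helix"`, `"commissural_u"`),
#'   `n_streamlines`, `jitter_mm`, `group`, `hemisphere`, and `regions` — a
#'   named 2-element list of `list(center_mm =, size_mm =)` endpoint boxes.
#' @param n_distractors number of random distractor streamlines.
#' @param seed base RNG seed for the scene.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40L, 44L, 40L), voxel_mm = 1,
                         bundles = list(), n_distractors = 0L, seed = 1L) {
  shape <- as.integer(shape)
  region_names <- character(0)
  for (b in bundles) {
    stopifnot(!is.null(b$name), !is.null(b$kind), !is.null(b$regions))
    if (length(b$regions) != 2L || is.null(names(b$regions)))
      stop("bundle '", b$name, "' needs exactly 2 named endpoint regions")
    if (b$n_streamlines < 0L) stop("n_streamlines must be >= 0")
    if (b$jitter_mm < 0) stop("jitter_mm must be >= 0")
    region_names <- c(region_names, names(b$regions))
  }
  if (anyDuplicated(region_names))
    stop("endpoint region names must be distinct across bundles")
  affine <- diag(c(rep(voxel_mm, 3), 1))
  affine[1:3, 4] <- -voxel_mm * (shape - 1) / 2   # world origin at grid center
  structure(list(grid = reference_grid(shape, affine), voxel_mm = voxel_mm,
                 bundles = bundles, n_distractors = as.integer(n_distractors),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

phantom_bundle <- function(name, kind, from, to, size_mm = c(6, 6, 6),
                           n_streamlines = 100L, jitter_mm = 1,
                           group = "association", hemisphere = "left",
                           region_names = NULL) {
  if (is.null(region_names)) region_names <- paste0(name, c("_a", "_b"))
  regions <- list(list(center_mm = from, size_mm = size_mm),
                  list(center_mm = to, size_mm = size_mm))
  names(regions) <- region_names
  list(name = name, kind = kind, n_streamlines = as.integer(n_streamlines),
       jitter_mm = jitter_mm, group = group, hemisphere = hemisphere,
       regions = regions)
}

#' Default four-bundle phantom scene
#'
#' The stated world used throughout the test suite: a 40x44x40 grid at 1 mm
#' with four planted bundles of deliberately unequal size — a dense straight
#' pyramidal-tract-like bundle (500 streamlines), a sparse fornix-like arc
#' (25 streamlines, 20x sparser), a commissural arch (200) and an arcuate-like
#' arc (150) — plus 100 distractor streamlines, all with 1 mm Gaussian
#' radial jitter.
#'
#' @param seed scene seed.
#' @param jitter_mm radial jitter applied to every bundle (default 1 mm).
#' @return a [phantom_spec()].
#' @export
default_phantom_spec <- function(seed = 1L, jitter_mm = 1) {
  bundles <- list(
    phantom_bundle("pyt_like", "straight",
                   from = c(-10, 0, -14), to = c(-10, 0, 14),
                   size_mm = c(8, 8, 6), n_streamlines = 500L,
                   jitter_mm = jitter_mm, group = "projection",
                   hemisphere = "left"),
    phantom_bundle("fx_like", "arc",
                   from = c(10, -14, 6), to = c(10, 14, 6),
                   n_streamlines = 25L, jitter_mm = jitter_mm,
                   group = "association", hemisphere = "left"),
    phantom_bundle("cc_like", "commissural_u",
                   from = c(-13, 6, -4), to = c(13, 6, -4),
                   n_streamlines = 200L, jitter_mm = jitter_mm,
                   group = "commissural", hemisphere = "midline"),
    phantom_bundle("af_like", "arc",
                   from = c(12, -13, -10), to = c(12, 13, -10),
                   n_streamlines = 150L, jitter_mm = jitter_mm,
                   group = "association", hemisphere = "right"))
  phantom_spec(bundles = bundles, n_distractors = 100L, seed = seed)
}

# ---- parcellation -----------------------------------------------------------

build_parcellation <- function(grid, regions) {
  data <- array(0L, grid$shape)
  ids <- integer(0); nms <- character(0)
  id <- 0L
  for (nm in names(regions)) {
    r <- regions[[nm]]
    id <- id + 1L
    half <- r$size_mm / 2
    m <- box_mask(grid, rbind(r$center_mm - half, r$center_mm + half))
    if (any(data[m$data] != 0L))
      stop("overlapping region request: ", nm)
    data[m$data] <- id
    ids <- c(ids, id); nms <- c(nms, nm)
  }
  wm_volume(data, grid, label_table = data.frame(id = ids, name = nms,
                                                 stringsAsFactors = FALSE))
}

#' Build the phantom parcellation
#'
#' One integer label per declared endpoint region (boxes in world mm),
#' background 0, label table populated.  Deterministic; overlapping region
#' requests are an error.
#'
#' @param spec a [phantom_spec()].
#' @return a [wm_volume()] parcellation.
#' @export
make_parcellation <- function(spec) {
  regions <- list()
  for (b in spec$bundles) for (nm in names(b$regions))
    regions[[nm]] <- b$regions[[nm]]
  build_parcellation(spec$grid, regions)
}

#' Miniature atlas parcellation for the 68-bundle protocol
#'
#' A deterministic 48x56x48 (2 mm) parcellation containing one box region
#' for every symbolic label of [protocol_label_names()], so that every VOI
#' of the default registry resolves.  A stand-in for the real FreeSurfer /
#' MSBP / SUIT / PD25 label volumes (synthetic; geometry is schematic, not
#' anatomical).
#'
#' @return a [wm_volume()] parcellation with 28 labels.
#' @export
atlas_parcellation <- function() {
  shape <- c(48L, 56L, 48L)
  voxel <- 2
  affine <- diag(c(rep(voxel, 3), 1))
  affine[1:3, 4] <- -voxel * (shape - 1) / 2
  grid <- reference_grid(shape, affine)
  bilateral <- c("frontal", "prefrontal", "premotor", "SMA", "motor",
                 "sensory", "parietal", "occipital", "temporal", "cingulate",
                 "hippocampus", "thalamus", "cerebellum")
  slots <- expand.grid(y = c(-42, -21, 0, 21, 42), z = c(30, 10, -10, -30))
  regions <- list()
  for (i in seq_along(bilateral)) {
    for (side in c("L", "R")) {
      x <- if (side == "L") -24 else 24
      regions[[paste0(bilateral[i], "_", side)]] <-
        list(center_mm = c(x, slots$y[i], slots$z[i]), size_mm = c(12, 12, 12))
    }
  }
  regions[["brainstem"]] <- list(center_mm = c(0, -10, -30),
                                 size_mm = c(12, 12, 12))
  regions[["optic_chiasm"]] <- list(center_mm = c(0, 10, -30),
                                    size_mm = c(12, 12, 12))
  build_parcellation(grid, regions)
}

# ---- centerlines and bundles ------------------------------------------------

perp_unit <- function(u, prefer = c(0, 0, 1)) {
  v <- prefer - sum(prefer * u) * u
  if (sqrt(sum(v^2)) < 1e-8) {
    prefer <- c(0, 1, 0)
    v <- prefer - sum(prefer * u) * u
  }
  v / sqrt(sum(v^2))
}

centerline_points <- function(kind, from, to, n_pts = NULL) {
  from <- as.numeric(from); to <- as.numeric(to)
  chord <- to - from
  L <- sqrt(sum(chord^2))
  if (L == 0) stop("centerline endpoints coincide")
  if (is.null(n_pts)) n_pts <- max(16L, ceiling(L) + 1L)
  t <- seq(0, 1, length.out = n_pts)
  u <- chord / L
  base <- outer(1 - t, from) + outer(t, to)
  switch(kind,
    straight = base,
    arc = {
      d <- perp_unit(u)
      base + outer(4 * t * (1 - t) * 0.35 * L / 2, d)
    },
    commissural_u = {
      d <- perp_unit(u)
      base + outer(4 * t * (1 - t) * 0.5 * L / 2, d)
    },
    helix = {
      d1 <- perp_unit(u)
      d2 <- pracma_cross(u, d1)
      amp <- 0.1 * L
      base + outer(amp * sin(2 * pi * t) * sin(pi * t), d1) +
        outer(amp * cos(2 * pi * t) * sin(pi * t), d2)
    },
    stop("unknown centerline kind: ", kind))
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Generate one jittered bundle
#'
#' Each streamline is the centerline translated by an independent offset
#' drawn from an isotropic Gaussian (sd = `jitter_mm`) and projected onto
#' the plane perpendicular to the chord, giving a 2-D radial Gaussian tube:
#' perpendicular distances to the centerline follow a Rayleigh(`jitter_mm`)
#' law with mean `jitter_mm * sqrt(pi/2)`.
#'
#' @param centerline n x 3 matrix, or a kind string (with `from`/`to`).
#' @param n_streamlines number of streamlines (>= 0).
#' @param jitter_mm radial jitter standard deviation.
#' @param seed RNG seed.
#' @param from,to endpoint centers when `centerline` is a kind string.
#' @return a [tractogram()] without a grid.
#' @export
make_bundle <- function(centerline, n_streamlines, jitter_mm, seed,
                        from = NULL, to = NULL) {
  if (is.character(centerline))
    centerline <- centerline_points(centerline, from, to)
  centerline <- as_points_matrix(centerline)
  chord <- centerline[nrow(centerline), ] - centerline[1, ]
  u <- chord / sqrt(sum(chord^2))
  streamlines <- with_seed(seed, {
    lapply(seq_len(n_streamlines), function(i) {
      v <- stats::rnorm(3, sd = jitter_mm)
      o <- v - sum(v * u) * u
      sweep(centerline, 2, o, "+")
    })
  })
  structure(list(streamlines = streamlines, grid = NULL),
            class = "wm_tractogram")
}

make_distractors <- function(grid, n, avoid_mask, seed, max_tries = 50L) {
  lo <- voxel_to_world(matrix(c(0, 0, 0), 1), grid)[1, ]
  hi <- voxel_to_world(matrix(grid$shape - 1, 1), grid)[1, ]
  with_seed(seed, {
    out <- vector("list", n)
    for (i in seq_len(n)) {
      for (try in seq_len(max_tries)) {
        a <- stats::runif(3, lo, hi)
        b <- stats::runif(3, lo, hi)
        if (sqrt(sum((b - a)^2)) < 5) next
        kind <- sample(c("straight", "arc"), 1)
        cl <- centerline_points(kind, a, b)
        hit <- hits_mask_cpp(list(cl), avoid_mask$data, grid$shape,
                             solve(grid$affine), min(voxel_sizes(grid)) / 2)
        if (!hit[1]) { out[[i]] <- cl; break }
      }
      if (is.null(out[[i]])) out[[i]] <- cl   # give up: keep last candidate
    }
    out
  })
}

#' Generate a complete phantom scene
#'
#' Builds the parcellation, all planted bundles, the distractors, the
#' ground-truth membership table and a registry of matching bundle
#' definitions (two pass-through label includes per bundle).
#'
#' @param spec a [phantom_spec()].
#' @return list with `parcellation`, `tractogram`, `membership` (data.frame
#'   `index`, `bundle`; distractors are labelled `"distractor"`),
#'   `registry`, and `spec`.
#' @export
make_phantom <- function(spec) {
  parc <- make_parcellation(spec)
  streamlines <- list()
  membership <- character(0)
  defs <- list()
  for (bi in seq_along(spec$bundles)) {
    b <- spec$bundles[[bi]]
    rn <- names(b$regions)
    cl <- centerline_points(b$kind, b$regions[[1]]$center_mm,
                            b$regions[[2]]$center_mm)
    tg <- make_bundle(cl, b$n_streamlines, b$jitter_mm,
                      seed = spec$seed + 1000L * bi)
    streamlines <- c(streamlines, tg$streamlines)
    membership <- c(membership, rep(b$name, b$n_streamlines))
    defs[[length(defs) + 1L]] <- bundle_definition(
      name = b$name, group = b$group, hemisphere = b$hemisphere,
      includes = list(voi_spec("labels", labels = rn[1]),
                      voi_spec("labels", labels = rn[2])))
  }
  if (spec$n_distractors > 0L) {
    avoid <- voi_mask(parc$data != 0L, spec$grid)
    dis <- make_distractors(spec$grid, spec$n_distractors, avoid,
                            seed = spec$seed + 999983L)
    streamlines <- c(streamlines, dis)
    membership <- c(membership, rep("distractor", length(dis)))
  }
  tg <- tractogram(streamlines, grid = spec$grid)
  list(parcellation = parc, tractogram = tg,
       membership = data.frame(index = seq_along(membership),
                               bundle = membership,
                               stringsAsFactors = FALSE),
       registry = bundle_registry(defs, version = "phantom"),
       spec = spec)
}

#' Test-retest phantom session pair
#'
#' Two scenes with identical geometry (grid, parcellation, centerlines,
#' counts) but independent jitter draws, emulating two acquisitions of the
#' same subject under one protocol.
#'
#' @param spec a [phantom_spec()].
#' @param seed_pair two distinct integer seeds.
#' @return list with `session1`, `session2` (each a [make_phantom()] scene).
#' @export
make_testretest <- function(spec, seed_pair) {
  if (length(seed_pair) != 2L || seed_pair[1] == seed_pair[2])
    stop("seed_pair must be two distinct seeds")
  s1 <- spec; s1$seed <- as.integer(seed_pair[1])
  s2 <- spec; s2$seed <- as.integer(seed_pair[2])
  list(session1 = make_phantom(s1), session2 = make_phantom(s2))
}
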