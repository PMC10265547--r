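test_that("streamline_intersects follows the arc-length sampling contract", {
  g <- toy_grid(c(9L, 9L, 9L), origin = c(0, 0, 0))
  slab <- array(FALSE, c(9, 9, 9)); slab[5, , ] <- TRUE
  m <- voi_mask(slab, g)
  # straight crossing
  expect_true(streamline_intersects(rbind(c(0, 4, 4), c(8, 4, 4)), m))
  # entirely outside the grid
  expect_false(streamline_intersects(rbind(c(50, 50, 50), c(60, 60, 60)), m))
  # a segment that jumps over a 1-voxel mask at coarse sampling but hits it
  # when sampled at half the voxel size (the default step)
  tiny <- array(FALSE, c(9, 9, 9)); tiny[5, 5, 5] <- TRUE
  mt <- voi_mask(tiny, g)
  sl <- rbind(c(3.1, 4, 4), c(4.9, 4, 4))  # 1.8 mm crossing voxel x=4
  expect_false(streamline_intersects(sl, mt, step_mm = 2))
  expect_true(streamline_intersects(sl, mt, step_mm = 0.5))
  expect_true(streamline_intersects(sl, mt))  # default = voxel/2
})

test_that("flag_failure matches the <10-streamline rule at the boundary", {
  expect_true(flag_failure(9, 9, 10))
  expect_false(flag_failure(10, 10, 10))
  expect_true(flag_failure(0, 0, 10))
  expect_true(flag_failure(100, 9, 10))   # failed after first filtering step
  expect_error(flag_failure(-1, 5, 10), "non-negative")
})

test_that("select_bundle applies include AND / exclude OR semantics", {
  g <- toy_grid(c(16L, 16L, 16L))
  parc <- toy_parcellation(g)
  # three hand-placed streamlines: #1 and #2 hit regA..regB; #2 also regC
  centers <- function(idx) voxel_to_world(idx, g)
  sA <- voxel_to_world(rbind(c(3, 3, 3), c(13, 3, 3)), g)          # A -> B
  sB <- voxel_to_world(rbind(c(3, 3, 3), c(13, 3, 3), c(3, 13, 13)), g)
  sC <- voxel_to_world(rbind(c(0, 8, 8), c(15, 8, 8)), g)          # misses all
  tg <- tractogram(list(sA, sB, sC), g)
  def <- bundle_definition(
    "t", "association", "left",
    includes = list(voi_spec("labels", labels = "regA"),
                    voi_spec("labels", labels = "regB")),
    excludes = list(voi_spec("labels", labels = "regC")),
    min_streamlines = 1L)
  res <- select_bundle(tg, def, parc, smooth_window = 1L)
  expect_identical(res$indices, 1L)
  expect_identical(res$counts,
                   list(initial_candidates = 3L, after_selection = 1L,
                        after_filtering = 1L))
  expect_false(res$failed)
  # exclude covering the whole grid -> nothing selected, failed
  def2 <- bundle_definition(
    "t2", "association", "left",
    includes = list(voi_spec("labels", labels = "regA")),
    excludes = list(voi_spec("box", corners_mm = rbind(c(-50, -50, -50),
                                                       c(50, 50, 50)))))
  res2 <- select_bundle(tg, def2, parc)
  expect_identical(res2$counts$after_selection, 0L)
  expect_true(res2$failed)
})

test_that("endpoint semantics require termination, not pass-through", {
  g <- toy_grid(c(16L, 16L, 16L))
  parc <- toy_parcellation(g)
  # passes through regA but terminates outside it
  through <- voxel_to_world(rbind(c(0, 3, 3), c(3, 3, 3), c(15, 3, 3)), g)
  # terminates inside regA
  ends_in <- voxel_to_world(rbind(c(15, 3, 3), c(3, 3, 3)), g)
  tg <- tractogram(list(through, ends_in), g)
  def <- bundle_definition(
    "ep", "association", "left",
    includes = list(voi_spec("labels", labels = "regA")),
    endpoint_includes = list(voi_spec("labels", labels = "regA")),
    min_streamlines = 1L)
  res <- select_bundle(tg, def, parc, smooth_window = 1L)
  expect_identical(res$indices, 2L)
})

test_that("filter_length keeps the closed [min, max] arc-length band", {
  g <- toy_grid()
  ten_mm <- rbind(c(0, 0, 0), c(10, 0, 0))
  tg <- tractogram(list(ten_mm), g)
  expect_identical(n_streamlines(filter_length(tg, 0, Inf)), 1L)
  expect_identical(n_streamlines(filter_length(tg, 11, 20)), 0L)
  expect_identical(n_streamlines(filter_length(tg, 10, 20)), 1L)  # closed
  empty <- tractogram(list(), g)
  expect_identical(n_streamlines(filter_length(empty, 0, 10)), 0L)
  expect_error(filter_length(tg, 5, 5), "min < max")
})

test_that("filter_outliers removes exactly the planted outlier", {
  g <- toy_grid(c(64L, 64L, 64L))
  set.seed(21)
  base <- cbind(seq(-20, 20, length.out = 20), 0, 0)
  bundle <- lapply(1:19, function(i)
    sweep(base, 2, c(0, runif(1, -1, 1), runif(1, -1, 1)), "+"))
  bundle[[20]] <- sweep(base, 2, c(0, 50, 0), "+")
  tg <- tractogram(bundle, g)
  filt <- filter_outliers(tg, z_threshold = 2)
  expect_identical(n_streamlines(filt), 19L)
  expect_true(all(vapply(filt$streamlines, function(s) max(abs(s[, 2])) < 2,
                         logical(1))))
  # brute-force check of the distance vector: outlier is the unique max
  keep <- wmtract:::outlier_keep(tg, 2)
  expect_identical(which(!keep), 20L)
  # identical streamlines: zero spread, none removed
  same <- tractogram(rep(list(base), 20), g)
  expect_identical(n_streamlines(filter_outliers(same, 2)), 20L)
  # fewer than 3: identity
  two <- tractogram(bundle[1:2], g)
  expect_identical(n_streamlines(filter_outliers(two, 2)), 2L)
})

test_that("smooth_streamlines damps zig-zag interiors, fixes endpoints", {
  g <- toy_grid()
  zig <- cbind(0:8, rep(c(0, 1), length.out = 9), 0)
  tg <- tractogram(list(zig), g)
  expect_identical(smooth_streamlines(tg, 1)$streamlines[[1]], zig)
  straight <- cbind(0:8, 0, 0)
  expect_equal(smooth_streamlines(tractogram(list(straight), g), 3)$
                 streamlines[[1]], straight)
  sm <- smooth_streamlines(tg, 3)$streamlines[[1]]
  expect_identical(sm[1, ], zig[1, ])
  expect_identical(sm[9, ], zig[9, ])
  # hand moving-averages of interior points: mean(0,1,0), mean(1,0,1)
  expect_equal(sm[2, 2], 1 / 3)
  expect_equal(sm[3, 2], 2 / 3)
  expect_true(all(abs(sm[2:8, 2] - 0.5) < abs(zig[2:8, 2] - 0.5) + 1e-12))
  # arc length changes by < 20% on a realistic wiggle
  wig <- cbind(0:8, 0.3 * rep(c(0, 1), length.out = 9), 0)
  tw <- tractogram(list(wig), g)
  l0 <- streamline_lengths(tw)
  l1 <- streamline_lengths(smooth_streamlines(tw, 3))
  expect_lt(abs(l1 - l0) / l0, 0.2)
  expect_error(smooth_streamlines(tg, 2), "odd")
})

test_that("selection is monotone in include/exclude sets and idempotent", {
  set.seed(31)
  g <- toy_grid(c(16L, 16L, 16L))
  parc <- toy_parcellation(g)
  tg <- tractogram(random_streamlines(40, g), g)
  incA <- voi_spec("labels", labels = "regA")
  incB <- voi_spec("labels", labels = "regB")
  excC <- voi_spec("labels", labels = "regC")
  sel <- function(includes, excludes = list()) {
    def <- bundle_definition("m", "association", "left", includes = includes,
                             excludes = excludes, min_streamlines = 1L)
    select_bundle(tg, def, parc, smooth_window = 1L)$indices
  }
  s1 <- sel(list(incA))
  s2 <- sel(list(incA, incB))
  s3 <- sel(list(incA), list(excC))
  expect_true(all(s2 %in% s1))   # adding an include never grows the set
  expect_true(all(s3 %in% s1))   # adding an exclude never grows the set
  # idempotence (outlier stage disabled): re-dissecting retains everything
  def <- bundle_definition("m", "association", "left",
                           includes = list(incA), min_streamlines = 1L)
  first <- select_bundle(tg, def, parc, smooth_window = 1L)
  second <- select_bundle(first$selected, def, parc, smooth_window = 1L)
  expect_identical(n_streamlines(second$selected),
                   n_streamlines(first$selected))
})

test_that("dissect_all collects per-bundle errors without aborting", {
  g <- toy_grid(c(16L, 16L, 16L))
  parc <- toy_parcellation(g)
  scene_def <- bundle_definition(
    "ok", "association", "left",
    includes = list(voi_spec("labels", labels = "regA")),
    min_streamlines = 1L)
  broken <- bundle_definition(
    "broken", "association", "left",
    includes = list(voi_spec("labels", labels = "no_such_region")))
  reg <- bundle_registry(list(scene_def, broken))
  tg <- tractogram(list(voxel_to_world(rbind(c(3, 3, 3), c(13, 3, 3)), g)), g)
  res <- dissect_all(tg, reg, parc)
  expect_length(res, 2L)
  expect_false(res$ok$failed)
  expect_true(res$broken$failed)
  expect_match(res$broken$failure_reason, "no_such_region")
  # empty tractogram: everything fails, nothing errors
  res2 <- dissect_all(tractogram(list(), g), reg, parc)
  expect_true(all(vapply(res2, `[[`, logical(1), "failed")))
})
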