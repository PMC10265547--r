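test_that("make_parcellation builds labelled boxes deterministically", {
  spec <- default_phantom_spec(seed = 3)
  p1 <- make_parcellation(spec)
  p2 <- make_parcellation(spec)
  expect_identical(p1$data, p2$data)
  expect_identical(nrow(p1$label_table), 8L)   # 4 bundles x 2 regions
  expect_setequal(sort(unique(as.vector(p1$data))), 0:8)
  # region volume matches the requested box geometry (8x8x6 mm at 1 mm)
  b <- spec$bundles[[1]]
  id <- p1$label_table$id[p1$label_table$name == names(b$regions)[1]]
  half <- b$regions[[1]]$size_mm / 2
  m <- box_mask(spec$grid, rbind(b$regions[[1]]$center_mm - half,
                                 b$regions[[1]]$center_mm + half))
  expect_identical(sum(p1$data == id), sum(m$data))
  # overlapping regions rejected
  bad <- spec
  bad$bundles[[2]]$regions[[1]]$center_mm <-
    bad$bundles[[1]]$regions[[1]]$center_mm
  expect_error(make_parcellation(bad), "overlap")
})

test_that("phantom_spec rejects duplicate region names and bad counts", {
  b1 <- wmtract:::phantom_bundle("x", "straight", c(-5, 0, 0), c(5, 0, 0),
                                 region_names = c("r1", "r2"))
  b2 <- wmtract:::phantom_bundle("y", "straight", c(0, -5, 0), c(0, 5, 0),
                                 region_names = c("r2", "r3"))
  expect_error(phantom_spec(bundles = list(b1, b2)), "distinct")
})

test_that("make_bundle is seeded, reproducible and jitter-faithful", {
  a <- make_bundle("straight", 10, 1, seed = 5,
                   from = c(0, 0, -10), to = c(0, 0, 10))
  b <- make_bundle("straight", 10, 1, seed = 5,
                   from = c(0, 0, -10), to = c(0, 0, 10))
  expect_identical(a$streamlines, b$streamlines)
  c_ <- make_bundle("straight", 10, 1, seed = 6,
                    from = c(0, 0, -10), to = c(0, 0, 10))
  expect_false(identical(a$streamlines, c_$streamlines))
  # jitter = 0: every streamline equals the centerline
  z <- make_bundle("straight", 5, 0, seed = 5,
                   from = c(0, 0, -10), to = c(0, 0, 10))
  for (s in z$streamlines) expect_equal(s, z$streamlines[[1]])
  expect_equal(max(abs(z$streamlines[[1]][, 1:2])), 0)
})

test_that("radial offsets follow the Rayleigh law (Monte-Carlo)", {
  n <- 1000
  tg <- make_bundle("straight", n, 1, seed = 9,
                    from = c(0, 0, -10), to = c(0, 0, 10))
  # perpendicular distance of each streamline to the straight centerline
  d <- vapply(tg$streamlines, function(s) sqrt(sum(s[1, 1:2]^2)), numeric(1))
  mean_expect <- sqrt(pi / 2)                 # Rayleigh(1) mean
  se <- sqrt((4 - pi) / 2) / sqrt(n)          # Rayleigh sd / sqrt(n)
  expect_lt(abs(mean(d) - mean_expect), 3 * se)
})

test_that("full scene is deterministic and distractors avoid regions", {
  spec <- default_phantom_spec(seed = 13)
  s1 <- make_phantom(spec)
  s2 <- make_phantom(spec)
  expect_identical(s1$tractogram$streamlines, s2$tractogram$streamlines)
  expect_identical(s1$membership, s2$membership)
  n_planted <- sum(vapply(spec$bundles, `[[`, integer(1), "n_streamlines"))
  expect_identical(n_streamlines(s1$tractogram),
                   n_planted + spec$n_distractors)
  # distractors never cross any endpoint region
  avoid <- voi_mask(s1$parcellation$data != 0L, spec$grid)
  dis <- s1$tractogram$streamlines[s1$membership$bundle == "distractor"]
  hits <- vapply(dis, streamline_intersects, logical(1), mask = avoid)
  expect_false(any(hits))
})

test_that("test-retest sessions share geometry but differ in jitter", {
  spec <- default_phantom_spec()
  tr <- make_testretest(spec, c(71, 72))
  expect_identical(tr$session1$parcellation$data,
                   tr$session2$parcellation$data)
  expect_false(identical(tr$session1$tractogram$streamlines,
                         tr$session2$tractogram$streamlines))
  # swapping seeds swaps sessions
  tr_swap <- make_testretest(spec, c(72, 71))
  expect_identical(tr_swap$session2$tractogram$streamlines,
                   tr$session1$tractogram$streamlines)
  expect_error(make_testretest(spec, c(5, 5)), "distinct")
})

test_that("zero jitter gives a perfect test-retest weighted Dice", {
  spec <- default_phantom_spec(jitter_mm = 0)
  spec$n_distractors <- 0L
  tr <- make_testretest(spec, c(81, 82))
  g <- spec$grid
  r1 <- dissect_all(tr$session1$tractogram, tr$session1$registry,
                    tr$session1$parcellation, smooth_window = 1L)
  r2 <- dissect_all(tr$session2$tractogram, tr$session2$registry,
                    tr$session2$parcellation, smooth_window = 1L)
  for (nm in names(r1)) {
    d1 <- density_map(r1[[nm]]$selected, g)
    d2 <- density_map(r2[[nm]]$selected, g)
    expect_identical(wdsc(d1, d2), 1)
  }
})
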