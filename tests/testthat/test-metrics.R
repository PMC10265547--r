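mk_mask <- function(g, idx) {
  d <- array(FALSE, g$shape)
  d[idx] <- TRUE
  voi_mask(d, g)
}

mk_density <- function(g, idx, counts) {
  d <- array(0L, g$shape)
  d[idx] <- as.integer(counts)
  structure(list(counts = d, grid = g, n_streamlines = sum(counts)),
            class = "wm_density")
}

test_that("dsc matches the closed form", {
  g <- toy_grid(c(4L, 4L, 4L))
  a <- mk_mask(g, 1:2); b <- mk_mask(g, 2:3)
  expect_identical(dsc(a, a), 1)
  expect_identical(dsc(mk_mask(g, 1:2), mk_mask(g, 3:4)), 0)
  expect_identical(dsc(a, b), 0.5)           # 2*1/(2+2)
  both_empty <- dsc(mk_mask(g, integer(0)), mk_mask(g, integer(0)))
  expect_identical(as.numeric(both_empty), 1)
  expect_true(attr(both_empty, "both_empty"))
  expect_error(dsc(a, mk_mask(toy_grid(c(5L, 5L, 5L)), 1)), "grids")
})

test_that("wdsc weights shared support by density proportions", {
  g <- toy_grid(c(4L, 4L, 4L))
  a <- mk_density(g, 1:2, c(3, 1))
  expect_identical(wdsc(a, a), 1)
  expect_identical(wdsc(a, mk_density(g, 3:4, c(1, 1))), 0)
  # A {v1:3, v2:1}, B {v2:1, v3:1} -> (0.25 + 0.5)/2 = 0.375
  b <- mk_density(g, 2:3, c(1, 1))
  expect_identical(wdsc(a, b), 0.375)
  expect_identical(wdsc(a, b), wdsc(b, a))
  expect_error(wdsc(a, mk_density(g, integer(0), integer(0))), "empty")
})

test_that("wdsc equals dsc for uniform equal-sized supports", {
  g <- toy_grid(c(5L, 5L, 5L))
  a <- mk_density(g, 1:4, rep(2, 4))
  b <- mk_density(g, 3:6, rep(5, 4))
  expect_equal(wdsc(a, b),
               as.numeric(dsc(mk_mask(g, 1:4), mk_mask(g, 3:6))))
})

test_that("density_correlation is Pearson over the support union", {
  g <- toy_grid(c(4L, 4L, 4L))
  a <- mk_density(g, 1:3, c(1, 2, 3))
  expect_equal(density_correlation(a, a), 1)
  expect_equal(density_correlation(a, mk_density(g, 1:3, c(2, 4, 6))), 1)
  expect_equal(density_correlation(a, mk_density(g, 1:3, c(3, 2, 1))), -1)
  expect_error(density_correlation(a, mk_density(g, 1:3, c(2, 2, 2))),
               "zero variance")
  expect_error(density_correlation(mk_density(g, 1:2, c(1, 2)),
                                   mk_density(g, 1:2, c(2, 1))),
               "3 voxels")
})

test_that("overlap_overreach counts against the reference", {
  g <- toy_grid(c(4L, 4L, 4L))
  r <- mk_mask(g, 1:4)
  expect_equal(overlap_overreach(r, r), c(overlap = 1, overreach = 0))
  expect_equal(overlap_overreach(mk_mask(g, integer(0)), r),
               c(overlap = 0, overreach = 0))
  cand <- mk_mask(g, c(1:3, 10, 11))       # 3 of R plus 2 outside
  expect_equal(overlap_overreach(cand, r),
               c(overlap = 0.75, overreach = 0.5))
  expect_error(overlap_overreach(cand, mk_mask(g, integer(0))), "empty")
})

test_that("bundle_adjacency averages one-sided nearest distances", {
  g <- toy_grid(c(10L, 10L, 10L), origin = c(0, 0, 0))
  one <- function(i, j, k) {
    d <- array(FALSE, c(10, 10, 10)); d[i, j, k] <- TRUE; voi_mask(d, g)
  }
  a <- one(2, 2, 2)
  expect_identical(bundle_adjacency(a, a), 0)
  b <- one(5, 2, 2)                        # 3 mm apart on a 1 mm grid
  expect_equal(bundle_adjacency(a, b), 3)
  expect_equal(bundle_adjacency(a, b), bundle_adjacency(b, a))
  # A subset of B with one adjacent extra voxel: 0.5 * (0 + 1)
  da <- array(FALSE, c(10, 10, 10)); da[2, 2, 2] <- TRUE
  db <- da; db[3, 2, 2] <- TRUE
  expect_equal(bundle_adjacency(voi_mask(da, g), voi_mask(db, g)), 0.5)
  expect_error(bundle_adjacency(a, voi_mask(array(FALSE, c(10, 10, 10)), g)),
               "non-empty")
})

test_that("summary_stats uses sample sd and interpolated quartiles", {
  s <- summary_stats(c(1, 2, 3, 4))
  expect_identical(s$median, 2.5)
  expect_equal(s$iqr, 1.5)
  expect_equal(s$stdev, sd(c(1, 2, 3, 4)))
  expect_identical(s$min, 1)
  cst <- summary_stats(rep(3, 5))
  expect_identical(cst$stdev, 0)
  expect_identical(cst$iqr, 0)
  expect_error(summary_stats(numeric(0)), "at least 1")
})

test_that("max_abs_intersession_diff is the max pairwise gap", {
  expect_equal(max_abs_intersession_diff(cbind(c(0.5, 0.9), c(0.6, 0.7))),
               0.2)
  expect_identical(max_abs_intersession_diff(cbind(1, 1)), 0)
  expect_identical(max_abs_intersession_diff(cbind(0, 1)), 1)
  expect_error(max_abs_intersession_diff(matrix(0, 0, 2)), "non-empty")
})

test_that("icc_single_agreement matches hand-checkable cases", {
  # identical across sessions, varying across items -> 1
  x <- cbind(1:6, 1:6)
  res <- icc_single_agreement(x)
  expect_equal(res$icc, 1)
  # all ratings equal -> undefined
  expect_error(icc_single_agreement(matrix(2, 4, 3)), "zero total variance")
  # 4x2 matrix against the brute-force ANOVA oracle
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), 4, 2, byrow = TRUE)
  expect_equal(icc_single_agreement(m)$icc, oracle_icc_a1(m),
               tolerance = 1e-10)
})

test_that("ratings_matrix drops incomplete rows and validates size", {
  x <- rbind(c(1, 2), c(NA, 3), c(4, 5), c(6, 7))
  expect_message(rm_ <- ratings_matrix(x), "dropped 1")
  expect_identical(nrow(rm_), 3L)
  expect_identical(attr(rm_, "n_dropped"), 1L)
  expect_error(suppressMessages(ratings_matrix(rbind(c(1, NA), c(2, 3)))),
               "at least 2")
})

test_that("similarity_report covers shared bundles with all six metrics", {
  spec <- default_phantom_spec()
  tr <- make_testretest(spec, c(61, 62))
  r1 <- dissect_all(tr$session1$tractogram, tr$session1$registry,
                    tr$session1$parcellation)
  r2 <- dissect_all(tr$session2$tractogram, tr$session2$registry,
                    tr$session2$parcellation)
  rep_df <- similarity_report(r1, r2, spec$grid)
  expect_setequal(rep_df$bundle,
                  c("pyt_like", "fx_like", "cc_like", "af_like"))
  expect_true(all(rep_df$wdsc > 0.5 & rep_df$wdsc <= 1))
  expect_true(all(rep_df$dsc > 0 & rep_df$dsc <= 1))
  expect_true(all(rep_df$overlap >= 0 & rep_df$overlap <= 1))
  expect_true(all(rep_df$overreach >= 0))
  expect_true(all(rep_df$adjacency_mm >= 0))
})
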