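# Shared fixture builders.  Everything is generated in code; no binary files.

# small grid with a non-trivial affine (anisotropic voxels + translation)
toy_grid <- function(shape = c(12L, 12L, 12L), voxel = c(1, 1, 1),
                     origin = -voxel * (shape - 1) / 2) {
  a <- diag(c(voxel, 1))
  a[1:3, 4] <- origin
  reference_grid(shape, a)
}

# deterministic toy parcellation: a handful of box labels on a toy grid
toy_parcellation <- function(grid = toy_grid(c(16L, 16L, 16L))) {
  data <- array(0L, grid$shape)
  data[2:5, 2:5, 2:5] <- 1L
  data[12:15, 2:5, 2:5] <- 2L
  data[2:5, 12:15, 12:15] <- 3L
  wm_volume(data, grid,
            label_table = data.frame(id = 1:3,
                                     name = c("regA", "regB", "regC"),
                                     stringsAsFactors = FALSE))
}

random_streamlines <- function(n, grid, n_pts = 8L, sd = NULL) {
  lo <- voxel_to_world(matrix(c(0, 0, 0), 1), grid)[1, ]
  hi <- voxel_to_world(matrix(grid$shape - 1, 1), grid)[1, ]
  lapply(seq_len(n), function(i) {
    start <- runif(3, lo, hi)
    end <- runif(3, lo, hi)
    t <- seq(0, 1, length.out = n_pts)
    base <- outer(1 - t, start) + outer(t, end)
    base + matrix(rnorm(n_pts * 3, sd = if (is.null(sd)) 0.3 else sd),
                  n_pts, 3)
  })
}

# brute-force selection oracle: rasterize every segment at a fine step and
# test voxel membership directly, without any shared code path with the
# package's resampling (pure R, per-segment sampling)
oracle_streamline_hits <- function(streamline, mask, step_mm) {
  inv <- solve(mask$grid$affine)
  sh <- mask$grid$shape
  pts <- streamline
  samples <- list(pts[1, , drop = FALSE])
  for (i in seq_len(nrow(pts) - 1)) {
    a <- pts[i, ]; b <- pts[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / step_mm))
    t <- seq_len(k) / k
    samples[[i + 1L]] <- outer(1 - t, a) + outer(t, b)
  }
  p <- do.call(rbind, samples)
  v <- cbind(p, 1) %*% t(inv[1:3, ])
  idx <- floor(v + 0.5)
  ok <- idx[, 1] >= 0 & idx[, 1] < sh[1] & idx[, 2] >= 0 & idx[, 2] < sh[2] &
    idx[, 3] >= 0 & idx[, 3] < sh[3]
  if (!any(ok)) return(FALSE)
  any(mask$data[idx[ok, , drop = FALSE] + 1L])
}

# independent ICC oracle: sums of squares by definition via aov()
oracle_icc_a1 <- function(x) {
  n <- nrow(x); k <- ncol(x)
  df <- data.frame(score = as.vector(x),
                   item = factor(rep(seq_len(n), k)),
                   sess = factor(rep(seq_len(k), each = n)))
  fit <- summary(stats::aov(score ~ item + sess, data = df))[[1]]
  MSR <- fit["item", "Mean Sq"]
  MSC <- fit["sess", "Mean Sq"]
  MSE <- fit["Residuals", "Mean Sq"]
  (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
}
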