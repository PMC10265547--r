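#' Ratings matrix for intraclass correlation
#'
#' Items (e.g. bundle-by-subject units) in rows, sessions/raters in columns.
#' Rows containing missing cells are dropped with a message; the drop count
#' is recorded in attribute `n_dropped`.
#'
#' @param values numeric matrix or data.frame, n items x k sessions.
#' @param items optional row labels.
#' @param sessions optional column labels.
#' @return object of class `ratings_matrix`.
#' @export
ratings_matrix <- function(values, items = NULL, sessions = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.null(items)) rownames(values) <- items
  if (!is.null(sessions)) colnames(values) <- sessions
  complete <- stats::complete.cases(values)
  n_dropped <- sum(!complete)
  if (n_dropped > 0L) {
    message("ratings_matrix: dropped ", n_dropped, " item(s) with missing cells")
    values <- values[complete, , drop = FALSE]
  }
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("ratings matrix needs at least 2 items and 2 sessions after ",
         "dropping incomplete rows")
  structure(values, class = c("ratings_matrix", "matrix"),
            n_dropped = n_dropped)
}

#' Single-measure absolute-agreement intraclass correlation
#'
#' Two-way random-effects, absolute-agreement, single-measure ICC (ICC(A,1)
#' in the McGraw & Wong taxonomy), from the two-way ANOVA decomposition:
#' `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))` with `MSR`, `MSC`,
#' `MSE` the item, session and residual mean squares.  The 95% confidence
#' bounds use the Satterthwaite-approximated F procedure of McGraw & Wong;
#' the p-value is from `F = MSR/MSE` on `(n-1, (n-1)(k-1))` degrees of
#' freedom.
#'
#' @param ratings a [ratings_matrix()] (or coercible matrix).
#' @param conf_level confidence level for the bounds (default 0.95).
#' @return list with `icc`, `lower`, `upper`, `p_value`, plus the mean
#'   squares (`MSR`, `MSC`, `MSE`) and dimensions.
#' @export
icc_single_agreement <- function(ratings, conf_level = 0.95) {
  if (!inherits(ratings, "ratings_matrix")) ratings <- ratings_matrix(ratings)
  x <- unclass(ratings)
  n <- nrow(x); k <- ncol(x)
  grand <- mean(x)
  row_m <- rowMeans(x); col_m <- colMeans(x)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((x - grand)^2)
  SSE <- SST - SSR - SSC
  if (SST <= .Machine$double.eps * max(1, abs(grand)))
    stop("ICC undefined: ratings have zero total variance")
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + (k / n) * (MSC - MSE))
  alpha <- 1 - conf_level
  if (MSE <= 0) {
    # degenerate perfect-agreement case: bounds collapse onto the estimate
    lower <- upper <- icc
    p <- 0
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    FL <- stats::qf(1 - alpha / 2, n - 1, v)
    FU <- stats::qf(1 - alpha / 2, v, n - 1)
    lower <- n * (MSR - FL * MSE) /
      (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    upper <- n * (FU * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
    Fobs <- MSR / MSE
    p <- stats::pf(Fobs, n - 1, (n - 1) * (k - 1), lower.tail = FALSE)
  }
  list(icc = icc, lower = lower, upper = upper, p_value = p,
       MSR = MSR, MSC = MSC, MSE = MSE, n_items = n, k_sessions = k)
}
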