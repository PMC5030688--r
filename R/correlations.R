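# Correlation primitives shared by the MGS-profiling and linking stages.
# Implemented directly from the definitions (centering, scaling, crossprod)
# so that constant profiles are flagged as undefined rather than silently
# propagated as NaN.

#' Pearson correlation of two vectors
#'
#' Standard product-moment coefficient. A constant vector has no defined
#' correlation; the result is `NA` (flagged, never coerced to 0).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
pearson_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  cx <- x - mean(x)
  cy <- y - mean(y)
  sx <- sqrt(sum(cx^2))
  sy <- sqrt(sum(cy^2))
  if (sx == 0 || sy == 0) return(NA_real_)
  r <- sum(cx * cy) / (sx * sy)
  max(-1, min(1, r))
}

#' Spearman rank correlation of two vectors
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). Undefined — `NA` — when either vector is constant.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`, or `NA` if either vector is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch", call. = FALSE)
  pearson_rho(rank(x, ties.method = "average"), rank(y, ties.method = "average"))
}

# Row-standardize a matrix: subtract row means, divide by root sum of squared
# deviations. Constant rows come back as all-NA (their correlation with
# anything is undefined).
standardize_rows <- function(m) {
  c0 <- m - rowMeans(m)
  ss <- sqrt(rowSums(c0^2))
  ss[ss == 0] <- NA_real_
  c0 / ss
}

# All pairwise Pearson correlations between the rows of a and the rows of b
# (same columns). Constant rows yield NA entries.
cross_correlate_rows <- function(a, b) {
  r <- tcrossprod(standardize_rows(a), standardize_rows(b))
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

# Average-rank each row of a matrix (for row-wise Spearman).
rank_rows <- function(m) {
  t(apply(m, 1, rank, ties.method = "average"))
}
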