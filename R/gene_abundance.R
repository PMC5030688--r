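# Removal of technical variability from shotgun gene counts: per-sample
# rarefaction to a fixed mappable depth, then RPKM+TC normalization to
# relative abundance.

#' Downsample each sample to a fixed read depth
#'
#' Rarefies every column of a count matrix to exactly `target_depth` reads by
#' drawing a uniform subsample without replacement from the reads the counts
#' imply (a multivariate hypergeometric draw, realized gene by gene through
#' successive univariate hypergeometric draws). Samples whose total is
#' already `target_depth` are returned unchanged; shallower samples are
#' handled per `on_shallow`.
#'
#' @param counts Integer count matrix (genes x samples).
#' @param target_depth Number of reads to retain per sample.
#' @param seed Integer seed; the draw is fully reproducible given the seed.
#' @param on_shallow What to do with samples whose total is below
#'   `target_depth`: `"error"` aborts naming the sample, `"keep"` passes the
#'   column through unchanged with a warning, `"drop"` removes it.
#' @return Count matrix with every retained column summing to
#'   `target_depth` (or its original total under `"keep"`).
#' @export
downsample_counts <- function(counts, target_depth, seed,
                              on_shallow = c("error", "keep", "drop")) {
  on_shallow <- match.arg(on_shallow)
  validate_count_matrix(counts, integral = TRUE)
  if (length(target_depth) != 1 || target_depth < 1 ||
      target_depth != round(target_depth)) {
    stop("target_depth must be a positive integer", call. = FALSE)
  }
  totals <- colSums(counts)
  shallow <- colnames(counts)[totals < target_depth]
  if (length(shallow)) {
    if (on_shallow == "error") {
      stop("sample(s) below target depth ", target_depth, ": ",
           paste(shallow, collapse = ", "), call. = FALSE)
    }
    if (on_shallow == "keep") {
      warning("keeping ", length(shallow), " sample(s) below target depth: ",
              paste(shallow, collapse = ", "), call. = FALSE)
    }
    if (on_shallow == "drop") {
      counts <- counts[, !(colnames(counts) %in% shallow), drop = FALSE]
      totals <- colSums(counts)
    }
  }
  out <- with_seed(seed, {
    res <- counts
    for (j in seq_len(ncol(counts))) {
      if (totals[j] > target_depth) {
        res[, j] <- rmvhyper(counts[, j], target_depth)
      }
    }
    res
  })
  out
}

# One multivariate hypergeometric draw: pick k of the sum(n) reads implied by
# the per-gene counts n, without replacement. Sequential conditional
# univariate hypergeometric draws are exact and O(#nonzero genes).
rmvhyper <- function(n, k) {
  out <- numeric(length(n))
  remaining_pool <- sum(n)
  remaining_draw <- k
  idx <- which(n > 0)
  for (i in idx) {
    if (remaining_draw == 0) break
    x <- stats::rhyper(1, m = n[i], n = remaining_pool - n[i], k = remaining_draw)
    out[i] <- x
    remaining_draw <- remaining_draw - x
    remaining_pool <- remaining_pool - n[i]
  }
  out
}

# Run code under a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' RPKM+TC normalization of gene counts
#'
#' Divides each count by its gene length, then by the per-sample total of the
#' length-normalized signal, yielding relative abundances whose columns sum
#' to 1. The constant "per kilobase, per million" factors of textbook RPKM
#' cancel under the total-count step and are omitted. Samples with all-zero
#' input are returned as all-zero columns and listed in the
#' `"zero_samples"` attribute.
#'
#' @param counts Count matrix (genes x samples); fractional values are
#'   accepted (the matrix may already be downsampled or scaled).
#' @param lengths Gene length table from [gene_length_table()], or a named
#'   numeric vector of lengths. Every row of `counts` must have a length.
#' @return Relative abundance matrix; columns with nonzero input sum to 1.
#' @export
normalize_rpkm_tc <- function(counts, lengths) {
  validate_count_matrix(counts, integral = FALSE)
  if (is.data.frame(lengths)) {
    lengths <- stats::setNames(lengths$length_nt, lengths$gene_id)
  }
  missing <- setdiff(rownames(counts), names(lengths))
  if (length(missing)) {
    stop("no gene length for: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  len <- lengths[rownames(counts)]
  rate <- counts / len
  tot <- colSums(rate)
  zero <- colnames(counts)[tot == 0]
  tot[tot == 0] <- 1  # leaves all-zero columns all zero
  ab <- sweep(rate, 2, tot, "/")
  attr(ab, "zero_samples") <- zero
  ab
}
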