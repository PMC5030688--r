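# The core linking method: convert MGS and OTU profiles to log ratios,
# filter by prevalence, correlate every query against every candidate with
# Pearson's coefficient, and report best and second-best hits against a
# cutoff.

#' Log-ratio normalization of an abundance or count table
#'
#' Converts each column to ratios (value / column sum), adds a pseudocount
#' on the ratio scale, and takes log10. The pseudocount guards against
#' underflow at zero: a zero count maps exactly to `log10(pseudocount)`
#' (-17 at the default). Adding the pseudocount after the ratio conversion
#' keeps its effect independent of sequencing depth.
#'
#' @param m Non-negative matrix (entities x samples).
#' @param pseudocount Positive constant added to the ratios (default 1e-17).
#' @return Matrix of log10 profiles; all values lie in
#'   `[log10(pseudocount), ~0]`.
#' @export
normalize_profiles <- function(m, pseudocount = 1e-17) {
  if (!is.matrix(m) || any(m < 0)) {
    stop("input must be a non-negative matrix", call. = FALSE)
  }
  if (length(pseudocount) != 1 || !is.finite(pseudocount) || pseudocount <= 0) {
    stop("pseudocount must be > 0", call. = FALSE)
  }
  tot <- colSums(m)
  if (any(tot == 0)) {
    stop("all-zero sample(s): ",
         paste(utils::head(colnames(m)[tot == 0], 5), collapse = ", "),
         "; drop them before normalization", call. = FALSE)
  }
  log10(sweep(m, 2, tot, "/") + pseudocount)
}

#' Prevalence filter
#'
#' Retains a row iff its number of samples with a value strictly greater
#' than zero exceeds `min_positive` (strict inequality: "more than
#' `min_positive` samples"). Works on counts or on real-valued MGS
#' abundances, where positive means mean tracer abundance > 0.
#'
#' @param m Matrix (entities x samples), values >= 0.
#' @param min_positive Exclusive threshold on the number of positive
#'   samples (default 10).
#' @return List with `kept` (the filtered matrix) and `dropped` (row ids
#'   removed).
#' @export
prevalence_filter <- function(m, min_positive = 10) {
  npos <- rowSums(m > 0)
  keep <- npos > min_positive
  list(kept = m[keep, , drop = FALSE], dropped = rownames(m)[!keep])
}

#' Cross-table Pearson correlations
#'
#' Pearson coefficient between every row of `a` and every row of `b`.
#' Sample ids must match exactly (same set, same order). Pairs where either
#' row is constant are undefined (`NA`) and never enter hit ranking.
#'
#' @param a,b Log-profile matrices over identical samples.
#' @return Matrix of correlations, rows of `a` x rows of `b`.
#' @export
pearson_cross <- function(a, b) {
  if (!identical(colnames(a), colnames(b))) {
    stop("sample ids of the two tables differ (set or order)", call. = FALSE)
  }
  if (ncol(a) < 3) stop("need at least 3 samples", call. = FALSE)
  cross_correlate_rows(a, b)
}

#' Best and second-best hits from a correlation table
#'
#' For every query, candidates are sorted by decreasing correlation with
#' ties broken by ascending candidate id; the best and second-best are
#' recorded and the best is tested against the cutoff (inclusive:
#' `best_r >= cutoff` passes). Undefined correlations are excluded, so a
#' constant profile can never be a hit; a query with no defined correlation
#' yields a result with missing hits that fails the cutoff.
#'
#' @param corr Correlation table from [pearson_cross()].
#' @param cutoff Passing threshold on the best correlation (default 0.65).
#' @param direction `"query_rows"` treats each row as a query over column
#'   candidates; `"query_cols"` the transpose.
#' @return data.frame with one row per query: `query_id`, `best_id`,
#'   `best_r`, `second_id`, `second_r`, `passes_cutoff`, `n_candidates`.
#' @export
best_hits <- function(corr, cutoff = 0.65,
                      direction = c("query_rows", "query_cols")) {
  direction <- match.arg(direction)
  if (direction == "query_cols") corr <- t(corr)
  if (nrow(corr) == 0 || ncol(corr) == 0) stop("empty correlation table", call. = FALSE)
  cand_ids <- colnames(corr)
  res <- lapply(seq_len(nrow(corr)), function(i) {
    r <- corr[i, ]
    ok <- !is.na(r)
    ord <- order(-r[ok], cand_ids[ok])
    ids <- cand_ids[ok][ord]
    vals <- r[ok][ord]
    data.frame(
      query_id = rownames(corr)[i],
      best_id = if (length(ids) >= 1) ids[1] else NA_character_,
      best_r = if (length(ids) >= 1) vals[1] else NA_real_,
      second_id = if (length(ids) >= 2) ids[2] else NA_character_,
      second_r = if (length(ids) >= 2) vals[2] else NA_real_,
      passes_cutoff = length(ids) >= 1 && vals[1] >= cutoff,
      n_candidates = sum(ok),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
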