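# OTU abundance tables: either parsed from a QIIME classic table
# (io_formats) or tallied from per-sample best-hit alignments of shotgun
# reads against OTU consensus sequences.

#' Tally best-hit alignments into an OTU count table
#'
#' Counts, per (OTU, sample), the distinct read ids whose best hit is that
#' OTU. The full OTU and sample universes are explicit inputs so that
#' zero-count rows and columns are representable (the prevalence filter
#' needs the complete table shape). Read ids are scoped per sample.
#'
#' @param hits data.frame with columns `sample_id`, `read_id`,
#'   `reference_id` (see [read_alignment_hits()]).
#' @param otu_ids Complete ordered OTU reference id list.
#' @param sample_ids Complete ordered sample id list.
#' @return Count matrix of shape `length(otu_ids)` x `length(sample_ids)`.
#' @export
counts_from_alignments <- function(hits, otu_ids, sample_ids) {
  if (anyDuplicated(otu_ids) || anyDuplicated(sample_ids)) {
    stop("otu_ids and sample_ids must be unique", call. = FALSE)
  }
  hits <- unique(hits[, c("sample_id", "read_id", "reference_id")])
  key <- paste(hits$sample_id, hits$read_id, sep = "\r")
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1]
    stop("read '", sub(".*\r", "", k), "' in sample '", sub("\r.*", "", k),
         "' has conflicting best hits", call. = FALSE)
  }
  unknown_ref <- setdiff(unique(hits$reference_id), otu_ids)
  if (length(unknown_ref)) {
    stop("unknown reference id(s): ",
         paste(utils::head(unknown_ref, 5), collapse = ", "), call. = FALSE)
  }
  unknown_smp <- setdiff(unique(hits$sample_id), sample_ids)
  if (length(unknown_smp)) {
    stop("unknown sample id(s): ",
         paste(utils::head(unknown_smp, 5), collapse = ", "), call. = FALSE)
  }
  m <- matrix(0, nrow = length(otu_ids), ncol = length(sample_ids),
              dimnames = list(otu_ids, sample_ids))
  if (nrow(hits)) {
    tab <- table(factor(hits$reference_id, levels = otu_ids),
                 factor(hits$sample_id, levels = sample_ids))
    m[] <- as.numeric(tab)
  }
  m
}

#' Row-concatenate two count matrices
#'
#' Row id sets must be disjoint and sample id sets identical (order of `a`
#' is kept); both row orders are preserved.
#'
#' @param a,b Count matrices over the same samples.
#' @return Combined matrix with `nrow(a) + nrow(b)` rows.
#' @export
merge_tables <- function(a, b) {
  if (nrow(b) == 0) return(a)
  if (nrow(a) == 0) return(b)
  if (!setequal(colnames(a), colnames(b))) {
    stop("sample id sets differ", call. = FALSE)
  }
  overlap <- intersect(rownames(a), rownames(b))
  if (length(overlap)) {
    stop("overlapping row id(s): ",
         paste(utils::head(overlap, 5), collapse = ", "), call. = FALSE)
  }
  rbind(a, b[, colnames(a), drop = FALSE])
}
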