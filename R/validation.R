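# Quantifying linking quality: genus concordance of linked pairs, cutoff
# calibration curves, second-hit agreement, gene-cluster-to-MGS assignment,
# and precision/recall scoring against a synthetic answer key.

# Canonical genus form for comparison: whitespace-stripped, lower-cased.
canon_genus <- function(g) tolower(trimws(g))

#' Resolve one usable genus per entity from an annotation table
#'
#' An annotation is usable iff a genus is present and the source is not RDP,
#' or is RDP with classification confidence at or above
#' `min_rdp_confidence`. When usable annotations from multiple sources
#' disagree (case-insensitively, after whitespace stripping) the entity is
#' treated as unannotated.
#'
#' @param annotations Annotation data.frame (see [annotation_table()]).
#' @param min_rdp_confidence Minimum RDP confidence (default 0.80).
#' @return Named character vector: entity id -> genus (`NA` dropped).
#' @export
resolve_genus <- function(annotations, min_rdp_confidence = 0.80) {
  a <- annotations[!is.na(annotations$genus), , drop = FALSE]
  usable <- a$source != "RDP" |
    (!is.na(a$confidence) & a$confidence >= min_rdp_confidence)
  a <- a[usable, , drop = FALSE]
  if (nrow(a) == 0) return(stats::setNames(character(0), character(0)))
  by_entity <- split(a$genus, a$entity_id)
  out <- vapply(by_entity, function(g) {
    u <- unique(canon_genus(g))
    if (length(u) == 1) g[1] else NA_character_  # conflicting sources: void
  }, character(1))
  out[!is.na(out)]
}

#' Genus concordance of passing links
#'
#' For links that pass the correlation cutoff, compares the genus of the
#' query with the genus of its best hit. Agreement is case-insensitive
#' string equality of genus names after whitespace stripping. Accuracy is
#' computed over links where both sides have a usable genus, and is missing
#' (not 0) when no link is annotated on both sides.
#'
#' @param links data.frame of passing link results (see [best_hits()]).
#' @param query_annotations,hit_annotations Annotation tables for the query
#'   and candidate entities.
#' @param min_rdp_confidence Minimum RDP confidence (default 0.80).
#' @return List with `n_links`, `n_annotated`, `n_agree`, `accuracy`.
#' @export
genus_concordance <- function(links, query_annotations, hit_annotations,
                              min_rdp_confidence = 0.80) {
  if (any(!links$passes_cutoff)) {
    stop("genus_concordance expects only passing links", call. = FALSE)
  }
  qg <- resolve_genus(query_annotations, min_rdp_confidence)
  hg <- resolve_genus(hit_annotations, min_rdp_confidence)
  q <- qg[links$query_id]
  h <- hg[links$best_id]
  annotated <- !is.na(q) & !is.na(h)
  agree <- annotated & canon_genus(q) == canon_genus(h)
  n_annotated <- sum(annotated)
  list(n_links = nrow(links),
       n_annotated = n_annotated,
       n_agree = sum(agree),
       accuracy = if (n_annotated > 0) sum(agree) / n_annotated else NA_real_)
}

#' Cutoff calibration curve
#'
#' For each cutoff in an ascending grid, counts the links whose best
#' correlation reaches the cutoff, how many of those are correct/incorrect
#' (links with missing truth are excluded from both), and the resulting
#' accuracy. Cutoff choice is left to the caller; see
#' [pick_cutoff()] for the accuracy-floor helper.
#'
#' @param links data.frame of link results with a `best_r` column.
#' @param agree Logical vector parallel to `links`: is the link correct
#'   (`NA` = unknown/unannotated).
#' @param cutoff_grid Ascending numeric grid of cutoffs.
#' @return data.frame with columns `cutoff`, `n_passing`, `n_correct`,
#'   `n_incorrect`, `accuracy`.
#' @export
calibrate_cutoff <- function(links, agree, cutoff_grid) {
  if (length(cutoff_grid) == 0) stop("empty cutoff grid", call. = FALSE)
  if (is.unsorted(cutoff_grid)) stop("cutoff grid must be ascending", call. = FALSE)
  if (length(agree) != nrow(links)) stop("agree length mismatch", call. = FALSE)
  rows <- lapply(cutoff_grid, function(cc) {
    pass <- !is.na(links$best_r) & links$best_r >= cc
    correct <- sum(pass & !is.na(agree) & agree)
    incorrect <- sum(pass & !is.na(agree) & !agree)
    data.frame(cutoff = cc, n_passing = sum(pass), n_correct = correct,
               n_incorrect = incorrect,
               accuracy = if (correct + incorrect > 0) {
                 correct / (correct + incorrect)
               } else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Smallest cutoff reaching an accuracy floor
#'
#' Scans a calibration curve in ascending cutoff order and returns the
#' smallest cutoff whose accuracy is defined and at least `accuracy_floor`,
#' or `NA` if none qualifies.
#'
#' @param curve data.frame from [calibrate_cutoff()].
#' @param accuracy_floor Required accuracy in `[0, 1]`.
#' @return A single cutoff value or `NA`.
#' @export
pick_cutoff <- function(curve, accuracy_floor) {
  ok <- !is.na(curve$accuracy) & curve$accuracy >= accuracy_floor
  if (any(ok)) curve$cutoff[which(ok)[1]] else NA_real_
}

#' Agreement between first and second hits
#'
#' Counts links where the second hit also reaches the cutoff, where both
#' hits carry a usable genus, and where those genera match — the multi-hit
#' ambiguity expected when closely related organisms share abundance
#' profiles.
#'
#' @param links data.frame of link results.
#' @param annotations Annotation table covering the candidate entities.
#' @param cutoff Correlation cutoff (default 0.65).
#' @param min_rdp_confidence Minimum RDP confidence (default 0.80).
#' @return List with `n_both_pass`, `n_both_annotated`, `n_same_genus`.
#' @export
second_hit_agreement <- function(links, annotations, cutoff = 0.65,
                                 min_rdp_confidence = 0.80) {
  same_id <- !is.na(links$best_id) & !is.na(links$second_id) &
    links$best_id == links$second_id
  if (any(same_id)) {
    stop("best and second hit are the same entity for query '",
         links$query_id[same_id][1],
         "'; candidate lists must be deduplicated upstream", call. = FALSE)
  }
  g <- resolve_genus(annotations, min_rdp_confidence)
  both_pass <- !is.na(links$second_r) & links$second_r >= cutoff &
    !is.na(links$best_r) & links$best_r >= cutoff
  g1 <- g[links$best_id]
  g2 <- g[links$second_id]
  both_annot <- both_pass & !is.na(g1) & !is.na(g2)
  same <- both_annot & canon_genus(g1) == canon_genus(g2)
  list(n_both_pass = sum(both_pass),
       n_both_annotated = sum(both_annot),
       n_same_genus = sum(same))
}

#' Assign a gene cluster to an MGS by majority membership
#'
#' Computes, for every MGS, the fraction of the cluster's genes that belong
#' to it, and returns the top MGS iff its fraction is at least
#' `min_fraction` (inclusive). A tie at the maximum is ambiguous and
#' returns `NA`, as does a top fraction below the threshold. Invariant to
#' gene order.
#'
#' @param cluster_genes Non-empty character vector of gene ids.
#' @param membership Membership table (`gene_id`, `mgs_id`).
#' @param min_fraction Minimum fraction of cluster genes in the MGS
#'   (default 0.70).
#' @return A single MGS id, or `NA` if none qualifies or the top is tied.
#' @export
assign_cluster_to_mgs <- function(cluster_genes, membership,
                                  min_fraction = 0.70) {
  cluster_genes <- unique(cluster_genes)
  if (length(cluster_genes) == 0) stop("empty gene cluster", call. = FALSE)
  hit <- membership[membership$gene_id %in% cluster_genes, , drop = FALSE]
  if (nrow(hit) == 0) return(NA_character_)
  frac <- table(hit$mgs_id) / length(cluster_genes)
  top <- max(frac)
  if (top < min_fraction) return(NA_character_)
  winners <- names(frac)[frac == top]
  if (length(winners) > 1) return(NA_character_)  # ambiguous tie
  winners
}

#' Score links against a synthetic answer key
#'
#' A passing link is correct iff its best hit is the MGS of the same
#' ground-truth organism as the query OTU. Precision is correct/passing
#' (missing when nothing passes); recall is correct/number of true pairs.
#'
#' @param links data.frame of link results (queries are OTU ids).
#' @param truth Synthetic truth object from [generate_community()], or a
#'   data.frame of true `(otu_id, mgs_id)` pairs as from [truth_links()].
#' @return List with `precision`, `recall`, `n_true_pairs`, `n_passing`,
#'   `n_correct`.
#' @export
evaluate_recovery <- function(links, truth) {
  pairs <- if (is.data.frame(truth)) truth else truth_links(truth)
  expected <- stats::setNames(pairs$mgs_id, pairs$otu_id)
  pass <- links[links$passes_cutoff, , drop = FALSE]
  correct <- sum(!is.na(expected[pass$query_id]) &
                   expected[pass$query_id] == pass$best_id)
  n_pass <- nrow(pass)
  list(precision = if (n_pass > 0) correct / n_pass else NA_real_,
       recall = if (nrow(pairs) > 0) correct / nrow(pairs) else NA_real_,
       n_true_pairs = nrow(pairs),
       n_passing = n_pass,
       n_correct = correct)
}
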