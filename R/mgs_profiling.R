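# Per-MGS abundance profiles: within each MGS, genes are ranked by their
# connectivity in a Spearman co-abundance network; the most connected
# ("tracer") genes carry the MGS's abundance signal as their mean profile.
# Accessory genes, whose presence varies across strains, are less connected
# to the core and are demoted by this ranking.

#' Gene connectivity within one MGS
#'
#' For each member gene, counts how many other member genes have a Spearman
#' correlation at or above `rho_threshold` with it, on the normalized
#' abundance matrix. Constant-profile genes have no defined correlation with
#' anything: they contribute no edges and get degree 0, flagged in the
#' `constant` column.
#'
#' @param abundance Abundance matrix restricted to one MGS's member genes
#'   (genes x samples).
#' @param rho_threshold Minimum Spearman rho for an edge (inclusive;
#'   default 0.7).
#' @return data.frame with columns `gene_id`, `degree`, `constant`.
#' @export
gene_connectivity <- function(abundance, rho_threshold = 0.7) {
  if (!is.matrix(abundance) || is.null(rownames(abundance))) {
    stop("abundance must be a matrix with gene row names", call. = FALSE)
  }
  if (nrow(abundance) < 2) {
    warning("MGS has fewer than 2 genes in the matrix; degree is 0",
            call. = FALSE)
    return(data.frame(gene_id = rownames(abundance),
                      degree = integer(nrow(abundance)),
                      constant = apply(abundance, 1, function(x) length(unique(x)) == 1),
                      stringsAsFactors = FALSE))
  }
  ranked <- rank_rows(abundance)
  rho <- cross_correlate_rows(ranked, ranked)
  diag(rho) <- NA_real_
  edge <- !is.na(rho) & rho >= rho_threshold
  constant <- apply(standardize_rows(abundance), 1, function(x) all(is.na(x)))
  data.frame(gene_id = rownames(abundance),
             degree = as.integer(rowSums(edge)),
             constant = as.logical(constant),
             stringsAsFactors = FALSE)
}

#' Select tracer genes by connectivity
#'
#' Sorts genes by decreasing degree, ties broken by ascending gene id (so
#' the selection is deterministic across runs and platforms), and returns
#' the first `min(k, n)`.
#'
#' @param connectivity data.frame from [gene_connectivity()].
#' @param k Number of tracers to select (default 50).
#' @return Character vector of tracer gene ids.
#' @export
select_tracers <- function(connectivity, k = 50) {
  if (nrow(connectivity) == 0) stop("empty connectivity table", call. = FALSE)
  if (k < 1) stop("k must be positive", call. = FALSE)
  ord <- order(-connectivity$degree, connectivity$gene_id)
  connectivity$gene_id[ord][seq_len(min(k, nrow(connectivity)))]
}

#' Build MGS models (members + tracers) from a membership table
#'
#' Runs [gene_connectivity()] and [select_tracers()] for every MGS whose
#' genes appear in the abundance matrix. Member genes absent from the matrix
#' are ignored; an MGS with no gene present is dropped with a warning.
#'
#' @param abundance Normalized gene abundance matrix (genes x samples).
#' @param membership Membership table (`gene_id`, `mgs_id`).
#' @param k Tracers per MGS (default 50).
#' @param rho_threshold Spearman edge threshold (default 0.7).
#' @return Named list of MGS models; each model is a list with `mgs_id`,
#'   `member_genes`, `tracer_genes`.
#' @export
build_mgs_models <- function(abundance, membership, k = 50, rho_threshold = 0.7) {
  membership <- membership_table(membership$gene_id, membership$mgs_id)
  present <- membership[membership$gene_id %in% rownames(abundance), ]
  lost <- setdiff(unique(membership$mgs_id), unique(present$mgs_id))
  if (length(lost)) {
    warning("MGS with no genes in the abundance matrix dropped: ",
            paste(lost, collapse = ", "), call. = FALSE)
  }
  by_mgs <- split(present$gene_id, present$mgs_id)
  models <- lapply(names(by_mgs), function(m) {
    genes <- sort(by_mgs[[m]])
    conn <- gene_connectivity(abundance[genes, , drop = FALSE], rho_threshold)
    list(mgs_id = m,
         member_genes = genes,
         tracer_genes = select_tracers(conn, k))
  })
  stats::setNames(models, names(by_mgs))
}

#' MGS abundance as the mean tracer vector
#'
#' The abundance profile of each MGS is the arithmetic mean, over its tracer
#' genes, of the genes' normalized abundance in each sample. Rows are MGS,
#' columns samples; columns need not sum to 1.
#'
#' @param abundance Normalized gene abundance matrix (genes x samples).
#' @param models List of MGS models from [build_mgs_models()].
#' @return Matrix (MGS x samples) of mean tracer abundances.
#' @export
mgs_abundance <- function(abundance, models) {
  if (length(models) == 0) stop("no MGS models", call. = FALSE)
  rows <- lapply(models, function(mod) {
    tr <- mod$tracer_genes
    if (length(tr) == 0) {
      stop("MGS '", mod$mgs_id, "' has an empty tracer list", call. = FALSE)
    }
    missing <- setdiff(tr, rownames(abundance))
    if (length(missing)) {
      stop("MGS '", mod$mgs_id, "': tracer gene(s) missing from matrix: ",
           paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
    }
    colMeans(abundance[tr, , drop = FALSE])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- vapply(models, `[[`, character(1), "mgs_id")
  colnames(out) <- colnames(abundance)
  out
}
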