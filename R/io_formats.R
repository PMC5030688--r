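# Readers and writers for the on-disk artifacts the pipeline touches.
# Count matrices are plain base-R matrices with unique row and column names;
# typed tables (gene lengths, MGS membership, annotations, alignment hits)
# are data.frames with fixed column names. Everything is tab-separated text.

#' Validate a count matrix
#'
#' Checks the invariants every count matrix in the pipeline must satisfy:
#' rectangular numeric matrix, unique non-empty row and column names, all
#' values finite and non-negative, and (optionally) integral.
#'
#' @param m A numeric matrix with row and column names.
#' @param integral If `TRUE` (default), fractional values are an error.
#' @param what Label used in error messages.
#' @return `m`, invisibly, with storage mode `double`.
#' @export
validate_count_matrix <- function(m, integral = TRUE, what = "count matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must have row and column names", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop(what, ": duplicate row identifier '",
         rownames(m)[duplicated(rownames(m))][1], "'", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop(what, ": duplicate sample identifier '",
         colnames(m)[duplicated(colnames(m))][1], "'", call. = FALSE)
  }
  if (any(!is.finite(m))) stop(what, " contains non-finite values", call. = FALSE)
  if (any(m < 0)) stop(what, " contains negative values", call. = FALSE)
  if (integral && any(m != round(m))) {
    bad <- which(m != round(m), arr.ind = TRUE)[1, ]
    stop(what, ": fractional value at row '", rownames(m)[bad[1]],
         "', sample '", colnames(m)[bad[2]], "'", call. = FALSE)
  }
  storage.mode(m) <- "double"
  invisible(m)
}

# Split a raw TSV line into fields. Trailing empty fields are kept so ragged
# rows are detected rather than silently padded.
split_tsv <- function(lines) strsplit(lines, "\t", fixed = TRUE)

#' Read a QIIME classic OTU table
#'
#' Parses the tab-delimited "classic" OTU table dialect: optional leading
#' comment lines starting with `#`, then a header row whose first field is
#' `#OTU ID`, then one row per OTU. A trailing taxonomy column (header
#' `taxonomy` or `Consensus Lineage`, case-insensitive) is stripped from the
#' counts and returned as a genus annotation table; the genus is the token
#' following `g__` in a Greengenes-style lineage string, missing when empty.
#'
#' @param path Path to the OTU table.
#' @return A list with elements `counts` (OTU x sample integer count matrix)
#'   and `taxonomy` (an annotation data.frame with columns `entity_id`,
#'   `genus`, `source`, `confidence`, or `NULL` when the file has no
#'   taxonomy column), plus `n_comment_lines`, the number of leading comment
#'   lines skipped.
#' @export
read_qiime_otu_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  header_at <- which(startsWith(lines, "#OTU ID"))
  if (length(header_at) == 0) {
    stop("not a QIIME classic OTU table: no '#OTU ID' header row in ", path,
         call. = FALSE)
  }
  header_at <- header_at[1]
  n_comment <- sum(startsWith(lines[seq_len(header_at - 1)], "#"))
  if (n_comment < header_at - 1) {
    stop("unexpected non-comment line before the '#OTU ID' header", call. = FALSE)
  }
  header <- split_tsv(lines[header_at])[[1]]
  tax_col <- which(tolower(trimws(header)) %in% c("taxonomy", "consensus lineage"))
  # taxonomy is recognized by header name only, and only as the last column
  tax_col <- tax_col[tax_col == length(header)]
  sample_cols <- setdiff(seq_along(header)[-1], tax_col)
  sample_ids <- header[sample_cols]

  body <- lines[-seq_len(header_at)]
  rows <- split_tsv(body)
  n_fields <- lengths(rows)
  if (any(n_fields != length(header))) {
    bad <- which(n_fields != length(header))[1]
    stop("row ", bad, " has ", n_fields[bad], " fields; header has ",
         length(header), call. = FALSE)
  }
  otu_ids <- vapply(rows, `[[`, character(1), 1)
  if (anyDuplicated(otu_ids)) {
    stop("duplicate OTU id '", otu_ids[duplicated(otu_ids)][1], "'", call. = FALSE)
  }
  counts <- matrix(0, nrow = length(rows), ncol = length(sample_ids),
                   dimnames = list(otu_ids, sample_ids))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][sample_cols]
    vals <- suppressWarnings(as.numeric(cells))
    if (anyNA(vals)) {
      j <- which(is.na(vals))[1]
      stop("non-numeric count '", cells[j], "' at OTU '", otu_ids[i],
           "', sample '", sample_ids[j], "'", call. = FALSE)
    }
    counts[i, ] <- vals
  }
  validate_count_matrix(counts, integral = TRUE, what = "OTU table")

  taxonomy <- NULL
  if (length(tax_col) == 1) {
    lineage <- vapply(rows, `[[`, character(1), tax_col)
    genus <- genus_from_lineage(lineage)
    taxonomy <- annotation_table(entity_id = otu_ids, genus = genus,
                                 source = "other", confidence = NA_real_)
  }
  list(counts = counts, taxonomy = taxonomy, n_comment_lines = n_comment)
}

#' Extract the genus from a Greengenes-style lineage string
#'
#' Takes the token after `g__` up to the next `;`; an absent or empty token
#' yields `NA`.
#'
#' @param lineage Character vector of lineage strings.
#' @return Character vector of genus names, `NA` where missing.
#' @export
genus_from_lineage <- function(lineage) {
  m <- regmatches(lineage, regexpr("g__[^;]*", lineage))
  out <- rep(NA_character_, length(lineage))
  hit <- grepl("g__", lineage, fixed = TRUE)
  out[hit] <- trimws(sub("^g__", "", m))
  out[!is.na(out) & !nzchar(out)] <- NA_character_
  out
}

#' Read a plain TSV count matrix
#'
#' First column holds entity identifiers, remaining columns one sample each,
#' with a header row. Round-trips with [write_count_matrix()].
#'
#' @param path Path to the TSV file.
#' @param integral Require integer values (default `TRUE`).
#' @return A count matrix (entities x samples).
#' @export
read_count_matrix <- function(path, integral = TRUE) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("count matrix needs an id column and >= 1 sample", call. = FALSE)
  ids <- df[[1]]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(df)[-1])))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric value at row '", ids[bad[1]], "', sample '",
         colnames(num)[bad[2]], "'", call. = FALSE)
  }
  validate_count_matrix(num, integral = integral)
  num
}

#' Write a count matrix as TSV
#'
#' Emits a header whose first field names the entity column, tab separators
#' and `\n` line endings.
#'
#' @param m Count matrix.
#' @param path Output path.
#' @param id_col Name for the identifier column (default `"id"`).
#' @export
write_count_matrix <- function(m, path, id_col = "id") {
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(rownames(m)[i], format(m[i, ], trim = TRUE, scientific = FALSE)),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path, sep = "\n")
  invisible(path)
}

#' Read a gene length table
#'
#' Two-column TSV (`gene_id`, `length_nt`) with header. Lengths must be
#' strictly positive integers; duplicate genes are rejected.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `gene_id`, `length_nt`.
#' @export
read_gene_lengths <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (ncol(df) < 2) stop("gene length table needs 2 columns", call. = FALSE)
  out <- data.frame(gene_id = as.character(df[[1]]),
                    length_nt = as.numeric(df[[2]]),
                    stringsAsFactors = FALSE)
  gene_length_table(out$gene_id, out$length_nt)
}

#' Construct and validate a gene length table
#'
#' @param gene_id Character vector of gene identifiers.
#' @param length_nt Positive integer gene lengths in nucleotides.
#' @return data.frame with columns `gene_id`, `length_nt`.
#' @export
gene_length_table <- function(gene_id, length_nt) {
  if (anyDuplicated(gene_id)) {
    stop("duplicate gene id '", gene_id[duplicated(gene_id)][1],
         "' in gene length table", call. = FALSE)
  }
  if (any(!is.finite(length_nt)) || any(length_nt <= 0) ||
      any(length_nt != round(length_nt))) {
    stop("gene lengths must be positive integers", call. = FALSE)
  }
  data.frame(gene_id = as.character(gene_id), length_nt = as.numeric(length_nt),
             stringsAsFactors = FALSE)
}

#' Read an MGS membership table
#'
#' Two-column TSV (`gene_id`, `mgs_id`) with header. A gene listed under two
#' different MGS is a validation error; exact duplicate rows are collapsed.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `gene_id`, `mgs_id`.
#' @export
read_membership <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("membership table needs 2 columns", call. = FALSE)
  membership_table(df[[1]], df[[2]])
}

#' Construct and validate an MGS membership table
#'
#' @param gene_id Character vector of gene identifiers.
#' @param mgs_id Character vector of MGS identifiers, parallel to `gene_id`.
#' @return data.frame with columns `gene_id`, `mgs_id`, one row per gene.
#' @export
membership_table <- function(gene_id, mgs_id) {
  df <- unique(data.frame(gene_id = as.character(gene_id),
                          mgs_id = as.character(mgs_id),
                          stringsAsFactors = FALSE))
  dup <- df$gene_id[duplicated(df$gene_id)]
  if (length(dup)) {
    stop("gene '", dup[1], "' is assigned to more than one MGS", call. = FALSE)
  }
  df
}

ANNOTATION_SOURCES <- c("SILVA", "NCBI_nt", "NCBI_WGS", "RDP", "other")

#' Construct and validate a taxonomic annotation table
#'
#' Each row annotates one entity (OTU or MGS) with a genus from one source.
#' RDP rows must carry a classification confidence in `[0, 1]`; other
#' sources may leave it missing. An entity may appear once per source.
#'
#' @param entity_id Character vector of entity identifiers.
#' @param genus Character vector of genus names (`NA` = unannotated).
#' @param source Annotation source, one of `"SILVA"`, `"NCBI_nt"`,
#'   `"NCBI_WGS"`, `"RDP"`, `"other"`.
#' @param confidence Numeric confidence in `[0, 1]` or `NA`.
#' @return data.frame with columns `entity_id`, `genus`, `source`,
#'   `confidence`.
#' @export
annotation_table <- function(entity_id, genus, source = "other",
                             confidence = NA_real_) {
  if (length(entity_id) == 0) {
    return(data.frame(entity_id = character(0), genus = character(0),
                      source = character(0), confidence = numeric(0),
                      stringsAsFactors = FALSE))
  }
  df <- data.frame(entity_id = as.character(entity_id),
                   genus = as.character(genus),
                   source = as.character(source),
                   confidence = as.numeric(confidence),
                   stringsAsFactors = FALSE)
  bad_src <- setdiff(unique(df$source), ANNOTATION_SOURCES)
  if (length(bad_src)) {
    stop("unknown annotation source '", bad_src[1], "'", call. = FALSE)
  }
  no_conf <- df$source == "RDP" & !is.na(df$genus) & is.na(df$confidence)
  if (any(no_conf)) {
    stop("RDP annotation for '", df$entity_id[no_conf][1],
         "' lacks a confidence value", call. = FALSE)
  }
  ok <- is.na(df$confidence) | (df$confidence >= 0 & df$confidence <= 1)
  if (!all(ok)) stop("confidence values must lie in [0, 1]", call. = FALSE)
  df
}

#' Read a taxonomic annotation table
#'
#' TSV with header and columns `entity_id`, `genus`, `source`, `confidence`
#' (confidence may be empty except for RDP rows).
#'
#' @param path Path to the TSV file.
#' @return Validated annotation data.frame.
#' @export
read_annotations <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character", na.strings = c("NA", ""))
  need <- c("entity_id", "genus", "source", "confidence")
  if (!all(need %in% colnames(df))) {
    stop("annotation table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  annotation_table(df$entity_id, df$genus, df$source, as.numeric(df$confidence))
}

#' Read best-hit alignment records
#'
#' Three-column TSV (`sample_id`, `read_id`, `reference_id`) with header.
#' Best-hit semantics require at most one reference per (sample, read);
#' a conflicting duplicate is an error.
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns `sample_id`, `read_id`, `reference_id`.
#' @export
read_alignment_hits <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                          colClasses = "character")
  need <- c("sample_id", "read_id", "reference_id")
  if (!all(need %in% colnames(df))) {
    stop("alignment hits need columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  hits <- unique(df[, need])
  key <- paste(hits$sample_id, hits$read_id, sep = "\r")
  if (anyDuplicated(key)) {
    k <- key[duplicated(key)][1]
    stop("read '", sub(".*\r", "", k), "' in sample '", sub("\r.*", "", k),
         "' maps to more than one reference (best-hit violation)", call. = FALSE)
  }
  hits
}

#' Write a simple data.frame as TSV
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE, na = "NA")
  invisible(path)
}
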