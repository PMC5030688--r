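# Shared fixtures: tiny matrices and on-disk TSV files built in code.

tmp_tsv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

random_count_matrix <- function(nr, nc, max = 50, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(sample(0:max, nr * nc, replace = TRUE), nrow = nr,
         dimnames = list(sprintf("g%02d", seq_len(nr)),
                         sprintf("s%02d", seq_len(nc))))
}

# Independent Pearson oracle: the textbook formula written with explicit
# sums, no shared code with the package implementation.
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  num <- sum((x - mx) * (y - my))
  den <- sqrt(sum((x - mx)^2)) * sqrt(sum((y - my)^2))
  if (den == 0) NA_real_ else num / den
}

oracle_spearman <- function(x, y) {
  oracle_pearson(rank(x, ties.method = "average"),
                 rank(y, ties.method = "average"))
}

# Exhaustive best/second-hit oracle: repeatedly scan for the maximum,
# breaking ties by the smallest id, never sorting.
oracle_best_two <- function(r, ids) {
  ok <- !is.na(r)
  r <- r[ok]; ids <- ids[ok]
  pick <- function(r, ids) {
    if (length(r) == 0) return(NULL)
    top <- r == max(r)
    list(id = min(ids[top]), r = max(r))
  }
  first <- pick(r, ids)
  if (is.null(first)) return(list(best = NULL, second = NULL))
  drop <- ids == first$id
  list(best = first, second = pick(r[!drop], ids[!drop]))
}

# A small community + pipeline run used by several test files.
small_community <- function(seed = 42, ...) {
  cfg <- community_config(n_organisms = 12, n_samples = 60,
                          genes_per_organism = c(20, 30),
                          gene_length_range = c(300, 3000),
                          otus_per_organism = c(1, 2),
                          shotgun_depth = 5e4, amplicon_depth = 1e4,
                          seed = seed, ...)
  generate_community(cfg)
}
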