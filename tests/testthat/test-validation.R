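# Helper to build a links data.frame quickly.
mk_links <- function(query, best, best_r, second = NA, second_r = NA,
                     passes = TRUE) {
  data.frame(query_id = query, best_id = best, best_r = best_r,
             second_id = second, second_r = second_r,
             passes_cutoff = passes,
             n_candidates = 5L, stringsAsFactors = FALSE)
}

test_that("genus resolution applies the RDP confidence rule and voids conflicts", {
  ann <- annotation_table(
    entity_id = c("a", "b", "c", "c", "d", "e"),
    genus = c("Dialister", "Prevotella", "Blautia", "Roseburia", NA, "Faecalibacterium"),
    source = c("RDP", "RDP", "SILVA", "NCBI_nt", "SILVA", "SILVA"),
    confidence = c(0.79, 0.95, NA, NA, NA, NA))
  g <- resolve_genus(ann)
  expect_false("a" %in% names(g))          # RDP below 0.80
  expect_equal(g[["b"]], "Prevotella")     # RDP at/above 0.80
  expect_false("c" %in% names(g))          # multi-source disagreement
  expect_false("d" %in% names(g))          # no genus
  expect_equal(g[["e"]], "Faecalibacterium")
  # agreeing sources are fine, case-insensitively
  ann2 <- annotation_table(c("x", "x"), c("Blautia", " blautia "),
                           c("SILVA", "NCBI_nt"), NA)
  expect_equal(resolve_genus(ann2)[["x"]], "Blautia")
})

test_that("genus concordance counts agreement over annotated links only", {
  links <- mk_links(paste0("q", 1:4), paste0("h", 1:4), c(0.9, 0.8, 0.7, 0.7))
  qa <- annotation_table(paste0("q", 1:4),
                         c("Dialister", "Blautia", NA, "Roseburia"), "SILVA", NA)
  ha <- annotation_table(paste0("h", 1:4),
                         c("dialister ", "Prevotella", "Blautia", NA), "SILVA", NA)
  cs <- genus_concordance(links, qa, ha)
  expect_equal(cs$n_links, 4)
  expect_equal(cs$n_annotated, 2)   # q3 and q4 lack a genus on one side
  expect_equal(cs$n_agree, 1)       # Dialister matches case-insensitively
  expect_equal(cs$accuracy, 0.5)
  expect_true(cs$n_agree <= cs$n_annotated && cs$n_annotated <= cs$n_links)
  # empty denominator: accuracy missing, not zero
  none <- genus_concordance(links, annotation_table(character(0), character(0)),
                            ha)
  expect_true(is.na(none$accuracy))
  expect_error(genus_concordance(mk_links("q", "h", 0.2, passes = FALSE), qa, ha),
               "passing")
})

test_that("calibration curve counts by cutoff and keeps n_passing monotone", {
  links <- mk_links(paste0("q", 1:4), paste0("h", 1:4), c(0.9, 0.8, 0.7, 0.6))
  agree <- c(TRUE, FALSE, TRUE, TRUE)
  curve <- calibrate_cutoff(links, agree, c(0.65, 0.75))
  expect_equal(curve$n_passing, c(3, 2))
  expect_equal(curve$n_correct, c(2, 1))
  expect_equal(curve$n_incorrect, c(1, 1))
  expect_equal(curve$accuracy, c(2 / 3, 0.5))
  expect_true(all(diff(curve$n_passing) <= 0))
  expect_error(calibrate_cutoff(links, agree, numeric(0)), "empty")
  expect_error(calibrate_cutoff(links, agree, c(0.7, 0.6)), "ascending")
  # all-correct links are perfect at every cutoff below their r
  perfect <- calibrate_cutoff(mk_links(c("a", "b"), c("x", "y"), c(0.95, 0.92)),
                              c(TRUE, TRUE), c(0.5, 0.7))
  expect_equal(perfect$accuracy, c(1, 1))
  expect_equal(pick_cutoff(curve, 0.6), 0.65)
  expect_true(is.na(pick_cutoff(curve, 0.9)))
})

test_that("second-hit agreement counts double-passing annotated pairs", {
  links <- mk_links(query = paste0("q", 1:4),
                    best = c("h1", "h2", "h3", "h4"),
                    best_r = c(0.9, 0.9, 0.9, 0.9),
                    second = c("h5", "h6", "h7", NA),
                    second_r = c(0.8, 0.7, 0.3, NA))
  ann <- annotation_table(paste0("h", 1:7),
                          c("Blautia", "Dialister", "x", "y", "blautia",
                            "Roseburia", "z"), "SILVA", NA)
  s <- second_hit_agreement(links, ann, cutoff = 0.65)
  expect_equal(s$n_both_pass, 2)       # q1, q2 (q3 second below cutoff, q4 none)
  expect_equal(s$n_both_annotated, 2)
  expect_equal(s$n_same_genus, 1)      # Blautia == blautia for q1
  dup <- mk_links("q", "h1", 0.9, second = "h1", second_r = 0.8)
  expect_error(second_hit_agreement(dup, ann), "deduplicated")
})

test_that("cluster-to-MGS assignment is inclusive at the threshold and void on ties", {
  mem <- membership_table(paste0("g", 1:20),
                          rep(c("A", "B"), each = 10))
  expect_equal(assign_cluster_to_mgs(paste0("g", 1:10), mem), "A")
  # 7 of 10 in A: exactly at 0.70, inclusive
  expect_equal(assign_cluster_to_mgs(paste0("g", c(1:7, 11:13)), mem), "A")
  # 6 of 10: below threshold
  expect_true(is.na(assign_cluster_to_mgs(paste0("g", c(1:6, 11:14)), mem)))
  # unknown genes dilute the fraction
  expect_true(is.na(assign_cluster_to_mgs(c(paste0("g", 1:7), paste0("u", 1:3)),
                                          mem, min_fraction = 0.71)))
  expect_error(assign_cluster_to_mgs(character(0), mem), "empty")
  # tie at the max is ambiguous, invariant to gene order
  tie_mem <- membership_table(paste0("g", 1:10), rep(c("A", "B"), each = 5))
  genes <- paste0("g", 1:10)
  expect_true(is.na(assign_cluster_to_mgs(genes, tie_mem, min_fraction = 0.5)))
  expect_true(is.na(assign_cluster_to_mgs(rev(genes), tie_mem, min_fraction = 0.5)))
})

test_that("recovery scoring computes precision and recall against truth pairs", {
  truth <- data.frame(otu_id = paste0("o", 1:10),
                      mgs_id = paste0("M", 1:10))
  links <- mk_links(paste0("o", 1:8),
                    c(paste0("M", 1:6), "M99", "M98"),
                    best_r = rep(0.9, 8))
  r <- evaluate_recovery(links, truth)
  expect_equal(r$precision, 6 / 8)
  expect_equal(r$recall, 6 / 10)
  expect_equal(r$n_true_pairs, 10)
  # perfect linking
  perfect <- mk_links(truth$otu_id, truth$mgs_id, rep(0.9, 10))
  expect_equal(evaluate_recovery(perfect, truth)$precision, 1)
  expect_equal(evaluate_recovery(perfect, truth)$recall, 1)
  # nothing passes: precision undefined, recall zero
  none <- mk_links("o1", "M1", 0.2, passes = FALSE)
  r0 <- evaluate_recovery(none, truth)
  expect_true(is.na(r0$precision))
  expect_equal(r0$recall, 0)
})
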