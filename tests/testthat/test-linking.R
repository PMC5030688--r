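test_that("log-ratio normalization follows the stated formula", {
  m <- matrix(c(1, 1), 2, 1, dimnames = list(c("a", "b"), "s1"))
  lp <- normalize_profiles(m)
  expect_equal(unname(lp[, 1]), rep(log10(0.5 + 1e-17), 2))
  # a zero maps exactly to log10(pseudocount) = -17 at the default
  z <- matrix(c(0, 5), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_equal(normalize_profiles(z)["a", 1], -17)
  expect_equal(formals(normalize_profiles)$pseudocount, 1e-17)
  expect_true(all(normalize_profiles(z) <= 0))
  expect_error(normalize_profiles(z, pseudocount = 0), "pseudocount")
  allzero <- matrix(c(1, 0, 2, 0), 2, 2,
                    dimnames = list(c("a", "b"), c("s1", "s2")))
  allzero[, 2] <- 0
  expect_error(normalize_profiles(allzero), "s2")
})

test_that("prevalence filter applies a strict inequality", {
  m <- matrix(0, 3, 138, dimnames = list(c("ten", "eleven", "none"),
                                         sprintf("s%03d", 1:138)))
  m["ten", 1:10] <- 5
  m["eleven", 1:11] <- 5
  out <- prevalence_filter(m, 10)
  expect_equal(rownames(out$kept), "eleven")
  expect_setequal(out$dropped, c("ten", "none"))
  expect_equal(formals(prevalence_filter)$min_positive, 10)
})

test_that("best_hits ranks by r with lexicographic tie-break", {
  corr <- matrix(c(0.9), 1, 1, dimnames = list("q", "A"))
  one <- best_hits(corr, cutoff = 0.65)
  expect_equal(one$best_id, "A")
  expect_true(is.na(one$second_id))
  expect_true(one$passes_cutoff)

  corr <- matrix(c(0.70, 0.70, 0.10), 1, 3,
                 dimnames = list("q", c("B", "A", "C")))
  res <- best_hits(corr, cutoff = 0.65)
  expect_equal(res$best_id, "A")
  expect_equal(res$second_id, "B")
  expect_equal(res$best_r, 0.70)
  expect_true(res$passes_cutoff)
  expect_equal(res$n_candidates, 3)
  expect_equal(formals(best_hits)$cutoff, 0.65)

  # all-undefined query: missing hits, fails cutoff
  corr <- matrix(NA_real_, 1, 2, dimnames = list("q", c("A", "B")))
  res <- best_hits(corr)
  expect_true(is.na(res$best_id))
  expect_false(res$passes_cutoff)
  expect_equal(res$n_candidates, 0)
})

test_that("best_hits matches the exhaustive-scan oracle on random tables", {
  set.seed(55)
  for (rep in 1:40) {
    nr <- sample(1:10, 1); nc <- sample(1:10, 1)
    corr <- matrix(round(runif(nr * nc, -1, 1), 2), nr,
                   dimnames = list(paste0("q", seq_len(nr)),
                                   sample(paste0("c", seq_len(nc)))))
    corr[runif(nr * nc) < 0.1] <- NA
    res <- best_hits(corr, cutoff = 0.3)
    for (i in seq_len(nr)) {
      oracle <- oracle_best_two(corr[i, ], colnames(corr))
      row <- res[res$query_id == paste0("q", i), ]
      if (is.null(oracle$best)) {
        expect_true(is.na(row$best_id))
      } else {
        expect_equal(row$best_id, oracle$best$id)
        expect_equal(row$best_r, oracle$best$r)
        expect_equal(row$passes_cutoff, oracle$best$r >= 0.3)
      }
      if (!is.null(oracle$second)) {
        expect_equal(row$second_id, oracle$second$id)
        expect_equal(row$second_r, oracle$second$r)
        expect_gte(row$best_r, row$second_r)
      }
    }
    # permutation invariance in candidate order
    perm <- corr[, sample(ncol(corr)), drop = FALSE]
    expect_identical(best_hits(perm, cutoff = 0.3), res)
  }
})

test_that("direction query_cols transposes the query role", {
  corr <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2,
                 dimnames = list(c("otu1", "otu2"), c("M1", "M2")))
  by_mgs <- best_hits(corr, direction = "query_cols")
  expect_equal(by_mgs$query_id, c("M1", "M2"))
  expect_equal(by_mgs$best_id, c("otu1", "otu2"))
})

test_that("Pearson on log profiles is invariant to the log base", {
  set.seed(77)
  m <- random_count_matrix(8, 20, max = 80)
  a <- normalize_profiles(m)
  r10 <- pearson_cross(a, a)
  rln <- pearson_cross(a * log(10), a * log(10))  # natural-log profiles
  expect_true(max(abs(r10 - rln)) < 1e-12)
})

test_that("raising the cutoff never increases the number of passing links", {
  set.seed(78)
  m1 <- normalize_profiles(random_count_matrix(10, 25, max = 60))
  m2 <- normalize_profiles(random_count_matrix(6, 25, max = 60))
  rownames(m2) <- paste0("M", 1:6)
  corr <- pearson_cross(m1, m2)
  passing <- vapply(seq(-1, 1, by = 0.1), function(cc) {
    sum(best_hits(corr, cutoff = cc)$passes_cutoff)
  }, numeric(1))
  expect_true(all(diff(passing) <= 0))
})
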