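test_that("connectivity counts edges at or above the threshold, symmetrically", {
  s <- paste0("s", 1:8)
  base <- c(1, 3, 2, 5, 4, 7, 6, 8)
  m <- rbind(g1 = base, g2 = base * 2,          # identical profile (rho 1)
             g3 = rev(base),                    # anti-correlated
             g4 = rep(2, 8))                    # constant
  colnames(m) <- s
  conn <- gene_connectivity(m, rho_threshold = 0.7)
  expect_equal(conn$degree[conn$gene_id %in% c("g1", "g2")], c(1L, 1L))
  expect_equal(conn$degree[conn$gene_id == "g3"], 0L)
  expect_equal(conn$degree[conn$gene_id == "g4"], 0L)
  expect_true(conn$constant[conn$gene_id == "g4"])
  expect_true(all(conn$degree <= nrow(m) - 1))
})

test_that("connectivity equals the all-pairs brute-force computation", {
  set.seed(21)
  m <- matrix(rpois(5 * 15, 20), 5,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:15)))
  conn <- gene_connectivity(m, rho_threshold = 0.5)
  for (i in 1:5) {
    deg <- 0L
    for (j in setdiff(1:5, i)) {
      rho <- oracle_spearman(m[i, ], m[j, ])
      if (!is.na(rho) && rho >= 0.5) deg <- deg + 1L
    }
    expect_equal(conn$degree[conn$gene_id == paste0("g", i)], deg)
  }
})

test_that("single-gene MGS degrades gracefully with a warning", {
  m <- matrix(1:4, 1, dimnames = list("g1", paste0("s", 1:4)))
  expect_warning(conn <- gene_connectivity(m), "fewer than 2")
  expect_equal(conn$degree, 0L)
})

test_that("tracer selection sorts by degree then gene id and caps at k", {
  conn <- data.frame(gene_id = c("g2", "g1", "g3"), degree = c(5L, 5L, 1L))
  expect_equal(select_tracers(conn, k = 2), c("g1", "g2"))
  expect_equal(select_tracers(conn, k = 50), c("g1", "g2", "g3"))
  expect_equal(formals(select_tracers)$k, 50)
  expect_error(select_tracers(conn[0, ], 5), "empty")
  # deterministic under permutation of the input rows
  set.seed(4)
  big <- data.frame(gene_id = sprintf("g%03d", 1:40),
                    degree = sample(0:5, 40, replace = TRUE))
  t1 <- select_tracers(big, 10)
  t2 <- select_tracers(big[sample(40), ], 10)
  expect_identical(t1, t2)
})

test_that("MGS abundance is the arithmetic mean of the tracer rows", {
  ab <- rbind(t1 = c(0.2, 0.4), t2 = c(0.0, 0.2), x = c(1, 1))
  colnames(ab) <- c("s1", "s2")
  models <- list(M1 = list(mgs_id = "M1", member_genes = c("t1", "t2"),
                           tracer_genes = c("t1", "t2")),
                 M2 = list(mgs_id = "M2", member_genes = "x",
                           tracer_genes = "x"))
  out <- mgs_abundance(ab, models)
  expect_equal(unname(out["M1", ]), c(0.1, 0.3))
  expect_equal(unname(out["M2", ]), ab["x", ], ignore_attr = TRUE)
  expect_error(mgs_abundance(ab, list(list(mgs_id = "M", tracer_genes = "nope",
                                           member_genes = "nope"))), "missing")
  expect_error(mgs_abundance(ab, list(list(mgs_id = "M", tracer_genes = character(0),
                                           member_genes = "x"))), "empty tracer")
})

test_that("on noiseless organisms the tracer mean tracks relative abundance", {
  # counts exactly proportional to organism abundance x gene length; after
  # TC normalization the tracer mean is proportional to the organism's
  # relative abundance, so the correlation with it is exactly 1
  latA <- c(5, 1, 8, 3, 9, 2, 7, 4)
  latB <- c(2, 6, 1, 9, 3, 8, 4, 5)
  lens <- c(a1 = 500, a2 = 1500, a3 = 1000, b1 = 800, b2 = 400, b3 = 2000)
  counts <- rbind(outer(lens[1:3], latA), outer(lens[4:6], latB)) * 2
  dimnames(counts) <- list(names(lens), paste0("s", 1:8))
  ab <- normalize_rpkm_tc(counts, gene_length_table(names(lens), lens))
  mem <- membership_table(names(lens), rep(c("MGS_A", "MGS_B"), each = 3))
  models <- build_mgs_models(ab, mem, k = 50)
  expect_setequal(models$MGS_A$tracer_genes, names(lens)[1:3])
  prof <- mgs_abundance(ab, models)["MGS_A", ]
  p_rel <- latA / (latA + latB)
  expect_equal(unname(pearson_rho(prof, p_rel)), 1, tolerance = 1e-12)
})
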