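test_that("a fibroblast-only gene is detected, matching the rank-sum oracle", {
  sc <- generate_sc_data(
    n_cells_per_type = 40,
    cell_types = c("fibroblast", "epithelial", "macrophage"),
    origin_true = c(MARK1 = "fibroblast"),
    n_background_genes = 60, seed = 21
  )
  # make the planted gene exclusive: zero outside its type
  sc$counts["MARK1", sc$cells$cell_type != "fibroblast"] <- 0L
  mk <- find_markers(sc)
  row <- mk[mk$gene == "MARK1" & mk$cell_type == "fibroblast", ]
  expect_true(row$specific)
  expect_lt(row$p_adj, 1e-6)
  # oracle: stats::wilcox.test on the same normalized values
  norm <- cell_norm(sc)
  w <- suppressWarnings(wilcox.test(
    norm["MARK1", sc$cells$cell_type == "fibroblast"],
    norm["MARK1", sc$cells$cell_type != "fibroblast"],
    exact = FALSE, correct = TRUE
  ))
  expect_equal(row$p, w$p.value, tolerance = 1e-9)
})

test_that("marker p-values agree with wilcox.test across many genes", {
  sc <- generate_sc_data(
    n_cells_per_type = 25,
    cell_types = c("fibroblast", "T cell"),
    n_background_genes = 40, seed = 22
  )
  mk <- find_markers(sc)
  norm <- cell_norm(sc)
  fib <- sc$cells$cell_type == "fibroblast"
  sub <- mk[mk$cell_type == "fibroblast", ][1:20, ]
  for (g in sub$gene) {
    w <- suppressWarnings(
      wilcox.test(norm[g, fib], norm[g, !fib], exact = FALSE, correct = TRUE)
    )
    expect_equal(sub$p[sub$gene == g], w$p.value, tolerance = 1e-9)
  }
})

test_that("all-zero genes are not tested and small cell types are skipped", {
  sc <- generate_sc_data(
    n_cells_per_type = 10,
    cell_types = c("fibroblast", "epithelial"),
    n_background_genes = 30, seed = 23
  )
  sc$counts[1, ] <- 0L
  dead <- rownames(sc$counts)[1]
  mk <- find_markers(sc)
  expect_false(dead %in% mk$gene)

  sc2 <- sc
  sc2$cells$cell_type <- c("mast cell", "mast cell",
                           rep(c("fibroblast", "epithelial"), each = 9))
  expect_warning(mk2 <- find_markers(sc2), "skipped")
  expect_false("mast cell" %in% mk2$cell_type)
})

test_that("null data keep the specificity false-positive rate at or below 1%", {
  sc <- generate_sc_data(
    n_cells_per_type = 40,
    cell_types = c("fibroblast", "epithelial", "macrophage", "T cell"),
    n_background_genes = 250, seed = 24
  )
  mk <- find_markers(sc)
  expect_lte(mean(mk$specific), 0.01)
})

test_that("origin assignment follows specificity then highest average expression", {
  # planted two-type example: gene specific in both, higher in macrophages
  set.seed(25)
  counts <- matrix(
    rnbinom(3 * 60, mu = 1, size = 2), 3, 60,
    dimnames = list(c("G1", "G2", "BG"), sprintf("c%02d", 1:60))
  )
  type <- rep(c("fibroblast", "macrophage", "B cell"), each = 20)
  counts["G1", type == "fibroblast"] <- counts["G1", type == "fibroblast"] + 20L
  counts["G1", type == "macrophage"] <- counts["G1", type == "macrophage"] + 40L
  counts["G2", type == "fibroblast"] <- counts["G2", type == "fibroblast"] + 30L
  cells <- cell_data_from_counts(counts, type)
  mk <- find_markers(cells)
  origins <- assign_origin(c("G1", "G2", "BG", "ABSENT"), cells, mk)
  norm <- cell_norm(cells)
  expect_equal(
    origins$origin[origins$gene == "G1"],
    c("fibroblast", "macrophage", "B cell")[
      which.max(tapply(norm["G1", ], type, mean)[
        c("fibroblast", "macrophage", "B cell")])]
  )
  expect_equal(origins$origin[origins$gene == "G1"], "macrophage")
  expect_equal(origins$origin[origins$gene == "G2"], "fibroblast")
  expect_equal(origins$origin[origins$gene == "BG"], "unassigned")
  expect_equal(origins$origin[origins$gene == "ABSENT"], "unassigned")
})

test_that("origin fractions sum to one and count unassigned genes", {
  origins <- tibble::tibble(
    gene = sprintf("G%02d", 1:10),
    origin = c(rep("fibroblast", 7), "epithelial", "unassigned", "unassigned"),
    specific_in = ""
  )
  fr <- origin_fractions(origins)
  expect_equal(sum(fr$fraction), 1)
  expect_equal(fr$fraction[fr$origin == "fibroblast"], 0.7)
  expect_error(origin_fractions(origins[0, ]), "empty")
})

test_that("planted fibroblast-origin genes are recovered as fibroblast", {
  genes <- sprintf("PEM%02d", 1:12)
  sc <- generate_sc_data(
    n_cells_per_type = 60,
    origin_true = setNames(rep("fibroblast", 12), genes),
    n_background_genes = 80, seed = 26
  )
  mk <- find_markers(sc)
  fr <- origin_fractions(assign_origin(genes, sc, mk))
  expect_gte(fr$fraction[fr$origin == "fibroblast"], 1 - 1e-9)
})

test_that("two planted fibroblast populations are separated exactly", {
  set.seed(27)
  n <- 60
  g <- 40
  counts <- matrix(rnbinom(g * 2 * n, mu = 0.5, size = 2), g, 2 * n,
                   dimnames = list(sprintf("M%02d", 1:g),
                                   sprintf("c%03d", 1:(2 * n))))
  counts[1:15, 1:n] <- counts[1:15, 1:n] + 30L        # program A
  counts[16:30, (n + 1):(2 * n)] <- counts[16:30, (n + 1):(2 * n)] + 30L
  cells <- cell_data_from_counts(counts, "fibroblast")
  labels <- fibroblast_subcluster(
    cells, feature_genes = rownames(counts),
    n_components = 10, resolution = 0.5, k_neighbors = 15, seed = 4
  )
  truth <- rep(c("A", "B"), each = n)
  expect_equal(length(unique(labels$cluster)), 2)
  expect_equal(adjusted_rand_index(labels$cluster, truth), 1)
  # determinism
  labels2 <- fibroblast_subcluster(
    cells, feature_genes = rownames(counts),
    n_components = 10, resolution = 0.5, k_neighbors = 15, seed = 4
  )
  expect_identical(labels$cluster, labels2$cluster)
  # resolution -> 0 collapses a connected graph to a single cluster
  set.seed(44)
  mild <- counts
  mild[1:30, ] <- matrix(rnbinom(30 * 2 * n, mu = 3, size = 2), 30, 2 * n)
  mild_cells <- cell_data_from_counts(mild, "fibroblast")
  one <- fibroblast_subcluster(
    mild_cells, feature_genes = rownames(mild),
    n_components = 10, resolution = 1e-5, k_neighbors = 15, seed = 4
  )
  expect_equal(length(unique(one$cluster)), 1)
  expect_error(
    fibroblast_subcluster(cells, feature_genes = "M01"),
    "fewer than 2"
  )
})

test_that("the per-cell score matches the brute-force running sum exactly", {
  genes <- paste0("g", 1:5)
  expr <- setNames(c(5, 4, 3, 2, 1), genes)
  counts <- matrix(as.integer(expr), 5, 1, dimnames = list(genes, "cellA"))
  cells <- cell_data_from_counts(counts, "fibroblast")
  s <- sc_score(cells, "g1", alpha = 0.25)
  norm <- cell_norm(cells)[, 1]
  expect_equal(s$score, ssgsea_oracle(norm, "g1", 0.25), tolerance = 1e-12)
})

test_that("score properties: identical cells, monotonicity, rank invariance", {
  set.seed(28)
  counts <- matrix(rnbinom(40 * 6, mu = 2, size = 2), 40, 6,
                   dimnames = list(sprintf("g%02d", 1:40), paste0("c", 1:6)))
  counts[, 2] <- counts[, 1]
  cells <- cell_data_from_counts(counts, "fibroblast")
  gs <- sprintf("g%02d", 1:5)
  s <- sc_score(cells, gs)
  expect_equal(s$score[1], s$score[2], tolerance = 1e-12)

  # cell with set genes on top scores above a cell with them at the bottom
  top <- setNames(c(100:96, 50:16), sprintf("g%02d", 1:40))
  bottom <- setNames(c(1:5, 50:16), sprintf("g%02d", 1:40))
  cts <- cbind(hi = as.integer(top), lo = as.integer(bottom))
  rownames(cts) <- names(top)
  two <- cell_data_from_counts(cts, "fibroblast")
  s2 <- sc_score(two, gs)
  expect_gt(s2$score[s2$barcode == "hi"], s2$score[s2$barcode == "lo"])

  # strictly monotone transformation of counts leaves scores unchanged
  cubed <- cells
  cubed$counts <- cells$counts^3
  expect_equal(sc_score(cubed, gs)$score, s$score, tolerance = 1e-12)

  expect_error(sc_score(cells, "nope"), "does not intersect")
  expect_error(sc_score(cells, rownames(counts)), "complement is empty")
})

test_that("correlation with the score behaves as hand-computed", {
  counts <- matrix(c(1, 2, 3,
                     3, 2, 1,
                     5, 5, 5), 3, byrow = TRUE,
                   dimnames = list(c("up", "down", "flat"), paste0("c", 1:3)))
  cells <- cell_data_from_counts(counts, "fibroblast")
  # score equal to the TPM expression of gene "up"
  tpm <- cell_tpm(cells)
  scores <- tibble::tibble(barcode = paste0("c", 1:3), score = tpm["up", ])
  out <- correlate_with_score(cells, scores, top_k = 2)
  expect_equal(out$r[out$gene == "up"], 1, tolerance = 1e-9)
  expect_equal(out$r[out$gene == "down"], -1, tolerance = 1e-9)
  expect_false("flat" %in% out$gene)
  expect_equal(attr(out, "n_zero_variance"), 1)
  expect_equal(attr(out, "top")[1], "up")
  expect_equal(out$prop_positive[out$gene == "up"], 1)
})

test_that("planted score-driving genes appear in the top correlated set", {
  sc <- generate_sc_data(
    n_cells_per_type = 80,
    origin_true = setNames(rep("fibroblast", 8), sprintf("PG%d", 1:8)),
    program_genes = sprintf("PG%d", 1:8),
    subpop_fraction = 0.4,
    n_background_genes = 60, seed = 30
  )
  fibro <- cell_subset(sc, "fibroblast")
  scores <- sc_score(fibro, sprintf("PG%d", 1:8))
  # the planted subpopulation over-expresses the program: higher scores
  expect_gt(
    mean(scores$score[fibro$cells$in_subpop]),
    mean(scores$score[!fibro$cells$in_subpop])
  )
  out <- correlate_with_score(fibro, scores, top_k = 10)
  expect_gte(length(intersect(sprintf("PG%d", 1:8), attr(out, "top"))), 6)
})
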