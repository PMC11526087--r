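toy_annotation <- tibble::tibble(
  gene = c("COL1A1", "LUM", "SERPINH1"),
  division = c("core matrisome", "core matrisome", "matrisome-associated"),
  category = c("COL", "PRO", "REG")
)

test_that("annotation is an exact-symbol lookup with none for unmatched", {
  out <- annotate_matrisome(c("COL1A1", "LUM", "GAPDH"), toy_annotation)
  expect_equal(out$category, c("COL", "PRO", "none"))
  expect_equal(out$division[3], "none")
  # case-sensitive by contract
  out2 <- annotate_matrisome("Col1a1", toy_annotation)
  expect_equal(out2$category, "none")
  counts <- attr(out, "counts")
  expect_equal(as.vector(counts[c("COL", "PRO", "none")]), rep(1L, 3))
  expect_error(annotate_matrisome("COL1A1", tibble::tibble()), "empty")
})

test_that("generated matrisome labels match the configured fraction", {
  co <- generate_cohort(tiny_cohort_config(
    n_proteins = 1000, matrisome_fraction = 0.1
  ))
  ann <- annotate_matrisome(co$quant$protein, co$annotation)
  expect_equal(sum(ann$category != "none"), 100)
})

test_that("RPC is percent-of-column with scale invariance", {
  m <- cbind(s1 = c(1, 1, 2), s2 = c(10, 10, 20))
  rownames(m) <- paste0("P", 1:3)
  out <- as.matrix(rpc(quant_from_matrix(m))[-1])
  expect_equal(unname(out[, "s1"]), c(25, 25, 50))
  # scaling a sample leaves its RPC unchanged
  expect_equal(out[, "s1"], out[, "s2"])
  expect_equal(unname(colSums(out)), c(100, 100), tolerance = 1e-6)
  zero <- cbind(s1 = c(0, 0))
  rownames(zero) <- c("P1", "P2")
  expect_error(rpc(quant_from_matrix(zero)), "zero total")
})

test_that("category composition recovers planted group differences", {
  # 6 samples, 4 proteins: PRO proteins elevated in group X
  ann <- tibble::tibble(
    gene = c("LUM", "DCN", "FN1", "GAPDH"),
    division = c("core matrisome", "core matrisome", "core matrisome", "none"),
    category = c("PRO", "PRO", "GLY", "none")
  )
  set.seed(1)
  base <- matrix(100, 4, 8, dimnames = list(ann$gene, paste0("s", 1:8)))
  base[c("LUM", "DCN"), 1:4] <- 300   # PRO enriched in group X
  base <- base * exp(matrix(rnorm(32, 0, 0.05), 4, 8))
  groups <- tibble::tibble(sample = paste0("s", 1:8),
                           group = rep(c("X", "Y"), each = 4))
  comp <- category_composition(rpc(quant_from_matrix(base)), ann, groups)
  pro_x <- comp$group_means$mean_rpc[comp$group_means$group == "X" &
                                       comp$group_means$category == "PRO"]
  pro_y <- comp$group_means$mean_rpc[comp$group_means$group == "Y" &
                                       comp$group_means$category == "PRO"]
  expect_gt(pro_x, pro_y)
  pro_p <- comp$tests$p[comp$tests$category == "PRO"]
  expect_lt(pro_p, 0.05)
  # independent oracle: Welch t-test on the per-sample PRO sums
  pro_sum <- colSums(sweep(base[c("LUM", "DCN"), ], 2, colSums(base), "/") * 100)
  oracle <- t.test(pro_sum[1:4], pro_sum[5:8])$p.value
  expect_equal(pro_p, oracle, tolerance = 1e-10)
  # per-sample category RPC sums to the matrisome share plus the remainder
  per_sample_tot <- comp$per_sample |>
    dplyr::group_by(sample) |>
    dplyr::summarise(tot = sum(rpc))
  expect_equal(per_sample_tot$tot, rep(100, 8), tolerance = 1e-6)
})

test_that("degenerate category compositions behave as documented", {
  ann <- tibble::tibble(gene = c("A", "B"), division = "core matrisome",
                        category = "COL")
  m <- matrix(c(1, 3, 2, 2), 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  groups <- tibble::tibble(sample = c("s1", "s2"), group = c("g1", "g2"))
  expect_warning(
    comp <- category_composition(rpc(quant_from_matrix(m)), ann, groups),
    "skipped"
  )
  # all proteins in one category: that category is 100% everywhere
  expect_true(all(comp$group_means$mean_rpc == 100))
  expect_null(comp$tests)
})

test_that("cumulative coverage matches hand computations and is monotone", {
  expect_equal(cumulative_coverage(rep(10, 10), 0.9), 9L)
  expect_equal(cumulative_coverage(c(50, 30, 15, 5), 0.9), 3L)
  expect_equal(cumulative_coverage(100, 0.9), 1L)
  expect_error(cumulative_coverage(numeric()), "empty")
  set.seed(3)
  v <- rexp(200)
  ks <- vapply(seq(0.1, 1, by = 0.1), function(th) {
    cumulative_coverage(v, th)
  }, integer(1))
  expect_true(all(diff(ks) >= 0))
})

test_that("top_abundant ranks by mean RPC with alphabetical ties", {
  ann <- tibble::tibble(
    gene = c("B2", "A1", "C3"), division = "core matrisome", category = "COL"
  )
  m <- matrix(c(30, 30, 40,
                30, 30, 40), 3, 2,
              dimnames = list(c("B2", "A1", "C3"), c("s1", "s2")))
  out <- top_abundant(rpc(quant_from_matrix(m)), ann, n = 3)
  expect_equal(out$protein, c("C3", "A1", "B2"))  # tie broken alphabetically
  expect_equal(length(out$sample_rpc[[1]]), 2)
  expect_warning(
    short <- top_abundant(rpc(quant_from_matrix(m)), ann, n = 20),
    "returning all"
  )
  expect_equal(nrow(short), 3)
})

test_that("the largest-baseline protein tops every group in a zero-effect cohort", {
  co <- generate_cohort(tiny_cohort_config(
    n_proteins = 100, noise_sd = 0.1, seed = 17
  ))
  norm <- normalize_quant(co$quant, co$design)
  r <- rpc(norm, co$design)
  mat <- co$annotation$gene[co$annotation$category != "none"]
  biggest <- names(which.max(co$truth$baseline_log2[mat]))
  out <- top_abundant(r, co$annotation, n = 5)
  expect_equal(out$protein[1], biggest)
})

test_that("duplicated samples merge first at height zero", {
  set.seed(2)
  m <- 2^matrix(rnorm(40, 10, 1), 10, 4,
                dimnames = list(paste0("P", 1:10), paste0("s", 1:4)))
  m[, "s2"] <- m[, "s1"]
  hc <- hcluster_samples(quant_from_matrix(m))
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_setequal(-hc$merge[1, ], which(colnames(m) %in% c("s1", "s2")))
})

test_that("first merge matches the brute-force smallest pairwise distance", {
  set.seed(5)
  m <- 2^matrix(rnorm(60, 12, 2), 20, 3,
                dimnames = list(paste0("P", 1:20), paste0("s", 1:3)))
  hc <- hcluster_samples(quant_from_matrix(m))
  z <- t(scale(t(log2(m))))
  d <- as.matrix(dist(t(z)))
  diag(d) <- Inf
  closest <- which(d == min(d), arr.ind = TRUE)[1, ]
  expect_setequal(-hc$merge[1, ], unname(closest))
})

test_that("clustering is invariant to protein row order and drops constants", {
  set.seed(6)
  m <- 2^matrix(rnorm(50, 10, 1), 10, 5,
                dimnames = list(paste0("P", 1:10), paste0("s", 1:5)))
  m[1, ] <- 4  # constant row
  expect_message(hc1 <- hcluster_samples(quant_from_matrix(m)), "constant")
  perm <- sample(10)
  expect_message(hc2 <- hcluster_samples(quant_from_matrix(m[perm, ])), "constant")
  expect_equal(hc1$height, hc2$height)
  expect_equal(hc1$merge, hc2$merge)
})

test_that("PCA orders variance, fixes signs, and maps duplicates together", {
  set.seed(7)
  m <- 2^matrix(rnorm(120, 12, 1.5), 20, 6,
                dimnames = list(paste0("P", 1:20), paste0("s", 1:6)))
  m[, "s4"] <- m[, "s3"]
  emb <- pca_embed(quant_from_matrix(m), n_components = 3)
  expect_true(all(diff(emb$explained_variance) <= 1e-12))
  expect_equal(
    as.numeric(emb$coords[emb$coords$sample == "s3", -1]),
    as.numeric(emb$coords[emb$coords$sample == "s4", -1]),
    tolerance = 1e-9
  )
  # sign convention: the largest-magnitude loading is positive
  for (j in seq_len(3)) {
    l <- emb$loadings[, j]
    expect_gt(l[which.max(abs(l))], 0)
  }
})

test_that("rank-2 data are reconstructed exactly from two components", {
  set.seed(8)
  u1 <- rnorm(30); u2 <- rnorm(30)
  v1 <- rnorm(8); v2 <- rnorm(8)
  x <- outer(u1, v1) + outer(u2, v2)  # proteins x samples, rank 2
  m <- 2^(x + 10)
  rownames(m) <- paste0("P", 1:30)
  colnames(m) <- paste0("s", 1:8)
  emb <- pca_embed(quant_from_matrix(m), n_components = 2)
  scores <- as.matrix(emb$coords[-1])
  recon <- scores %*% t(emb$loadings)
  centered <- scale(t(log2(m)), center = TRUE, scale = FALSE)
  expect_lt(max(abs(recon - centered)), 1e-9)
})

test_that("PCA reduces requested components with a warning when samples are few", {
  m <- 2^matrix(rnorm(30, 10, 1), 10, 3,
                dimnames = list(paste0("P", 1:10), paste0("s", 1:3)))
  expect_warning(emb <- pca_embed(quant_from_matrix(m), n_components = 5),
                 "reducing")
  expect_equal(length(emb$explained_variance), 2)
})
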