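test_that("UPGMA reproduces the hand example and merges monotonically", {
  # 3 points on a line at 0, 1, 5: merge {0,1} at height 1, then at
  # mean(5, 4) = 4.5
  m <- matrix(c(0, 1, 5), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  hc <- hierarchical_cluster(m, axis = "genes")
  expect_equal(hc$height, c(1, 4.5))

  # identical rows merge first at height 0
  m2 <- rbind(a = c(1, 2), b = c(1, 2), c = c(9, 9))
  hc2 <- hierarchical_cluster(m2, axis = "genes")
  expect_equal(hc2$height[1], 0)

  set.seed(14)
  mr <- matrix(rnorm(200), 40, 5)
  hcr <- hierarchical_cluster(mr, axis = "genes")
  expect_true(all(diff(hcr$height) >= 0))
  expect_length(hcr$height, 39)

  nwk <- dendrogram_newick(hc)
  expect_match(nwk, "^\\(", all = FALSE)
  expect_error(hierarchical_cluster(m[1, , drop = FALSE]),
               class = "xplatde_validation_error")
})

test_that("k-means is seeded, reproducible and sane", {
  set.seed(70)
  blob1 <- matrix(rnorm(60, 0), 30, 2)
  blob2 <- matrix(rnorm(60, 10), 30, 2)
  m <- rbind(blob1, blob2)
  rownames(m) <- sprintf("i%02d", 1:60)
  km <- kmeans_cluster(m, k = 2, seed = 4)
  expect_identical(km, kmeans_cluster(m, k = 2, seed = 4))
  # blobs 10 SDs apart are perfectly separated
  lab <- km$assignments
  expect_identical(length(unique(lab[1:30])), 1L)
  expect_identical(length(unique(lab[31:60])), 1L)
  expect_false(lab[1] == lab[31])

  km1 <- kmeans_cluster(m, k = 1, seed = 1)
  expect_equal(unname(km1$centroids[1, ]), unname(colMeans(m)))
  expect_true(all(km1$assignments == 1))

  # inertia beats a random assignment
  set.seed(8)
  rand_lab <- sample(1:2, 60, replace = TRUE)
  cent <- rbind(colMeans(m[rand_lab == 1, , drop = FALSE]),
                colMeans(m[rand_lab == 2, , drop = FALSE]))
  rand_inertia <- sum((m - cent[rand_lab, ])^2)
  expect_lte(km$inertia, rand_inertia)
  expect_error(kmeans_cluster(m, k = 61), class = "xplatde_validation_error")
  expect_identical(nrow(tidy(km)), 60L)
})

test_that("PCA satisfies the decomposition identities", {
  set.seed(9)
  m <- matrix(rnorm(30 * 8), 30, 8, dimnames = list(NULL, paste0("s", 1:8)))
  p <- pca_study(m)
  expect_equal(sum(p$variance_fraction), 1, tolerance = 1e-9)
  recon <- p$scores %*% t(p$loadings)
  centered <- scale(t(m), center = TRUE, scale = FALSE)
  expect_equal(unname(recon), unname(centered), tolerance = 1e-9,
               ignore_attr = TRUE)

  rank1 <- outer(rnorm(20), c(1, 2, 3, 4))
  colnames(rank1) <- paste0("s", 1:4)
  p1 <- pca_study(rank1)
  expect_equal(p1$variance_fraction[1], 1, tolerance = 1e-9)

  const <- matrix(5, 10, 3, dimnames = list(NULL, paste0("s", 1:3)))
  expect_error(pca_study(const), class = "xplatde_validation_error")
})

test_that("chromosome distribution counts and fractions are exact", {
  ann <- tibble::tibble(gene_id = 1:20 + 0L, symbol = "x",
                        chromosome = c(rep("1", 10), rep("X", 6), rep("21", 4)),
                        probe_id = sprintf("p%d", 1:20))
  d <- chromosome_distribution(1:20, ann)
  expect_identical(d$n_genes[d$chromosome == "1"], 10L)
  expect_equal(d$fraction[d$chromosome == "1"], 0.5)
  expect_equal(sum(d$fraction), 1, tolerance = 1e-9)

  empty <- chromosome_distribution(integer(0), ann)
  expect_true(all(empty$n_genes == 0L))
  expect_true(all(is.na(empty$fraction)))

  expect_error(chromosome_distribution(c(1L, 999L), ann), "999",
               class = "xplatde_validation_error")

  set.seed(44)
  genes <- sample(1:20, 12)
  d2 <- chromosome_distribution(genes, ann)
  want <- table(factor(ann$chromosome[match(genes, ann$gene_id)],
                       levels = xplatde:::CHROMOSOME_LABELS))
  expect_identical(d2$n_genes, as.integer(want))
})

test_that("per-chromosome mean expression averages the member genes", {
  ann <- tibble::tibble(gene_id = c(1L, 2L, 3L), symbol = "x",
                        chromosome = c("5", "5", "X"),
                        probe_id = c("p1", "p2", "p3"))
  r <- tibble::new_tibble(
    tibble::tibble(gene_id = c(1L, 2L, 3L),
                   s1 = c(1, 3, -2), s2 = c(1, 3, -4)),
    class = "ratio_matrix", id_col = "gene_id"
  )
  cm <- chromosome_mean_expression(r, ann, up = c(1L, 2L), down = 3L)
  expect_equal(cm$mean_up[cm$chromosome == "5"], 2)
  expect_equal(cm$mean_down[cm$chromosome == "X"], -3)
  expect_true(is.na(cm$mean_up[cm$chromosome == "1"]))  # no members
  expect_identical(cm$n_up[cm$chromosome == "5"], 2L)
})

test_that("correlation maps match the direct formula, both methods", {
  ann <- tibble::tibble(gene_id = 1:10 + 0L, symbol = "x", chromosome = "7",
                        probe_id = sprintf("p%d", 1:10))
  set.seed(26)
  m <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("s", 1:4)))
  r <- tibble::new_tibble(
    tibble::tibble(gene_id = 1:10 + 0L, !!!as.data.frame(m)),
    class = "ratio_matrix", id_col = "gene_id"
  )
  cmap <- chromosome_correlation_map(r, ann, "7", "pearson")
  expect_equal(unname(diag(cmap$matrix)), rep(1, 4))
  expect_equal(cmap$matrix, t(cmap$matrix))
  # element-wise against the covariance formula
  for (i in 1:4) for (j in 1:4) {
    x <- m[, i]; y <- m[, j]
    want <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(cmap$matrix[i, j], want, tolerance = 1e-12)
  }
  # spearman equals pearson on within-sample ranks
  smap <- chromosome_correlation_map(r, ann, "7", "spearman")
  ranked <- apply(m, 2, rank)
  expect_equal(unname(smap$matrix), unname(cor(ranked)), tolerance = 1e-12)

  # a sample against its own negation has pearson -1
  r2 <- r
  r2$s2 <- -r2$s1
  neg <- chromosome_correlation_map(r2, ann, "7", "pearson")
  expect_equal(neg$matrix["s1", "s2"], -1)

  expect_error(chromosome_correlation_map(r, ann, "13", "pearson"),
               class = "xplatde_validation_error")
})

test_that("structure results are invariant to gene row order", {
  ann <- tibble::tibble(gene_id = 1:12 + 0L, symbol = "x", chromosome = "2",
                        probe_id = sprintf("p%d", 1:12))
  set.seed(62)
  m <- matrix(rnorm(48), 12, 4, dimnames = list(NULL, paste0("s", 1:4)))
  r <- tibble::new_tibble(
    tibble::tibble(gene_id = 1:12 + 0L, !!!as.data.frame(m)),
    class = "ratio_matrix", id_col = "gene_id"
  )
  shuf <- r[sample(12), ]
  expect_equal(chromosome_correlation_map(r, ann, "2", "pearson")$matrix,
               chromosome_correlation_map(shuf, ann, "2", "pearson")$matrix,
               tolerance = 1e-12)
  expect_equal(
    chromosome_mean_expression(r, ann, up = c(1L, 5L), down = 8L),
    chromosome_mean_expression(shuf, ann, up = c(1L, 5L), down = 8L)
  )
})
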