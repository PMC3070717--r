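make_h <- function(m, meta) {
  tibble::new_tibble(
    tibble::tibble(gene_id = seq_len(nrow(m)) + 100L,
                   !!!as.data.frame(m)),
    class = "harmonized_study", id_col = "gene_id", meta = meta
  )
}

test_that("pooled t-test reproduces the textbook example and t.test", {
  meta <- tibble::tibble(
    sample_id = c("a1", "a2", "a3", "c1", "c2", "c3"), platform_id = "p",
    class = c(rep("tumor", 3), rep("control", 3)), group = c(rep("g", 3), rep("", 3))
  )
  m <- rbind(c(1, 2, 3, 2, 3, 4),   # classic (1,2,3) vs (2,3,4)
             c(1, 2, 3, 1, 2, 3),   # identical groups
             c(5, 5, 5, 5, 5, 5))   # zero variance, equal means
  colnames(m) <- meta$sample_id
  h <- make_h(m, meta)
  calls <- group_vs_controls_ttest(h, meta, group = "g")
  expect_equal(calls$statistic[1], -1.224745, tolerance = 1e-6)
  expect_equal(calls$p[1], 0.2878641, tolerance = 1e-6)
  expect_equal(calls$statistic[2], 0)
  expect_equal(calls$p[2], 1)
  expect_equal(calls$p[3], 1)  # zero pooled variance, equal means

  # swapping group and control negates t, p unchanged
  meta_sw <- dplyr::mutate(meta, class = rev(class), group = rev(group))
  sw <- group_vs_controls_ttest(h, meta_sw, group = "g")
  expect_equal(sw$statistic[1], -calls$statistic[1])
  expect_equal(sw$p[1], calls$p[1])

  # random matrices agree with stats::t.test in both variants
  set.seed(17)
  mr <- matrix(rnorm(50 * 6), 50, dimnames = list(NULL, meta$sample_id))
  hr <- make_h(mr, meta)
  for (ve in c(TRUE, FALSE)) {
    got <- group_vs_controls_ttest(hr, meta, "g", var_equal = ve)
    want <- apply(mr, 1, function(row) {
      tt <- t.test(row[1:3], row[4:6], var.equal = ve)
      c(tt$statistic, tt$p.value)
    })
    expect_equal(got$statistic, unname(want[1, ]), tolerance = 1e-12)
    expect_equal(got$p, unname(want[2, ]), tolerance = 1e-12)
  }

  # zero variance with unequal means is flagged, not silently called
  m2 <- rbind(c(1, 1, 1, 2, 2, 2)); colnames(m2) <- meta$sample_id
  degen <- group_vs_controls_ttest(make_h(m2, meta), meta, "g")
  expect_true(degen$degenerate[1])
  expect_true(is.na(degen$p[1]))
})

test_that("intra-experimental z standardizes within the sample column", {
  r <- tibble::new_tibble(
    tibble::tibble(gene_id = 1:5 + 0L,
                   s1 = c(0, 0, 0, 0, 10), s2 = c(1, 2, 3, 4, 5)),
    class = "ratio_matrix", id_col = "gene_id"
  )
  calls <- intra_experimental_ztest(r)
  s1 <- calls[calls$unit == "s1", ]
  expect_equal(s1$statistic, (c(0, 0, 0, 0, 10) - 2) / sd(c(0, 0, 0, 0, 10)))
  # gene at the column mean has z = 0, p = 1
  s2 <- calls[calls$unit == "s2", ]
  expect_equal(s2$statistic[3], 0)
  expect_equal(s2$p[3], 1)

  # a gene sitting at mu + 1.959964 sigma of its column obtains p = 0.05:
  # construct a column with mean 0, sd 1 that contains 1.959964 exactly
  target <- 1.959964
  zc <- seq(-1, 1, length.out = 99); zc <- zc - mean(zc)
  a <- -target / 99
  b <- sqrt((99 - target^2 - 99 * a^2) / sum(zc^2))
  col <- c(target, a + b * zc)
  expect_equal(mean(col), 0, tolerance = 1e-12)
  expect_equal(sd(col), 1, tolerance = 1e-12)
  rc <- tibble::new_tibble(
    tibble::tibble(gene_id = seq_along(col) + 0L, s = col),
    class = "ratio_matrix", id_col = "gene_id"
  )
  pc <- intra_experimental_ztest(rc)
  expect_equal(pc$p[1], 0.05, tolerance = 1e-4)

  expect_error(
    intra_experimental_ztest(
      tibble::new_tibble(tibble::tibble(gene_id = 1:3 + 0L, s = c(1, 1, 1)),
                         class = "ratio_matrix", id_col = "gene_id")
    ),
    "zero", class = "xplatde_validation_error"
  )
})

test_that("intra z-test is calibrated under the null", {
  set.seed(99)
  r <- tibble::new_tibble(
    tibble::tibble(gene_id = seq_len(10000) + 0L, s1 = rnorm(10000)),
    class = "ratio_matrix", id_col = "gene_id"
  )
  calls <- intra_experimental_ztest(r, alpha = 0.05)
  expect_lt(abs(mean(calls$significant) - 0.05), 0.01)
})

test_that("inter-experimental z standardizes within the gene row", {
  r <- tibble::new_tibble(
    tibble::tibble(gene_id = c(1L, 2L),
                   s1 = c(0, 1), s2 = c(0, 1), s3 = c(0, 1),
                   s4 = c(0, 1), s5 = c(5, 1)),
    class = "ratio_matrix", id_col = "gene_id"
  )
  calls <- inter_experimental_ztest(r)
  g1 <- calls[calls$gene_id == 1, ]
  expect_identical(g1$unit[which.max(abs(g1$statistic))], "s5")
  g2 <- calls[calls$gene_id == 2, ]  # constant row: inter-unchanged
  expect_true(all(g2$p == 1))
  expect_true(all(!g2$significant))

  set.seed(23)
  m <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(NULL, paste0("s", 1:10)))
  rr <- tibble::new_tibble(
    tibble::tibble(gene_id = 1:50 + 0L, !!!as.data.frame(m)),
    class = "ratio_matrix", id_col = "gene_id"
  )
  calls2 <- inter_experimental_ztest(rr)
  want <- t(apply(m, 1, function(row) (row - mean(row)) / sd(row)))
  got <- matrix(calls2$statistic, nrow = 50, byrow = TRUE)
  expect_equal(got, unname(want), tolerance = 1e-12)
})

test_that("Storey q-values follow the step-down formula", {
  qr <- storey_qvalues(c(0.01, 0.02, 0.9, 0.95), lambda = 0.5)
  expect_equal(qr$pi0, 1)  # 2 / (4 * 0.5)
  expect_equal(qr$q, c(0.04, 0.04, 0.95, 0.95))

  all1 <- storey_qvalues(rep(1, 10))
  expect_equal(all1$pi0, 1)
  expect_equal(all1$q, rep(1, 10))

  set.seed(5)
  u <- runif(10000)
  expect_lt(abs(storey_qvalues(u)$pi0 - 1), 0.05)

  # q is monotone in p and respects the rank bound q >= pi0 * p
  p <- runif(200)
  qr2 <- storey_qvalues(p)
  o <- order(p)
  expect_true(all(diff(qr2$q[o]) >= -1e-15))
  expect_true(all(qr2$q >= qr2$pi0 * p - 1e-15))
  expect_true(all(qr2$q <= 1))

  expect_error(storey_qvalues(numeric(0)), class = "xplatde_validation_error")
  expect_error(storey_qvalues(c(0.5, 1.2)), class = "xplatde_validation_error")
  expect_identical(glance(qr)$m, 4L)
})

test_that("significance calling uses a strict threshold and signs direction", {
  calls <- tibble::tibble(
    gene_id = 1:3 + 0L, unit = "u", mode = "intra_z",
    statistic = c(2, -2, 1), p = c(0.049, 0.05, 0.2),
    q = NA_real_, direction = "none", significant = FALSE
  )
  out <- call_de(calls, alpha = 0.05)
  expect_identical(out$significant, c(TRUE, FALSE, FALSE))
  expect_identical(out$direction, c("up", "none", "none"))

  set.seed(2)
  rnd <- random_calls(n_genes = 200, units = "u", seed = 2)
  for (a in c(0.01, 0.05, 0.2)) {
    re <- call_de(rnd, a)
    expect_identical(sum(re$significant), sum(rnd$p < a))
  }
})

test_that("q-values are computed per comparison family", {
  calls <- random_calls(n_genes = 100, units = c("u1", "u2"), seed = 4)
  out <- add_qvalues(calls, lambda = 0.5)
  for (u in c("u1", "u2")) {
    ix <- out$unit == u
    expect_equal(out$q[ix], storey_qvalues(out$p[ix])$q)
  }
  expect_named(attr(out, "pi0"), c("u1", "u2"))
})
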