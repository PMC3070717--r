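# Brute-force set oracles: re-derive each rule by explicit per-unit set
# manipulation and compare with the implementation.

per_unit_sets <- function(calls, dir = NULL) {
  lapply(split(calls, calls$unit), function(d) {
    sel <- d$significant
    if (!is.null(dir)) sel <- sel & d$direction == dir
    d$gene_id[sel]
  })
}

test_that("DE-in-all-units equals the brute-force intersection", {
  calls <- random_calls(n_genes = 60, units = paste0("u", 1:6), seed = 31,
                        alpha = 0.3)
  rep <- intersect_de_all_units(calls)
  want <- sort(Reduce(intersect, per_unit_sets(calls)))
  expect_identical(rep$gene_id, as.integer(want))

  # gene DE in 9/10 units is excluded; 10/10 included
  units <- paste0("s", 1:10)
  hand <- tibble::tibble(
    gene_id = rep(c(1L, 2L), each = 10), unit = rep(units, 2),
    mode = "intra_z", statistic = 3,
    p = c(rep(0.01, 10), c(rep(0.01, 9), 0.5)),
    q = NA_real_, direction = "none", significant = FALSE
  ) |> call_de(0.05)
  rep2 <- intersect_de_all_units(hand)
  expect_identical(rep2$gene_id, 1L)

  # row order and unit relabeling do not matter
  shuffled <- calls[sample(nrow(calls)), ]
  shuffled$unit <- paste0("x_", shuffled$unit)
  expect_identical(intersect_de_all_units(shuffled)$gene_id, rep$gene_id)
})

test_that("unmeasured genes count as not-DE and are reported separately", {
  calls <- random_calls(n_genes = 20, units = c("u1", "u2"), seed = 8,
                        alpha = 0.9)
  partial <- calls[!(calls$gene_id == 101L & calls$unit == "u2"), ]
  rep <- intersect_de_all_units(partial)
  expect_false(101L %in% rep$gene_id)
  expect_identical(attr(rep, "not_everywhere"), 101L)
})

test_that("simultaneous direction sets are directional and disjoint", {
  units <- paste0("s", 1:4)
  mk <- function(gene, stats, ps) {
    tibble::tibble(gene_id = gene, unit = units, mode = "intra_z",
                   statistic = stats, p = ps, q = NA_real_,
                   direction = "none", significant = FALSE)
  }
  calls <- call_de(dplyr::bind_rows(
    mk(1L, rep(3, 4), rep(0.01, 4)),       # up everywhere
    mk(2L, rep(-3, 4), rep(0.01, 4)),      # down everywhere
    mk(3L, c(3, 3, 3, -3), rep(0.01, 4)),  # mixed: neither set
    mk(4L, rep(3, 4), c(0.01, 0.01, 0.01, 0.5))  # not DE everywhere
  ), 0.05)
  rep <- simultaneous_direction_sets(calls)
  expect_identical(rep$gene_id[rep$rule_id == "up_in_all"], 1L)
  expect_identical(rep$gene_id[rep$rule_id == "down_in_all"], 2L)

  calls_r <- random_calls(n_genes = 80, units = paste0("u", 1:5), seed = 77,
                          alpha = 0.4)
  rep_r <- simultaneous_direction_sets(calls_r)
  up_want <- sort(Reduce(intersect, per_unit_sets(calls_r, "up")))
  dn_want <- sort(Reduce(intersect, per_unit_sets(calls_r, "down")))
  expect_identical(rep_r$gene_id[rep_r$rule_id == "up_in_all"],
                   as.integer(up_want))
  expect_identical(rep_r$gene_id[rep_r$rule_id == "down_in_all"],
                   as.integer(dn_want))
  expect_length(intersect(rep_r$gene_id[rep_r$rule_id == "up_in_all"],
                          rep_r$gene_id[rep_r$rule_id == "down_in_all"]), 0)
  # directional sets are contained in the any-direction intersection
  all_rep <- intersect_de_all_units(calls_r)
  expect_true(all(rep_r$gene_id %in% all_rep$gene_id))
})

test_that("group-pair combinations enumerate the four directional cases", {
  a <- random_calls(n_genes = 50, units = "gA", seed = 41, alpha = 0.4)
  b <- random_calls(n_genes = 50, units = "gB", seed = 42, alpha = 0.4)
  rep <- group_pair_combinations(a, b, labels = c("A", "B"))
  sa <- per_unit_sets(a); sb <- per_unit_sets(b)
  expect_identical(rep$gene_id[rep$rule_id == "common_A_B"],
                   as.integer(sort(intersect(sa[[1]], sb[[1]]))))
  for (case in list(c("up", "up"), c("down", "down"),
                    c("up", "down"), c("down", "up"))) {
    rule <- sprintf("%sA_%sB", case[1], case[2])
    want <- sort(intersect(per_unit_sets(a, case[1])[[1]],
                           per_unit_sets(b, case[2])[[1]]))
    expect_identical(rep$gene_id[rep$rule_id == rule], as.integer(want))
  }

  # identical calls: common set equals either; cross-direction sets empty
  same <- group_pair_combinations(a, dplyr::mutate(a, unit = "gB"),
                                  labels = c("A", "B"))
  expect_identical(same$gene_id[same$rule_id == "common_A_B"],
                   as.integer(sort(sa[[1]])))
  expect_length(same$gene_id[same$rule_id == "upA_downB"], 0)

  # disjoint DE sets: everything empty
  none_a <- dplyr::mutate(a, significant = FALSE, direction = "none")
  expect_identical(nrow(group_pair_combinations(none_a, b)), 0L)
})

test_that("combined intra/inter cases match a truth-table evaluation", {
  units <- c("s1", "s2", "s3")
  genes <- 1:20 + 0L
  set.seed(55)
  intra <- random_calls(n_genes = 20, units = units, seed = 55, alpha = 0.2)
  inter <- random_calls(n_genes = 20, units = units, seed = 56, alpha = 0.2)
  a_rep <- combined_case_selection(intra, inter, "intra_unchanged_inter_DE")
  b_rep <- combined_case_selection(intra, inter, "inter_unchanged_intra_DE")
  # exhaustive truth table over all genes
  for (g in genes) {
    gi <- intra[intra$gene_id == g + 100L, ]
    ge <- inter[inter$gene_id == g + 100L, ]
    null_intra <- all(gi$p >= 0.2)
    null_inter <- all(ge$p >= 0.2)
    de_intra <- any(gi$significant)
    de_inter <- any(ge$significant)
    expect_identical((g + 100L) %in% a_rep$gene_id, null_intra && de_inter)
    expect_identical((g + 100L) %in% b_rep$gene_id, null_inter && de_intra)
  }
  # a gene DE in both modes is selected in neither case
  expect_length(intersect(
    intersect(a_rep$gene_id, unique(intra$gene_id[intra$significant])),
    unique(inter$gene_id[inter$significant])
  ), 0)
  expect_error(
    combined_case_selection(intra, dplyr::mutate(inter, unit = "other")),
    class = "xplatde_validation_error"
  )
})

test_that("incidence ranking tallies and orders correctly", {
  units <- paste0("s", 1:10)
  calls <- call_de(tibble::tibble(
    gene_id = rep(c(5L, 9L), each = 10), unit = rep(units, 2),
    mode = "intra_z", statistic = 3,
    p = c(rep(0.001, 10), rep(c(0.001, 0.9), 5)),
    q = NA_real_, direction = "none", significant = FALSE
  ), 0.05)
  r <- de_incidence_ranking(calls)
  expect_identical(r$gene_id[1], 5L)
  expect_equal(r$fraction[1], 1.0)
  expect_identical(r$n_units_de[r$gene_id == 9L], 5L)

  rnd <- random_calls(n_genes = 40, units = units, seed = 3, alpha = 0.3)
  rr <- de_incidence_ranking(rnd)
  tal <- tapply(rnd$significant, rnd$gene_id, sum)
  expect_identical(rr$n_units_de[match(as.integer(names(tal)), rr$gene_id)],
                   as.integer(tal))
  expect_true(all(diff(rr$n_units_de) <= 0))
})

test_that("group-common markers honor the tolerance", {
  units <- paste0("g", 1:11)
  calls <- call_de(tibble::tibble(
    gene_id = rep(c(1L, 2L), each = 11), unit = rep(units, 2),
    mode = "group_t", statistic = 3,
    p = c(rep(0.01, 11), c(rep(0.01, 10), 0.9)),
    q = NA_real_, direction = "none", significant = FALSE
  ), 0.05)
  expect_identical(group_common_marker(calls, 0)$gene_id, 1L)
  # the 10-of-11 marker appears at tolerance 1
  expect_setequal(group_common_marker(calls, 1)$gene_id, c(1L, 2L))
  expect_error(group_common_marker(calls, 11), class = "xplatde_validation_error")

  rnd <- random_calls(n_genes = 30, units = units, seed = 61, alpha = 0.4)
  for (tol in 0:2) {
    got <- group_common_marker(rnd, tol)$gene_id
    tal <- tapply(rnd$significant, rnd$gene_id, sum)
    want <- sort(as.integer(names(tal)[tal >= 11 - tol]))
    expect_identical(got, want)
  }
})

test_that("cross-platform intersection keeps only rule-consistent genes", {
  mk_rep <- function(up, down) {
    calls <- call_de(tibble::tibble(
      gene_id = c(up, down), unit = "p", mode = "allvsall_t",
      statistic = c(rep(3, length(up)), rep(-3, length(down))),
      p = 0.001, q = NA_real_, direction = "none", significant = FALSE
    ), 0.05)
    simultaneous_direction_sets(calls)
  }
  r1 <- mk_rep(c(1L, 2L, 3L), c(10L, 11L))
  r2 <- mk_rep(c(2L, 3L, 4L), c(11L, 12L))
  r3 <- mk_rep(c(3L, 2L), c(11L, 13L))
  got <- cross_platform_commonality(list(r1, r2, r3))
  expect_setequal(got$gene_id[got$rule_id == "up_in_all"], c(2L, 3L))
  expect_identical(got$gene_id[got$rule_id == "down_in_all"], 11L)
})
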