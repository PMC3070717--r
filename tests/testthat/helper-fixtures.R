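# Shared fixtures: small study configurations and a random call-table
# builder. All randomness is seeded per use site.

tiny_config <- function(seed = 1L, ...) {
  args <- list(
    n_genes_universe = 300,
    platforms = tibble::tibble(
      platform_id = c("pA", "pB"),
      probe_subset_fraction = 0.9,
      n_controls = c(4L, 5L),
      n_tumors = c(8L, 10L)
    ),
    groups = c("g1", "g2", "g3"),
    n_common_up = 10, n_common_down = 15, n_group_specific = 3,
    seed = seed
  )
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# A call table with units x genes and random significance structure.
random_calls <- function(n_genes = 20, units = c("u1", "u2", "u3"),
                         seed = 1, alpha = 0.05, mode = "intra_z") {
  set.seed(seed)
  grid <- expand.grid(gene_id = seq_len(n_genes) + 100L, unit = units,
                      stringsAsFactors = FALSE)
  stat <- rnorm(nrow(grid), sd = 2)
  calls <- tibble::tibble(
    gene_id = grid$gene_id, unit = grid$unit, mode = mode,
    statistic = stat, p = 2 * pnorm(-abs(stat)), q = NA_real_,
    direction = "none", significant = FALSE
  )
  call_de(calls, alpha)
}

extdata <- function(name) {
  system.file("extdata", name, package = "xplatde", mustWork = TRUE)
}
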