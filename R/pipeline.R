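# End-to-end orchestration: simulate -> preprocess -> harmonize -> DE ->
# commonality -> structure -> enrichment, seeded and logged. Identical
# config + seed yields byte-identical outputs.

#' Pipeline configuration
#'
#' @param sim A [sim_config()] describing the study to simulate (or emulate).
#' @param alpha Significance threshold in `(0, 1)`.
#' @param lambda Storey q-value tuning parameter.
#' @param k k-means preset (cluster count).
#' @param tolerance Group-common marker tolerance (groups a gene may miss).
#' @param min_pathways Multi-pathway selection threshold.
#' @param seed Integer master seed; overrides `sim$seed`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), alpha = 0.05, lambda = 0.5,
                            k = 49L, tolerance = 1L, min_pathways = 2L,
                            seed = sim$seed) {
  if (alpha <= 0 || alpha >= 1) {
    abort("alpha must lie in (0, 1)", class = "xplatde_config_error")
  }
  if (lambda < 0 || lambda >= 1) {
    abort("lambda must lie in [0, 1)", class = "xplatde_config_error")
  }
  sim$seed <- as.integer(seed)
  validate_sim_config(sim)
  structure(list(sim = sim, alpha = alpha, lambda = lambda, k = as.integer(k),
                 tolerance = as.integer(tolerance),
                 min_pathways = as.integer(min_pathways),
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Simulates the configured multi-platform study, preprocesses each platform
#' (global-median normalization, log2 ratios against the platform's control
#' mean, probe collapsing to Gene IDs), harmonizes across platforms
#' (common gene list + quantile cross-normalization), runs the four DE
#' comparison modes with per-family Storey q-values, derives the commonality
#' reports (per-platform direction sets intersected across platforms,
#' per-group direction sets, combined intra/inter cases, incidence ranking,
#' tolerant group-common markers), summarizes chromosomes, and tests the
#' planted annotation terms for over-representation.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every stage output is
#'   written as TSV together with a provenance log of all parameters.
#' @return A list of stage results (see the vignette for a walk-through).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  sim <- simulate_multiplatform(config$sim)
  terms <- simulate_terms(config$sim)

  # per-platform preprocessing: normalize, ratio vs control mean (controls
  # included so the harmonized matrix carries every sample), collapse probes
  ratios <- imap(sim$studies, function(st, pid) {
    st |> global_median_normalize() |>
      compute_log_ratios(sim$meta, include_controls = TRUE) |>
      collapse_probes(sim$annotations[[pid]])
  })

  harmonized <- harmonize_studies(ratios, sim$meta, group_spec = config$sim$groups)
  common_list <- attr(harmonized, "common_gene_list")

  # mode 1/2: pooled and per-group t-tests on the harmonized study
  all_t <- group_vs_controls_ttest(harmonized, sim$meta, group = "ALL",
                                   alpha = config$alpha) |>
    add_qvalues(lambda = config$lambda)
  group_t <- all_groups_ttest(harmonized, sim$meta, alpha = config$alpha) |>
    add_qvalues(lambda = config$lambda)

  # mode 3/4: per-sample z-tests on tumor ratio columns of the harmonized study
  tumor_ids <- attr(harmonized, "groups")$sample_id
  tumor_view <- harmonized[c("gene_id", tumor_ids)]
  intra <- intra_experimental_ztest(tumor_view, alpha = config$alpha)
  inter <- inter_experimental_ztest(tumor_view, alpha = config$alpha)

  # per-platform direction sets, computed on the harmonized scale so each
  # platform's tumors are tested against the pooled control group, then
  # intersected across platforms
  platform_reports <- map(names(sim$studies), function(pid) {
    meta_p <- filter(sim$meta, .data$class == "control" | .data$platform_id == pid)
    calls <- group_vs_controls_ttest(harmonized, meta_p, group = "ALL",
                                     alpha = config$alpha)
    calls$unit <- pid
    simultaneous_direction_sets(calls)
  })
  cross_platform <- cross_platform_commonality(platform_reports)

  group_direction <- simultaneous_direction_sets(group_t)
  de_all_groups <- intersect_de_all_units(group_t, "DE_in_all_groups")
  markers <- group_common_marker(group_t, tolerance = config$tolerance)
  incidence <- de_incidence_ranking(intra)
  case_a <- combined_case_selection(intra, inter, "intra_unchanged_inter_DE",
                                    alpha = config$alpha)
  case_b <- combined_case_selection(intra, inter, "inter_unchanged_intra_DE",
                                    alpha = config$alpha)

  up_set <- cross_platform$gene_id[cross_platform$rule_id == "up_in_all"]
  down_set <- cross_platform$gene_id[cross_platform$rule_id == "down_in_all"]
  chrom_dist <- chromosome_distribution(c(up_set, down_set), sim$universe)
  chrom_mean <- chromosome_mean_expression(tumor_view, sim$universe,
                                           up = up_set, down = down_set)
  query <- intersect(c(up_set, down_set), common_list)
  enrich <- if (length(query)) {
    enrich_hypergeometric(query, terms, common_list, lambda = config$lambda)
  } else {
    tibble(term_id = character(0), term_name = character(0),
           k = integer(0), K = integer(0), n = integer(0), N = integer(0),
           p = numeric(0), q = numeric(0))
  }

  # structure stage: sample dendrogram, PCA, k-means over the DE genes,
  # and a correlation map for the most gene-rich chromosome
  de_any <- unique(all_t$gene_id[all_t$significant])
  km <- if (length(de_any) >= 3) {
    sub <- harmonized[harmonized$gene_id %in% de_any, ]
    kmeans_cluster(sub, k = min(config$k, nrow(sub) - 1L), seed = config$seed)
  }
  chrom_tab <- table(sim$universe$chromosome[sim$universe$gene_id %in%
                                               harmonized$gene_id])
  top_chrom <- names(chrom_tab)[which.max(chrom_tab)]
  structure_res <- list(
    sample_tree = hierarchical_cluster(harmonized, axis = "samples"),
    pca = pca_study(harmonized),
    kmeans = km,
    correlation_map = chromosome_correlation_map(tumor_view, sim$universe,
                                                 top_chrom, "pearson")
  )

  result <- list(
    config = config, sim = sim, terms = terms, ratios = ratios,
    harmonized = harmonized, structure = structure_res,
    calls = list(all_t = all_t, group_t = group_t, intra = intra, inter = inter),
    reports = list(cross_platform = cross_platform,
                   group_direction = group_direction,
                   de_all_groups = de_all_groups, markers = markers,
                   case_a = case_a, case_b = case_b),
    incidence = incidence,
    chromosome = list(distribution = chrom_dist, mean_expression = chrom_mean),
    enrichment = enrich
  )
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  invisible(result)
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) readr::write_tsv(as_tibble(x), file.path(out_dir, name),
                                          na = "NA", progress = FALSE)
  w(result$harmonized, "harmonized_matrix.tsv")
  w(tibble(gene_id = attr(result$harmonized, "common_gene_list")),
    "common_gene_list.tsv")
  w(result$sim$meta, "sample_meta.tsv")
  w(result$sim$truth, "ground_truth.tsv")
  for (nm in names(result$calls)) {
    w(result$calls[[nm]], sprintf("de_calls_%s.tsv", nm))
  }
  for (nm in names(result$reports)) {
    w(result$reports[[nm]], sprintf("report_%s.tsv", nm))
  }
  w(result$incidence, "incidence_ranking.tsv")
  w(result$chromosome$distribution, "chromosome_distribution.tsv")
  w(result$chromosome$mean_expression, "chromosome_mean_expression.tsv")
  w(result$enrichment, "enrichment.tsv")
  writeLines(dendrogram_newick(result$structure$sample_tree),
             file.path(out_dir, "sample_dendrogram.nwk"))
  w(tidy(result$structure$pca), "pca_scores.tsv")
  w(glance(result$structure$pca), "pca_variance.tsv")
  if (!is.null(result$structure$kmeans)) {
    w(tidy(result$structure$kmeans), "kmeans_assignments.tsv")
  }
  w(tidy(result$structure$correlation_map), "correlation_map.tsv")
  cfg <- result$config
  prov <- c(
    sprintf("alpha\t%g", cfg$alpha), sprintf("lambda\t%g", cfg$lambda),
    sprintf("k\t%d", cfg$k), sprintf("tolerance\t%d", cfg$tolerance),
    sprintf("min_pathways\t%d", cfg$min_pathways),
    sprintf("seed\t%d", cfg$seed),
    sprintf("n_genes_universe\t%d", cfg$sim$n_genes_universe),
    sprintf("noise_sd\t%g", cfg$sim$noise_sd),
    sprintf("effect_common\t%g", cfg$sim$effect_common),
    sprintf("n_dropped_incomplete\t%d",
            attr(result$harmonized, "n_dropped_incomplete"))
  )
  writeLines(c("key\tvalue", prov), file.path(out_dir, "provenance.tsv"))
  invisible(out_dir)
}

#' Summarize a pipeline run
#'
#' Joins the commonality reports with chromosome assignments and incidence
#' counts into one gene-level summary table.
#'
#' @param result A [run_pipeline()] result.
#' @return Tibble `rule_id`, `gene_id`, `direction`, `chromosome`,
#'   `n_units_de`, `truth_label`.
#' @export
pipeline_report <- function(result) {
  all_reports <- bind_rows(map(result$reports, as_tibble))
  if (nrow(all_reports) == 0L) {
    return(tibble(rule_id = character(0), gene_id = integer(0),
                  direction = character(0), chromosome = character(0),
                  n_units_de = integer(0), truth_label = character(0)))
  }
  all_reports |>
    left_join(result$sim$universe[c("gene_id", "chromosome")], by = "gene_id") |>
    left_join(select(result$incidence, "gene_id", "n_units_de"), by = "gene_id") |>
    left_join(rename(result$sim$truth, truth_label = "label"), by = "gene_id") |>
    arrange(.data$rule_id, .data$gene_id)
}

#' Recovery of planted ground truth by a commonality report
#'
#' Compares a directional commonality report against the generator's planted
#' sets: sensitivity is the fraction of planted genes recovered under the
#' matching rule, precision the fraction of reported genes that were
#' planted.
#'
#' @param report A `commonality_report` with rules `up_in_all` /
#'   `down_in_all`.
#' @param truth Ground-truth tibble (`gene_id`, `label`).
#' @param universe Optional gene-id vector (typically the cross-platform
#'   common gene list). When given, planted sets are restricted to it:
#'   genes absent from some platform cannot appear in any cross-platform
#'   intersection, so sensitivity is measured over the recoverable truth.
#' @return Tibble with one row per direction plus a pooled row.
#' @export
recovery_metrics <- function(report, truth, universe = NULL) {
  if (!is.null(universe)) {
    truth <- truth[truth$gene_id %in% as.integer(universe), ]
  }
  eval_set <- function(found, planted) {
    tp <- length(intersect(found, planted))
    tibble(n_found = length(found), n_planted = length(planted),
           sensitivity = if (length(planted)) tp / length(planted) else NA_real_,
           precision = if (length(found)) tp / length(found) else NA_real_)
  }
  up_f <- report$gene_id[report$rule_id == "up_in_all"]
  dn_f <- report$gene_id[report$rule_id == "down_in_all"]
  up_t <- truth$gene_id[truth$label == "common_up"]
  dn_t <- truth$gene_id[truth$label == "common_down"]
  bind_rows(
    mutate(eval_set(up_f, up_t), direction = "up"),
    mutate(eval_set(dn_f, dn_t), direction = "down"),
    mutate(eval_set(c(up_f, dn_f), c(up_t, dn_t)), direction = "both")
  ) |> select("direction", dplyr::everything())
}
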