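# Seeded multi-platform generator with planted ground truth. Defaults encode
# the pooled study design this package targets: 17 controls + 129 tumors over
# three platforms, 11 stage-grade tumor groups, a small core of genes shifted
# in every tumor on top of a large null background.

DEFAULT_GROUPS <- c(
  "Ta-GradeI", "Ta-GradeII", "Ta-GradeIII",
  "T1-GradeI", "T1-GradeII", "T1-GradeIII",
  "T2-GradeII", "T2-GradeIII", "T3-GradeIII",
  "T4-GradeIII", "Cis"
)

#' Simulation configuration
#'
#' Bundles every knob of the synthetic multi-platform study. Defaults mirror
#' the pooled design the pipeline targets: a 2000-gene universe measured by
#' three platforms carrying 5+10, 9+60 and 3+59 control+tumor samples
#' (17 controls and 129 tumors in total), tumors partitioned into 11
#' stage-grade groups, 30 genes planted up- and 80 planted down-regulated in
#' every tumor at a log2 effect of twice the noise SD, and 10 extra
#' group-specific genes per group.
#'
#' @param n_genes_universe Number of genes in the shared universe.
#' @param platforms Tibble with columns `platform_id`,
#'   `probe_subset_fraction` (fraction of the universe each platform
#'   measures, sampled without replacement), `n_controls`, `n_tumors`.
#' @param groups Character vector of tumor group labels; tumors are assigned
#'   round-robin so group sizes are fixed by the design, not random.
#' @param n_common_up,n_common_down Numbers of genes planted up-/down-shifted
#'   in every tumor sample.
#' @param effect_common Mean log2 shift of planted common genes (sign applied
#'   per direction).
#' @param n_group_specific Genes planted per group, shifted only in that
#'   group's tumors.
#' @param effect_group Log2 shift of group-specific genes.
#' @param noise_sd SD of the per-measurement log2 noise.
#' @param baseline_mean,baseline_sd Log2 location/scale of the per-gene
#'   baseline (log-normal intensities).
#' @param platform_shift,platform_scale Per-platform location/scale effects
#'   on the log2 scale (recycled to the number of platforms).
#' @param dup_probe_fraction Fraction of each platform's genes carrying a
#'   second probe (exercises probe collapsing).
#' @param chrom_labels,chrom_weights Chromosome labels and sampling weights
#'   for gene placement (default uniform over the 24 nuclear labels).
#' @param n_null_terms,term_size Random (non-enriched) annotation terms.
#' @param n_planted_terms,planted_overlap Terms constructed to overlap the
#'   planted common set by `planted_overlap` of their `term_size` members.
#' @param seed Integer seed; every generator draws from a stream derived
#'   deterministically from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes_universe = 2000,
                       platforms = tibble(
                         platform_id = c("codelink", "platformB", "platformC"),
                         probe_subset_fraction = 0.9,
                         n_controls = c(5L, 9L, 3L),
                         n_tumors = c(10L, 60L, 59L)
                       ),
                       groups = DEFAULT_GROUPS,
                       n_common_up = 30, n_common_down = 80,
                       effect_common = 1.0,
                       n_group_specific = 10, effect_group = 1.0,
                       noise_sd = 0.5,
                       baseline_mean = 8, baseline_sd = 1,
                       platform_shift = c(0, 0.5, -0.3),
                       platform_scale = c(1, 1.1, 0.9),
                       dup_probe_fraction = 0.05,
                       chrom_labels = c(as.character(1:22), "X", "Y"),
                       chrom_weights = NULL,
                       n_null_terms = 50, term_size = 20,
                       n_planted_terms = 1, planted_overlap = 15,
                       seed = 1L) {
  cfg <- list(
    n_genes_universe = as.integer(n_genes_universe),
    platforms = as_tibble(platforms), groups = groups,
    n_common_up = as.integer(n_common_up),
    n_common_down = as.integer(n_common_down),
    effect_common = effect_common,
    n_group_specific = as.integer(n_group_specific),
    effect_group = effect_group, noise_sd = noise_sd,
    baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    platform_shift = rep_len(platform_shift, nrow(platforms)),
    platform_scale = rep_len(platform_scale, nrow(platforms)),
    dup_probe_fraction = dup_probe_fraction,
    chrom_labels = chrom_labels,
    chrom_weights = chrom_weights %||% rep(1 / length(chrom_labels), length(chrom_labels)),
    n_null_terms = as.integer(n_null_terms), term_size = as.integer(term_size),
    n_planted_terms = as.integer(n_planted_terms),
    planted_overlap = as.integer(planted_overlap),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (cfg$n_common_up < 0 || cfg$n_common_down < 0 || cfg$n_group_specific < 0) {
    abort("planted counts must be non-negative", class = "xplatde_config_error")
  }
  planted <- cfg$n_common_up + cfg$n_common_down +
    cfg$n_group_specific * length(cfg$groups)
  if (planted > cfg$n_genes_universe) {
    abort("planted gene counts exceed the gene universe",
          class = "xplatde_config_error")
  }
  frac <- cfg$platforms$probe_subset_fraction
  if (any(frac <= 0 | frac > 1)) {
    abort("probe_subset_fraction must lie in (0, 1]", class = "xplatde_config_error")
  }
  if (cfg$noise_sd <= 0) {
    abort("noise_sd must be positive", class = "xplatde_config_error")
  }
  if (cfg$planted_overlap > cfg$term_size) {
    abort("planted_overlap cannot exceed term_size", class = "xplatde_config_error")
  }
  invisible(cfg)
}

# Deterministic sub-stream: run `expr` under a seed derived from (seed, tag)
# without disturbing the caller's RNG state.
with_substream <- function(seed, tag, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  offset <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  set.seed((as.integer(seed) %% 1000000L) * 2017L + offset %% 1000003L)
  force(expr)
}

#' Generate the planted truth and shared gene universe
#'
#' @param config A [sim_config()].
#' @return List with `genes` (tibble `gene_id`, `symbol`, `chromosome`,
#'   `baseline`) and `truth` (tibble `gene_id`, `label`).
#' @keywords internal
simulate_universe <- function(config) {
  with_substream(config$seed, "universe", {
    n <- config$n_genes_universe
    gene_id <- 10000L + seq_len(n)
    chromosome <- sample(config$chrom_labels, n, replace = TRUE,
                         prob = config$chrom_weights)
    baseline <- rnorm(n, config$baseline_mean, config$baseline_sd)
    pool <- sample(gene_id)
    take <- function(k) {
      out <- pool[seq_len(k)]
      pool <<- pool[-seq_len(k)]
      out
    }
    common_up <- sort(take(config$n_common_up))
    common_down <- sort(take(config$n_common_down))
    group_specific <- setNames(
      map(config$groups, ~ sort(take(config$n_group_specific))),
      config$groups
    )
    label <- rep("null", n)
    names(label) <- as.character(gene_id)
    label[as.character(common_up)] <- "common_up"
    label[as.character(common_down)] <- "common_down"
    for (g in config$groups) {
      label[as.character(group_specific[[g]])] <- paste0("group:", g)
    }
    list(
      genes = tibble(gene_id = gene_id,
                     symbol = sprintf("GENE%05d", seq_len(n)),
                     chromosome = chromosome, baseline = baseline),
      truth = tibble(gene_id = gene_id, label = unname(label)),
      common_up = common_up, common_down = common_down,
      group_specific = group_specific
    )
  })
}

#' Generate a multi-platform study with planted ground truth
#'
#' Control expression is log-normal (configurable log2 baseline per gene);
#' tumor samples add `effect_common` (signed per direction) to the planted
#' common genes and `effect_group` to their own group's genes; each platform
#' applies its location/scale effect on the log2 scale and measures only its
#' probe subset. The same seed yields byte-identical output.
#'
#' @param config A [sim_config()].
#' @return List with `studies` (one intensity-scale [expr_study] per
#'   platform), `meta` (sample metadata tibble), `annotations` (one
#'   probe-annotation tibble per platform), `universe` (gene-level annotation
#'   of the whole universe) and `truth` (tibble `gene_id`, `label`).
#' @examples
#' sim <- simulate_multiplatform(sim_config(
#'   n_genes_universe = 100,
#'   platforms = tibble::tibble(platform_id = "p1", probe_subset_fraction = 1,
#'                              n_controls = 3L, n_tumors = 6L),
#'   groups = c("g1", "g2"), n_common_up = 5, n_common_down = 5,
#'   n_group_specific = 2, seed = 7
#' ))
#' names(sim$studies)
#' @export
simulate_multiplatform <- function(config) {
  validate_sim_config(config)
  uni <- simulate_universe(config)

  # Global tumor ordering by platform; groups assigned round-robin so the
  # partition is a design constant, not a random draw.
  n_tum <- sum(config$platforms$n_tumors)
  tumor_groups <- rep_len(config$groups, n_tum)
  tum_offset <- 0L

  studies <- list(); annotations <- list(); meta <- list()
  for (i in seq_len(nrow(config$platforms))) {
    p <- config$platforms[i, ]
    res <- with_substream(config$seed, paste0("platform_", p$platform_id), {
      n_sel <- max(2L, round(p$probe_subset_fraction * config$n_genes_universe))
      sel <- sort(sample(seq_len(config$n_genes_universe), n_sel))
      n_dup <- round(config$dup_probe_fraction * n_sel)
      dup <- if (n_dup > 0) sample(sel, n_dup) else integer(0)
      gene_idx <- c(sel, dup)
      ann <- tibble(
        probe_id = sprintf("%s_p%05d", p$platform_id, seq_along(gene_idx)),
        gene_id = uni$genes$gene_id[gene_idx],
        symbol = uni$genes$symbol[gene_idx],
        chromosome = uni$genes$chromosome[gene_idx]
      )
      ctrl_ids <- sprintf("%s_C%02d", p$platform_id, seq_len(p$n_controls))
      tum_ids <- sprintf("%s_T%03d", p$platform_id, seq_len(p$n_tumors))
      grp <- tumor_groups[tum_offset + seq_len(p$n_tumors)]

      effect <- matrix(0, nrow = length(gene_idx), ncol = p$n_controls + p$n_tumors)
      gid <- uni$genes$gene_id[gene_idx]
      up_rows <- gid %in% uni$common_up
      down_rows <- gid %in% uni$common_down
      for (j in seq_len(p$n_tumors)) {
        col <- p$n_controls + j
        effect[up_rows, col] <- effect[up_rows, col] + config$effect_common
        effect[down_rows, col] <- effect[down_rows, col] - config$effect_common
        gs <- uni$group_specific[[grp[j]]]
        if (length(gs)) {
          effect[gid %in% gs, col] <- effect[gid %in% gs, col] + config$effect_group
        }
      }
      base <- uni$genes$baseline[gene_idx]
      noise <- matrix(rnorm(length(effect), 0, config$noise_sd),
                      nrow = nrow(effect))
      log2val <- config$platform_shift[i] +
        config$platform_scale[i] * (base + effect + noise)
      vals <- 2^log2val
      colnames(vals) <- c(ctrl_ids, tum_ids)
      df <- tibble(probe_id = ann$probe_id, !!!as.data.frame(vals))
      list(
        study = expr_study(df, platform_id = p$platform_id, scale = "intensity"),
        ann = ann,
        meta = tibble(
          sample_id = c(ctrl_ids, tum_ids),
          platform_id = p$platform_id,
          class = c(rep("control", p$n_controls), rep("tumor", p$n_tumors)),
          group = c(rep("", p$n_controls), grp)
        )
      )
    })
    tum_offset <- tum_offset + p$n_tumors
    studies[[p$platform_id]] <- res$study
    annotations[[p$platform_id]] <- res$ann
    meta[[i]] <- res$meta
  }

  list(
    studies = studies,
    meta = validate_sample_meta(bind_rows(meta)),
    annotations = annotations,
    universe = uni$genes[c("gene_id", "symbol", "chromosome")],
    truth = uni$truth
  )
}

#' Generate raw spot tables for the single-channel platform
#'
#' Emits one table per array of the first configured platform, with per-spot
#' signal, local background, local background SD and the array's global
#' background median. A configured fraction of spots is constructed to fall
#' below the low-signal flagging threshold `bg_local + k_sigma * bg_local_sd`
#' so the flagger has known positives and negatives.
#'
#' @param config A [sim_config()].
#' @param n_spots Spots per array.
#' @param fraction_low Fraction of spots drawn below the flagging threshold.
#' @param k_sigma Flagging multiplier the spots are constructed against.
#' @return Named list of raw spot tibbles, one per array.
#' @export
simulate_codelink_raw <- function(config, n_spots = 1000, fraction_low = 0.1,
                                  k_sigma = 1.5) {
  validate_sim_config(config)
  p <- config$platforms[1, ]
  arrays <- c(sprintf("%s_C%02d", p$platform_id, seq_len(p$n_controls)),
              sprintf("%s_T%03d", p$platform_id, seq_len(p$n_tumors)))
  out <- lapply(seq_along(arrays), function(a) {
    with_substream(config$seed, paste0("raw_", arrays[a]), {
      bg_local <- pmax(1, rnorm(n_spots, 100, 10))
      bg_sd <- runif(n_spots, 5, 15)
      low <- runif(n_spots) < fraction_low
      thresh <- bg_local + k_sigma * bg_sd
      signal <- numeric(n_spots)
      # low spots sit strictly below the threshold, the rest strictly above
      signal[low] <- thresh[low] * runif(sum(low), 0.5, 0.99)
      signal[!low] <- thresh[!low] + 2^rnorm(sum(!low), config$baseline_mean,
                                             config$baseline_sd)
      validate_raw_spots(tibble(
        probe_id = sprintf("spot%05d", seq_len(n_spots)),
        signal = signal, bg_local = bg_local, bg_local_sd = bg_sd,
        bg_global = stats::median(bg_local) * 0.95,
        flag = "ok"
      ))
    })
  })
  setNames(out, arrays)
}

#' Generate annotation terms with planted enrichment
#'
#' Produces `n_null_terms` random gene sets plus `n_planted_terms` sets built
#' to overlap the planted common (up plus down) genes by `planted_overlap`
#' members, so downstream over-representation has known positives.
#'
#' @param config A [sim_config()].
#' @return Tidy term tibble (`term_id`, `term_name`, `gene_ids`).
#' @export
simulate_terms <- function(config) {
  validate_sim_config(config)
  uni <- simulate_universe(config)
  with_substream(config$seed, "terms", {
    planted_pool <- c(uni$common_up, uni$common_down)
    others <- setdiff(uni$genes$gene_id, planted_pool)
    null_terms <- map(seq_len(config$n_null_terms), function(i) {
      sort(sample(uni$genes$gene_id, config$term_size))
    })
    planted <- map(seq_len(config$n_planted_terms), function(i) {
      k <- min(config$planted_overlap, length(planted_pool))
      sort(c(sample(planted_pool, k),
             sample(others, config$term_size - k)))
    })
    validate_term_sets(tibble(
      term_id = c(sprintf("NULL%03d", seq_len(config$n_null_terms)),
                  sprintf("PLANTED%02d", seq_len(config$n_planted_terms))),
      term_name = c(sprintf("random set %d", seq_len(config$n_null_terms)),
                    sprintf("planted enriched set %d", seq_len(config$n_planted_terms))),
      gene_ids = c(null_terms, planted)
    ))
  })
}
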