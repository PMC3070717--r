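# Single-channel spot-level preprocessing: quality flagging, background
# correction, fold-over-background cutoff, global-median normalization and
# log2 ratios against the control mean. Deterministic throughout (no RNG).

#' Preprocessing configuration
#'
#' @param k_sigma Multiplier of the local-background SD in the low-signal
#'   flag rule `signal < bg_local + k_sigma * bg_local_sd`. Default 1.5, the
#'   conventional single-channel rule; exposed because reasonable scanners
#'   differ.
#' @param cutoff_fold Fold-over-background threshold: corrected signal must
#'   be at least `cutoff_fold` times the array's median local background.
#'   Default 2.
#' @param floor Small positive intensity floor applied after background
#'   correction.
#' @param background `"offset"` subtracts the array-level offset
#'   `median(bg_local) - bg_global` from every signal (the default reading);
#'   `"local"` subtracts each spot's own local background instead.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(k_sigma = 1.5, cutoff_fold = 2, floor = 1.0,
                              background = c("offset", "local")) {
  background <- match.arg(background)
  if (k_sigma <= 0 || cutoff_fold <= 0 || floor <= 0) {
    abort("k_sigma, cutoff_fold and floor must be positive",
          class = "xplatde_config_error")
  }
  structure(list(k_sigma = k_sigma, cutoff_fold = cutoff_fold, floor = floor,
                 background = background),
            class = "preprocess_config")
}

#' Flag low-signal spots
#'
#' A spot is flagged `low_signal` when its signal lies below the local
#' background plus `k_sigma` local-background SDs. Other flags are left
#' untouched.
#'
#' @param spots Raw spot tibble (see [validate_raw_spots()]).
#' @param config A [preprocess_config()].
#' @return The spot tibble with updated `flag`.
#' @examples
#' spots <- tibble::tibble(probe_id = "a", signal = 100, bg_local = 90,
#'                         bg_local_sd = 10, bg_global = 80, flag = "ok")
#' flag_low_signal(spots, preprocess_config())$flag  # 100 < 90 + 1.5*10
#' @export
flag_low_signal <- function(spots, config = preprocess_config()) {
  spots <- validate_raw_spots(spots)
  low <- spots$signal < spots$bg_local + config$k_sigma * spots$bg_local_sd
  spots$flag <- ifelse(low, "low_signal", spots$flag)
  spots
}

#' Background-correct spot signals
#'
#' Default `"offset"` method: subtract the array-level offset between the
#' median local background and the global background median from every
#' signal, clamped at `floor`. The `"local"` method subtracts each spot's own
#' local background instead.
#'
#' @inheritParams flag_low_signal
#' @return Spot tibble with a `corrected` column.
#' @export
background_correct <- function(spots, config = preprocess_config()) {
  spots <- validate_raw_spots(spots)
  if (all(spots$flag != "ok")) {
    abort("no unflagged spots on this array", class = "xplatde_validation_error")
  }
  if (config$background == "offset") {
    offset <- stats::median(spots$bg_local) - spots$bg_global[1]
    spots$corrected <- pmax(config$floor, spots$signal - offset)
  } else {
    spots$corrected <- pmax(config$floor, spots$signal - spots$bg_local)
  }
  spots
}

#' Apply the fold-over-background intensity cutoff
#'
#' Spots whose corrected signal is below `cutoff_fold` times the array's
#' median local background are flagged `below_cutoff`; a spot exactly at the
#' threshold is retained (inclusive comparison). Spots surviving all flags
#' form the analyzable set.
#'
#' @inheritParams flag_low_signal
#' @return Spot tibble with updated `flag`.
#' @export
apply_intensity_cutoff <- function(spots, config = preprocess_config()) {
  spots <- validate_raw_spots(spots)
  if (!"corrected" %in% names(spots)) {
    abort("run background_correct() before the intensity cutoff",
          class = "xplatde_validation_error")
  }
  thresh <- config$cutoff_fold * stats::median(spots$bg_local)
  below <- spots$corrected < thresh & spots$flag == "ok"
  spots$flag[below] <- "below_cutoff"
  spots
}

#' Assemble preprocessed arrays into an expression study
#'
#' Flagged spots become masked (`NA`) entries; the analyzable value is the
#' background-corrected signal.
#'
#' @param spot_list Named list of processed spot tibbles (names are sample
#'   ids), each with `corrected` and `flag`.
#' @param platform_id Platform label for the assembled study.
#' @return An intensity-scale [expr_study].
#' @export
spots_to_study <- function(spot_list, platform_id) {
  probes <- spot_list[[1]]$probe_id
  cols <- imap(spot_list, function(sp, nm) {
    stopifnot(identical(sp$probe_id, probes))
    ifelse(sp$flag == "ok", sp$corrected, NA_real_)
  })
  df <- tibble(probe_id = probes, !!!cols)
  expr_study(df, platform_id = platform_id, scale = "intensity")
}

#' Global-median normalization
#'
#' Divides each sample's intensities by that sample's median analyzable
#' (unmasked) intensity, so every array's analyzable median becomes 1.
#'
#' @param study Intensity-scale [expr_study]; masked entries stay masked.
#' @return Normalized intensity-scale [expr_study].
#' @examples
#' s <- expr_study(tibble::tibble(probe_id = c("a", "b", "c"), x = c(2, 4, 8)),
#'                 platform_id = "p", scale = "intensity")
#' study_matrix(global_median_normalize(s))  # 0.5, 1, 2
#' @export
global_median_normalize <- function(study) {
  validate_expr_study(study)
  if (!identical(attr(study, "scale"), "intensity")) {
    abort("global-median normalization applies to intensity-scale studies",
          class = "xplatde_validation_error")
  }
  m <- study_matrix(study)
  med <- apply(m, 2, stats::median, na.rm = TRUE)
  zero <- which(!is.finite(med) | med <= 0)
  if (length(zero)) {
    abort(sprintf("non-positive analyzable median in sample(s): %s",
                  paste(colnames(m)[zero], collapse = ", ")),
          class = "xplatde_validation_error")
  }
  matrix_to_study(sweep(m, 2, med, "/"), study)
}

#' Log2 ratios against the control mean
#'
#' For every tumor sample, each gene's normalized intensity is divided by the
#' arithmetic mean of the control samples' intensities for that gene and
#' log2-transformed. Entries are masked where any operand is masked or
#' non-positive.
#'
#' @param study Normalized intensity-scale [expr_study].
#' @param meta Sample metadata covering the study's samples.
#' @param include_controls When `TRUE`, control samples also receive ratio
#'   columns (their intensity over the control mean), so a full
#'   genes-by-all-samples ratio matrix can feed cross-platform
#'   harmonization.
#' @return A tibble of class `ratio_matrix`: feature id column plus one log2
#'   ratio column per tumor sample (and per control when
#'   `include_controls`), with the per-gene control mean in attribute
#'   `control_mean`.
#' @examples
#' s <- expr_study(tibble::tibble(probe_id = "g", c1 = 4, c2 = 16, t1 = 5),
#'                 platform_id = "p", scale = "intensity")
#' meta <- tibble::tibble(sample_id = c("c1", "c2", "t1"), platform_id = "p",
#'                        class = c("control", "control", "tumor"),
#'                        group = c("", "", "g1"))
#' compute_log_ratios(s, meta)$t1  # log2(5/10) = -1
#' @export
compute_log_ratios <- function(study, meta, include_controls = FALSE) {
  validate_expr_study(study)
  meta <- validate_sample_meta(meta, require_groups = FALSE)
  m <- study_matrix(study)
  here <- meta[meta$sample_id %in% colnames(m), ]
  ctrl <- here$sample_id[here$class == "control"]
  tum <- here$sample_id[here$class == "tumor"]
  if (length(ctrl) == 0L) {
    abort("no control samples available for ratio computation",
          class = "xplatde_validation_error")
  }
  cm <- rowMeans(m[, ctrl, drop = FALSE], na.rm = TRUE)
  cm[!is.finite(cm) | cm <= 0] <- NA_real_
  keep <- if (include_controls) c(ctrl, tum) else tum
  ratios <- log2(sweep(m[, keep, drop = FALSE], 1, cm, "/"))
  ratios[!is.finite(ratios)] <- NA_real_
  id_col <- attr(study, "id_col")
  out <- tibble(!!id_col := study[[id_col]], !!!as.data.frame(ratios))
  new_tibble(out, class = "ratio_matrix", id_col = id_col,
             platform_id = attr(study, "platform_id"),
             control_mean = setNames(cm, study[[id_col]]))
}

#' Collapse probe-level ratios to gene level
#'
#' Platforms carry multiple probes per NCBI Gene ID; ratios are collapsed to
#' one row per gene by the per-sample median over that gene's probes
#' (order-independent and robust to a single bad probe).
#'
#' @param ratios A `ratio_matrix` (or any probe-by-sample tibble).
#' @param annotation Probe annotation with `probe_id` and `gene_id`.
#' @return Gene-level tibble: `gene_id` column plus the sample columns.
#'   Probes without an annotation row are dropped (the count is reported via
#'   attribute `n_unannotated`).
#' @export
collapse_probes <- function(ratios, annotation) {
  annotation <- validate_gene_annotation(annotation)
  id_col <- attr(ratios, "id_col") %||% names(ratios)[1]
  samp <- setdiff(names(ratios), id_col)
  joined <- inner_join(
    tibble(probe_id = ratios[[id_col]]) |> mutate(.row = dplyr::row_number()),
    annotation[c("probe_id", "gene_id")], by = "probe_id"
  )
  n_unann <- nrow(ratios) - nrow(joined)
  m <- as.matrix(ratios[samp])[joined$.row, , drop = FALSE]
  split_idx <- split(seq_len(nrow(joined)), joined$gene_id)
  collapsed <- t(vapply(split_idx, function(ix) {
    apply(m[ix, , drop = FALSE], 2, stats::median, na.rm = TRUE)
  }, numeric(length(samp))))
  collapsed[!is.finite(collapsed)] <- NA_real_
  out <- tibble(gene_id = as.integer(names(split_idx)),
                !!!as.data.frame(collapsed)) |> arrange(.data$gene_id)
  new_tibble(out, class = "ratio_matrix", id_col = "gene_id",
             platform_id = attr(ratios, "platform_id"),
             n_unannotated = n_unann)
}

#' Run the spot-level pipeline for one platform
#'
#' Fixed order: flag low signal, background-correct, intensity cutoff,
#' assemble, global-median normalize. Returns the normalized study plus a
#' per-array flag summary.
#'
#' @param spot_list Named list of raw spot tibbles (names are sample ids).
#' @param platform_id Platform label.
#' @param config A [preprocess_config()].
#' @return List with `study` (normalized [expr_study]) and `flags` (tibble
#'   `sample_id`, `n_ok`, `n_low_signal`, `n_below_cutoff`).
#' @export
preprocess_arrays <- function(spot_list, platform_id,
                              config = preprocess_config()) {
  processed <- map(spot_list, function(sp) {
    sp |> flag_low_signal(config) |> background_correct(config) |>
      apply_intensity_cutoff(config)
  })
  flags <- imap(processed, function(sp, nm) {
    tibble(sample_id = nm,
           n_ok = sum(sp$flag == "ok"),
           n_low_signal = sum(sp$flag == "low_signal"),
           n_below_cutoff = sum(sp$flag == "below_cutoff"))
  }) |> bind_rows()
  study <- spots_to_study(processed, platform_id) |> global_median_normalize()
  list(study = study, flags = flags)
}
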