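# Cross-platform harmonization: NCBI-Gene-ID common list, quantile
# cross-normalization on the log2-ratio scale, and tumor-group assembly.

#' Build the cross-platform common gene list
#'
#' The set intersection of the per-platform NCBI Gene ID sets, sorted
#' ascending. Probes without a valid Gene ID never reach this point (they are
#' rejected at annotation load).
#'
#' @param annotations List (>= 2) of per-platform annotation tibbles, or of
#'   integer gene-id vectors.
#' @return Sorted integer vector of gene ids present on every platform.
#' @examples
#' build_common_gene_list(list(c(1L, 2L, 3L), c(2L, 3L, 4L), c(2L, 3L)))
#' @export
build_common_gene_list <- function(annotations) {
  if (length(annotations) < 2L) {
    abort("need at least two platforms to intersect",
          class = "xplatde_validation_error")
  }
  sets <- map(annotations, function(a) {
    if (is.data.frame(a)) unique(as.integer(a$gene_id)) else unique(as.integer(a))
  })
  common <- reduce(sets, intersect)
  if (length(common) == 0L) {
    abort("empty cross-platform gene intersection",
          class = "xplatde_validation_error")
  }
  sort(common)
}

#' Quantile normalization with mean-over-tied-span ties
#'
#' Every column is replaced by the reference distribution (the mean of the
#' sorted columns) mapped back through its ranks; tied values receive the
#' mean of the reference values over the tied rank span. Afterwards all
#' columns share an identical sorted multiset.
#'
#' @param m Numeric matrix (features x samples), complete (no `NA`).
#' @return Matrix of the same shape.
#' @keywords internal
quantile_normalize_matrix <- function(m) {
  if (anyNA(m)) {
    abort("quantile normalization requires complete columns; drop or impute masked entries first",
          class = "xplatde_validation_error")
  }
  if (ncol(m) == 1L) return(m)
  ref <- rowMeans(apply(m, 2, sort))
  out <- apply(m, 2, function(col) {
    o <- order(col)
    runs <- rle(col[o])
    res <- numeric(length(col))
    pos <- 1L
    for (len in runs$lengths) {
      idx <- pos:(pos + len - 1L)
      res[o[idx]] <- mean(ref[idx])  # tied block gets the span mean
      pos <- pos + len
    }
    res
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Assign tumor samples to analysis groups
#'
#' @param meta Sample metadata tibble.
#' @param group_spec Character vector of allowed group labels; defaults to
#'   the labels present among tumor samples.
#' @return Tibble `group`, `sample_id`: a disjoint cover of the tumor
#'   samples, controls excluded.
#' @export
assign_groups <- function(meta, group_spec = NULL) {
  meta <- validate_sample_meta(meta)
  tum <- meta[meta$class == "tumor", ]
  group_spec <- group_spec %||% unique(tum$group)
  unknown <- setdiff(unique(tum$group), group_spec)
  if (length(unknown)) {
    abort(sprintf("tumor group label(s) not in the configured scheme: %s",
                  paste(unknown, collapse = ", ")),
          class = "xplatde_validation_error")
  }
  tibble(group = tum$group, sample_id = tum$sample_id) |>
    arrange(match(.data$group, group_spec), .data$sample_id)
}

#' Harmonize studies across platforms
#'
#' Restricts each platform's gene-level log2-ratio matrix to the common gene
#' list, binds samples, drops genes with any masked entry (quantile
#' normalization needs complete columns; the count is recorded), and
#' quantile cross-normalizes so every sample shares one empirical
#' distribution.
#'
#' @param ratio_list Named list of gene-level `ratio_matrix` tibbles (one per
#'   platform, `gene_id` first column).
#' @param meta Sample metadata covering all samples.
#' @param group_spec Optional configured group-label vector.
#' @return A tibble of class `harmonized_study`: `gene_id` plus one column
#'   per sample, with attributes `meta`, `groups` (tibble group/sample_id),
#'   `platform` (named vector sample -> platform) and `n_dropped_incomplete`.
#' @export
harmonize_studies <- function(ratio_list, meta, group_spec = NULL) {
  if (length(ratio_list) < 2L) {
    abort("need at least two platforms to harmonize",
          class = "xplatde_validation_error")
  }
  meta <- validate_sample_meta(meta, require_groups = FALSE)
  common <- build_common_gene_list(map(ratio_list, ~ .x$gene_id))
  mats <- map(ratio_list, function(r) {
    m <- study_matrix(r, id_col = "gene_id")
    m[as.character(common), , drop = FALSE]
  })
  m <- do.call(cbind, unname(mats))
  complete <- !apply(m, 1, anyNA)
  n_dropped <- sum(!complete)
  m <- m[complete, , drop = FALSE]
  if (nrow(m) < 2L) {
    abort("fewer than two complete common genes after masking",
          class = "xplatde_validation_error")
  }
  qn <- quantile_normalize_matrix(m)
  platform <- unlist(imap(ratio_list, function(r, nm) {
    setNames(rep(nm, length(sample_ids(r, "gene_id"))), sample_ids(r, "gene_id"))
  }))
  tum_meta <- meta[meta$sample_id %in% colnames(qn) & meta$class == "tumor", ]
  groups <- assign_groups(
    meta[meta$sample_id %in% colnames(qn), ],
    group_spec %||% unique(tum_meta$group)
  )
  out <- tibble(gene_id = as.integer(rownames(qn)), !!!as.data.frame(qn))
  new_tibble(out, class = "harmonized_study", id_col = "gene_id",
             meta = meta[meta$sample_id %in% colnames(qn), ],
             groups = groups, platform = platform,
             common_gene_list = common,
             n_dropped_incomplete = n_dropped)
}
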