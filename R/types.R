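# Core tabular containers. Everything is a tibble with a conventional column
# layout plus a thin S3 class carrying invariant checks; math happens on
# matrices extracted with study_matrix().

CHROMOSOME_LABELS <- c(as.character(1:22), "X", "Y", "MT")

#' Construct an expression study
#'
#' An expression study is a tibble whose first column (`probe_id` or
#' `gene_id`) identifies the measured feature and whose remaining columns are
#' one numeric column per sample. The object records the platform that
#' produced it and whether values are raw intensities (non-negative) or log2
#' ratios against the control mean.
#'
#' @param x Data frame with an id column followed by numeric sample columns.
#' @param platform_id Platform label, e.g. `"codelink"`.
#' @param scale Either `"intensity"` (values must be >= 0 where unmasked) or
#'   `"log2ratio"`.
#' @param id_col Name of the feature id column; default the first column.
#' @return A tibble of class `expr_study` with attributes `platform_id`,
#'   `scale` and `id_col`.
#' @examples
#' expr_study(
#'   tibble::tibble(probe_id = c("a", "b"), s1 = c(1, 2), s2 = c(3, 4)),
#'   platform_id = "p1", scale = "intensity"
#' )
#' @export
expr_study <- function(x, platform_id, scale = c("intensity", "log2ratio"),
                       id_col = names(x)[1]) {
  scale <- match.arg(scale)
  x <- as_tibble(x)
  out <- new_tibble(x, class = "expr_study",
                    platform_id = platform_id, scale = scale, id_col = id_col)
  validate_expr_study(out)
  out
}

#' @export
validate_expr_study <- function(study) {
  id_col <- attr(study, "id_col")
  ids <- study[[id_col]]
  if (anyDuplicated(ids)) {
    abort(sprintf("duplicate feature id(s): %s",
                  paste(unique(ids[duplicated(ids)])[1:3], collapse = ", ")),
          class = "xplatde_validation_error")
  }
  samp <- setdiff(names(study), id_col)
  if (length(samp) == 0L) {
    abort("study has no sample columns", class = "xplatde_validation_error")
  }
  if (anyDuplicated(samp)) {
    abort(sprintf("duplicate sample id(s): %s",
                  paste(unique(samp[duplicated(samp)]), collapse = ", ")),
          class = "xplatde_validation_error")
  }
  bad <- samp[!vapply(study[samp], is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("non-numeric sample column(s): %s", paste(bad, collapse = ", ")),
          class = "xplatde_parse_error")
  }
  if (identical(attr(study, "scale"), "intensity")) {
    m <- as.matrix(study[samp])
    if (any(m < 0, na.rm = TRUE)) {
      abort("intensity-scale study contains negative values",
            class = "xplatde_validation_error")
    }
  }
  invisible(study)
}

#' Extract the numeric matrix of a study-like tibble
#'
#' @param study An `expr_study`, ratio tibble or harmonized tibble whose
#'   first/id column identifies features and whose other columns are samples.
#' @param id_col Feature id column; defaults to the recorded one or the first
#'   column.
#' @return Numeric matrix, features x samples, with feature ids as rownames.
#' @export
study_matrix <- function(study, id_col = attr(study, "id_col") %||% names(study)[1]) {
  samp <- setdiff(names(study), id_col)
  m <- as.matrix(study[samp])
  rownames(m) <- as.character(study[[id_col]])
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
sample_ids <- function(study, id_col = attr(study, "id_col") %||% names(study)[1]) {
  setdiff(names(study), id_col)
}

# Rebuild an expr_study from a matrix, preserving metadata of a template.
matrix_to_study <- function(m, template, scale = attr(template, "scale")) {
  id_col <- attr(template, "id_col") %||% names(template)[1]
  out <- as_tibble(as.data.frame(m))
  out <- tibble(!!id_col := template[[id_col]], !!!out)
  new_tibble(out, class = "expr_study",
             platform_id = attr(template, "platform_id"),
             scale = scale, id_col = id_col)
}

#' Validate a sample metadata table
#'
#' Required columns: `sample_id`, `platform_id`, `class` (one of
#' `"control"`/`"tumor"`), `group` (stage-grade label for tumors, empty string
#' for controls).
#'
#' @param meta Data frame of per-sample metadata.
#' @param require_groups If `TRUE`, tumor rows with an empty group are
#'   rejected.
#' @return The validated tibble, invisibly classed `sample_meta`.
#' @export
validate_sample_meta <- function(meta, require_groups = TRUE) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "platform_id", "class", "group")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(sprintf("sample metadata missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "xplatde_validation_error")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicate sample_id in metadata", class = "xplatde_validation_error")
  }
  bad <- setdiff(unique(meta$class), c("control", "tumor"))
  if (length(bad)) {
    abort(sprintf("unknown class value(s): %s", paste(bad, collapse = ", ")),
          class = "xplatde_validation_error")
  }
  meta$group[is.na(meta$group)] <- ""
  if (any(meta$class == "control" & meta$group != "")) {
    abort("control samples must carry an empty group",
          class = "xplatde_validation_error")
  }
  if (require_groups && any(meta$class == "tumor" & meta$group == "")) {
    abort("tumor sample(s) with empty group", class = "xplatde_validation_error")
  }
  class(meta) <- c("sample_meta", class(setdiff(class(meta), "sample_meta")))
  new_tibble(meta, class = "sample_meta")
}

#' Validate a probe-to-gene annotation table
#'
#' Columns: `probe_id`, `gene_id` (positive integer NCBI Gene ID), `symbol`,
#' `chromosome` (one of 1..22, X, Y, MT).
#'
#' @param ann Data frame of probe annotations for one platform.
#' @return The validated tibble.
#' @export
validate_gene_annotation <- function(ann) {
  ann <- as_tibble(ann)
  need <- c("probe_id", "gene_id", "symbol", "chromosome")
  miss <- setdiff(need, names(ann))
  if (length(miss)) {
    abort(sprintf("annotation missing column(s): %s", paste(miss, collapse = ", ")),
          class = "xplatde_validation_error")
  }
  if (anyDuplicated(ann$probe_id)) {
    abort("duplicate probe_id in annotation", class = "xplatde_validation_error")
  }
  if (any(ann$gene_id <= 0 | ann$gene_id != as.integer(ann$gene_id))) {
    abort("gene_id must be a positive integer", class = "xplatde_validation_error")
  }
  bad <- setdiff(unique(ann$chromosome), CHROMOSOME_LABELS)
  if (length(bad)) {
    abort(sprintf("unknown chromosome label(s): %s", paste(bad, collapse = ", ")),
          class = "xplatde_validation_error")
  }
  ann$gene_id <- as.integer(ann$gene_id)
  ann
}

#' Validate a term-to-gene-set table
#'
#' A tidy term table has one row per term with columns `term_id`, `term_name`
#' and a list-column `gene_ids` of integer vectors.
#'
#' @param terms Data frame with `term_id`, `term_name`, `gene_ids` columns.
#' @return The validated tibble.
#' @export
validate_term_sets <- function(terms) {
  terms <- as_tibble(terms)
  need <- c("term_id", "term_name", "gene_ids")
  miss <- setdiff(need, names(terms))
  if (length(miss)) {
    abort(sprintf("term table missing column(s): %s", paste(miss, collapse = ", ")),
          class = "xplatde_validation_error")
  }
  if (anyDuplicated(terms$term_id)) {
    abort("duplicate term_id", class = "xplatde_validation_error")
  }
  if (any(lengths(terms$gene_ids) == 0L)) {
    abort("term with empty gene set", class = "xplatde_validation_error")
  }
  terms$gene_ids <- map(terms$gene_ids, ~ sort(unique(as.integer(.x))))
  terms
}

#' Validate a raw spot table
#'
#' One row per spot of a single array: `probe_id`, `signal`, `bg_local`,
#' `bg_local_sd`, `bg_global` (global background median, constant per array)
#' and `flag` (one of `"ok"`, `"low_signal"`, `"below_cutoff"`).
#'
#' @param spots Data frame of raw spot measurements.
#' @return The validated tibble.
#' @export
validate_raw_spots <- function(spots) {
  spots <- as_tibble(spots)
  need <- c("probe_id", "signal", "bg_local", "bg_local_sd", "bg_global")
  miss <- setdiff(need, names(spots))
  if (length(miss)) {
    abort(sprintf("raw spot table missing column(s): %s",
                  paste(miss, collapse = ", ")),
          class = "xplatde_validation_error")
  }
  if (!"flag" %in% names(spots)) spots$flag <- "ok"
  if (anyDuplicated(spots$probe_id)) {
    abort("duplicate probe_id in raw spot table", class = "xplatde_validation_error")
  }
  if (any(spots$bg_local_sd < 0, na.rm = TRUE)) {
    abort("negative local background SD", class = "xplatde_validation_error")
  }
  bad <- setdiff(unique(spots$flag), c("ok", "low_signal", "below_cutoff"))
  if (length(bad)) {
    abort(sprintf("unknown flag value(s): %s", paste(bad, collapse = ", ")),
          class = "xplatde_validation_error")
  }
  spots
}
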