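# Readers/writers for every external table the pipeline touches.
# Canonical format: tab-separated text, header row, decimal point, "NA" for
# masked entries. Readers validate strictly and never drop rows silently.

#' Read an expression matrix from TSV
#'
#' First row is the sample header, first column the feature ids; remaining
#' cells are numeric with `NA` marking masked entries.
#'
#' @param path Path to a tab-separated file.
#' @param scale `"intensity"` or `"log2ratio"`.
#' @param platform_id Platform label stored on the returned study.
#' @return An [expr_study] tibble.
#' @export
read_expression_tsv <- function(path, scale = c("intensity", "log2ratio"),
                                platform_id = "unknown") {
  scale <- match.arg(scale)
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "xplatde_io_error")
  }
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (anyDuplicated(header[-1])) {
    abort(sprintf("duplicated sample id in header: %s",
                  paste(unique(header[-1][duplicated(header[-1])]), collapse = ", ")),
          class = "xplatde_validation_error")
  }
  x <- suppressWarnings(readr::read_tsv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), na = "NA", progress = FALSE, show_col_types = FALSE))
  prob <- readr::problems(x)
  if (nrow(prob) > 0L) {
    abort(sprintf("non-numeric cell at row %d, column %d of %s",
                  prob$row[1], prob$col[1], path),
          class = "xplatde_parse_error")
  }
  names(x)[1] <- header[1]
  expr_study(x, platform_id = platform_id, scale = scale)
}

#' Write an expression matrix to TSV
#'
#' @param study An [expr_study] or any feature-by-sample tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(study, path) {
  readr::write_tsv(as_tibble(study), path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read term-to-gene sets in GMT format
#'
#' Standard GMT dialect: one term per line, tab-separated — term id,
#' description, then one gene id per remaining field.
#'
#' @param path Path to a GMT file.
#' @return Tidy term tibble (`term_id`, `term_name`, list-column `gene_ids`).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "xplatde_io_error")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(validate_term_sets(tibble(term_id = character(), term_name = character(),
                                     gene_ids = list())))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    abort(sprintf("GMT line %d has fewer than 3 columns", short[1]),
          class = "xplatde_parse_error")
  }
  validate_term_sets(tibble(
    term_id = map_chr(fields, 1),
    term_name = map_chr(fields, 2),
    gene_ids = map(fields, ~ as.integer(.x[-(1:2)]))
  ))
}

#' Write term-to-gene sets in GMT format
#'
#' @param terms Tidy term tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  terms <- validate_term_sets(terms)
  lines <- pmap(terms, function(term_id, term_name, gene_ids, ...) {
    paste(c(term_id, term_name, gene_ids), collapse = "\t")
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read sample metadata from TSV
#'
#' Expected columns: `sample_id`, `platform_id`, `class`
#' (`control`/`tumor`), `group` (empty for controls).
#'
#' @param path Path to a tab-separated metadata file.
#' @param require_groups Reject tumor rows without a group label.
#' @return Validated `sample_meta` tibble.
#' @export
read_sample_meta <- function(path, require_groups = TRUE) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "xplatde_io_error")
  }
  meta <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          na = character(), progress = FALSE, show_col_types = FALSE)
  validate_sample_meta(meta, require_groups = require_groups)
}

#' @rdname read_sample_meta
#' @param meta A `sample_meta` tibble.
#' @export
write_sample_meta <- function(meta, path) {
  readr::write_tsv(as_tibble(meta), path, progress = FALSE)
  invisible(path)
}

#' Read a probe annotation table from TSV
#'
#' Columns: `probe_id`, `gene_id`, `symbol`, `chromosome`.
#'
#' @param path Path to a tab-separated annotation file.
#' @return Validated annotation tibble.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "xplatde_io_error")
  }
  ann <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), gene_id = readr::col_integer(),
    symbol = readr::col_character(), chromosome = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  validate_gene_annotation(ann)
}

#' @rdname read_gene_annotation
#' @param ann Annotation tibble.
#' @export
write_gene_annotation <- function(ann, path) {
  readr::write_tsv(as_tibble(ann), path, progress = FALSE)
  invisible(path)
}

#' Read a motif incidence table
#'
#' Mirrors the published TFBM layout: columns `motif`, `inc` (printed
#' incidence) and `gene_ids` (comma-separated NCBI Gene IDs). Returned as a
#' tidy term table so motif sets flow through the same over-representation
#' machinery as GO/pathway sets.
#'
#' @param path Path to a tab-separated motif table.
#' @return Tidy term tibble with an extra `inc` column holding the printed
#'   incidence values.
#' @export
read_motif_table <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "xplatde_io_error")
  }
  x <- readr::read_tsv(path, col_types = readr::cols(
    motif = readr::col_character(), inc = readr::col_integer(),
    gene_ids = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  out <- validate_term_sets(tibble(
    term_id = x$motif, term_name = x$motif,
    gene_ids = map(strsplit(x$gene_ids, ",", fixed = TRUE), as.integer)
  ))
  out$inc <- x$inc
  out
}

#' Read or write a raw spot table
#'
#' @param path Path to a tab-separated spot table with columns `probe_id`,
#'   `signal`, `bg_local`, `bg_local_sd`, `bg_global` and optionally `flag`.
#' @return Validated raw spot tibble.
#' @export
read_raw_spots <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "xplatde_io_error")
  }
  spots <- readr::read_tsv(path, col_types = readr::cols(
    probe_id = readr::col_character(), flag = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
  validate_raw_spots(spots)
}

#' @rdname read_raw_spots
#' @param spots Raw spot tibble.
#' @export
write_raw_spots <- function(spots, path) {
  readr::write_tsv(as_tibble(spots), path, progress = FALSE)
  invisible(path)
}

#' Read or write a ground-truth table
#'
#' Two columns: `gene_id` and `label` (`common_up`, `common_down`,
#' `group:<label>` or `null`).
#'
#' @param path Path to a tab-separated truth table.
#' @return Tibble with `gene_id` (integer) and `label`.
#' @export
read_ground_truth <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_integer(), label = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
}

#' @rdname read_ground_truth
#' @param truth Ground-truth tibble.
#' @export
write_ground_truth <- function(truth, path) {
  readr::write_tsv(as_tibble(truth), path, progress = FALSE)
  invisible(path)
}
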