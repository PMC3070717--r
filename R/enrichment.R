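# Annotation over-representation via the upper-tail hypergeometric test,
# motif-incidence tabulation and multi-pathway gene selection.

#' Hypergeometric over-representation of annotation terms
#'
#' For each term, tests whether the query set overlaps it more than chance
#' given the universe: `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)`
#' with `N` the universe size, `K` the term size after intersection with the
#' universe, `n` the query size and `k` the observed overlap
#' (upper-tail inclusive; under-representation is not tested). q-values are
#' Storey over the term family. Terms with fewer than 2 genes after
#' universe intersection are skipped (counted in attribute `n_skipped`).
#'
#' @param query Integer gene ids, a subset of `universe`.
#' @param terms Tidy term tibble (`term_id`, `term_name`, `gene_ids`).
#' @param universe Integer gene ids forming the tested universe (typically
#'   the harmonized common gene list).
#' @param lambda Storey tuning parameter for the q-values.
#' @return Tibble `term_id`, `term_name`, `k`, `K`, `n`, `N`, `p`, `q`,
#'   ordered by `p`.
#' @examples
#' terms <- tibble::tibble(term_id = "t", term_name = "t",
#'                         gene_ids = list(1:5))
#' enrich_hypergeometric(1:5, terms, 1:10)$p  # 1 / choose(10, 5)
#' @export
enrich_hypergeometric <- function(query, terms, universe, lambda = 0.5) {
  terms <- validate_term_sets(terms)
  universe <- unique(as.integer(universe))
  query <- unique(as.integer(query))
  if (length(universe) == 0L || length(query) == 0L) {
    abort("query and universe must be non-empty", class = "xplatde_validation_error")
  }
  if (length(setdiff(query, universe))) {
    abort("query contains genes outside the universe",
          class = "xplatde_validation_error")
  }
  N <- length(universe); n <- length(query)
  rows <- pmap(terms, function(term_id, term_name, gene_ids, ...) {
    members <- intersect(gene_ids, universe)
    K <- length(members)
    if (K < 2L) return(NULL)
    k <- length(intersect(members, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(term_id = term_id, term_name = term_name,
           k = k, K = K, n = n, N = N, p = p)
  })
  skipped <- sum(vapply(rows, is.null, logical(1)))
  out <- bind_rows(rows)
  if (nrow(out) > 0L) {
    out$q <- storey_qvalues(out$p, lambda = lambda)$q
    out <- arrange(out, .data$p, .data$term_id)
  } else {
    out$q <- numeric(0)
  }
  attr(out, "n_skipped") <- skipped
  out
}

#' Motif incidence tabulation
#'
#' Tallies, over a motif-to-gene table, how many genes carry each motif and
#' how many motifs each gene appears in; the top gene(s) are those with the
#' maximal motif count (ties listed).
#'
#' @param motifs Tidy term tibble restricted to motifs (e.g. from
#'   [read_motif_table()]).
#' @param annotation Optional annotation tibble used to attach gene symbols.
#' @return A `motif_incidence`: list with `motif_counts` (tibble `term_id`,
#'   `n_genes`), `gene_counts` (tibble `gene_id`, `n_motifs`, descending)
#'   and `top_genes` (integer vector).
#' @export
motif_incidence <- function(motifs, annotation = NULL) {
  motifs <- validate_term_sets(motifs)
  motif_counts <- tibble(term_id = motifs$term_id,
                         n_genes = lengths(motifs$gene_ids))
  all_genes <- unlist(motifs$gene_ids, use.names = FALSE)
  gene_counts <- tibble(gene_id = as.integer(names(table(all_genes))),
                        n_motifs = as.integer(table(all_genes))) |>
    arrange(dplyr::desc(.data$n_motifs), .data$gene_id)
  if (!is.null(annotation)) {
    ann <- distinct(as_tibble(annotation)[c("gene_id", "symbol")])
    gene_counts <- left_join(gene_counts, ann, by = "gene_id")
  }
  top <- gene_counts$gene_id[gene_counts$n_motifs == max(gene_counts$n_motifs)]
  structure(list(motif_counts = motif_counts, gene_counts = gene_counts,
                 top_genes = top),
            class = "motif_incidence")
}

#' @export
print.motif_incidence <- function(x, ...) {
  cat(sprintf("motif incidence: %d motifs, %d genes; top gene(s): %s\n",
              nrow(x$motif_counts), nrow(x$gene_counts),
              paste(x$top_genes, collapse = ", ")))
  invisible(x)
}

#' @rdname motif_incidence
#' @param x A `motif_incidence`.
#' @param ... Unused.
#' @export
tidy.motif_incidence <- function(x, ...) {
  x$gene_counts
}

#' Genes participating in multiple pathways
#'
#' From a pathway membership table, selects the genes of interest that
#' belong to at least `min_pathways` distinct pathways — the rationale being
#' that genes sitting at pathway cross-roads are the strongest candidates
#' among a common set.
#'
#' @param pathway_sets Tidy term tibble of pathway memberships.
#' @param genes Integer gene ids to screen (e.g. the cross-platform common
#'   set).
#' @param min_pathways Minimal number of distinct pathways (>= 1).
#' @return Tibble `gene_id`, `n_pathways`, restricted to qualifying genes,
#'   descending by `n_pathways`.
#' @export
multi_pathway_gene_selection <- function(pathway_sets, genes, min_pathways = 2L) {
  pathway_sets <- validate_term_sets(pathway_sets)
  genes <- unique(as.integer(genes))
  member <- unlist(map2(pathway_sets$term_id, pathway_sets$gene_ids,
                        function(t, g) setNames(intersect(g, genes),
                                                rep(t, length(intersect(g, genes))))))
  if (length(member) == 0L) {
    return(tibble(gene_id = integer(0), n_pathways = integer(0)))
  }
  tibble(gene_id = as.integer(member), term_id = names(member)) |>
    distinct() |>
    count(.data$gene_id, name = "n_pathways") |>
    filter(.data$n_pathways >= min_pathways) |>
    arrange(dplyr::desc(.data$n_pathways), .data$gene_id)
}
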