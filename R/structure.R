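# Clustering, PCA and chromosome-level summaries. Masked entries are
# mean-imputed per gene for clustering/PCA only (never for statistics); the
# imputation count is recorded on the result.

impute_row_means <- function(m) {
  n_imp <- sum(is.na(m))
  if (n_imp > 0) {
    rm <- rowMeans(m, na.rm = TRUE)
    ix <- which(is.na(m), arr.ind = TRUE)
    m[ix] <- rm[ix[, 1]]
  }
  attr(m, "n_imputed") <- n_imp
  m
}

#' Average-linkage hierarchical clustering
#'
#' UPGMA agglomeration on Euclidean distances over genes or samples,
#' delegated to [stats::hclust()] (whose tie handling is deterministic for a
#' fixed input order).
#'
#' @param x Feature-by-sample tibble (first column ids) or numeric matrix.
#' @param axis Cluster `"genes"` (rows) or `"samples"` (columns).
#' @return An `hclust` object with attribute `n_imputed`.
#' @export
hierarchical_cluster <- function(x, axis = c("genes", "samples")) {
  axis <- match.arg(axis)
  m <- if (is.matrix(x)) x else study_matrix(x)
  if (axis == "samples") m <- t(m)
  if (nrow(m) < 2L) {
    abort("need at least two items to cluster", class = "xplatde_validation_error")
  }
  m <- impute_row_means(m)
  hc <- stats::hclust(stats::dist(m, method = "euclidean"), method = "average")
  attr(hc, "n_imputed") <- attr(m, "n_imputed")
  hc
}

#' Export a dendrogram as Newick text
#'
#' @param hc An `hclust` object.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to `path`).
#' @export
dendrogram_newick <- function(hc, path = NULL) {
  tree <- ape::as.phylo(hc)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

# k-means++ seeding: spread initial centers with probability proportional to
# squared distance from the nearest chosen center.
kmeanspp_centers <- function(m, k) {
  n <- nrow(m)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((m - matrix(m[centers[1], ], n, ncol(m), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1] <- sample.int(n, 1, prob = prob)
    nd <- rowSums((m - matrix(m[centers[i + 1], ], n, ncol(m), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  m[centers, , drop = FALSE]
}

#' Seeded k-means clustering
#'
#' k-means++ initialization with an explicit seed, Lloyd iterations via
#' [stats::kmeans()], best of `n_restarts` restarts by total
#' within-cluster sum of squares. Bit-reproducible for a fixed seed.
#'
#' @param x Feature-by-sample tibble or numeric matrix (rows are clustered).
#' @param k Number of clusters (presets used in practice: 24, 49, 81, 100).
#' @param seed Integer seed.
#' @param n_restarts Independent restarts; default 10.
#' @return A `kmeans_result`: list with `k`, `assignments`, `centroids`,
#'   `inertia`, `seed`, `n_restarts`, `n_imputed`.
#' @export
kmeans_cluster <- function(x, k, seed = 1L, n_restarts = 10L) {
  m <- if (is.matrix(x)) x else study_matrix(x)
  if (k > nrow(m)) {
    abort("k exceeds the number of items", class = "xplatde_validation_error")
  }
  m <- impute_row_means(m)
  best <- NULL
  with_substream(seed, "kmeans", {
    for (r in seq_len(n_restarts)) {
      init <- kmeanspp_centers(m, k)
      km <- suppressWarnings(stats::kmeans(m, centers = init, iter.max = 100,
                                           algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  structure(list(
    k = k, assignments = setNames(best$cluster, rownames(m)),
    centroids = best$centers, inertia = best$tot.withinss,
    seed = seed, n_restarts = n_restarts,
    n_imputed = attr(m, "n_imputed")
  ), class = "kmeans_result")
}

#' @export
print.kmeans_result <- function(x, ...) {
  cat(sprintf("k-means: k = %d, inertia = %.4g, %d restarts (seed %d)\n",
              x$k, x$inertia, x$n_restarts, x$seed))
  invisible(x)
}

#' @rdname kmeans_cluster
#' @param x A `kmeans_result`.
#' @param ... Unused.
#' @export
tidy.kmeans_result <- function(x, ...) {
  tibble(item = names(x$assignments), cluster = unname(x$assignments))
}

#' @rdname kmeans_cluster
#' @export
glance.kmeans_result <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, n_restarts = x$n_restarts,
         seed = x$seed, n_imputed = x$n_imputed)
}

#' Principal component analysis of a study
#'
#' Column-centered singular value decomposition over samples; variance
#' fractions sum to 1 and the reconstruction from all components equals the
#' centered input.
#'
#' @param x Feature-by-sample tibble or matrix; samples are the observations.
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `loadings`, `variance_fraction`, `n_imputed`.
#' @export
pca_study <- function(x) {
  m <- if (is.matrix(x)) x else study_matrix(x)
  if (ncol(m) < 2L) {
    abort("need at least two samples for PCA", class = "xplatde_validation_error")
  }
  m <- impute_row_means(m)
  if (all(apply(t(m), 2, stats::sd) == 0)) {
    abort("constant matrix has no principal components",
          class = "xplatde_validation_error")
  }
  pr <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
  vf <- pr$sdev^2 / sum(pr$sdev^2)
  structure(list(scores = pr$x, loadings = pr$rotation,
                 variance_fraction = vf, center = pr$center,
                 n_imputed = attr(m, "n_imputed")),
            class = "pca_result")
}

#' @rdname pca_study
#' @param x A `pca_result`.
#' @param ... Unused.
#' @export
tidy.pca_result <- function(x, ...) {
  as_tibble(x$scores, rownames = "sample_id")
}

#' @rdname pca_study
#' @export
glance.pca_result <- function(x, ...) {
  tibble(component = seq_along(x$variance_fraction),
         variance_fraction = x$variance_fraction)
}

#' Chromosome distribution of a gene set
#'
#' Counts and fractions per chromosome label for a set of genes. Every gene
#' must be annotated; fractions are `NA`-flagged for an empty set.
#'
#' @param genes Integer gene ids.
#' @param annotation Annotation tibble with `gene_id` and `chromosome`
#'   (probe-level tables are collapsed to unique gene rows).
#' @return Tibble `chromosome`, `n_genes`, `fraction`, covering every
#'   allowed label.
#' @export
chromosome_distribution <- function(genes, annotation) {
  ann <- distinct(as_tibble(annotation)[c("gene_id", "chromosome")])
  genes <- unique(as.integer(genes))
  missing <- setdiff(genes, ann$gene_id)
  if (length(missing)) {
    abort(sprintf("unannotated gene id(s): %s",
                  paste(head(missing, 5), collapse = ", ")),
          class = "xplatde_validation_error")
  }
  chroms <- ann$chromosome[match(genes, ann$gene_id)]
  counts <- table(factor(chroms, levels = CHROMOSOME_LABELS))
  tibble(chromosome = CHROMOSOME_LABELS,
         n_genes = as.integer(counts),
         fraction = if (length(genes)) as.integer(counts) / length(genes)
                    else NA_real_)
}

#' Mean expression per chromosome for up- and down-regulated sets
#'
#' For each chromosome, the arithmetic mean of the log2 ratios (over genes
#' and samples) of the member genes of each direction set; chromosomes with
#' no members are masked.
#'
#' @param ratios Gene-level `ratio_matrix` (or harmonized study).
#' @param annotation Annotation with `gene_id`, `chromosome`.
#' @param up,down Integer gene-id sets.
#' @return Tibble `chromosome`, `mean_up`, `mean_down`, `n_up`, `n_down`.
#' @export
chromosome_mean_expression <- function(ratios, annotation, up, down) {
  ann <- distinct(as_tibble(annotation)[c("gene_id", "chromosome")])
  m <- study_matrix(ratios, id_col = "gene_id")
  per_set <- function(set) {
    set <- intersect(as.integer(set), as.integer(rownames(m)))
    chroms <- ann$chromosome[match(set, ann$gene_id)]
    map(CHROMOSOME_LABELS, function(ch) {
      members <- set[!is.na(chroms) & chroms == ch]
      if (length(members) == 0L) {
        list(mean = NA_real_, n = 0L)
      } else {
        list(mean = mean(m[as.character(members), , drop = FALSE], na.rm = TRUE),
             n = length(members))
      }
    })
  }
  u <- per_set(up); d <- per_set(down)
  tibble(chromosome = CHROMOSOME_LABELS,
         mean_up = map_dbl(u, "mean"), mean_down = map_dbl(d, "mean"),
         n_up = map_int(u, "n"), n_down = map_int(d, "n"))
}

#' Chromosomal correlation map
#'
#' Sample-by-sample correlation matrix computed from the expression of the
#' genes residing on one chromosome; consecutive genes on a chromosome are
#' often co-expressed, so shared patterns surface as blocks.
#'
#' @param ratios Gene-level `ratio_matrix` or harmonized study.
#' @param annotation Annotation with `gene_id`, `chromosome`.
#' @param chromosome Chromosome label.
#' @param method `"pearson"` or `"spearman"`.
#' @return A `correlation_map`: list with `chromosome`, `method`, `matrix`
#'   (sample x sample, unit diagonal), `n_genes`.
#' @export
chromosome_correlation_map <- function(ratios, annotation, chromosome,
                                       method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ann <- distinct(as_tibble(annotation)[c("gene_id", "chromosome")])
  m <- study_matrix(ratios, id_col = "gene_id")
  members <- ann$gene_id[ann$chromosome == chromosome]
  members <- intersect(as.character(members), rownames(m))
  if (length(members) < 3L) {
    abort(sprintf("chromosome %s has fewer than 3 measured genes", chromosome),
          class = "xplatde_validation_error")
  }
  sub <- m[members, , drop = FALSE]
  cmat <- stats::cor(sub, method = method, use = "pairwise.complete.obs")
  structure(list(chromosome = chromosome, method = method, matrix = cmat,
                 n_genes = length(members)),
            class = "correlation_map")
}

#' @rdname chromosome_correlation_map
#' @param x A `correlation_map`.
#' @param ... Unused.
#' @export
tidy.correlation_map <- function(x, ...) {
  as_tibble(x$matrix, rownames = "sample_a") |>
    tidyr::pivot_longer(-"sample_a", names_to = "sample_b", values_to = "r")
}
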