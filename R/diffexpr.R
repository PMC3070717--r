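# The four comparison modes plus Storey FDR. All statistics are vectorized
# base-R arithmetic; masked entries are excluded pairwise.

de_call_tibble <- function(gene_id, unit, mode, statistic, p, alpha) {
  # feature ids are integer NCBI Gene IDs after probe collapsing, but calls
  # on probe-level matrices keep their character probe ids
  gid <- suppressWarnings(as.integer(gene_id))
  if (anyNA(gid)) gid <- as.character(gene_id)
  calls <- tibble(
    gene_id = gid, unit = unit, mode = mode,
    statistic = statistic, p = p, q = NA_real_,
    direction = "none", significant = FALSE
  )
  call_de(calls, alpha)
}

#' Threshold differential-expression calls
#'
#' Marks a call significant when `p < alpha` (strict) and assigns direction
#' from the sign of the statistic; non-significant calls carry direction
#' `"none"`.
#'
#' @param calls DE call tibble with `statistic` and `p`.
#' @param alpha Significance threshold (recorded in attribute `alpha`).
#' @return The call tibble with updated `significant` and `direction`.
#' @export
call_de <- function(calls, alpha = 0.05) {
  sig <- !is.na(calls$p) & calls$p < alpha
  calls$significant <- sig
  calls$direction <- ifelse(!sig, "none",
                            ifelse(calls$statistic > 0, "up", "down"))
  attr(calls, "alpha") <- alpha
  calls
}

#' Group-versus-controls t-test
#'
#' Per gene, a two-tailed two-sample t-test of one tumor group (or all
#' tumors pooled, `group = "ALL"`) against all control samples. Default is
#' the pooled-variance Student test with `nA + nB - 2` degrees of freedom;
#' `var_equal = FALSE` switches to Welch. Zero pooled variance with equal
#' means gives `p = 1` by convention; with unequal means the gene is flagged
#' in the `degenerate` column and `p` is masked.
#'
#' @param h A `harmonized_study` (or any gene-by-sample tibble).
#' @param meta Sample metadata; defaults to the one attached to `h`.
#' @param group A tumor group label, or `"ALL"` for all tumors as one group.
#' @param alpha Significance threshold.
#' @param var_equal Pooled-variance Student t (default) or Welch.
#' @return DE call tibble, mode `"group_t"` (`"allvsall_t"` for `"ALL"`),
#'   one row per gene with the group label as `unit`.
#' @export
group_vs_controls_ttest <- function(h, meta = attr(h, "meta"), group = "ALL",
                                    alpha = 0.05, var_equal = TRUE) {
  meta <- validate_sample_meta(meta, require_groups = FALSE)
  m <- study_matrix(h)
  ctrl <- intersect(meta$sample_id[meta$class == "control"], colnames(m))
  gsel <- if (identical(group, "ALL")) {
    meta$class == "tumor"
  } else {
    meta$class == "tumor" & meta$group == group
  }
  gs <- intersect(meta$sample_id[gsel], colnames(m))
  if (length(ctrl) < 2L) {
    abort("need at least two control samples", class = "xplatde_validation_error")
  }
  if (length(gs) < 2L) {
    abort(sprintf("group '%s' has fewer than two samples", group),
          class = "xplatde_validation_error")
  }
  A <- m[, gs, drop = FALSE]; B <- m[, ctrl, drop = FALSE]
  nA <- rowSums(!is.na(A)); nB <- rowSums(!is.na(B))
  mA <- rowMeans(A, na.rm = TRUE); mB <- rowMeans(B, na.rm = TRUE)
  vA <- apply(A, 1, stats::var, na.rm = TRUE)
  vB <- apply(B, 1, stats::var, na.rm = TRUE)
  if (var_equal) {
    sp2 <- ((nA - 1) * vA + (nB - 1) * vB) / (nA + nB - 2)
    se <- sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  } else {
    se <- sqrt(vA / nA + vB / nB)
    df <- (vA / nA + vB / nB)^2 /
      ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1))
  }
  tstat <- (mA - mB) / se
  p <- 2 * stats::pt(-abs(tstat), df)
  zero_var <- is.finite(se) & se == 0
  eq <- zero_var & mA == mB
  tstat[eq] <- 0; p[eq] <- 1
  degen <- (zero_var & mA != mB) | nA < 2 | nB < 2
  p[degen] <- NA_real_
  calls <- de_call_tibble(
    rownames(m), unit = if (identical(group, "ALL")) "ALL" else group,
    mode = if (identical(group, "ALL")) "allvsall_t" else "group_t",
    statistic = unname(tstat), p = unname(p), alpha = alpha
  )
  calls$degenerate <- unname(degen)
  calls
}

#' Per-group t-tests against controls
#'
#' Runs [group_vs_controls_ttest()] for every tumor group of the study.
#'
#' @inheritParams group_vs_controls_ttest
#' @param groups Group labels; default all groups in the metadata.
#' @return DE call tibble with one unit per group.
#' @export
all_groups_ttest <- function(h, meta = attr(h, "meta"), groups = NULL,
                             alpha = 0.05, var_equal = TRUE) {
  meta <- validate_sample_meta(meta, require_groups = FALSE)
  groups <- groups %||% sort(unique(meta$group[meta$class == "tumor" & meta$group != ""]))
  out <- map(groups, ~ group_vs_controls_ttest(h, meta, group = .x,
                                               alpha = alpha, var_equal = var_equal))
  calls <- bind_rows(out)
  attr(calls, "alpha") <- alpha
  calls
}

#' Intra-experimental z-test
#'
#' Per tumor sample, each gene's log2 ratio is standardized against the mean
#' and SD of all genes within that sample's column; two-tailed p from the
#' standard normal. A gene called significant here deviates from the bulk of
#' that sample's comparison to the controls.
#'
#' @param ratios A `ratio_matrix` (gene-by-tumor-sample log2 ratios).
#' @param samples Sample ids to test; default all columns.
#' @param alpha Significance threshold.
#' @return DE call tibble, mode `"intra_z"`, one row per (gene, sample) with
#'   the sample id as `unit`.
#' @export
intra_experimental_ztest <- function(ratios, samples = NULL, alpha = 0.05) {
  m <- study_matrix(ratios)
  samples <- samples %||% colnames(m)
  out <- map(samples, function(s) {
    col <- m[, s]
    ok <- !is.na(col)
    if (sum(ok) < 3L) {
      abort(sprintf("sample '%s' has fewer than 3 unmasked genes", s),
            class = "xplatde_validation_error")
    }
    mu <- mean(col[ok]); sigma <- stats::sd(col[ok])
    if (sigma == 0) {
      abort(sprintf("zero within-sample SD in sample '%s'", s),
            class = "xplatde_validation_error")
    }
    z <- (col - mu) / sigma
    de_call_tibble(rownames(m), unit = s, mode = "intra_z",
                   statistic = unname(z),
                   p = unname(2 * stats::pnorm(-abs(z))), alpha = alpha)
  })
  calls <- bind_rows(out)
  attr(calls, "alpha") <- alpha
  calls
}

#' Inter-experimental z-test
#'
#' Per gene, each sample's log2 ratio is standardized against that gene's
#' mean and SD across samples. A gene is "inter-DE" when significant in at
#' least one sample and "inter-unchanged" otherwise; a constant gene row
#' (zero SD) is inter-unchanged with `p = 1` everywhere.
#'
#' @param ratios A `ratio_matrix`.
#' @param genes Gene ids to test; default all rows.
#' @param alpha Significance threshold.
#' @return DE call tibble, mode `"inter_z"`, one row per (gene, sample).
#' @export
inter_experimental_ztest <- function(ratios, genes = NULL, alpha = 0.05) {
  m <- study_matrix(ratios)
  rows <- if (is.null(genes)) rownames(m) else as.character(genes)
  out <- map(rows, function(g) {
    row <- m[g, ]
    ok <- !is.na(row)
    if (sum(ok) < 3L) {
      abort(sprintf("gene '%s' has fewer than 3 unmasked samples", g),
            class = "xplatde_validation_error")
    }
    mu <- mean(row[ok]); sigma <- stats::sd(row[ok])
    if (sigma == 0) {
      z <- rep(0, length(row)); p <- rep(1, length(row))
    } else {
      z <- (row - mu) / sigma
      p <- 2 * stats::pnorm(-abs(z))
    }
    de_call_tibble(rep(g, length(row)), unit = colnames(m), mode = "inter_z",
                   statistic = unname(z), p = unname(p), alpha = alpha)
  })
  calls <- bind_rows(out)
  attr(calls, "alpha") <- alpha
  calls
}

#' Storey q-values
#'
#' Estimates the null proportion as
#' `pi0 = #{p > lambda} / (m * (1 - lambda))`, clamped to `(1/m, 1]`, and
#' computes step-down q-values `q(p_(i)) = min_{j >= i} pi0 * m * p_(j) / j`,
#' capped at 1.
#'
#' @param p Vector of p-values in `[0, 1]`.
#' @param lambda Tuning parameter in `[0, 1)`; default 0.5.
#' @return An object of class `qvalue_result` with elements `q` (aligned to
#'   `p`), `pi0`, `lambda` and `m`.
#' @examples
#' storey_qvalues(c(0.01, 0.02, 0.9, 0.95))$q  # 0.04 0.04 0.95 0.95
#' @export
storey_qvalues <- function(p, lambda = 0.5) {
  if (length(p) == 0L) {
    abort("empty p-value vector", class = "xplatde_validation_error")
  }
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("p-values must lie in [0, 1] with no missing entries",
          class = "xplatde_validation_error")
  }
  if (lambda < 0 || lambda >= 1) {
    abort("lambda must lie in [0, 1)", class = "xplatde_validation_error")
  }
  m <- length(p)
  pi0 <- sum(p > lambda) / (m * (1 - lambda))
  pi0 <- min(1, max(1 / m, pi0))
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(q = q, pi0 = pi0, lambda = lambda, m = m),
            class = "qvalue_result")
}

#' @export
print.qvalue_result <- function(x, ...) {
  cat(sprintf("Storey q-values: m = %d tests, lambda = %g, pi0 = %.4f\n",
              x$m, x$lambda, x$pi0))
  invisible(x)
}

#' @rdname storey_qvalues
#' @param x A `qvalue_result`.
#' @param ... Unused.
#' @export
tidy.qvalue_result <- function(x, ...) {
  tibble(q = x$q)
}

#' @rdname storey_qvalues
#' @export
glance.qvalue_result <- function(x, ...) {
  tibble(pi0 = x$pi0, lambda = x$lambda, m = x$m)
}

#' Attach q-values per comparison family
#'
#' FDR is estimated separately within each comparison family (one q-value
#' run per unit: per sample for the z modes, per group contrast for the t
#' modes).
#'
#' @param calls DE call tibble.
#' @param lambda Storey tuning parameter.
#' @return The call tibble with its `q` column filled and a `pi0` attribute
#'   (named per unit).
#' @export
add_qvalues <- function(calls, lambda = 0.5) {
  pi0s <- c()
  for (u in unique(calls$unit)) {
    ix <- which(calls$unit == u & !is.na(calls$p))
    if (length(ix) == 0L) next
    qr <- storey_qvalues(calls$p[ix], lambda = lambda)
    calls$q[ix] <- qr$q
    pi0s[u] <- qr$pi0
  }
  attr(calls, "pi0") <- pi0s
  calls
}
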