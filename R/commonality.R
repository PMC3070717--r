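# Set-algebra commonality rules over DE call tables: simultaneous
# intersections, directional group-pair combinations, combined intra/inter
# cases, incidence ranking and tolerant group-common markers. Pure set
# operations: results are invariant to row order and unit relabeling.

new_report <- function(rule_id, gene_id, direction, units, alpha,
                       not_everywhere = integer(0)) {
  out <- tibble(rule_id = rule_id,
                gene_id = as.integer(gene_id),
                direction = direction) |> arrange(.data$gene_id)
  new_tibble(out, class = "commonality_report",
             provenance = list(units = units, alpha = alpha),
             not_everywhere = sort(as.integer(not_everywhere)))
}

# Per-gene tallies over a call table: units present, significant, up, down.
call_tallies <- function(calls) {
  units <- unique(calls$unit)
  calls |>
    group_by(.data$gene_id) |>
    summarise(
      n_present = dplyr::n_distinct(.data$unit),
      n_sig = sum(.data$significant),
      n_up = sum(.data$direction == "up"),
      n_down = sum(.data$direction == "down"),
      .groups = "drop"
    ) |>
    mutate(n_units = length(units))
}

#' Genes differentially expressed in every unit
#'
#' Returns the genes significant (either direction) in every unit of the
#' call table simultaneously. Genes not measured in every unit count as
#' not-DE and are reported separately in attribute `not_everywhere`.
#'
#' @param calls DE call tibble covering every unit.
#' @param rule_id Label recorded on the report.
#' @return A `commonality_report` tibble (`rule_id`, `gene_id`,
#'   `direction`).
#' @export
intersect_de_all_units <- function(calls, rule_id = "DE_in_all_units") {
  t <- call_tallies(calls)
  sel <- t$n_present == t$n_units & t$n_sig == t$n_units
  new_report(rule_id, t$gene_id[sel], rep("any", sum(sel)),
             units = unique(calls$unit), alpha = attr(calls, "alpha"),
             not_everywhere = t$gene_id[t$n_present < t$n_units])
}

#' Simultaneously up- and down-regulated gene sets
#'
#' `up_in_all` holds genes significant with direction up in every unit;
#' `down_in_all` symmetrically. The two sets are disjoint by construction.
#'
#' @param calls DE call tibble.
#' @return A `commonality_report` with rules `up_in_all` and `down_in_all`.
#' @export
simultaneous_direction_sets <- function(calls) {
  t <- call_tallies(calls)
  full <- t$n_present == t$n_units
  up <- full & t$n_up == t$n_units
  down <- full & t$n_down == t$n_units
  new_report(
    c(rep("up_in_all", sum(up)), rep("down_in_all", sum(down))),
    c(t$gene_id[up], t$gene_id[down]),
    c(rep("up", sum(up)), rep("down", sum(down))),
    units = unique(calls$unit), alpha = attr(calls, "alpha"),
    not_everywhere = t$gene_id[!full]
  ) |> arrange(.data$rule_id, .data$gene_id)
}

#' Directional combinations between two tumor groups
#'
#' For two per-group call tables, emits the common-DE set (any direction)
#' and the four directional combinations: up in both, down in both, up in A
#' and down in B, down in A and up in B.
#'
#' @param calls_a,calls_b Single-unit DE call tibbles (one row per gene).
#' @param labels Length-2 labels used in the rule ids.
#' @return A `commonality_report` with five rules.
#' @export
group_pair_combinations <- function(calls_a, calls_b,
                                    labels = c(unique(calls_a$unit)[1],
                                               unique(calls_b$unit)[1])) {
  set_of <- function(calls, dir = NULL) {
    sel <- calls$significant
    if (!is.null(dir)) sel <- sel & calls$direction == dir
    calls$gene_id[sel]
  }
  a_any <- set_of(calls_a); b_any <- set_of(calls_b)
  a_up <- set_of(calls_a, "up"); a_dn <- set_of(calls_a, "down")
  b_up <- set_of(calls_b, "up"); b_dn <- set_of(calls_b, "down")
  rules <- list(
    common = intersect(a_any, b_any),
    up_up = intersect(a_up, b_up),
    down_down = intersect(a_dn, b_dn),
    up_down = intersect(a_up, b_dn),
    down_up = intersect(a_dn, b_up)
  )
  rule_names <- c(
    sprintf("common_%s_%s", labels[1], labels[2]),
    sprintf("up%s_up%s", labels[1], labels[2]),
    sprintf("down%s_down%s", labels[1], labels[2]),
    sprintf("up%s_down%s", labels[1], labels[2]),
    sprintf("down%s_up%s", labels[1], labels[2])
  )
  dirs <- c("any", "up", "down", "mixed", "mixed")
  new_report(
    rep(rule_names, lengths(rules)),
    unlist(rules, use.names = FALSE) %||% integer(0),
    rep(dirs, lengths(rules)),
    units = labels, alpha = attr(calls_a, "alpha")
  ) |> arrange(match(.data$rule_id, rule_names), .data$gene_id)
}

#' Combined intra/inter case selection
#'
#' Case `intra_unchanged_inter_DE`: genes with `p >= alpha` in every
#' intra-experimental unit and significant in at least one
#' inter-experimental unit — genes that move between samples without moving
#' against the controls. Case `inter_unchanged_intra_DE` is the converse.
#'
#' @param intra,inter DE call tibbles from the intra- and inter-experimental
#'   z-tests over the same units.
#' @param case Which combined case to select.
#' @param alpha Threshold; defaults to the one recorded on `intra`.
#' @return A `commonality_report` for the selected case.
#' @export
combined_case_selection <- function(intra, inter,
                                    case = c("intra_unchanged_inter_DE",
                                             "inter_unchanged_intra_DE"),
                                    alpha = attr(intra, "alpha") %||% 0.05) {
  case <- match.arg(case)
  if (!setequal(unique(intra$unit), unique(inter$unit))) {
    abort("intra and inter call tables cover different units",
          class = "xplatde_validation_error")
  }
  unchanged_in <- function(calls) {
    t <- calls |> group_by(.data$gene_id) |>
      summarise(all_null = all(!is.na(.data$p) & .data$p >= alpha),
                n_present = dplyr::n_distinct(.data$unit), .groups = "drop")
    t$gene_id[t$all_null & t$n_present == length(unique(calls$unit))]
  }
  de_somewhere <- function(calls) unique(calls$gene_id[calls$significant])
  sel <- if (case == "intra_unchanged_inter_DE") {
    intersect(unchanged_in(intra), de_somewhere(inter))
  } else {
    intersect(unchanged_in(inter), de_somewhere(intra))
  }
  new_report(case, sel, rep("any", length(sel)),
             units = unique(intra$unit), alpha = alpha)
}

#' Rank genes by differential-expression incidence
#'
#' Tallies, per gene, the number of units in which it is called significant,
#' ordered descending by count with ties broken by ascending gene id. The
#' fraction is count over the total number of units.
#'
#' @param calls DE call tibble (typically per-sample intra-experimental
#'   calls).
#' @return Tibble `gene_id`, `n_units_de`, `n_units`, `fraction`, ordered.
#' @export
de_incidence_ranking <- function(calls) {
  n_units <- length(unique(calls$unit))
  calls |>
    group_by(.data$gene_id) |>
    summarise(n_units_de = sum(.data$significant), .groups = "drop") |>
    mutate(n_units = n_units, fraction = .data$n_units_de / n_units) |>
    arrange(dplyr::desc(.data$n_units_de), .data$gene_id)
}

#' Group-common marker genes with tolerance
#'
#' Genes significant in at least `n_groups - tolerance` groups — tolerance 1
#' captures the "all groups but one" pattern.
#'
#' @param group_calls DE call tibble whose units are group labels (>= 2).
#' @param tolerance Number of groups a gene may miss; must be smaller than
#'   the number of groups.
#' @return A `commonality_report` with rule `DE_in_all_groups_tol_<k>`.
#' @export
group_common_marker <- function(group_calls, tolerance = 0L) {
  n_groups <- length(unique(group_calls$unit))
  if (n_groups < 2L) {
    abort("need at least two groups", class = "xplatde_validation_error")
  }
  if (tolerance >= n_groups) {
    abort("tolerance must be smaller than the number of groups",
          class = "xplatde_validation_error")
  }
  t <- call_tallies(group_calls)
  sel <- t$n_sig >= n_groups - tolerance
  new_report(sprintf("DE_in_all_groups_tol_%d", tolerance),
             t$gene_id[sel], rep("any", sum(sel)),
             units = unique(group_calls$unit),
             alpha = attr(group_calls, "alpha"))
}

#' Intersect commonality reports across platforms
#'
#' Cross-platform commonality is the set intersection of per-platform
#' reports, rule by rule: a gene survives only if every platform's report
#' lists it under the same rule (and direction).
#'
#' @param reports List (>= 2) of `commonality_report` tibbles.
#' @return A `commonality_report` restricted to genes present in every
#'   input report under the same rule.
#' @export
cross_platform_commonality <- function(reports) {
  if (length(reports) < 2L) {
    abort("need at least two reports to intersect",
          class = "xplatde_validation_error")
  }
  keys <- map(reports, ~ paste(.x$rule_id, .x$direction, .x$gene_id, sep = "\r"))
  common <- reduce(keys, intersect)
  parts <- strsplit(common, "\r", fixed = TRUE)
  new_report(
    map_chr(parts, 1) %||% character(0),
    as.integer(map_chr(parts, 3) %||% character(0)),
    map_chr(parts, 2) %||% character(0),
    units = unlist(map(reports, ~ attr(.x, "provenance")$units)),
    alpha = attr(reports[[1]], "provenance")$alpha
  ) |> arrange(.data$rule_id, .data$gene_id)
}
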