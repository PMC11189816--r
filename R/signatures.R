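# Peptide-ID sets present for one (group, condition) cell.
present_set <- function(matrix, group, condition) {
  calls <- matrix$calls
  calls$peptide_id[calls$group == group & calls$condition == condition & calls$present]
}

# The two group labels of a contrastable design, in design order.
contrast_groups <- function(matrix) {
  gs <- names(matrix$design$groups)
  if (length(gs) != 2) abort("group contrast requires exactly two groups")
  gs
}

#' Group Venn partition at one condition
#'
#' Partitions the condition's present-peptide union into peptides present
#' only in the first group (e.g. SZ), present in both, and present only
#' in the second group (e.g. HC).
#'
#' @param matrix A `presence_matrix`.
#' @param condition Condition label.
#' @return List with `counts` (named integer vector: `<g1>_only`,
#'   `shared`, `<g2>_only`) and `members` (the corresponding peptide-ID
#'   sets).
#' @export
group_contrast <- function(matrix, condition) {
  if (!condition %in% matrix$design$conditions) {
    abort(sprintf("unknown condition: %s", condition))
  }
  gs <- contrast_groups(matrix)
  a <- present_set(matrix, gs[1], condition)
  b <- present_set(matrix, gs[2], condition)
  members <- list(setdiff(a, b), intersect(a, b), setdiff(b, a))
  names(members) <- c(paste0(gs[1], "_only"), "shared", paste0(gs[2], "_only"))
  list(
    counts = stats::setNames(lengths(members), names(members)),
    members = members
  )
}

#' Condition Venn partition within one group
#'
#' Partitions a group's present-peptide union across the two conditions:
#' stimulated-only (e.g. KCl-only), both, and basal-only.
#'
#' @param matrix A `presence_matrix`.
#' @param group Group label.
#' @return List with `counts` (named: `<c1>_only`, `both`, `<c2>_only`)
#'   and `members`.
#' @export
condition_contrast <- function(matrix, group) {
  if (!group %in% names(matrix$design$groups)) {
    abort(sprintf("unknown group: %s", group))
  }
  cs <- matrix$design$conditions
  if (length(cs) != 2) abort("condition contrast requires exactly two conditions")
  a <- present_set(matrix, group, cs[1])
  b <- present_set(matrix, group, cs[2])
  members <- list(setdiff(a, b), intersect(a, b), setdiff(b, a))
  names(members) <- c(paste0(cs[1], "_only"), "both", paste0(cs[2], "_only"))
  list(
    counts = stats::setNames(lengths(members), names(members)),
    members = members
  )
}

#' Per-precursor presence tally at one condition
#'
#' For each precursor: how many of its peptides are present in each
#' group, how many are unique to each group, how many are shared, and
#' the precursor's contribution to the condition union. Ambiguous
#' peptides are excluded from these per-precursor tallies (they have no
#' unique precursor assignment) but still count in whole-condition
#' totals reported elsewhere.
#'
#' @param matrix A `presence_matrix`.
#' @param condition Condition label.
#' @return Tibble: `precursor_symbol`, `<g1>` (present count),
#'   `<g1>_only`, `<g2>`, `<g2>_only`, `shared`, `total`, one row per
#'   precursor with any mapped peptide, zeros where nothing is present.
#' @export
precursor_tally <- function(matrix, condition) {
  gs <- contrast_groups(matrix)
  gc <- group_contrast(matrix, condition)
  pep <- matrix$peptides[!matrix$peptides$ambiguous, , drop = FALSE]
  tal <- pep |>
    dplyr::mutate(
      in_a = .data$peptide_id %in% c(gc$members[[1]], gc$members$shared),
      in_b = .data$peptide_id %in% c(gc$members[[3]], gc$members$shared),
      only_a = .data$peptide_id %in% gc$members[[1]],
      only_b = .data$peptide_id %in% gc$members[[3]],
      shared = .data$peptide_id %in% gc$members$shared
    ) |>
    dplyr::group_by(.data$precursor_symbol) |>
    dplyr::summarise(
      a = sum(.data$in_a), a_only = sum(.data$only_a),
      b = sum(.data$in_b), b_only = sum(.data$only_b),
      shared = sum(.data$shared),
      total = sum(.data$in_a | .data$in_b),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$precursor_symbol)
  names(tal) <- c(
    "precursor_symbol", gs[1], paste0(gs[1], "_only"),
    gs[2], paste0(gs[2], "_only"), "shared", "total"
  )
  tal
}

#' Label each peptide's differential status at one condition
#'
#' @param matrix A `presence_matrix`.
#' @param condition Condition label.
#' @return Tibble `peptide_id`, `precursor_symbol`, `peptide`
#'   (`"start-end"`), `label` in `{<g1>-only, <g2>-only, shared, absent}`.
#' @export
label_peptides <- function(matrix, condition) {
  gs <- contrast_groups(matrix)
  gc <- group_contrast(matrix, condition)
  lab <- function(id) {
    if (id %in% gc$members$shared) "shared"
    else if (id %in% gc$members[[1]]) paste0(gs[1], "-only")
    else if (id %in% gc$members[[3]]) paste0(gs[2], "-only")
    else "absent"
  }
  matrix$peptides |>
    dplyr::transmute(
      .data$peptide_id, .data$precursor_symbol,
      peptide = paste0(.data$start, "-", .data$end),
      label = vapply(.data$peptide_id, lab, "", USE.NAMES = FALSE)
    )
}

#' Full differential-signature report
#'
#' Assembles, per condition: the union size, per-group totals, the group
#' Venn partition, per-precursor tallies, and peptide labels; per group:
#' the condition Venn partition. Partition identities (shared +
#' group-unique = group total; union = sum of the three Venn classes)
#' are asserted on every build.
#'
#' @param matrix A `presence_matrix`.
#' @return Object of class `signature_report`: list with `conditions`
#'   (named list of per-condition results), `groups` (named list of
#'   condition contrasts), and `design`.
#' @export
signature_report <- function(matrix) {
  gs <- contrast_groups(matrix)
  conditions <- lapply(matrix$design$conditions, function(cond) {
    gc <- group_contrast(matrix, cond)
    totals <- stats::setNames(
      c(
        length(present_set(matrix, gs[1], cond)),
        length(present_set(matrix, gs[2], cond))
      ),
      gs
    )
    union_n <- sum(gc$counts)
    stopifnot(
      gc$counts[["shared"]] + gc$counts[[paste0(gs[1], "_only")]] == totals[[gs[1]]],
      gc$counts[["shared"]] + gc$counts[[paste0(gs[2], "_only")]] == totals[[gs[2]]]
    )
    list(
      union = union_n,
      totals = totals,
      venn = gc,
      precursor_tally = precursor_tally(matrix, cond),
      labels = label_peptides(matrix, cond)
    )
  })
  names(conditions) <- matrix$design$conditions
  groups <- lapply(gs, function(g) condition_contrast(matrix, g))
  names(groups) <- gs
  structure(
    list(conditions = conditions, groups = groups, design = matrix$design),
    class = "signature_report"
  )
}

#' @export
print.signature_report <- function(x, ...) {
  gs <- names(x$conditions[[1]]$totals)
  cat("<signature_report>\n")
  for (cond in names(x$conditions)) {
    cc <- x$conditions[[cond]]
    cat(sprintf(
      "  %s: union %d | %s %d, %s %d | venn (%s)\n",
      cond, cc$union, gs[1], cc$totals[[1]], gs[2], cc$totals[[2]],
      paste(sprintf("%s=%d", names(cc$venn$counts), cc$venn$counts), collapse = ", ")
    ))
  }
  for (g in names(x$groups)) {
    cat(sprintf(
      "  %s across conditions: %s\n", g,
      paste(sprintf("%s=%d", names(x$groups[[g]]$counts), x$groups[[g]]$counts),
        collapse = ", "
      )
    ))
  }
  invisible(x)
}

#' Serialise a signature report to JSON
#'
#' @param report A `signature_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signature_report <- function(report, path) {
  out <- list(
    conditions = lapply(report$conditions, function(cc) {
      list(
        union = cc$union,
        totals = as.list(cc$totals),
        venn_counts = as.list(cc$venn$counts),
        venn_members = cc$venn$members,
        precursor_tally = cc$precursor_tally,
        labels = cc$labels
      )
    }),
    groups = lapply(report$groups, function(gc) {
      list(counts = as.list(gc$counts), members = gc$members)
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
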