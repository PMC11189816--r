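#' Culture-level presence call
#'
#' A peptide is present in one culture replicate when its detections span
#' at least `tech_threshold` *distinct* technical injections (repeat
#' features within one injection count once).
#'
#' @param tech_reps Integer vector of technical-replicate indices carrying
#'   a detection (possibly with repeats), for one peptide x subject x
#'   condition x culture replicate.
#' @param tech_threshold Minimum number of distinct injections.
#' @return Logical.
#' @export
call_culture <- function(tech_reps, tech_threshold = 1L) {
  length(unique(tech_reps)) >= tech_threshold
}

#' Subject-level presence call
#'
#' A peptide is present in a subject when at least `culture_threshold` of
#' its culture replicates carry a culture-level call.
#'
#' @param culture_calls Logical vector, one entry per culture replicate.
#' @param culture_threshold Minimum number of positive cultures.
#' @param n_culture_reps Expected number of entries; mismatched arity is
#'   an error. `NULL` skips the arity check (incomplete designs are
#'   called on the available replicates against the same absolute
#'   threshold).
#' @return Logical.
#' @export
call_subject <- function(culture_calls, culture_threshold = 2L,
                         n_culture_reps = length(culture_calls)) {
  if (!is.null(n_culture_reps) && length(culture_calls) != n_culture_reps) {
    abort(sprintf(
      "expected %d culture calls, got %d", n_culture_reps, length(culture_calls)
    ))
  }
  sum(culture_calls) >= culture_threshold
}

#' Group-level presence call
#'
#' A peptide is present in a group when at least the group's subject
#' threshold of its subjects carry a subject-level call (5 of 7 SZ, 4 of
#' 6 HC under the default design).
#'
#' @param subject_calls Named logical vector, one entry per subject in
#'   the group (names are subject IDs).
#' @param group Group label.
#' @param design A [study_design()].
#' @return Logical.
#' @export
call_group <- function(subject_calls, group, design = study_design()) {
  if (!group %in% names(design$groups)) {
    abort(sprintf("unknown group: %s", group))
  }
  expected <- design$groups[[group]]
  if (!is.null(names(subject_calls))) {
    stray <- setdiff(names(subject_calls), expected)
    if (length(stray) > 0) {
      abort(sprintf(
        "subject(s) not in group %s: %s", group, paste(stray, collapse = ", ")
      ))
    }
  } else if (length(subject_calls) != length(expected)) {
    abort(sprintf(
      "expected %d subject calls for group %s, got %d",
      length(expected), group, length(subject_calls)
    ))
  }
  sum(subject_calls) >= design$group_presence_threshold[[group]]
}

#' Build the hierarchical presence matrix
#'
#' Composes the three presence rules over a filtered, mapped observation
#' table. Peptide identity is `(precursor_symbol, start, end)`:
#' modification states of one coordinate span collapse to one peptide.
#' Ambiguous peptides are called at their primary site and carry the
#' `ambiguous` flag through. Every peptide entering the table is kept in
#' the matrix even when all four group x condition calls are negative.
#'
#' @param obs Filtered observation tibble.
#' @param mapping Mapping tibble from [map_peptides()]; observations whose
#'   backbone is absent from the mapping (e.g. decoys) are dropped with a
#'   count recorded in attribute `"n_unmapped_obs"`.
#' @param design A [study_design()].
#' @return An object of class `presence_matrix`: list with
#'   * `peptides`: tibble `peptide_id`, `precursor_symbol`, `start`,
#'     `end`, `sequence`, `ambiguous`;
#'   * `calls`: tibble `peptide_id` x `group` x `condition` -> `present`;
#'   * `subject_detail`: `peptide_id` x `subject_id` x `condition` ->
#'     `present`;
#'   * `culture_detail`: `peptide_id` x `subject_id` x `condition` x
#'     `culture_rep` -> `present`;
#'   * `design`.
#' @export
build_presence_matrix <- function(obs, mapping, design = study_design()) {
  if ("is_decoy" %in% names(obs)) obs <- obs[!obs$is_decoy, , drop = FALSE]

  peptides <- mapping |>
    dplyr::transmute(
      peptide_id = paste0(.data$precursor_symbol, ":", .data$start, "-", .data$end),
      .data$precursor_symbol, .data$start, .data$end, .data$sequence,
      .data$ambiguous
    ) |>
    dplyr::distinct(.data$peptide_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$precursor_symbol, .data$start, .data$end)

  seq2id <- mapping |>
    dplyr::transmute(
      .data$sequence,
      peptide_id = paste0(.data$precursor_symbol, ":", .data$start, "-", .data$end)
    ) |>
    dplyr::distinct()

  obs2 <- dplyr::inner_join(obs, seq2id, by = "sequence")
  n_unmapped <- nrow(obs) - nrow(dplyr::semi_join(obs, seq2id, by = "sequence"))

  subj <- design_subjects(design)
  grid <- tidyr::expand_grid(
    peptide_id = peptides$peptide_id,
    subj,
    condition = design$conditions,
    culture_rep = seq_len(design$n_culture_reps)
  )

  detected <- obs2 |>
    dplyr::group_by(
      .data$peptide_id, .data$subject_id, .data$condition, .data$culture_rep
    ) |>
    dplyr::summarise(
      n_tech = dplyr::n_distinct(.data$tech_rep), .groups = "drop"
    )

  culture_detail <- grid |>
    dplyr::left_join(
      detected,
      by = c("peptide_id", "subject_id", "condition", "culture_rep")
    ) |>
    dplyr::mutate(
      present = dplyr::coalesce(.data$n_tech, 0L) >= design$tech_threshold
    ) |>
    dplyr::select(-"n_tech")

  subject_detail <- culture_detail |>
    dplyr::group_by(
      .data$peptide_id, .data$subject_id, .data$group, .data$condition
    ) |>
    dplyr::summarise(
      present = sum(.data$present) >= design$culture_threshold, .groups = "drop"
    )

  thr <- tibble::tibble(
    group = names(design$group_presence_threshold),
    .thr = as.integer(design$group_presence_threshold)
  )
  calls <- subject_detail |>
    dplyr::group_by(.data$peptide_id, .data$group, .data$condition) |>
    dplyr::summarise(n_subjects = sum(.data$present), .groups = "drop") |>
    dplyr::left_join(thr, by = "group") |>
    dplyr::mutate(present = .data$n_subjects >= .data$.thr) |>
    dplyr::select("peptide_id", "group", "condition", "present")

  structure(
    list(
      peptides = peptides,
      calls = calls,
      subject_detail = subject_detail,
      culture_detail = culture_detail,
      design = design,
      n_unmapped_obs = n_unmapped
    ),
    class = "presence_matrix"
  )
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf(
    "<presence_matrix> %d peptides x %d groups x %d conditions\n",
    nrow(x$peptides), length(x$design$groups), length(x$design$conditions)
  ))
  print(utils::head(presence_wide(x), 10))
  invisible(x)
}

#' Presence matrix in wide +/- form
#'
#' One row per peptide, one `+`/`-` column per group x condition cell, in
#' the column order group-major (e.g. SZ-KCl, SZ-basal, HC-KCl,
#' HC-basal) — the layout of a printed presence table.
#'
#' @param matrix A `presence_matrix`.
#' @return Tibble: `precursor_symbol`, `peptide` (`"start-end"`), one
#'   character column per cell.
#' @export
presence_wide <- function(matrix) {
  cells <- tidyr::expand_grid(
    group = names(matrix$design$groups),
    condition = matrix$design$conditions
  )
  cell_cols <- paste(cells$group, cells$condition, sep = "_")
  if (nrow(matrix$peptides) == 0) {
    out <- tibble::tibble(precursor_symbol = character(), peptide = character())
    for (cc in cell_cols) out[[cc]] <- character()
    return(out)
  }
  wide <- matrix$calls |>
    dplyr::mutate(
      cell = paste(.data$group, .data$condition, sep = "_"),
      mark = ifelse(.data$present, "+", "-")
    ) |>
    dplyr::select("peptide_id", "cell", "mark") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "mark")
  matrix$peptides |>
    dplyr::transmute(
      .data$peptide_id, .data$precursor_symbol,
      peptide = paste0(.data$start, "-", .data$end)
    ) |>
    dplyr::left_join(wide, by = "peptide_id") |>
    dplyr::select("precursor_symbol", "peptide", dplyr::all_of(cell_cols))
}

#' Per-subject presence detail in wide form
#'
#' One row per peptide and condition, one `+`/`-` column per subject —
#' the layout of a per-subject presence table.
#'
#' @param matrix A `presence_matrix`.
#' @param condition Condition to tabulate.
#' @return Tibble with `precursor_symbol`, `peptide`, and one column per
#'   subject ID.
#' @export
subject_detail_wide <- function(matrix, condition) {
  if (!condition %in% matrix$design$conditions) {
    abort(sprintf("unknown condition: %s", condition))
  }
  subjects <- unlist(matrix$design$groups, use.names = FALSE)
  det <- matrix$subject_detail |>
    dplyr::filter(.data$condition == !!condition) |>
    dplyr::mutate(mark = ifelse(.data$present, "+", "-")) |>
    dplyr::select("peptide_id", "subject_id", "mark") |>
    tidyr::pivot_wider(names_from = "subject_id", values_from = "mark")
  matrix$peptides |>
    dplyr::transmute(
      .data$peptide_id, .data$precursor_symbol,
      peptide = paste0(.data$start, "-", .data$end)
    ) |>
    dplyr::left_join(det, by = "peptide_id") |>
    dplyr::select("precursor_symbol", "peptide", dplyr::all_of(subjects))
}
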