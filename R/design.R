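#' Study design: subjects, replicates, and presence thresholds
#'
#' Describes the secretion experiment's layout: which subjects belong to
#' which group, how many culture replicates and technical injections each
#' sample has, which secretion conditions were assayed, and the minimum
#' counts the hierarchical presence rule requires at each level (technical
#' injections per culture, cultures per subject, subjects per group).
#'
#' The default reproduces the study layout this package targets: 7
#' schizophrenia (SZ) and 6 healthy-control (HC) subjects (labelled A-M),
#' 3 culture replicates each injected twice, assayed under KCl-depolarised
#' and basal secretion, with a peptide called present in a culture when
#' seen in at least 1 of 2 injections, in a subject when present in at
#' least 2 of 3 cultures, and in a group when present in at least 5 of 7
#' SZ or 4 of 6 HC subjects.
#'
#' @param groups Named list mapping each group label to a character vector
#'   of subject IDs. Subject IDs must be unique across groups.
#' @param n_culture_reps Number of cell-culture replicates per subject.
#' @param n_tech_reps Number of technical injections per culture replicate.
#' @param conditions Character vector of secretion conditions.
#' @param group_presence_threshold Named integer vector (one entry per
#'   group): minimum number of presence-positive subjects for a group call.
#' @param tech_threshold Minimum number of distinct technical replicates
#'   with a detection for a culture-level call.
#' @param culture_threshold Minimum number of presence-positive culture
#'   replicates for a subject-level call.
#'
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design()
#' d$group_presence_threshold
#' @export
study_design <- function(groups = list(SZ = LETTERS[1:7], HC = LETTERS[8:13]),
                         n_culture_reps = 3L,
                         n_tech_reps = 2L,
                         conditions = c("KCl", "basal"),
                         group_presence_threshold = c(SZ = 5L, HC = 4L),
                         tech_threshold = 1L,
                         culture_threshold = 2L) {
  stopifnot(is.list(groups), length(groups) >= 1, !is.null(names(groups)))
  subjects <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(subjects)) {
    abort("every subject must belong to exactly one group")
  }
  if (!all(names(groups) %in% names(group_presence_threshold))) {
    abort("group_presence_threshold must name every group")
  }
  for (g in names(groups)) {
    if (group_presence_threshold[[g]] > length(groups[[g]])) {
      abort(sprintf(
        "group threshold for %s (%d) exceeds its subject count (%d)",
        g, group_presence_threshold[[g]], length(groups[[g]])
      ))
    }
  }
  if (tech_threshold > n_tech_reps) {
    abort("tech_threshold exceeds n_tech_reps")
  }
  if (culture_threshold > n_culture_reps) {
    abort("culture_threshold exceeds n_culture_reps")
  }
  structure(
    list(
      groups = groups,
      n_culture_reps = as.integer(n_culture_reps),
      n_tech_reps = as.integer(n_tech_reps),
      conditions = as.character(conditions),
      group_presence_threshold = stats::setNames(
        as.integer(group_presence_threshold[names(groups)]), names(groups)
      ),
      tech_threshold = as.integer(tech_threshold),
      culture_threshold = as.integer(culture_threshold)
    ),
    class = "study_design"
  )
}

#' @export
print.study_design <- function(x, ...) {
  cat("<study_design>\n")
  for (g in names(x$groups)) {
    cat(sprintf(
      "  %s: %d subjects (%s), group threshold >= %d\n",
      g, length(x$groups[[g]]), paste(x$groups[[g]], collapse = ","),
      x$group_presence_threshold[[g]]
    ))
  }
  cat(sprintf(
    "  %d culture reps (>= %d), %d tech reps (>= %d); conditions: %s\n",
    x$n_culture_reps, x$culture_threshold,
    x$n_tech_reps, x$tech_threshold,
    paste(x$conditions, collapse = ", ")
  ))
  invisible(x)
}

#' Group membership lookup
#'
#' @param design A `study_design`.
#' @return Tibble with columns `subject_id`, `group`.
#' @export
design_subjects <- function(design) {
  stopifnot(inherits(design, "study_design"))
  purrr::imap_dfr(design$groups, function(subj, g) {
    tibble::tibble(subject_id = subj, group = g)
  })
}

#' Identification filter thresholds
#'
#' Quality gates applied to observation tables before presence calling.
#' Abundance and quality cuts are strict (`>`): a feature exactly at a
#' threshold is rejected. Defaults follow the quantification restrictions
#' used for the secretion study: XIC area above 1e4, feature quality above
#' 0.3, retention-time agreement within 3 min across replicate injections,
#' 20 ppm precursor-mass tolerance, and a 0.3% target-decoy FDR when the
#' decoy filter is enabled.
#'
#' @param min_abundance Minimum XIC area under the curve (exclusive),
#'   arbitrary intensity units.
#' @param min_quality Minimum feature quality (exclusive), unitless.
#' @param rt_tolerance_min Maximum retention-time span within a replicate
#'   feature group, minutes.
#' @param fdr_max Maximum target-decoy false discovery rate, proportion.
#' @param ms1_ppm_tol Maximum precursor m/z deviation from the feature
#'   group median, parts per million.
#'
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_abundance = 1e4,
                          min_quality = 0.3,
                          rt_tolerance_min = 3.0,
                          fdr_max = 0.003,
                          ms1_ppm_tol = 20.0) {
  vals <- c(min_abundance, min_quality, rt_tolerance_min, fdr_max, ms1_ppm_tol)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("all filter thresholds must be finite and >= 0")
  }
  if (fdr_max > 1) abort("fdr_max must lie in [0, 1]")
  structure(
    list(
      min_abundance = min_abundance,
      min_quality = min_quality,
      rt_tolerance_min = rt_tolerance_min,
      fdr_max = fdr_max,
      ms1_ppm_tol = ms1_ppm_tol
    ),
    class = "filter_config"
  )
}

#' @export
print.filter_config <- function(x, ...) {
  cat("<filter_config>\n")
  cat(sprintf("  abundance > %g, quality > %g\n", x$min_abundance, x$min_quality))
  cat(sprintf(
    "  RT span <= %g min, MS1 <= %g ppm, FDR <= %g\n",
    x$rt_tolerance_min, x$ms1_ppm_tol, x$fdr_max
  ))
  invisible(x)
}
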