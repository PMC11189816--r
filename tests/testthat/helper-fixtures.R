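# Builders for small in-code fixtures.

# One or more canonical observation rows with overridable fields; vector
# arguments recycle.
make_obs <- function(sequence = "PEPTIDEK", modifications = "",
                     precursor_accession = "P1", abundance = 5e5,
                     quality = 0.9, rt_min = 20, mz = 500,
                     subject_id = "A", group = "SZ", condition = "KCl",
                     culture_rep = 1L, tech_rep = 1L, is_decoy = FALSE) {
  tibble::tibble(
    sequence = sequence, modifications = modifications,
    precursor_accession = precursor_accession, abundance = abundance,
    quality = quality, rt_min = rt_min, mz = mz, subject_id = subject_id,
    group = group, condition = condition,
    culture_rep = as.integer(culture_rep), tech_rep = as.integer(tech_rep),
    is_decoy = is_decoy
  )
}

# A presence_matrix object built directly from a calls table, for
# set-algebra tests that need arbitrary matrices without observations.
make_matrix <- function(calls, peptides = NULL, design = study_design()) {
  if (is.null(peptides)) {
    ids <- unique(calls$peptide_id)
    parts <- strsplit(ids, "[:-]")
    peptides <- tibble::tibble(
      peptide_id = ids,
      precursor_symbol = vapply(parts, `[`, "", 1),
      start = as.integer(vapply(parts, `[`, "", 2)),
      end = as.integer(vapply(parts, `[`, "", 3)),
      sequence = strrep("A", 5),
      ambiguous = FALSE
    )
  }
  structure(
    list(peptides = peptides, calls = calls, subject_detail = NULL,
         culture_detail = NULL, design = design),
    class = "presence_matrix"
  )
}

# Random calls table over n peptides for the two default groups/conditions.
random_calls <- function(n, design = study_design(), prob = 0.5) {
  grid <- tidyr::expand_grid(
    peptide_id = sprintf("P%02d:%d-%d", seq_len(n), seq_len(n), seq_len(n) + 4L),
    group = names(design$groups),
    condition = design$conditions
  )
  grid$present <- runif(nrow(grid)) < prob
  grid
}

# Independent all-positions substring scan (oracle for map_peptide).
naive_sites <- function(backbone, precursors) {
  out <- NULL
  for (i in seq_len(nrow(precursors))) {
    s <- precursors$sequence[i]
    len <- nchar(backbone)
    for (p in seq_len(max(0L, nchar(s) - len + 1L))) {
      if (substr(s, p, p + len - 1L) == backbone) {
        out <- rbind(out, data.frame(
          precursor_symbol = precursors$symbol[i], start = p, end = p + len - 1L
        ))
      }
    }
  }
  out
}

# Brute-force FDR filter: try every cutoff ascending, keep the smallest
# one whose decoy/target ratio among scores >= cutoff meets the bound.
brute_fdr_retained <- function(scores, is_decoy, fdr_max) {
  for (c in sort(unique(scores))) {
    nt <- sum(!is_decoy & scores >= c)
    nd <- sum(is_decoy & scores >= c)
    if (nt > 0 && nd / nt <= fdr_max) {
      return(sort(scores[!is_decoy & scores >= c]))
    }
  }
  numeric()
}

# Exact binomial composition of the hierarchical presence rule:
# probability one group call is positive when each injection detects
# independently with probability p. Written from the rule definition,
# independent of the package's implementation.
exact_group_call_prob <- function(p, n_tech, tech_thr, n_cult, cult_thr,
                                  n_subj, subj_thr) {
  tail_ge <- function(k, n, pr) sum(dbinom(k:n, n, pr))
  p_cult <- tail_ge(tech_thr, n_tech, p)
  p_subj <- tail_ge(cult_thr, n_cult, p_cult)
  tail_ge(subj_thr, n_subj, p_subj)
}
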