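#' Subject-level abundance of one peptide
#'
#' Aggregates replicate XIC areas respecting the nested design: each
#' culture replicate's value is the mean over its technical injections,
#' and the subject value is the mean over available culture replicates.
#' Missing injections or cultures are ignored, never imputed as zero.
#'
#' @param abundance Numeric XIC areas (NA allowed).
#' @param culture_rep Parallel culture-replicate indices.
#' @return The subject abundance, or `NA` when no value is available.
#' @examples
#' subject_abundance(c(100, 200), c(1, 1)) # 150: one culture, two injections
#' subject_abundance(c(100, 200), c(1, 2)) # 150: two single-injection cultures
#' @export
subject_abundance <- function(abundance, culture_rep) {
  keep <- !is.na(abundance)
  if (!any(keep)) return(NA_real_)
  culture_means <- tapply(abundance[keep], culture_rep[keep], mean)
  mean(culture_means)
}

#' Group summary: n, mean, standard error of the mean
#'
#' s.e.m. is the sample (n-1) standard deviation over sqrt(n); it is `NA`
#' (unavailable) for a single value.
#'
#' @param values Subject-level abundances; NAs dropped.
#' @return Named list `n`, `mean`, `sem`.
#' @export
group_stats <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n == 0) return(list(n = 0L, mean = NA_real_, sem = NA_real_))
  list(
    n = n,
    mean = mean(values),
    sem = if (n >= 2) sd(values) / sqrt(n) else NA_real_
  )
}

#' Pooled-variance two-tailed Student's t-test
#'
#' Classical two-sample Student's t with pooled variance and
#' n1 + n2 - 2 degrees of freedom, two-tailed p from the t distribution.
#' The equal-variance form is appropriate where group variances are
#' similar. Degenerate inputs (both variances zero): equal means give
#' t = 0, p = 1 by convention; unequal means give p = 0 with a warning
#' (the test statistic is unbounded).
#'
#' @param x,y Numeric vectors, each of length >= 2 after NA removal.
#' @return Named list `t`, `df`, `p`.
#' @export
pooled_t_test <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  n1 <- length(x)
  n2 <- length(y)
  if (n1 < 2 || n2 < 2) abort("pooled_t_test requires n >= 2 per group")
  df <- n1 + n2 - 2
  v1 <- stats::var(x)
  v2 <- stats::var(y)
  if (v1 == 0 && v2 == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = df, p = 1))
    }
    warn("both group variances are zero with unequal means; p = 0 is degenerate")
    return(list(t = sign(mean(x) - mean(y)) * Inf, df = df, p = 0))
  }
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

#' Per-peptide LFQ summaries and group/condition contrasts
#'
#' Computes, for every peptide in the presence matrix: subject-level
#' abundances (culture means of injection means), per group x condition
#' cell the `(n, mean, sem)` summary, the between-group pooled t-test at
#' each condition, and the between-condition test within each group.
#' Between-group tests are computed only where the presence matrix calls
#' the peptide present in both groups at that condition (quantities of
#' absent peptides are not imputed); the same rule applies across
#' conditions within a group.
#'
#' @param obs Filtered observation tibble.
#' @param matrix A `presence_matrix` built from `obs`.
#' @param paired Use a paired t-test for the condition contrast (subjects
#'   matched across conditions). Default unpaired.
#' @param p_adjust Optional p-value adjustment method applied across
#'   peptides per contrast (e.g. `"BH"`); `"none"` (default) reports raw
#'   p-values.
#' @param alpha Significance level; `significant` flags `p < alpha`.
#' @return List of tibbles: `cells` (peptide x group x condition
#'   summaries) and `contrasts` (one row per peptide and contrast with
#'   `t`, `df`, `p`, `p_adj`, `significant`).
#' @export
quantify_peptides <- function(obs, matrix, paired = FALSE,
                              p_adjust = "none", alpha = 0.05) {
  design <- matrix$design
  seqs <- matrix$peptides[, c("peptide_id", "sequence")]
  obs2 <- dplyr::inner_join(obs, seqs, by = "sequence")

  subj_ab <- obs2 |>
    dplyr::group_by(
      .data$peptide_id, .data$subject_id, .data$group, .data$condition
    ) |>
    dplyr::summarise(
      abundance = subject_abundance(.data$abundance, .data$culture_rep),
      .groups = "drop"
    )

  cells <- subj_ab |>
    dplyr::group_by(.data$peptide_id, .data$group, .data$condition) |>
    dplyr::summarise(
      n = sum(!is.na(.data$abundance)),
      mean = mean(.data$abundance, na.rm = TRUE),
      sem = {
        v <- .data$abundance[!is.na(.data$abundance)]
        if (length(v) >= 2) sd(v) / sqrt(length(v)) else NA_real_
      },
      .groups = "drop"
    )

  calls <- matrix$calls
  is_present <- function(pid, g, cond) {
    any(calls$present[
      calls$peptide_id == pid & calls$group == g & calls$condition == cond
    ])
  }
  values_for <- function(pid, g, cond) {
    v <- subj_ab$abundance[
      subj_ab$peptide_id == pid & subj_ab$group == g & subj_ab$condition == cond
    ]
    v[!is.na(v)]
  }

  gs <- names(design$groups)
  rows <- list()
  add_row <- function(pid, contrast, res) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      peptide_id = pid, contrast = contrast,
      t = res$t, df = res$df, p = res$p
    )
  }
  for (pid in matrix$peptides$peptide_id) {
    for (cond in design$conditions) {
      if (length(gs) == 2 && is_present(pid, gs[1], cond) &&
        is_present(pid, gs[2], cond)) {
        a <- values_for(pid, gs[1], cond)
        b <- values_for(pid, gs[2], cond)
        if (length(a) >= 2 && length(b) >= 2) {
          add_row(
            pid, sprintf("%s_vs_%s@%s", gs[1], gs[2], cond),
            pooled_t_test(a, b)
          )
        }
      }
    }
    if (length(design$conditions) == 2) {
      cs <- design$conditions
      for (g in gs) {
        if (is_present(pid, g, cs[1]) && is_present(pid, g, cs[2])) {
          if (paired) {
            sub <- subj_ab[subj_ab$peptide_id == pid & subj_ab$group == g, ]
            w <- tidyr::pivot_wider(
              sub[, c("subject_id", "condition", "abundance")],
              names_from = "condition", values_from = "abundance"
            )
            d <- w[[cs[1]]] - w[[cs[2]]]
            d <- d[!is.na(d)]
            if (length(d) >= 2 && sd(d) > 0) {
              t <- mean(d) / (sd(d) / sqrt(length(d)))
              add_row(
                pid, sprintf("%s_vs_%s@%s(paired)", cs[1], cs[2], g),
                list(t = t, df = length(d) - 1, p = 2 * pt(-abs(t), length(d) - 1))
              )
            }
          } else {
            a <- values_for(pid, g, cs[1])
            b <- values_for(pid, g, cs[2])
            if (length(a) >= 2 && length(b) >= 2) {
              add_row(
                pid, sprintf("%s_vs_%s@%s", cs[1], cs[2], g),
                pooled_t_test(a, b)
              )
            }
          }
        }
      }
    }
  }
  contrasts <- dplyr::bind_rows(rows)
  if (nrow(contrasts) == 0) {
    contrasts <- tibble::tibble(
      peptide_id = character(), contrast = character(),
      t = double(), df = double(), p = double()
    )
  }
  contrasts <- contrasts |>
    dplyr::group_by(.data$contrast) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = p_adjust)) |>
    dplyr::ungroup() |>
    dplyr::mutate(significant = .data$p_adj < alpha)
  list(cells = cells, contrasts = contrasts)
}
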