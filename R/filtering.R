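#' Target-decoy FDR filter
#'
#' Standard target-decoy score filtering: among observations scored by the
#' identification engine and labelled target/decoy, retain targets at the
#' smallest score cutoff whose estimated FDR
#' (#decoys >= cutoff) / (#targets >= cutoff) stays at or below `fdr_max`.
#' Decoy rows are always removed from the output, whatever the cutoff.
#'
#' Real identification-engine exports are typically already FDR-filtered
#' upstream, so this gate is optional in [run_pipeline()] (off by default
#' there); the synthetic generator labels decoys so the gate can be
#' exercised end-to-end.
#'
#' @param obs Observation tibble with `is_decoy` and a score column.
#' @param fdr_max Maximum acceptable FDR, in (0, 1].
#' @param score Name of the score column (default `"quality"`).
#' @return Retained target observations, with attribute `"cutoff"` (the
#'   score threshold applied) and `"fdr"` (the achieved estimate).
#' @export
fdr_filter <- function(obs, fdr_max = 0.003, score = "quality") {
  if (!is.numeric(fdr_max) || fdr_max <= 0) abort("fdr_max must be > 0")
  if (!score %in% names(obs)) abort(sprintf("no score column '%s'", score))
  s <- obs[[score]]
  if (any(is.na(s))) abort("score column contains missing values")
  is_target <- !obs$is_decoy
  if (!any(is_target)) abort("no target observations to filter")

  # candidate cutoffs: every observed score, scanned best-first; FDR at
  # cutoff c counts decoys/targets with score >= c
  cand <- sort(unique(s), decreasing = TRUE)
  cutoff <- NA_real_
  fdr_at <- NA_real_
  for (c in rev(cand)) { # ascending: prefer the most permissive passing cutoff
    nt <- sum(is_target & s >= c)
    nd <- sum(!is_target & s >= c)
    if (nt > 0 && nd / nt <= fdr_max) {
      cutoff <- c
      fdr_at <- nd / nt
      break
    }
  }
  if (is.na(cutoff)) {
    # no cutoff meets the bound; retain nothing
    out <- obs[is_target & s > max(s), , drop = FALSE]
    attr(out, "cutoff") <- Inf
    attr(out, "fdr") <- NA_real_
    return(out)
  }
  out <- obs[is_target & s >= cutoff, , drop = FALSE]
  attr(out, "cutoff") <- cutoff
  attr(out, "fdr") <- fdr_at
  out
}

#' Abundance/quality gate
#'
#' Retains observations with abundance strictly above `min_abundance` and
#' quality strictly above `min_quality`; a feature exactly at either
#' threshold is rejected. Rows with missing abundance or quality fail the
#' corresponding gate (an unquantified feature cannot certify the cut).
#'
#' @param obs Observation tibble.
#' @param config A [filter_config()].
#' @return Retained observations with attribute `"rejections"`: named
#'   counts of rows failing each gate.
#' @export
quality_filter <- function(obs, config = filter_config()) {
  ab_ok <- !is.na(obs$abundance) & obs$abundance > config$min_abundance
  q_ok <- !is.na(obs$quality) & obs$quality > config$min_quality
  out <- obs[ab_ok & q_ok, , drop = FALSE]
  attr(out, "rejections") <- c(
    low_abundance = sum(!ab_ok),
    low_quality = sum(ab_ok & !q_ok)
  )
  out
}

# Does a subset (row indices into rt/mz vectors) satisfy the RT-span and
# ppm constraints? ppm deviation is measured against the subset's median m/z.
subset_consistent <- function(idx, rt, mz, rt_tol, ppm_tol) {
  if (length(idx) <= 1) return(TRUE)
  if (diff(range(rt[idx])) > rt_tol) return(FALSE)
  med <- median(mz[idx])
  all(abs(mz[idx] - med) / med * 1e6 <= ppm_tol)
}

# Largest RT/ppm-consistent subset of one feature group; ties broken by
# total abundance, then earliest RT. Groups are technical injections of
# one peptide in one culture, so exhaustive subset enumeration is cheap.
best_consistent_subset <- function(rt, mz, abundance, rt_tol, ppm_tol) {
  n <- length(rt)
  if (n == 1) return(1L)
  if (n > 12) { # defensive: fall back to greedy RT-sorted window
    ord <- order(rt)
    best <- integer()
    for (i in seq_len(n)) {
      j <- i
      while (j < n && rt[ord[j + 1]] - rt[ord[i]] <= rt_tol) j <- j + 1
      cand <- ord[i:j]
      cand <- cand[subset_consistent(cand, rt, mz, rt_tol, ppm_tol)]
      if (length(cand) > length(best)) best <- cand
    }
    return(sort(best))
  }
  best <- integer()
  best_ab <- -Inf
  best_rt <- Inf
  ab0 <- ifelse(is.na(abundance), 0, abundance)
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (!subset_consistent(idx, rt, mz, rt_tol, ppm_tol)) next
    tot <- sum(ab0[idx])
    mn <- min(rt[idx])
    better <- length(idx) > length(best) ||
      (length(idx) == length(best) &&
        (tot > best_ab || (tot == best_ab && mn < best_rt)))
    if (better) {
      best <- idx
      best_ab <- tot
      best_rt <- mn
    }
  }
  sort(best)
}

#' Retention-time / mass feature-reliability filter
#'
#' Replicate injections of the same peptide feature must agree in
#' retention time and precursor mass to count as reliable detections.
#' Observations are grouped by peptide identity (sequence +
#' modifications) within subject x condition x culture replicate; within
#' each group the largest subset whose RT span is at most
#' `rt_tolerance_min` and whose m/z deviations from the subset median are
#' at most `ms1_ppm_tol` ppm is retained (ties: larger total abundance,
#' then earlier RT). Singleton groups pass unconditionally.
#'
#' @param obs Observation tibble.
#' @param config A [filter_config()].
#' @return Retained observations with attribute `"rejections"` (count of
#'   dropped rows).
#' @export
rt_reliability_filter <- function(obs, config = filter_config()) {
  if (nrow(obs) == 0) {
    attr(obs, "rejections") <- c(rt_mass_inconsistent = 0L)
    return(obs)
  }
  key <- paste(obs$sequence, obs$modifications, obs$subject_id,
    obs$condition, obs$culture_rep,
    sep = "\r"
  )
  keep <- logical(nrow(obs))
  for (idx in split(seq_len(nrow(obs)), key)) {
    sel <- best_consistent_subset(
      obs$rt_min[idx], obs$mz[idx], obs$abundance[idx],
      config$rt_tolerance_min, config$ms1_ppm_tol
    )
    keep[idx[sel]] <- TRUE
  }
  out <- obs[keep, , drop = FALSE]
  attr(out, "rejections") <- c(rt_mass_inconsistent = sum(!keep))
  out
}

#' Apply the full identification filter chain
#'
#' Optional target-decoy FDR gate, then the abundance/quality gate, then
#' the RT/mass feature-reliability gate, with a per-stage row-count
#' report.
#'
#' @param obs Observation tibble.
#' @param config A [filter_config()].
#' @param use_fdr Apply [fdr_filter()] first (use for data carrying decoy
#'   labels; engine exports already FDR-filtered upstream should leave
#'   this off).
#' @return Filtered observations with attribute `"filter_report"`: tibble
#'   of `stage`, `n_in`, `n_out`, `n_rejected`.
#' @export
apply_filters <- function(obs, config = filter_config(), use_fdr = FALSE) {
  report <- list()
  log_stage <- function(stage, n_in, n_out) {
    report[[length(report) + 1]] <<- tibble::tibble(
      stage = stage, n_in = n_in, n_out = n_out, n_rejected = n_in - n_out
    )
  }
  n0 <- nrow(obs)
  if (use_fdr) {
    obs <- fdr_filter(obs, fdr_max = config$fdr_max)
  } else if ("is_decoy" %in% names(obs)) {
    obs <- obs[!obs$is_decoy, , drop = FALSE]
  }
  log_stage("decoy/fdr", n0, nrow(obs))
  n1 <- nrow(obs)
  obs <- quality_filter(obs, config)
  log_stage("abundance_quality", n1, nrow(obs))
  n2 <- nrow(obs)
  obs <- rt_reliability_filter(obs, config)
  log_stage("rt_mass_reliability", n2, nrow(obs))
  attr(obs, "filter_report") <- dplyr::bind_rows(report)
  obs
}
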