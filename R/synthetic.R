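# Monoisotopic residue masses (Da); water and proton for [M+zH]^z+.
AA_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)
MASS_WATER <- 18.010565
MASS_PROTON <- 1.007276

#' Theoretical precursor m/z of a peptide
#'
#' Monoisotopic `[M + zH]^z+` from residue masses.
#'
#' @param sequence Peptide string.
#' @param charge Charge state.
#' @return m/z in Thomson.
#' @export
peptide_mz <- function(sequence, charge = 2L) {
  res <- strsplit(toupper(sequence), "")
  m <- vapply(res, function(r) sum(AA_MONO[r]) + MASS_WATER, 0)
  (m + charge * MASS_PROTON) / charge
}

# Lengths of the proneuropeptide precursors the presence fixture maps to
# (full-length human proteins, signal peptide included).
PRECURSOR_LENGTHS <- c(
  ADM = 185L, CHGB = 677L, NPPC = 126L, NTS = 170L, SST = 116L,
  TMSB10 = 44L, TMSB4X = 44L
)

#' Synthetic stand-in proneuropeptide precursor sequences
#'
#' Deterministic random amino-acid sequences at the lengths of the seven
#' precursor proteins the presence fixture refers to (ADM, CHGB, NPPC,
#' NTS, SST, TMSB10, TMSB4X). These are *synthetic* sequences — not the
#' real human proteins — generated so that every fixture peptide
#' coordinate span exists and maps back uniquely; they let the whole
#' pipeline run end-to-end without shipping database sequences.
#' Generation is seeded internally and verified: each fixture peptide's
#' substring occurs exactly once across the set.
#'
#' @return Precursor tibble (`accession`, `symbol`, `sequence`) usable
#'   everywhere a [read_precursors()] result is.
#' @export
synthetic_precursors <- function() {
  fix <- reference_presence_matrix()
  for (seed_try in 804001L:804020L) {
    prec <- withr::with_seed(seed_try, {
      tibble::tibble(
        accession = paste0("SYN_", names(PRECURSOR_LENGTHS)),
        symbol = names(PRECURSOR_LENGTHS),
        sequence = unname(vapply(
          PRECURSOR_LENGTHS,
          function(n) paste(sample(names(AA_MONO), n, replace = TRUE), collapse = ""),
          ""
        ))
      )
    })
    ok <- all(vapply(seq_len(nrow(fix)), function(i) {
      pep <- substr(
        prec$sequence[prec$symbol == fix$precursor_symbol[i]],
        fix$start[i], fix$end[i]
      )
      hits <- sum(vapply(
        prec$sequence,
        function(s) length(substring_starts(pep, s)),
        0L
      ))
      hits == 1L
    }, TRUE))
    if (ok) return(prec)
  }
  abort("could not generate unambiguous synthetic precursors") # nocov
}

#' Ground truth for the synthetic observation generator
#'
#' Defines a peptide panel drawn from a precursor set, a true presence
#' state per peptide x group x condition, and the stochastic detection /
#' intensity / retention-time / quality models used to emulate an
#' identification engine's peptide export.
#'
#' @param precursors Precursor tibble.
#' @param design A [study_design()].
#' @param n_peptides Panel size; peptides are random unique-mapping
#'   substrings of the precursors.
#' @param length_range Min/max peptide length (residues).
#' @param presence_prob Probability a panel peptide is truly present in
#'   a given group x condition cell.
#' @param detection_prob Per-injection detection probability for a truly
#'   present peptide.
#' @param false_detect_prob Per-injection spurious-detection probability
#'   for a truly absent peptide.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity model:
#'   each peptide draws a log-mean around `intensity_meanlog` (between-
#'   peptide sd 0.7); injections add log-sd `intensity_sdlog` noise.
#' @param rt_jitter_sd Gaussian retention-time jitter around each
#'   peptide's mean RT, minutes.
#' @param quality_shape1,quality_shape2 Beta parameters of the target
#'   feature-quality model (defaults put ~95% of draws above 0.3).
#' @param decoy_fraction Decoy rows appended, as a fraction of target
#'   rows.
#' @param seed Integer seed; the same truth generates identical tables.
#' @return Object of class `ground_truth`: list with `panel` (tibble
#'   `peptide_id`, `precursor_symbol`, `start`, `end`, `sequence`,
#'   `accession`, `meanlog`, `rt_mean`), `presence` (tibble `peptide_id`
#'   x `group` x `condition` -> `present`), and the model parameters.
#' @export
ground_truth <- function(precursors,
                         design = study_design(),
                         n_peptides = 20L,
                         length_range = c(8L, 30L),
                         presence_prob = 0.5,
                         detection_prob = 0.9,
                         false_detect_prob = 0.01,
                         intensity_meanlog = log(1e6),
                         intensity_sdlog = 0.5,
                         rt_jitter_sd = 0.5,
                         quality_shape1 = 4.5,
                         quality_shape2 = 3,
                         decoy_fraction = 0.05,
                         seed = 1L) {
  probs <- c(presence_prob, detection_prob, false_detect_prob, decoy_fraction)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (n_peptides < 1) abort("panel must contain at least one peptide")
  withr::with_seed(seed, {
    panel <- list()
    tries <- 0L
    while (length(panel) < n_peptides && tries < 50L * n_peptides) {
      tries <- tries + 1L
      i <- sample(nrow(precursors), 1, prob = nchar(precursors$sequence))
      len <- sample(seq(length_range[1], length_range[2]), 1)
      pmax_start <- nchar(precursors$sequence[i]) - len + 1L
      if (pmax_start < 1) next
      start <- sample(pmax_start, 1)
      pep <- substr(precursors$sequence[i], start, start + len - 1L)
      hits <- sum(vapply(
        precursors$sequence,
        function(s) length(substring_starts(pep, s)), 0L
      ))
      id <- paste0(precursors$symbol[i], ":", start, "-", start + len - 1L)
      if (hits != 1L || id %in% names(panel)) next
      panel[[id]] <- tibble::tibble(
        peptide_id = id,
        precursor_symbol = precursors$symbol[i],
        start = start, end = start + len - 1L,
        sequence = pep,
        accession = precursors$accession[i]
      )
    }
    if (length(panel) < n_peptides) {
      abort("could not draw a uniquely-mapping peptide panel; precursors too short?")
    }
    panel <- dplyr::bind_rows(panel)
    panel$meanlog <- rnorm(n_peptides, intensity_meanlog, 0.7)
    panel$rt_mean <- runif(n_peptides, 10, 45)

    presence <- tidyr::expand_grid(
      peptide_id = panel$peptide_id,
      group = names(design$groups),
      condition = design$conditions
    )
    presence$present <- runif(nrow(presence)) < presence_prob
  })
  structure(
    list(
      panel = panel, presence = presence, design = design,
      detection_prob = detection_prob, false_detect_prob = false_detect_prob,
      intensity_sdlog = intensity_sdlog, rt_jitter_sd = rt_jitter_sd,
      quality_shape1 = quality_shape1, quality_shape2 = quality_shape2,
      decoy_fraction = decoy_fraction, seed = as.integer(seed)
    ),
    class = "ground_truth"
  )
}

# Shuffle a peptide until it matches no precursor substring.
make_decoy_sequence <- function(sequence, precursors, max_tries = 100L) {
  for (i in seq_len(max_tries)) {
    cand <- paste(sample(strsplit(sequence, "")[[1]]), collapse = "")
    hits <- sum(vapply(
      precursors$sequence,
      function(s) length(substring_starts(cand, s)), 0L
    ))
    if (hits == 0L) return(cand)
  }
  abort("could not shuffle a non-matching decoy sequence") # nocov
}

#' Generate a synthetic peptide observation table
#'
#' One row per realised detection per technical injection. A truly
#' present peptide is detected in each injection with
#' `detection_prob`, an absent one with `false_detect_prob`;
#' intensities are log-normal around the peptide's log-mean, RT is
#' jittered around the peptide's mean, quality is Beta-distributed, and
#' m/z is the theoretical value with 2 ppm Gaussian error. Decoy rows
#' (length-preserving shuffles matching no precursor) are appended at
#' `decoy_fraction` with a down-shifted quality distribution.
#' Deterministic given `truth$seed`.
#'
#' @param truth A [ground_truth()].
#' @param precursors The precursor tibble the truth was drawn from
#'   (needed for decoy rejection sampling).
#' @return Observation tibble in canonical column order.
#' @export
generate_observations <- function(truth, precursors) {
  design <- truth$design
  withr::with_seed(truth$seed + 1L, {
    grid <- tidyr::expand_grid(
      truth$panel[, c("peptide_id", "sequence", "accession", "meanlog", "rt_mean")],
      design_subjects(design),
      condition = design$conditions,
      culture_rep = seq_len(design$n_culture_reps),
      tech_rep = seq_len(design$n_tech_reps)
    )
    grid <- dplyr::left_join(
      grid, truth$presence,
      by = c("peptide_id", "group", "condition")
    )
    p <- ifelse(grid$present, truth$detection_prob, truth$false_detect_prob)
    hit <- rbinom(nrow(grid), 1L, p) == 1L
    g <- grid[hit, , drop = FALSE]
    n <- nrow(g)
    obs <- tibble::tibble(
      sequence = g$sequence,
      modifications = "",
      precursor_accession = g$accession,
      abundance = rlnorm(n, g$meanlog, truth$intensity_sdlog),
      quality = rbeta(n, truth$quality_shape1, truth$quality_shape2),
      rt_min = rnorm(n, g$rt_mean, truth$rt_jitter_sd),
      mz = peptide_mz(g$sequence) * (1 + rnorm(n, 0, 2e-6)),
      subject_id = g$subject_id,
      group = g$group,
      condition = g$condition,
      culture_rep = g$culture_rep,
      tech_rep = g$tech_rep,
      is_decoy = FALSE
    )
    n_decoys <- round(truth$decoy_fraction * n)
    if (n_decoys > 0 && n > 0) {
      pick <- sample(n, n_decoys, replace = TRUE)
      dec <- obs[pick, , drop = FALSE]
      dec$sequence <- vapply(
        dec$sequence, make_decoy_sequence, "",
        precursors = precursors, USE.NAMES = FALSE
      )
      dec$precursor_accession <- "DECOY"
      dec$quality <- rbeta(n_decoys, 2, 5)
      dec$mz <- peptide_mz(dec$sequence) * (1 + rnorm(n_decoys, 0, 2e-6))
      dec$is_decoy <- TRUE
      obs <- dplyr::bind_rows(obs, dec)
    }
    obs
  })
}

# Mapping tibble straight from a truth panel (panel peptides map uniquely
# by construction, so no search is needed).
panel_mapping <- function(truth) {
  truth$panel |>
    dplyr::transmute(
      .data$sequence, .data$precursor_symbol, .data$start, .data$end,
      ambiguous = FALSE, n_sites = 1L,
      all_sites = purrr::pmap(
        list(.data$precursor_symbol, .data$start, .data$end),
        function(s, a, b) tibble::tibble(precursor_symbol = s, start = a, end = b)
      )
    )
}

#' Monte-Carlo recovery of presence calls against ground truth
#'
#' Repeatedly generates observation tables from one truth (fresh seeds
#' derived from `seed`), runs them through presence calling, and
#' estimates per group x condition the sensitivity
#' P(called present | truly present) and specificity
#' P(called absent | truly absent) of the hierarchical rule.
#'
#' By default the quality/RT filter chain is not applied, so that the
#' only stochastic gate between truth and call is the detection model —
#' the regime in which sensitivity has a closed form by composing
#' binomial tails over injections, cultures, and subjects. With
#' `apply_filters = TRUE` the full chain runs and the effective
#' per-injection detection probability is reduced by the probability of
#' passing the quality gate.
#'
#' @param truth A [ground_truth()].
#' @param precursors Precursor tibble for the generator.
#' @param n_sims Number of simulated experiments (>= 1).
#' @param seed Integer seed for the experiment series.
#' @param apply_filters Run [apply_filters()] before presence calling.
#' @param config [filter_config()] used when `apply_filters = TRUE`.
#' @return Tibble: `group`, `condition`, `sensitivity`, `specificity`,
#'   `n_pos`, `n_neg` (Bernoulli trial counts behind each estimate),
#'   `n_sims`.
#' @export
recovery_experiment <- function(truth, precursors, n_sims = 100L, seed = 1L,
                                apply_filters = FALSE,
                                config = filter_config()) {
  if (n_sims < 1) abort("n_sims must be >= 1")
  mapping <- panel_mapping(truth)
  acc <- NULL
  for (i in seq_len(n_sims)) {
    truth_i <- truth
    truth_i$seed <- (seed * 10007L + i) %% .Machine$integer.max
    obs <- generate_observations(truth_i, precursors)
    if (apply_filters) {
      obs <- apply_filters(obs, config, use_fdr = truth$decoy_fraction > 0)
    } else {
      obs <- obs[!obs$is_decoy, , drop = FALSE]
    }
    mat <- build_presence_matrix(obs, mapping, truth$design)
    cmp <- dplyr::left_join(
      truth$presence,
      dplyr::rename(mat$calls, called = "present"),
      by = c("peptide_id", "group", "condition")
    )
    cmp$called <- dplyr::coalesce(cmp$called, FALSE)
    tab <- cmp |>
      dplyr::group_by(.data$group, .data$condition) |>
      dplyr::summarise(
        tp = sum(.data$present & .data$called),
        fn = sum(.data$present & !.data$called),
        tn = sum(!.data$present & !.data$called),
        fp = sum(!.data$present & .data$called),
        .groups = "drop"
      )
    acc <- if (is.null(acc)) tab else {
      m <- dplyr::bind_rows(acc, tab)
      dplyr::summarise(
        dplyr::group_by(m, .data$group, .data$condition),
        dplyr::across(c("tp", "fn", "tn", "fp"), sum),
        .groups = "drop"
      )
    }
  }
  acc |>
    dplyr::mutate(
      sensitivity = ifelse(.data$tp + .data$fn > 0,
        .data$tp / (.data$tp + .data$fn), NA_real_
      ),
      specificity = ifelse(.data$tn + .data$fp > 0,
        .data$tn / (.data$tn + .data$fp), NA_real_
      ),
      n_pos = .data$tp + .data$fn,
      n_neg = .data$tn + .data$fp,
      n_sims = n_sims
    ) |>
    dplyr::select(
      "group", "condition", "sensitivity", "specificity",
      "n_pos", "n_neg", "n_sims"
    )
}

#' Closed-form presence-recovery sensitivity
#'
#' Exact probability that the hierarchical rule calls a truly present
#' peptide present, composing binomial tails bottom-up: per culture,
#' detection in at least `tech_threshold` of `n_tech_reps` injections;
#' per subject, at least `culture_threshold` of `n_culture_reps`
#' positive cultures; per group, at least the group threshold of
#' positive subjects. Assumes detections are independent Bernoulli
#' (`detection_prob`) per injection with no further gating — the
#' regime [recovery_experiment()] simulates by default.
#'
#' @param detection_prob Per-injection detection probability.
#' @param group Group label.
#' @param design A [study_design()].
#' @return Named list `p_culture`, `p_subject`, `p_group`.
#' @export
recovery_sensitivity_exact <- function(detection_prob, group,
                                       design = study_design()) {
  p_culture <- 1 - pbinom(design$tech_threshold - 1L, design$n_tech_reps, detection_prob)
  p_subject <- 1 - pbinom(design$culture_threshold - 1L, design$n_culture_reps, p_culture)
  n_subj <- length(design$groups[[group]])
  thr <- design$group_presence_threshold[[group]]
  p_group <- 1 - pbinom(thr - 1L, n_subj, p_subject)
  list(p_culture = p_culture, p_subject = p_subject, p_group = p_group)
}
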