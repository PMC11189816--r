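# Observations realising one detection pattern for a single peptide:
# pattern is a list group -> condition -> subject -> culture -> tech vector.
obs_from_pattern <- function(det, design = study_design()) {
  rows <- list()
  for (r in seq_len(nrow(det))) {
    rows[[r]] <- make_obs(
      sequence = "MKTAYIAKQR",
      subject_id = det$subject_id[r], group = det$group[r],
      condition = det$condition[r], culture_rep = det$culture_rep[r],
      tech_rep = det$tech_rep[r]
    )
  }
  dplyr::bind_rows(rows)
}

simple_mapping <- tibble::tibble(
  sequence = "MKTAYIAKQR", precursor_symbol = "S1",
  start = 1L, end = 10L, ambiguous = FALSE, n_sites = 1L,
  all_sites = list(tibble::tibble(precursor_symbol = "S1", start = 1L, end = 10L))
)

test_that("culture call counts distinct technical replicates", {
  expect_true(call_culture(c(1L)))          # 1 of 2 injections suffices
  expect_false(call_culture(integer()))     # no detection
  expect_true(call_culture(c(1L, 1L)))      # repeats in one injection count once
  expect_false(call_culture(c(1L, 1L), tech_threshold = 2L))
  expect_true(call_culture(c(2L, 1L), tech_threshold = 2L))
})

test_that("subject call needs the culture threshold and exact arity", {
  expect_true(call_subject(c(TRUE, TRUE, FALSE)))
  expect_false(call_subject(c(TRUE, FALSE, FALSE)))
  expect_false(call_subject(c(FALSE, FALSE, FALSE)))
  expect_error(call_subject(c(TRUE, TRUE), n_culture_reps = 3L), "expected 3")
  # incomplete designs: available replicates against the same absolute bar
  expect_true(call_subject(c(TRUE, TRUE), n_culture_reps = NULL))
})

test_that("group call applies the per-group subject threshold", {
  d <- study_design()
  expect_true(call_group(rep(c(TRUE, FALSE), c(5, 2)), "SZ", d))
  expect_false(call_group(rep(c(TRUE, FALSE), c(4, 3)), "SZ", d))
  expect_true(call_group(rep(c(TRUE, FALSE), c(4, 2)), "HC", d))
  expect_error(call_group(c(A = TRUE), "XX", d), "unknown group")
  expect_error(
    call_group(stats::setNames(rep(TRUE, 7), LETTERS[1:7]), "HC", d),
    "not in group"
  )
})

test_that("every level of the rule matches brute-force counting, exhaustively", {
  # technical level: all 2^2 injection patterns
  for (mask in 0:3) {
    pat <- which(as.logical(bitwAnd(mask, c(1L, 2L))))
    for (thr in 1:2) {
      expect_equal(call_culture(pat, thr), length(pat) >= thr)
    }
  }
  # culture level: all 2^3 patterns
  for (mask in 0:7) {
    pat <- as.logical(bitwAnd(mask, c(1L, 2L, 4L)))
    for (thr in 1:3) {
      expect_equal(call_subject(pat, thr), sum(pat) >= thr)
    }
  }
  # subject level: all 2^7 SZ and 2^6 HC patterns at the study thresholds
  d <- study_design()
  for (mask in 0:127) {
    pat <- as.logical(bitwAnd(mask, 2^(0:6)))
    expect_equal(call_group(pat, "SZ", d), sum(pat) >= 5)
  }
  for (mask in 0:63) {
    pat <- as.logical(bitwAnd(mask, 2^(0:5)))
    expect_equal(call_group(pat, "HC", d), sum(pat) >= 4)
  }
})

test_that("threshold extremes reduce to detected-everywhere / detected-once", {
  all_max <- study_design(
    group_presence_threshold = c(SZ = 7L, HC = 6L),
    tech_threshold = 2L, culture_threshold = 3L
  )
  all_min <- study_design(
    group_presence_threshold = c(SZ = 1L, HC = 1L),
    tech_threshold = 1L, culture_threshold = 1L
  )
  withr::local_seed(31)
  for (rep in 1:10) {
    det <- tidyr::expand_grid(
      design_subjects(study_design()),
      condition = "KCl",
      culture_rep = 1:3, tech_rep = 1:2
    )
    det <- det[runif(nrow(det)) < 0.8, ]
    obs <- obs_from_pattern(det)
    for (g in c("SZ", "HC")) {
      everywhere <- nrow(dplyr::distinct(
        det[det$group == g, ], subject_id, culture_rep, tech_rep
      )) == length(all_max$groups[[g]]) * 3 * 2
      once <- any(det$group == g)
      mat_max <- build_presence_matrix(obs, simple_mapping, all_max)
      mat_min <- build_presence_matrix(obs, simple_mapping, all_min)
      call_at <- function(mat) {
        mat$calls$present[mat$calls$group == g & mat$calls$condition == "KCl"]
      }
      expect_equal(call_at(mat_max), everywhere)
      expect_equal(call_at(mat_min), once)
    }
  }
})

test_that("presence matrix satisfies cross-level threshold invariants", {
  prec <- synthetic_precursors()
  truth <- ground_truth(prec, n_peptides = 10, seed = 9,
                        detection_prob = 0.6, decoy_fraction = 0)
  obs <- generate_observations(truth, prec)
  d <- truth$design
  mat <- build_presence_matrix(obs, map_peptides(obs, prec), d)
  # group call <=> enough positive subjects
  chk <- mat$subject_detail |>
    dplyr::group_by(.data$peptide_id, .data$group, .data$condition) |>
    dplyr::summarise(n_pos = sum(.data$present), .groups = "drop") |>
    dplyr::inner_join(mat$calls, by = c("peptide_id", "group", "condition"))
  thr <- unname(d$group_presence_threshold[chk$group])
  expect_equal(chk$present, chk$n_pos >= thr)
  # subject call <=> enough positive cultures
  chk2 <- mat$culture_detail |>
    dplyr::group_by(.data$peptide_id, .data$subject_id, .data$condition) |>
    dplyr::summarise(n_pos = sum(.data$present), .groups = "drop") |>
    dplyr::inner_join(
      mat$subject_detail,
      by = c("peptide_id", "subject_id", "condition")
    )
  expect_equal(chk2$present, chk2$n_pos >= d$culture_threshold)
})

test_that("adding a detection never flips a call to absent (monotonicity)", {
  withr::local_seed(37)
  d <- study_design()
  for (rep in 1:5) {
    det <- tidyr::expand_grid(
      design_subjects(d), condition = c("KCl", "basal"),
      culture_rep = 1:3, tech_rep = 1:2
    )
    base_det <- det[runif(nrow(det)) < 0.5, ]
    extra <- dplyr::anti_join(
      det, base_det,
      by = c("subject_id", "group", "condition", "culture_rep", "tech_rep")
    )
    extra <- extra[sample(nrow(extra), 3), ]
    before <- build_presence_matrix(obs_from_pattern(base_det), simple_mapping, d)
    after <- build_presence_matrix(
      obs_from_pattern(dplyr::bind_rows(base_det, extra)), simple_mapping, d
    )
    joined <- dplyr::inner_join(
      before$calls, after$calls,
      by = c("peptide_id", "group", "condition"), suffix = c("_b", "_a")
    )
    expect_false(any(joined$present_b & !joined$present_a))
  }
})

test_that("empty observation sets give an empty matrix; fixture rows all survive", {
  empty <- make_obs()[0, ]
  mat <- build_presence_matrix(empty, simple_mapping[0, ], study_design())
  expect_equal(nrow(mat$peptides), 0)
  expect_equal(nrow(presence_wide(mat)), 0)
})

test_that("the fixture observations reconstruct the printed 29 x 4 matrix exactly", {
  fx <- reference_presence_matrix()
  prec <- synthetic_precursors()
  obs <- observations_from_fixture(fx, study_design(), prec)
  mat <- build_presence_matrix(obs, map_peptides(obs, prec), study_design())
  wide <- presence_wide(mat)
  expect_equal(nrow(wide), 29)
  got <- dplyr::arrange(wide, .data$precursor_symbol, .data$peptide)
  want <- fx |>
    dplyr::mutate(peptide = paste0(start, "-", end)) |>
    dplyr::arrange(.data$precursor_symbol, .data$peptide)
  for (col in c("SZ_KCl", "SZ_basal", "HC_KCl", "HC_basal")) {
    expect_equal(got[[col]] == "+", want[[col]], info = col)
  }
  # all-absent rows are retained in the matrix (2 such rows printed)
  expect_equal(sum(got$SZ_KCl == "-" & got$SZ_basal == "-" &
    got$HC_KCl == "-" & got$HC_basal == "-"), 2)
})
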