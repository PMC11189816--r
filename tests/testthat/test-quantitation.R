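test_that("subject abundance is the mean of culture means", {
  # two injections in one culture
  expect_equal(subject_abundance(c(100, 200), c(1, 1)), 150)
  # three cultures, one value missing: mean of the available cultures
  expect_equal(subject_abundance(c(100, 200, NA), c(1, 2, 3)), 150)
  # nesting matters: culture means first, then subject mean
  expect_equal(subject_abundance(c(100, 200, 400), c(1, 1, 2)), 275)
  # no detections -> missing, never zero
  expect_true(is.na(subject_abundance(numeric(), integer())))
  expect_true(is.na(subject_abundance(NA_real_, 1L)))
})

test_that("group stats use the sample standard deviation for the s.e.m.", {
  gs <- group_stats(c(2, 4, 6))
  expect_equal(gs$mean, 4)
  expect_equal(gs$sem, 2 / sqrt(3))
  expect_equal(group_stats(c(5, 5, 5, 5))$sem, 0)
  one <- group_stats(7)
  expect_equal(one$mean, 7)
  expect_true(is.na(one$sem))
  expect_equal(group_stats(numeric())$n, 0L)
})

test_that("pooled t-test reproduces the hand-computed reference case", {
  same <- pooled_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # pooled sd = 1, se = sqrt(2/3), t = -3/se, df = 4 (hand formula)
  r <- pooled_t_test(c(10, 11, 12), c(13, 14, 15))
  expect_equal(r$t, -3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * pt(-3 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_equal(r$p, 0.0213116, tolerance = 1e-5)
  expect_warning(res0 <- pooled_t_test(c(0, 0), c(1, 1)), "degenerate")
  expect_equal(res0$p, 0)
  expect_error(pooled_t_test(1, c(1, 2)), "n >= 2")
})

test_that("pooled t-test agrees with the reference implementation to 1e-8", {
  withr::local_seed(61)
  for (rep in 1:300) {
    n1 <- sample(2:9, 1)
    n2 <- sample(2:9, 1)
    x <- rnorm(n1, sd = runif(1, 0.5, 3))
    y <- rnorm(n2, mean = runif(1, -1, 1))
    mine <- pooled_t_test(x, y)
    ref <- stats::t.test(x, y, var.equal = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$df, unname(ref$parameter))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-8)
    # antisymmetry under group swap; p invariant
    swap <- pooled_t_test(y, x)
    expect_equal(swap$t, -mine$t, tolerance = 1e-12)
    expect_equal(swap$p, mine$p, tolerance = 1e-12)
    # positive rescaling leaves t and p unchanged
    k <- runif(1, 0.1, 1e6)
    sc <- pooled_t_test(k * x, k * y)
    expect_equal(sc$t, mine$t, tolerance = 1e-8)
    expect_equal(sc$p, mine$p, tolerance = 1e-8)
  }
})

test_that("quantify_peptides aggregates cells and tests only co-present peptides", {
  d <- study_design()
  prec <- synthetic_precursors()
  fx <- reference_presence_matrix()
  # two peptides: one shared in KCl (row 588-596), one HC-only (523-535)
  sub <- fx[fx$precursor_symbol == "CHGB" &
    paste0(fx$start, "-", fx$end) %in% c("588-596", "523-535"), ]
  obs <- observations_from_fixture(sub, d, prec)
  # give abundances a deterministic subject-dependent spread
  obs$abundance <- 1e5 + 1e4 * as.integer(factor(obs$subject_id)) +
    1e3 * obs$culture_rep
  mapping <- map_peptides(obs, prec)
  mat <- build_presence_matrix(obs, mapping, d)
  q <- quantify_peptides(obs, mat)

  shared_id <- "CHGB:588-596"
  hconly_id <- "CHGB:523-535"
  # SZ-vs-HC test exists only for the co-present peptide at KCl
  expect_true(any(
    q$contrasts$peptide_id == shared_id & q$contrasts$contrast == "SZ_vs_HC@KCl"
  ))
  expect_false(any(
    q$contrasts$peptide_id == hconly_id & grepl("SZ_vs_HC", q$contrasts$contrast)
  ))
  # cell summary equals a direct computation from subject means
  cell <- q$cells[q$cells$peptide_id == shared_id &
    q$cells$group == "SZ" & q$cells$condition == "KCl", ]
  subj_means <- obs |>
    dplyr::filter(
      .data$group == "SZ", .data$condition == "KCl",
      .data$sequence == mapping$sequence[mapping$precursor_symbol == "CHGB" &
        mapping$start == 588]
    ) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      ab = subject_abundance(.data$abundance, .data$culture_rep),
      .groups = "drop"
    )
  expect_equal(cell$n, nrow(subj_means))
  expect_equal(cell$mean, mean(subj_means$ab))
  expect_equal(cell$sem, sd(subj_means$ab) / sqrt(nrow(subj_means)))
  # the contrast row reproduces a direct pooled test of the subject means
  hc_means <- obs |>
    dplyr::filter(
      .data$group == "HC", .data$condition == "KCl",
      .data$sequence == mapping$sequence[mapping$precursor_symbol == "CHGB" &
        mapping$start == 588]
    ) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(
      ab = subject_abundance(.data$abundance, .data$culture_rep),
      .groups = "drop"
    )
  want <- pooled_t_test(subj_means$ab, hc_means$ab)
  got <- q$contrasts[q$contrasts$peptide_id == shared_id &
    q$contrasts$contrast == "SZ_vs_HC@KCl", ]
  expect_equal(got$t, want$t)
  expect_equal(got$p, want$p)
  expect_equal(got$significant, want$p < 0.05)
})

test_that("BH adjustment and paired condition tests are available", {
  d <- study_design()
  prec <- synthetic_precursors()
  fx <- reference_presence_matrix()
  sub <- fx[fx$SZ_KCl & fx$SZ_basal, ][1:3, ]
  obs <- observations_from_fixture(sub, d, prec)
  withr::local_seed(71)
  obs$abundance <- 1e5 * (1 + runif(nrow(obs)))
  mat <- build_presence_matrix(obs, map_peptides(obs, prec), d)
  raw <- quantify_peptides(obs, mat)
  bh <- quantify_peptides(obs, mat, p_adjust = "BH")
  merged <- dplyr::inner_join(
    raw$contrasts, bh$contrasts,
    by = c("peptide_id", "contrast"), suffix = c("_raw", "_bh")
  )
  expect_equal(merged$p_raw, merged$p_bh) # adjustment never alters raw p
  for (ct in unique(merged$contrast)) {
    sel <- merged$contrast == ct
    expect_equal(
      sort(merged$p_adj_bh[sel]),
      sort(p.adjust(merged$p_raw[sel], "BH")),
      tolerance = 1e-12
    )
  }
  paired <- quantify_peptides(obs, mat, paired = TRUE)
  expect_true(any(grepl("paired", paired$contrasts$contrast)))
})
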