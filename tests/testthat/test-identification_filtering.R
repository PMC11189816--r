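test_that("fdr_filter matches the brute-force all-cutoffs oracle", {
  obs <- make_obs(
    sequence = rep("PEPTIDEK", 5),
    quality = c(10, 9, 8, 7, 7.5),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  # below the boundary the decoy forces the cutoff up
  kept <- fdr_filter(obs, fdr_max = 0.2)
  expect_equal(sort(kept$quality), brute_fdr_retained(obs$quality, obs$is_decoy, 0.2))
  expect_equal(sort(kept$quality), c(8, 9, 10))
  expect_equal(attr(kept, "cutoff"), 8)
  # at the boundary 1 decoy / 4 targets = 0.25 satisfies <= 0.25
  kept25 <- fdr_filter(obs, fdr_max = 0.25)
  expect_equal(sort(kept25$quality), brute_fdr_retained(obs$quality, obs$is_decoy, 0.25))
  # decoys are always removed whatever the cutoff
  expect_false(any(kept25$is_decoy))
})

test_that("fdr_filter edge contracts: no decoys, all decoys, bad fdr_max", {
  clean <- make_obs(sequence = rep("PEPTIDEK", 4), quality = c(4, 3, 2, 1))
  kept <- fdr_filter(clean, fdr_max = 0.01)
  expect_equal(nrow(kept), 4) # FDR estimate is 0 at every cutoff
  expect_equal(attr(kept, "cutoff"), 1)
  expect_error(fdr_filter(dplyr::mutate(clean, is_decoy = TRUE), 0.01), "no target")
  expect_error(fdr_filter(clean, fdr_max = 0), "> 0")
})

test_that("fdr_filter is monotone in fdr_max (property)", {
  withr::local_seed(7)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    obs <- make_obs(
      sequence = rep("PEPTIDEK", n),
      quality = round(runif(n, 0, 10), 2),
      is_decoy = runif(n) < 0.3
    )
    if (all(obs$is_decoy)) obs$is_decoy[1] <- FALSE
    lo <- tryCatch(fdr_filter(obs, 0.05), error = function(e) NULL)
    hi <- tryCatch(fdr_filter(obs, 0.3), error = function(e) NULL)
    expect_lte(NROW(lo), NROW(hi))
    # and both agree with the brute-force oracle
    for (fm in c(0.05, 0.3)) {
      got <- fdr_filter(obs, fm)
      expect_equal(sort(got$quality), brute_fdr_retained(obs$quality, obs$is_decoy, fm))
    }
  }
})

test_that("abundance/quality gates are strict inequalities at the printed cuts", {
  cfg <- filter_config()
  obs <- make_obs(
    sequence = rep("PEPTIDEK", 4),
    abundance = c(10001, 10000, 20000, 20000),
    quality = c(0.31, 0.9, 0.3, 0.9)
  )
  kept <- quality_filter(obs, cfg)
  expect_equal(kept$abundance, c(10001, 20000))
  expect_equal(kept$quality, c(0.31, 0.9))
  rej <- attr(kept, "rejections")
  expect_equal(unname(rej["low_abundance"]), 1)
  expect_equal(unname(rej["low_quality"]), 1)
})

test_that("quality_filter is idempotent and order-independent", {
  withr::local_seed(11)
  obs <- make_obs(
    sequence = rep("PEPTIDEK", 40),
    abundance = 10^runif(40, 3, 6), quality = runif(40)
  )
  once <- quality_filter(obs)
  twice <- quality_filter(once)
  expect_equal(nrow(once), nrow(twice))
  expect_equal(once$abundance, twice$abundance)
  expect_equal(once$quality, twice$quality)
  expect_equal(unname(attr(twice, "rejections")), c(0L, 0L))
  perm <- obs[sample(nrow(obs)), ]
  expect_setequal(quality_filter(perm)$abundance, once$abundance)
  # missing abundance/quality cannot certify the cut
  na_obs <- make_obs(abundance = NA_real_)
  expect_equal(nrow(quality_filter(na_obs)), 0)
})

test_that("rt reliability keeps the largest consistent injection subset", {
  cfg <- filter_config()
  base <- function(rt, ab = 5e5, tech = seq_along(rt)) {
    make_obs(
      sequence = "PEPTIDEK", rt_min = rt, abundance = ab,
      tech_rep = tech, mz = 500.25
    )
  }
  # span 1.5 min <= 3: both kept
  both <- rt_reliability_filter(base(c(20, 21.5)), cfg)
  expect_equal(nrow(both), 2)
  # span 4.5 min: only the higher-abundance injection survives
  apart <- rt_reliability_filter(base(c(20, 24.5), ab = c(1e5, 9e5)), cfg)
  expect_equal(nrow(apart), 1)
  expect_equal(apart$rt_min, 24.5)
  # three features: the {20.0, 20.5} pair beats any singleton
  trio <- rt_reliability_filter(
    make_obs(
      sequence = "PEPTIDEK", rt_min = c(20, 20.5, 25),
      culture_rep = 1L, tech_rep = c(1L, 2L, 2L), mz = 500.25
    ),
    cfg
  )
  expect_equal(sort(trio$rt_min), c(20, 20.5))
  # singletons pass unconditionally
  single <- rt_reliability_filter(base(99), cfg)
  expect_equal(nrow(single), 1)
})

test_that("rt/ppm selection agrees with exhaustive subset enumeration (property)", {
  cfg <- filter_config()
  withr::local_seed(23)
  enumerate_best <- function(rt, mz, ab, rt_tol, ppm_tol) {
    n <- length(rt)
    best <- integer(); best_key <- c(-1, -Inf, Inf)
    for (mask in seq_len(2^n - 1)) {
      idx <- which(bitwAnd(mask, bitwShiftL(1L, 0:(n - 1))) != 0L)
      if (length(idx) > 1) {
        if (diff(range(rt[idx])) > rt_tol) next
        med <- median(mz[idx])
        if (any(abs(mz[idx] - med) / med * 1e6 > ppm_tol)) next
      }
      key <- c(length(idx), sum(ab[idx]), -min(rt[idx]))
      if (key[1] > best_key[1] ||
        (key[1] == best_key[1] && (key[2] > best_key[2] ||
          (key[2] == best_key[2] && key[3] > best_key[3])))) {
        best <- idx; best_key <- key
      }
    }
    sort(best)
  }
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    obs <- make_obs(
      sequence = "PEPTIDEK",
      rt_min = round(runif(n, 18, 27), 2),
      mz = 500 * (1 + rnorm(n, 0, 2e-5)),
      abundance = round(10^runif(n, 4, 6)),
      culture_rep = 1L, tech_rep = rep(1L, n)
    )
    kept <- rt_reliability_filter(obs, cfg)
    want <- enumerate_best(
      obs$rt_min, obs$mz, obs$abundance,
      cfg$rt_tolerance_min, cfg$ms1_ppm_tol
    )
    expect_equal(sort(kept$rt_min), sort(obs$rt_min[want]))
    # post-hoc: the retained subset always satisfies both constraints
    if (nrow(kept) > 1) {
      expect_lte(diff(range(kept$rt_min)), cfg$rt_tolerance_min)
      med <- median(kept$mz)
      expect_true(all(abs(kept$mz - med) / med * 1e6 <= cfg$ms1_ppm_tol))
    }
  }
})

test_that("apply_filters chains stages and reports per-stage counts", {
  prec <- synthetic_precursors()
  truth <- ground_truth(prec, n_peptides = 8, seed = 5, decoy_fraction = 0.1)
  obs <- generate_observations(truth, prec)
  out <- apply_filters(obs, use_fdr = TRUE)
  rep <- attr(out, "filter_report")
  expect_equal(rep$stage, c("decoy/fdr", "abundance_quality", "rt_mass_reliability"))
  expect_equal(rep$n_in[1], nrow(obs))
  expect_equal(rep$n_out[3], nrow(out))
  expect_true(all(rep$n_in - rep$n_out == rep$n_rejected))
  expect_false(any(out$is_decoy))
})
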