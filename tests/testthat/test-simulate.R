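test_that("generation is seed-reproducible and shapes are consistent", {
  cfg <- sim_config(n_euploid = 6, n_bins = 700, depth = 2e5, seed = 42,
                    trisomy = data.frame(chrom = c(21, 18), f = c(0.1, 0.2),
                                         twin = c(FALSE, TRUE)))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$bins$gc, b$bins$gc)
  expect_equal(ncol(a$counts), 8L)
  expect_equal(a$manifest$karyotype,
               c(rep("euploid", 6), "T21", "T18"))
  expect_equal(a$manifest$twin, c(rep(FALSE, 6), FALSE, TRUE))
  expect_true(all(a$counts >= 0))
  expect_equal(nrow(a$bins), nrow(a$counts))
})

test_that("trisomy inflation follows 1 + f/2 and twin dilution halves f", {
  # expected-count level check: the injected multiplier is exact
  cfg <- sim_config(n_euploid = 0, n_bins = 900, depth = 1e6, seed = 9,
                    trisomy = data.frame(chrom = 21, f = c(0.2, 0.2),
                                         twin = c(FALSE, TRUE)))
  co <- simulate_cohort(cfg)
  expect_equal(unname(colnames(co$counts)), c("T21_001", "T21_002"))

  # Monte-Carlo at the pipeline level on a shared genome
  bins <- synthetic_bins(sim_config(n_bins = 2000, seed = 10))
  eu <- simulate_cohort(sim_config(n_euploid = 40, n_bins = 2000, seed = 11),
                        bins = bins)
  tri <- simulate_cohort(
    sim_config(n_euploid = 0, n_bins = 2000, seed = 12,
               trisomy = data.frame(chrom = 21, f = rep(0.2, 40))),
    bins = bins)
  ps_eu <- profile_cohort(eu$counts, bins)
  ps_tri <- profile_cohort(tri$counts, bins)
  inflation <- mean(ps_tri$rf[, 21]) / mean(ps_eu$rf[, 21])
  expect_equal(inflation, 1.10, tolerance = 0.01)
  # parameter recovery: invert the inflation model to get f back
  expect_lt(abs((inflation - 1) * 2 - 0.2), 0.025)

  twin <- simulate_cohort(
    sim_config(n_euploid = 0, n_bins = 2000, seed = 13,
               trisomy = data.frame(chrom = 21, f = rep(0.2, 40),
                                    twin = TRUE)),
    bins = bins)
  ps_twin <- profile_cohort(twin$counts, bins)
  expect_equal(mean(ps_twin$rf[, 21]) / mean(ps_eu$rf[, 21]), 1.05,
               tolerance = 0.01)
})

test_that("zero fetal fraction is indistinguishable from euploid", {
  bins <- synthetic_bins(sim_config(n_bins = 1200, seed = 20))
  eu <- simulate_cohort(sim_config(n_euploid = 40, n_bins = 1200, seed = 21),
                        bins = bins)
  null_tri <- simulate_cohort(
    sim_config(n_euploid = 0, n_bins = 1200, seed = 22,
               trisomy = data.frame(chrom = 21, f = rep(0, 40))),
    bins = bins)
  rf_eu <- profile_cohort(eu$counts, bins)$rf[, 21]
  rf_0 <- profile_cohort(null_tri$counts, bins)$rf[, 21]
  expect_gt(suppressWarnings(ks.test(rf_eu, rf_0)$p.value), 0.001)
})

test_that("per-sample reads fractions and GC contents respect the envelope", {
  co <- simulate_cohort(sim_config(n_euploid = 60, seed = 30))
  ps <- profile_cohort(co$counts, co$bins)
  expect_equal(unname(rowSums(ps$rf)), rep(1, 60), tolerance = 1e-12)
  env <- co$config$gc_envelope
  for (ch in c(13, 18, 21)) {
    expect_true(all(ps$gc[, ch] >= env[1]))
    expect_true(all(ps$gc[, ch] <= env[2]))
  }
})

test_that("stratified panels verify their own separation at generation time", {
  co <- strat_cohort(seed = 41, n_euploid = 120)
  expect_true(all(c(1, 2) %in% co$truth$subpop))
  # realized full-panel chr21 CV exceeds both within-subpopulation CVs
  ps <- profile_cohort(co$counts, co$bins)
  cv <- function(v) sd(v) / mean(v)
  full <- cv(ps$rf[, 21])
  within <- tapply(ps$rf[, 21], co$truth$subpop, cv)
  expect_gt(full, max(within))

  # indistinguishable subpopulations are rejected as infeasible
  expect_error(
    simulate_gc_stratified_panel(sim_config(n_euploid = 60, seed = 41),
                                 subpop_modes = c(0.47, 0.47)),
    "infeasible")

  # a single subpopulation degrades to the plain generator
  single <- simulate_gc_stratified_panel(
    sim_config(n_euploid = 5, n_bins = 700, depth = 2e5, seed = 42),
    subpop_modes = 0.47)
  expect_null(single$truth$subpop)
})

test_that("the adaptive pipeline recruits references from the right subpopulation", {
  co <- strat_cohort(seed = 50, n_euploid = 150)
  panel <- nipt_panel(profile_cohort(co$counts, co$bins), chromosomes = 21)
  te <- simulate_gc_stratified_panel(sim_config(n_euploid = 1, seed = 51),
                                     bins = co$bins, subpop = 1L,
                                     check = FALSE)
  tp <- profile_cohort(te$counts, co$bins)
  sel <- expand_and_choose(panel, tp[1], 21)
  expect_false(sel$fallback)
  expect_gte(mean(co$truth$subpop[sel$members] == 1), 0.9)
})

test_that("cohorts round-trip through the on-disk layout", {
  co <- simulate_cohort(sim_config(n_euploid = 3, n_bins = 700,
                                   depth = 1e5, seed = 60))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  bins <- read_bins(file.path(dir, "bins.bed"))
  expect_equal(bins$gc, co$bins$gc)
  bc <- read_counts(file.path(dir, "counts", "E0001.tsv"), bins)
  expect_equal(bc$counts, unname(co$counts[, "E0001"]))
  man <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(man, co$manifest)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(trisomy = data.frame(chrom = 21, f = 0.9)),
               "fetal fraction")
  expect_error(sim_config(trisomy = data.frame(chrom = 12, f = 0.1)),
               "13, 18 or 21")
  expect_error(simulate_cohort(sim_config(n_euploid = 0)), "no samples")
})
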