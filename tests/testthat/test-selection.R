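test_that("window membership follows the shared-range definition", {
  # the rf window is centred on the FITTED value, so make the panel flat
  # in rf: membership is then driven by the GC window alone
  ps <- profile_set21(rep(0.013, 3), c(0.420, 0.424, 0.430),
                      ids = c("lo", "mid", "hi"))
  panel <- nipt_panel(ps, chromosomes = 21)
  test <- profile21(0.013, 0.424)
  w <- select_window(panel, test, 21, g = 0.001, r = Inf)
  expect_equal(w$sample_id, "mid")
  expect_equal(w$n, 1L)
  expect_true(is.na(w$cv))

  # unbounded windows recover the whole panel
  w_all <- select_window(panel, test, 21, g = Inf, r = Inf)
  expect_equal(w_all$n, 3L)
  expect_equal(w_all$sample_id, c("lo", "mid", "hi"))
})

test_that("window membership equals the brute-force filter on random panels", {
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(20:120, 1)
    gc21 <- runif(n, 0.40, 0.46)
    rf21 <- 0.004 + 0.022 * gc21 + rnorm(n, 0, 2e-4)
    panel <- nipt_panel(profile_set21(rf21, gc21), chromosomes = 21)
    test <- profile21(runif(1, 0.012, 0.015), runif(1, 0.41, 0.45))
    g <- runif(1, 5e-4, 0.02)
    r <- runif(1, 1e-5, 2e-3) * 22   # normalized scale is ~22x smaller
    w <- select_window(panel, test, 21, g, r)

    # independent double-loop oracle
    gc_c <- test$gc[1, 21]
    rf_c <- panel$fits$chr21$alpha + panel$fits$chr21$beta * gc_c
    keep <- logical(n)
    for (k in seq_len(n)) {
      keep[k] <- abs(panel$gc[k, 21] - gc_c) <= g &&
        abs(panel$rf_norm[k, 21] - rf_c) <= r
    }
    expect_equal(w$members, which(keep))
  }
})

test_that("memberships grow monotonically with the window half-widths", {
  set.seed(99)
  n <- 150
  gc21 <- runif(n, 0.40, 0.46)
  rf21 <- 0.004 + 0.022 * gc21 + rnorm(n, 0, 2e-4)
  panel <- nipt_panel(profile_set21(rf21, gc21), chromosomes = 21)
  test <- profile21(0.0135, 0.43)
  grid <- expand_and_choose(panel, test, 21)$grid
  for (rr in unique(grid$r)) {
    sub <- grid[grid$r == rr, ]
    expect_true(all(diff(sub$n[order(sub$g)]) >= 0))
  }
  for (gg in unique(grid$g)) {
    sub <- grid[grid$g == gg, ]
    expect_true(all(diff(sub$n[order(sub$r)]) >= 0))
  }
})

test_that("two-subpopulation panels select the test sample's subpopulation", {
  set.seed(5)
  nA <- 60; nB <- 60
  gcA <- rnorm(nA, 0.418, 0.002); gcB <- rnorm(nB, 0.442, 0.002)
  # rf tracks gc strongly between subpopulations
  rfA <- 0.0128 + rnorm(nA, 0, 6e-5); rfB <- 0.0140 + rnorm(nB, 0, 6e-5)
  ps <- profile_set21(c(rfA, rfB), c(gcA, gcB))
  panel <- nipt_panel(ps, chromosomes = 21)
  test <- profile21(0.0128, 0.418)
  sel <- expand_and_choose(panel, test, 21)
  expect_false(sel$fallback)
  expect_true(all(sel$members <= nA))       # members all from subpop A
  expect_lt(panel_cv(panel, 21, sel$members), panel_cv(panel, 21))
})

test_that("homogeneous panels lose little and fall back when too small", {
  set.seed(6)
  n <- 120
  gc21 <- rnorm(n, 0.428, 0.003)
  rf21 <- 0.0132 + rnorm(n, 0, 6e-5)
  panel <- nipt_panel(profile_set21(rf21, gc21), chromosomes = 21)
  test <- profile21(0.0132, 0.428)
  sel <- expand_and_choose(panel, test, 21)
  full_cv <- panel_cv(panel, 21)
  chosen_cv <- panel_cv(panel, 21, sel$members)
  expect_lte(chosen_cv, full_cv * 1.01)   # no harm
  expect_gte(chosen_cv, full_cv * 0.3)    # and no absurd noise-chasing

  # min_panel above the panel size forces the full-panel fallback
  expect_warning(
    fb <- expand_and_choose(panel, test, 21,
                            selection_params(min_panel = n + 1L)),
    "falling back")
  expect_true(fb$fallback)
  expect_equal(fb$members, seq_len(n))
})

test_that("CV ties resolve to larger then tighter windows deterministically", {
  # all panel samples inside the smallest window: every window has the
  # same membership and CV, so the tie-break must pick the smallest (g, r)
  set.seed(7)
  gc21 <- 0.43 + runif(40, -1e-5, 1e-5)
  rf21 <- 0.013 * (1 + runif(40, -1e-4, 1e-4))
  panel <- nipt_panel(profile_set21(rf21, gc21), chromosomes = 21)
  test <- profile21(0.013, 0.43)
  sel <- expand_and_choose(panel, test, 21)
  w <- sel$grid[sel$chosen, ]
  expect_equal(w$g, selection_params()$gc_unit)
  expect_equal(w$r, selection_params()$rf_unit)
  expect_equal(w$n, 40L)
})

test_that("grid export marks the chosen window", {
  set.seed(8)
  gc21 <- runif(60, 0.41, 0.44)
  rf21 <- 0.004 + 0.022 * gc21 + rnorm(60, 0, 1e-4)
  panel <- nipt_panel(profile_set21(rf21, gc21), chromosomes = 21)
  sel <- expand_and_choose(panel, profile21(0.0133, 0.428), 21)
  df <- as.data.frame(sel)
  expect_equal(sum(df$chosen), 1L)
  expect_equal(df$n[df$chosen], length(sel$members))
})

test_that("GC-region grouping uses floor bins of the given width", {
  ps <- profile_set21(rep(0.013, 4), c(0.416, 0.424, 0.437, 0.446),
                      ids = c("a", "b", "c", "d"))
  groups <- group_by_gc_region(ps, 21)
  expect_setequal(names(groups), c("0.41", "0.42", "0.43", "0.44"))
  expect_equal(groups[["0.42"]], "b")

  # exact boundary falls in its own region
  ps2 <- profile_set21(rep(0.013, 2), c(0.420, 0.4199), ids = c("x", "y"))
  g2 <- group_by_gc_region(ps2, 21)
  expect_equal(g2[["0.42"]], "x")
  expect_equal(g2[["0.41"]], "y")

  expect_equal(group_by_gc_region(list(), 21), list())
})

test_that("representatives are the median-GC sample, with small-group conventions", {
  ps3 <- profile_set21(rep(0.013, 3), c(0.421, 0.428, 0.424),
                       ids = c("a", "b", "c"))
  expect_equal(choose_representative(ps3, 21), "c")  # gc 0.424 is median

  # five samples: lower-median convention -> third-smallest gc
  ps5 <- profile_set21(rep(0.013, 5),
                       c(0.420, 0.422, 0.424, 0.426, 0.428))
  expect_equal(choose_representative(ps5, 21), "P003")

  # even n > 2 uses the lower median
  ps4 <- profile_set21(rep(0.013, 4), c(0.421, 0.423, 0.425, 0.427))
  expect_equal(choose_representative(ps4, 21), "P002")

  two <- profile_set21(rep(0.013, 2), c(0.42, 0.43), ids = c("zz", "aa"))
  expect_equal(choose_representative(two, 21), "aa")
  one <- profile_set21(0.013, 0.42, ids = "only")
  expect_equal(choose_representative(one, 21), "only")
  expect_error(choose_representative(list(), 21))
})
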