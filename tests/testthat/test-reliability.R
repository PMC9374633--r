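test_that("the generic builder reproduces the four dyadic formulas term for term", {
  reps <- replication_counts(j = 3, k = 11, l = 4)
  for (lv in c("BC", "BP", "WPD", "WPM")) {
    spec <- build_reliability_spec(dyadic_terms, lv, reps)
    ref <- hardcoded_rel_structure(lv, j = 3, k = 11, l = 4)
    got_num <- setNames(spec$divisor[spec$in_numerator],
                        spec$term[spec$in_numerator])
    got_den <- setNames(spec$divisor[!spec$in_numerator],
                        spec$term[!spec$in_numerator])
    expect_equal(got_num[sort(names(got_num))],
                 ref$num[sort(names(ref$num))], label = lv)
    expect_equal(got_den[sort(names(got_den))],
                 ref$den[sort(names(ref$den))], label = lv)
  }
})

test_that("non-dyadic daily formulas arise from the reduced term set", {
  reps <- replication_counts(j = 2, k = 10)
  bp <- build_reliability_spec(daily_terms, "BP", reps)
  expect_setequal(bp$term[bp$in_numerator], c("P", "PI"))
  expect_equal(setNames(bp$divisor, bp$term)[c("P", "PI", "D", "PD", "DI",
                                               "e")],
               c(P = 1, PI = 2, D = 10, PD = 10, DI = 20, e = 20))
  wpd <- build_reliability_spec(daily_terms, "WPD", reps)
  expect_setequal(wpd$term[wpd$in_numerator], "PD")
  expect_equal(setNames(wpd$divisor, wpd$term)[c("PD", "D", "DI", "e")],
               c(PD = 1, D = 1, DI = 2, e = 2))
  # worked example: sigma2_PD = .5, sigma2_e = .5, j = 1 -> 0.5
  expect_equal(reliability_nondyadic(c(PD = .5, e = .5),
                                     replication_counts(j = 1, k = 10),
                                     "WPD"), 0.5)
  expect_equal(reliability_nondyadic(c(P = .4, e = 0.0001),
                                     replication_counts(j = 1, k = 1e9),
                                     "BP"), 1, tolerance = 1e-6)
})

test_that("dyadic formulas with couple and moment terms zeroed at l = 1 reduce to the daily formulas", {
  # PDI is confounded with error in the daily design, so it is zero here
  comp <- c(P = .3, D = .05, PD = .2, PI = .1, DI = .03, e = .4)
  reps_d <- replication_counts(j = 2, k = 12, l = 1)
  reps_n <- replication_counts(j = 2, k = 12)
  expect_equal(reliability_dyadic(comp, reps_d, "BP"),
               reliability_nondyadic(comp, reps_n, "BP"))
  expect_equal(reliability_dyadic(comp, reps_d, "WPD"),
               reliability_nondyadic(comp, reps_n, "WPD"))
})

test_that("moment-level worked examples evaluate as printed", {
  reps <- replication_counts(j = 2, k = 14, l = 4.13)
  expect_equal(reliability_dyadic(c(PDM = .17, e = .34), reps, "WPM"), 0.5)
  expect_equal(reliability_dyadic(c(PDM = .42, e = 0), reps, "WPM"), 1)
  # couple level for the four-item communal scale, S1 constants
  comp <- dplyr::filter(esm_reference_components(), sample == "S1",
                        scale == "communal")
  des <- dplyr::filter(esm_reference_design(), sample == "S1",
                       scale == "communal")
  r_bc <- reliability_dyadic(comp, replication_counts(j = des$j, k = des$k,
                                                      l = des$l_eff), "BC")
  expect_equal(r_bc, 0.50, tolerance = 0.02)
})

test_that("purely fixed components can never influence a reliability", {
  reps <- replication_counts(j = 3, k = 14, l = 4)
  base <- c(C = .1, P = .2, PD = .1, PDM = .1, PI = .05, e = .3)
  inflated <- c(base, M = 50, I = 50, MI = 50)
  for (lv in c("BC", "BP", "WPD", "WPM")) {
    expect_equal(reliability_dyadic(inflated, reps, lv),
                 reliability_dyadic(base, reps, lv), label = lv)
  }
})

test_that("reliabilities stay in [0,1] for arbitrary nonnegative components", {
  reps <- replication_counts(j = 2, k = 7, l = 3)
  set.seed(8)
  for (i in 1:25) {
    comp <- setNames(runif(23, 0, .5), c(dyadic_terms$term, "e"))
    for (lv in c("BC", "BP", "WPD", "WPM")) {
      r <- reliability_dyadic(comp, reps, lv)
      expect_gte(r, 0); expect_lte(r, 1)
    }
  }
})

test_that("reliabilities are monotone in the replication counts and reach their limits", {
  comp <- c(C = .1, P = .2, D = .02, PD = .1, PDM = .15, PI = .08,
            DI = .01, PDI = .04, e = .35)
  grid <- c(1, 2, 4, 8, 16)
  wpm <- vapply(grid, function(j) {
    reliability_dyadic(comp, replication_counts(j, 14, 4), "WPM")
  }, 0)
  expect_true(all(diff(wpm) > 0))
  wpd_j <- vapply(grid, function(j) {
    reliability_dyadic(comp, replication_counts(j, 14, 4), "WPD")
  }, 0)
  wpd_l <- vapply(grid, function(l) {
    reliability_dyadic(comp, replication_counts(2, 14, l), "WPD")
  }, 0)
  expect_true(all(diff(wpd_j) > 0) && all(diff(wpd_l) > 0))
  bp_k <- vapply(grid, function(k) {
    reliability_dyadic(comp, replication_counts(2, k, 4), "BP")
  }, 0)
  expect_true(all(diff(bp_k) > 0))
  # limits
  expect_equal(reliability_dyadic(comp, replication_counts(2, 1e9, 4), "BP"),
               1, tolerance = 1e-6)
  expect_equal(reliability_dyadic(comp, replication_counts(1e9, 14, 4),
                                  "WPM"), 1, tolerance = 1e-6)
})

test_that("effective replications follow the answered-survey conventions", {
  d <- simulate_esm(small_spec())
  sc <- scale_def("s", c("i1", "i2"))
  reps <- effective_replications(d, sc)
  expect_equal(reps$l, 2); expect_equal(reps$k, 3); expect_equal(reps$j, 2)
  # delete exactly half of all surveys
  surveys <- dplyr::distinct(d, person_id, day, moment)
  drop <- surveys[seq(1, nrow(surveys), by = 2), ]
  d2 <- esm_dataset(dplyr::anti_join(d, drop,
                                     by = c("person_id", "day", "moment")),
                    n_days = 3, n_moments = 2)
  reps2 <- effective_replications(d2, sc)
  expect_equal(reps2$l, 1)  # half of l = 2
  # l_eff = answered / (persons x declared days), by hand
  n_answered <- nrow(dplyr::distinct(d2, person_id, day, moment))
  expect_equal(reps2$l, n_answered / (8 * 3))
  sched <- effective_replications(d2, sc, use_scheduled = TRUE)
  expect_equal(sched$l, 2)
  expect_error(effective_replications(d[0, ], sc), "no answered")
})

test_that("rounding-interval propagation brackets the plug-in value", {
  comp <- dplyr::filter(esm_reference_components(), sample == "S1",
                       scale == "independence")
  reps <- replication_counts(j = 2, k = 14, l = 4.129)
  for (lv in c("BC", "BP", "WPD", "WPM")) {
    b <- reliability_bounds(comp, reps, lv)
    expect_lte(b$lower, b$point)
    expect_gte(b$upper, b$point)
    expect_gt(b$half_width, 0)
  }
  # wider rounding widens the interval
  b1 <- reliability_bounds(comp, reps, "WPM", rounding = 0.005)
  b2 <- reliability_bounds(comp, reps, "WPM", rounding = 0.02)
  expect_gt(b2$half_width, b1$half_width)
})
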