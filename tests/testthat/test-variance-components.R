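test_that("neg_loglik matches closed forms and a dense-covariance oracle", {
  one <- tibble::tibble(couple_id = "c1", person_id = "p1", day = 1L,
                        moment = 1L, item = "a", value = 1.7)
  comp0 <- setNames(numeric(23), c(dyadic_terms$term, "e"))
  comp0["e"] <- 1
  expect_equal(neg_loglik(comp0, one, dyadic_terms, mu = 1.7), log(2 * pi))

  d <- simulate_esm(sim_spec(n_couples = 3, n_days = 2, n_moments = 2,
                             n_items = 2, missing_rate = .2, seed = 3))
  comp <- c(C = .1, P = .1, PD = .05, PDM = .1, PI = .05, DM = .02, e = .3)
  v_sparse <- neg_loglik(comp, d, dyadic_terms, mu = 0.1)
  V <- diag(comp[["e"]], nrow(d))
  for (tt in setdiff(names(comp), "e")) {
    g <- build_group_labels(d, tt)
    Z <- outer(g, seq_len(attr(g, "n_groups")), "==") + 0
    V <- V + comp[[tt]] * tcrossprod(Z)
  }
  r <- d$value - 0.1
  v_dense <- as.numeric(nrow(d) * log(2 * pi) + determinant(V)$modulus +
                          t(r) %*% solve(V, r))
  expect_equal(v_sparse, v_dense, tolerance = 1e-8)

  expect_warning(ok <- neg_loglik(c(P = .1, e = 0), d, dyadic_terms),
                 "infinite")
  expect_equal(ok, Inf)
})

test_that("the likelihood at the ML solution beats the generating truth", {
  d <- simulate_esm(small_spec(seed = 7))
  fit <- fit_components(d)
  truth <- setNames(numeric(23), c(dyadic_terms$term, "e"))
  truth[c("C", "P", "PD", "PDM", "PI", "e")] <- c(.2, .3, .15, .2, .1, .25)
  expect_lte(fit$minus2loglik,
             neg_loglik(truth, d, dyadic_terms, mu = 0))
  # the reported -2logL equals the kernel evaluated at the estimates
  est <- setNames(c(fit$components$sigma2, fit$sigma2_e),
                  c(fit$components$term, "e"))
  expect_equal(fit$minus2loglik, neg_loglik(est, d, mu = fit$mu),
               tolerance = 1e-6)
})

test_that("EMS oracle reproduces textbook identities", {
  # one-facet design, p persons x j items: sigma2_P = (MS_P - MS_e) / j
  set.seed(21)
  p <- 6; j <- 4
  d <- tidyr::expand_grid(person_id = sprintf("p%d", 1:p),
                          item = sprintf("i%d", 1:j))
  d$couple_id <- "x"; d$day <- 1L; d$moment <- 1L
  d$value <- rnorm(p, 0, 1)[as.integer(factor(d$person_id))] +
    rnorm(nrow(d), 0, .5)
  single <- tibble::tibble(facet = "P", column = "person_id",
                           role = "random", nested_in = NA_character_)
  an <- anova_balanced(d, enumerate_terms(single))
  pm <- tapply(d$value, d$person_id, mean)
  ms_p <- j * sum((pm - mean(d$value))^2) / (p - 1)
  ms_e <- sum((d$value - pm[d$person_id])^2) / (p * (j - 1))
  expect_equal(an$sigma2_raw[an$term == "P"], (ms_p - ms_e) / j)
  expect_equal(an$sigma2_raw[an$term == "e"], ms_e)

  # zero noise: y exactly person means -> sigma2_e = 0
  d0 <- d
  d0$value <- pm[d0$person_id]
  an0 <- anova_balanced(d0, enumerate_terms(single))
  expect_equal(an0$sigma2[an0$term == "e"], 0, tolerance = 1e-12)
})

test_that("EMS oracle matches brute-force sums of squares on a 4x3 grid", {
  set.seed(5)
  a <- 4; b <- 3
  d <- tidyr::expand_grid(person_id = sprintf("p%d", 1:a),
                          item = sprintf("i%d", 1:b))
  d$couple_id <- "x"; d$day <- 1L; d$moment <- 1L
  d$value <- rnorm(nrow(d))
  fac <- tibble::tibble(facet = c("P", "I"),
                        column = c("person_id", "item"),
                        role = "random", nested_in = NA_character_)
  an <- anova_balanced(d, enumerate_terms(fac))
  # explicit sums of squares
  gm <- mean(d$value)
  am <- tapply(d$value, d$person_id, mean)
  bm <- tapply(d$value, d$item, mean)
  ss_a <- b * sum((am - gm)^2)
  ss_b <- a * sum((bm - gm)^2)
  ss_e <- sum((d$value - am[d$person_id] - bm[d$item] + gm)^2)
  ms_a <- ss_a / (a - 1); ms_b <- ss_b / (b - 1)
  ms_e <- ss_e / ((a - 1) * (b - 1))
  expect_equal(an$sigma2_raw[an$term == "P"], (ms_a - ms_e) / b)
  expect_equal(an$sigma2_raw[an$term == "I"], (ms_b - ms_e) / a)
  expect_equal(an$sigma2_raw[an$term == "e"], ms_e)

  expect_error(anova_balanced(d[-1, ], enumerate_terms(fac)), "unbalanced")
})

test_that("a pure-noise model recovers zero components and unit error", {
  d <- simulate_esm(sim_spec(n_couples = 16, n_days = 7, n_moments = 4,
                             n_items = 2, sigma2 = c(C = 0), sigma2_e = 1,
                             missing_rate = 0, seed = 42))
  expect_gte(nrow(d), 1000)
  fit <- fit_components(d)
  # sampling SD of a component is about sqrt(2/df) * sigma2_e / c, with c
  # the observations per group; terms averaging over many replications
  # (c >= 4) resolve below .01, the partner-contrast terms (c = 2) only to
  # about 3 * sqrt(2/df)/2
  comp <- fit$components
  geo_c <- nrow(d) / comp$n_groups
  expect_true(all(comp$sigma2[geo_c >= 4] < .01))
  expect_true(all(comp$sigma2 < .025))
  expect_lt(abs(fit$sigma2_e - 1), .05)
})

test_that("REML equals the EMS oracle on balanced crossed data", {
  # the classical identity holds whenever the EMS solution is interior
  n_interior <- 0
  for (s in 1:4) {
    g <- crossed_pdi(seed = 30 + s)
    an <- anova_balanced(g, terms = daily_terms)
    if (!all(an$sigma2_raw > 1e-4)) next
    n_interior <- n_interior + 1
    fr <- fit_components(g, terms = daily_terms, method = "REML")
    est <- setNames(c(fr$components$sigma2, fr$sigma2_e),
                    c(fr$components$term, "e"))
    expect_equal(unname(est[an$term]), an$sigma2_raw, tolerance = 1e-4)
  }
  expect_gte(n_interior, 1)
})

test_that("the stratum and mixed-model engines agree on balanced data", {
  d <- simulate_esm(small_spec(seed = 13))
  f1 <- fit_components(d, engine = "strata")
  f2 <- fit_components(d, engine = "lmer")
  expect_equal(f1$components$sigma2, f2$components$sigma2, tolerance = 2e-3)
  expect_equal(f1$sigma2_e, f2$sigma2_e, tolerance = 2e-3)
  expect_true(f1$converged && f2$converged)
})

test_that("estimates are invariant to relabeling couples and persons", {
  d <- simulate_esm(small_spec(seed = 23))
  f1 <- fit_components(d)
  relab <- d
  relab$couple_id <- chartr("1234", "4321", relab$couple_id)
  relab$person_id <- chartr("1234", "4321", relab$person_id)
  f2 <- fit_components(relab)
  expect_equal(f1$components$sigma2, f2$components$sigma2, tolerance = 1e-6)
  expect_equal(f1$sigma2_e, f2$sigma2_e, tolerance = 1e-6)
})

test_that("estimates are nonnegative with boundary terms flagged, and degenerate designs error", {
  d <- simulate_esm(small_spec(seed = 77))
  fit <- fit_components(d)
  expect_true(all(fit$components$sigma2 >= 0))
  expect_gte(fit$sigma2_e, 0)
  expect_true(any(fit$components$boundary))  # 17 generating zeros
  expect_true(all(fit$components$sigma2[fit$components$boundary] == 0))

  oneday <- dplyr::filter(d, day == 1)
  expect_error(fit_components(oneday), "single group.*D|D.*single group")
})

test_that("relative shares partition the systematic variance", {
  comp <- tibble::tibble(term = c("C", "P", "e"), sigma2 = c(.1, .3, .6))
  sh <- relative_shares(comp)
  expect_equal(sh$share, c(25, 75))
  expect_equal(sum(sh$share), 100, tolerance = 1e-9)
  single <- tibble::tibble(term = c("P", "e"), sigma2 = c(.4, .6))
  expect_equal(relative_shares(single)$share, 100)
  zero <- tibble::tibble(term = c("P", "e"), sigma2 = c(0, 1))
  expect_error(relative_shares(zero), "zero")
})

test_that("tidy and glance expose the fit in broom style", {
  d <- simulate_esm(small_spec(seed = 3))
  fit <- fit_components(d)
  td <- tidy(fit)
  expect_named(td, c("term", "sigma2", "boundary"))
  expect_equal(nrow(td), 23L)  # 22 terms + residual
  gl <- glance(fit)
  expect_equal(gl$n_terms, 22L)
  expect_true(gl$converged)
})
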