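# shared fixtures: all generated in code, tiny by design

toy_csv <- function() {
  system.file("extdata", "toy_surveys.csv", package = "esmrel")
}

# small balanced dyadic study with known components
small_spec <- function(seed = 99, missing_rate = 0, ...) {
  sim_spec(n_couples = 4, n_days = 3, n_moments = 2, n_items = 2,
           sigma2 = c(C = .2, P = .3, PD = .15, PDM = .2, PI = .1),
           sigma2_e = .25, missing_rate = missing_rate, seed = seed, ...)
}

dyadic_terms <- enumerate_terms(esm_facets())
daily_terms <- enumerate_terms(esm_facets(dyadic = FALSE, moments = FALSE))

# crossed non-dyadic P x D x I table with known effects, balanced
crossed_pdi <- function(n_p = 8, n_d = 6, n_i = 4, seed = 1,
                        sig = c(P = .5, D = .3, I = .2, PD = .4, PI = .3,
                                DI = .2), sig_e = .4) {
  set.seed(seed)
  g <- tidyr::expand_grid(person_id = sprintf("p%02d", seq_len(n_p)),
                          day = seq_len(n_d),
                          item = sprintf("i%02d", seq_len(n_i)))
  g$couple_id <- "none"
  g$moment <- 1L
  draw <- function(fac) {
    key <- interaction(g[fac], drop = TRUE)
    rnorm(nlevels(key))[as.integer(key)]
  }
  g$value <- sqrt(sig[["P"]]) * draw("person_id") +
    sqrt(sig[["D"]]) * draw("day") +
    sqrt(sig[["I"]]) * draw("item") +
    sqrt(sig[["PD"]]) * draw(c("person_id", "day")) +
    sqrt(sig[["PI"]]) * draw(c("person_id", "item")) +
    sqrt(sig[["DI"]]) * draw(c("day", "item")) +
    rnorm(nrow(g), 0, sqrt(sig_e))
  g
}

# reference term structures of the four dyadic reliability formulas,
# written out term by term with their divisors (j items, k days, l moments,
# 2 persons); the generic builder must reproduce these exactly
hardcoded_rel_structure <- function(level, j, k, l) {
  num_den <- switch(level,
    BC = list(
      num = c(C = 1, CI = j, CM = l, CMI = l * j),
      den = c(CD = k, CDM = k * l, CDI = k * j, CDMI = k * l * j,
              P = 2, D = k, PD = 2 * k, PM = 2 * l, PI = 2 * j,
              DM = k * l, DI = k * j, PDM = 2 * k * l, PDI = 2 * k * j,
              PMI = 2 * l * j, DMI = k * l * j, e = 2 * k * l * j)),
    BP = list(
      num = c(P = 1, PI = j, PM = l, PMI = l * j),
      den = c(D = k, PD = k, DM = k * l, DI = k * j, PDM = k * l,
              PDI = k * j, DMI = k * l * j, e = k * l * j)),
    WPD = list(
      num = c(PD = 1, PDI = j, PDM = l),
      den = c(D = 1, DM = l, DI = j, DMI = l * j, e = l * j)),
    WPM = list(
      num = c(PDM = 1),
      den = c(e = j)))
  num_den
}

eval_hardcoded <- function(comp, level, j, k, l) {
  st <- hardcoded_rel_structure(level, j, k, l)
  val <- function(v) {
    x <- comp[names(v)]
    x[is.na(x)] <- 0
    sum(x / v)
  }
  val(st$num) / (val(st$num) + val(st$den))
}
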