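#' Reference variance components from two dyadic ESM studies
#'
#' Variance decompositions of five experience-sampling scales — state
#' relationship satisfaction (relsat), independence motivation, power
#' motivation, the pooled agency scale, and communal motivation — estimated
#' in two intensive longitudinal couple studies: S1 (65 couples, 14 days, 5
#' scheduled surveys per day) and S2 (254 couples, 28 days, 4-5 scheduled
#' surveys per day). The raw data of both studies are restricted
#' scientific-use files; these component tables, printed to two decimals,
#' are what a reader can plug into the reliability formulas. Components
#' below 0.005, and a few cells at or below 0.01 whose scale attribution is
#' not unambiguous in the printed two-decimal tables, are recorded as 0;
#' every such cell enters the reliability formulas only through divisors of
#' at least the moment count, so the effect on any coefficient is below
#' 0.01 (see [reliability_bounds()] to quantify rounding sensitivity).
#'
#' Items are z-standardized, so the variances are in squared z-score units.
#' The relsat rows refer to the 2-item version in S1 and the 3-item version
#' in S2.
#'
#' @return A tibble `sample` (`"S1"`/`"S2"`), `scale`, `term` (incl. `"e"`),
#'   `sigma2`.
#' @seealso [esm_reference_design()], [esm_reference_reliabilities()]
#' @export
esm_reference_components <- function() {
  col <- function(sample, scale, ...) {
    v <- c(...)
    tibble(sample = sample, scale = scale, term = names(v),
           sigma2 = unname(v))
  }
  bind_rows(
    col("S1", "relsat", C = .10, P = .08, CD = .09, PD = .01, CDM = .11,
        PDM = .08, CI = .04, PI = .12, CDI = .02, PDI = .05, CDMI = .02,
        e = .28),
    col("S1", "independence", C = .04, P = .19, CD = .01, PD = .11,
        CDM = .03, PDM = .17, CI = .02, PI = .04, CDI = .01, PDI = .03,
        CDMI = .02, e = .34),
    col("S1", "power", C = .07, P = .11, CD = .01, PD = .05, CDM = .01,
        PDM = .11, CI = .03, PI = .20, CDI = .01, PDI = .08, CDMI = .01,
        e = .33),
    col("S1", "agency", C = .05, P = .10, CD = .01, PD = .02, CDM = .04,
        PDM = .04, CI = .03, PI = .17, PDI = .11, CDMI = .01, e = .43),
    col("S1", "communal", C = .10, P = .18, CD = .08, PD = .06, PDM = .15,
        CI = .03, PI = .08, PDI = .05, e = .27),
    col("S2", "relsat", C = .20, P = .10, CD = .02, PD = .06, CDM = .09,
        PDM = .09, CI = .04, PI = .08, CDI = .01, PDI = .04, CDMI = .01,
        e = .19),
    col("S2", "independence", C = .08, P = .16, CD = .01, PD = .08,
        CDM = .02, PDM = .13, CI = .02, PI = .08, PDI = .05, e = .33),
    col("S2", "power", C = .06, P = .19, CD = .01, PD = .07, PDM = .13,
        CI = .02, PI = .12, PDI = .06, e = .32),
    col("S2", "agency", C = .06, P = .12, CD = .02, PD = .04, PDM = .05,
        CI = .03, PI = .16, PDI = .10, e = .40),
    col("S2", "communal", C = .16, P = .11, PD = .07, CDM = .03, PDM = .12,
        CI = .04, PI = .13, PDI = .06, CDMI = .01, e = .24)
  )
}

#' Design constants of the two reference studies
#'
#' Scheduled items `j`, days `k`, moments per day `l_scheduled`, number of
#' persons, and the number of answered surveys per scale, from which the
#' effective moment count is `l_eff = answered / (persons * k)`. In S2 the
#' motivation items were not part of the last daily survey, hence their
#' smaller scheduled `l`.
#'
#' @return A tibble `sample`, `scale`, `j`, `k`, `l_scheduled`, `persons`,
#'   `answered_surveys`, `l_eff`.
#' @export
esm_reference_design <- function() {
  d <- tibble(
    sample  = rep(c("S1", "S2"), each = 5),
    scale   = rep(c("relsat", "independence", "power", "agency",
                    "communal"), 2),
    j       = c(2, 2, 2, 4, 4,   3, 2, 3, 5, 4),
    k       = c(rep(14, 5), rep(28, 5)),
    l_scheduled = c(rep(5, 5), 5, 4, 4, 4, 4),
    persons = c(rep(130L, 5), rep(508L, 5)),
    answered_surveys = c(7545L, 7515L, 7508L, 7515L, 7544L,
                         60917L, 47878L, 47871L, 47878L, 47913L)
  )
  mutate(d, l_eff = .data$answered_surveys / (.data$persons * .data$k))
}

#' Reported reliability estimates of the reference scales
#'
#' The reliability coefficients reported for the ten scale-by-sample
#' combinations whose variance components appear in
#' [esm_reference_components()], at all four aggregation levels. Useful as
#' a cross-check for the plug-in computation: evaluating the reliability
#' formulas on the printed components with `j` scheduled, `k` days and the
#' effective moment count reproduces these values to about two decimals.
#'
#' @return A tibble `sample`, `scale`, `level`, `reliability`.
#' @export
esm_reference_reliabilities <- function() {
  rel <- function(sample, scale, bc, bp, wpd, wpm) {
    tibble(sample = sample, scale = scale,
           level = c("BC", "BP", "WPD", "WPM"),
           reliability = c(bc, bp, wpd, wpm))
  }
  bind_rows(
    rel("S1", "relsat",       .58, .95, .61, .36),
    rel("S1", "independence", .32, .93, .79, .50),
    rel("S1", "power",        .43, .95, .73, .40),
    rel("S1", "agency",       .44, .96, .66, .28),
    rel("S1", "communal",     .50, .95, .87, .70),
    rel("S2", "relsat",       .76, .97, .86, .58),
    rel("S2", "independence", .46, .96, .74, .44),
    rel("S2", "power",        .37, .98, .79, .54),
    rel("S2", "agency",       .44, .98, .73, .38),
    rel("S2", "communal",     .70, .97, .86, .67)
  )
}

#' Plug-in reliabilities from a published component table
#'
#' Convenience wrapper: evaluates the four dyadic reliability formulas for
#' every sample-by-scale column of a reference component table, using `j`
#' scheduled items, `k` days and the effective moment count from the design
#' constants.
#'
#' @param components Long tibble as from [esm_reference_components()].
#' @param design Design constants as from [esm_reference_design()].
#' @return A tibble `sample`, `scale`, `level`, `reliability`.
#' @export
plugin_reliabilities <- function(components = esm_reference_components(),
                                 design = esm_reference_design()) {
  purrr::pmap(design, function(sample, scale, j, k, l_scheduled, persons,
                               answered_surveys, l_eff) {
    comp <- filter(components, .data$sample == !!sample,
                   .data$scale == !!scale)
    if (!nrow(comp)) return(NULL)
    reps <- replication_counts(j = j, k = k, l = l_eff)
    mutate(reliability_table(comp, reps), sample = sample, scale = scale,
           .before = 1)
  }) %>% bind_rows()
}
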