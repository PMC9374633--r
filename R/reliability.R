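#' Replication counts for reliability formulas
#'
#' The reliability of an aggregated score grows with the number of
#' replications averaged into it: `j` items per survey, `l` surveys
#' (moments) per day, `k` days per person, and the constant 2 persons per
#' couple. With missing surveys the scheduled counts overstate the
#' aggregation, so effective (average realized) counts are substituted.
#'
#' @param j Items per survey (>= 1; may be fractional when effective).
#' @param k Days per person.
#' @param l Moments (surveys) per day.
#' @param persons_per_couple Fixed at 2 for dyads.
#' @return An `esm_reps` object.
#' @export
replication_counts <- function(j, k, l = 1, persons_per_couple = 2) {
  vals <- c(j = j, k = k, l = l, p = persons_per_couple)
  if (any(!is.finite(vals)) || any(vals < 1)) {
    abort("replication counts must be finite and >= 1")
  }
  structure(list(j = j, k = k, l = l,
                 persons_per_couple = persons_per_couple),
            class = "esm_reps")
}

#' @export
print.esm_reps <- function(x, ...) {
  cat(sprintf("<replications: j = %.3g items, k = %.3g days, l = %.3g moments>\n",
              x$j, x$k, x$l))
  invisible(x)
}

#' Effective replication counts under missingness
#'
#' Computes the average realized aggregation of a scale:
#' `l` = answered surveys / (persons x declared days) — the response rate
#' times the scheduled moments; `k` = mean number of days with at least one
#' answered survey per person; `j` = mean number of the scale's items
#' answered per answered survey.
#'
#' @param data An experience-sampling dataset.
#' @param scale Optional [scale_def()]; rows are filtered to its items.
#' @param n_days,n_moments Declared design size; default from the dataset's
#'   attributes.
#' @param use_scheduled Return the scheduled counts instead (sensitivity
#'   analysis).
#' @return An `esm_reps` object; the scheduled counts are attached as
#'   attribute `scheduled`.
#' @export
effective_replications <- function(data, scale = NULL,
                                   n_days = attr(data, "n_days"),
                                   n_moments = attr(data, "n_moments"),
                                   use_scheduled = FALSE) {
  if (!is.null(scale)) data <- filter(data, .data$item %in% scale$items)
  if (!nrow(data)) abort("no answered surveys for this scale")
  n_days <- n_days %||% max(data$day)
  n_moments <- n_moments %||% max(data$moment)
  j_sched <- if (!is.null(scale)) length(scale$items) else
    n_distinct(data$item)
  surveys <- count(data, .data$person_id, .data$day, .data$moment,
                   name = "n_items")
  n_persons <- n_distinct(data$person_id)
  l_eff <- nrow(surveys) / (n_persons * n_days)
  k_eff <- mean(pull(count(distinct(surveys, .data$person_id, .data$day),
                           .data$person_id), "n"))
  j_eff <- mean(surveys$n_items)
  reps <- if (use_scheduled) {
    replication_counts(j = j_sched, k = n_days, l = n_moments)
  } else {
    replication_counts(j = j_eff, k = k_eff, l = l_eff)
  }
  attr(reps, "scheduled") <- list(j = j_sched, k = n_days, l = n_moments)
  reps
}

# ---- the generic numerator/denominator builder ---------------------------

.levels_dyadic <- c("BC", "BP", "WPD", "WPM")

level_focal <- function(level, terms) {
  has_m <- any(purrr::map_lgl(terms$facets, function(f) "M" %in% f))
  focal <- switch(level,
    BC = "C", BP = "P",
    WPD = "PD",
    WPM = if (has_m) "PDM" else
      abort("moment-level reliability needs a design with a moment facet"))
  if (!focal %in% terms$term) {
    abort(paste0("focal term '", focal, "' not in the term set"))
  }
  focal
}

#' Construct the term structure of a reliability coefficient
#'
#' Builds, for one focal aggregation level, the generalizability-theory
#' reliability ratio: the numerator (true-score variance) collects the focal
#' term and its interactions with the fixed facets (moments and items by
#' default), each divided by the product of the replication counts of its
#' fixed facets; the denominator adds the random terms that vary within the
#' focal units — every remaining random term at the couple level, the
#' day-family terms at the person and person-day levels, and nothing beyond
#' the residual at the moment level — plus the residual error divided by all
#' replications averaged within a focal unit (including the factor 2 for the
#' two partners at couple level). Purely fixed terms (M, I, MI) never enter.
#'
#' @param terms A term set from [enumerate_terms()].
#' @param level `"BC"` (between couples), `"BP"` (between persons), `"WPD"`
#'   (within persons, day to day), `"WPM"` (within persons, moment to
#'   moment).
#' @param reps Replication counts ([replication_counts()] or
#'   [effective_replications()]).
#' @param fixed Fixed facets; defaults to the roles declared in the design.
#' @return A tibble of class `esm_rel_spec`: `term` (incl. `"e"`),
#'   `in_numerator`, `divisor_facets` (e.g. `"lj"`), `divisor` (numeric).
#' @export
build_reliability_spec <- function(terms, level = .levels_dyadic, reps,
                                   fixed = NULL) {
  level <- match.arg(level)
  facets <- attr(terms, "design")
  fixed <- fixed %||% facets$facet[facets$role == "fixed"]
  focal_lab <- level_focal(level, terms)
  focal <- terms$facets[[match(focal_lab, terms$term)]]
  focal_closure <- facet_closure(focal, facets)
  pure_fixed <- purrr::map_lgl(terms$facets, function(f) all(f %in% fixed))
  in_num <- purrr::map_lgl(terms$facets, function(f) {
    all(focal %in% f) && all(setdiff(f, focal) %in% fixed)
  })
  in_den <- switch(level,
    BC  = !pure_fixed,
    BP  = !pure_fixed & !purrr::map_lgl(terms$facets, function(f) "C" %in% f),
    WPD = purrr::map_lgl(terms$facets, function(f) {
      "D" %in% f && all(f %in% c("D", fixed))
    }),
    WPM = rep(FALSE, nrow(terms)))
  keep <- in_num | in_den
  rep_of <- function(f) {
    switch(f, P = reps$persons_per_couple, D = reps$k, M = reps$l,
           I = reps$j,
           abort(paste0("no replication count for facet ", f)))
  }
  div_facets <- purrr::map(terms$facets[keep], function(f) {
    sort_facets(setdiff(f, focal_closure))
  })
  divisors <- purrr::map_dbl(div_facets, function(fs) {
    prod(purrr::map_dbl(fs, rep_of))
  })
  e_facets <- sort_facets(setdiff(facets$facet, focal_closure))
  out <- tibble(
    term = c(terms$term[keep], "e"),
    in_numerator = c(in_num[keep], FALSE),
    divisor_facets = c(purrr::map_chr(div_facets, paste, collapse = ""),
                       paste(e_facets, collapse = "")),
    divisor = c(divisors, prod(purrr::map_dbl(e_facets, rep_of)))
  )
  attr(out, "level") <- level
  attr(out, "focal") <- focal_lab
  class(out) <- c("esm_rel_spec", class(out))
  out
}

# normalize components input to a named vector with an "e" entry;
# terms absent from the input enter as 0
as_component_vector <- function(components) {
  if (inherits(components, "esm_vc")) {
    v <- setNames(components$components$sigma2, components$components$term)
    return(c(v, e = components$sigma2_e))
  }
  if (is.data.frame(components)) {
    return(setNames(components$sigma2, components$term))
  }
  stopifnot(is.numeric(components), !is.null(names(components)))
  components
}

eval_rel_spec <- function(spec, comp) {
  x <- comp[spec$term]
  x[is.na(x)] <- 0
  contrib <- x / spec$divisor
  num <- sum(contrib[spec$in_numerator])
  den <- sum(contrib)
  if (den <= 0) abort("reliability undefined: denominator is zero")
  num / den
}

#' Reliability of a dyadic experience-sampling scale at one level
#'
#' Evaluates the generalizability coefficient `R = sigma2_T / (sigma2_T +
#' sigma2_E)` for the dyadic five-facet design at the requested aggregation
#' level, from estimated (or published) variance components and replication
#' counts. Components missing from the input — boundary zeros, or blank
#' cells when plugging in a printed variance table — enter as 0.
#'
#' @param components An `esm_vc` fit, a tidy tibble (`term`, `sigma2`), or a
#'   named numeric vector with entry `"e"` for the residual.
#' @param reps Replication counts.
#' @param level `"BC"`, `"BP"`, `"WPD"` or `"WPM"`.
#' @param terms Term set; defaults to the full dyadic design.
#' @return The reliability, a number in `[0, 1]`.
#' @examples
#' comp <- c(PDM = 0.17, e = 0.34)
#' reliability_dyadic(comp, replication_counts(j = 2, k = 14, l = 4), "WPM")
#' @export
reliability_dyadic <- function(components, reps,
                               level = .levels_dyadic,
                               terms = enumerate_terms(esm_facets())) {
  level <- match.arg(level)
  spec <- build_reliability_spec(terms, level, reps)
  eval_rel_spec(spec, as_component_vector(components))
}

#' Reliability for designs without dyads or without moments
#'
#' For a non-dyadic daily design (facets P, D, I; terms P, D, I, PD, PI, DI
#' plus residual), the between-person and day-to-day formulas lose all
#' couple and moment terms. The same construction rules apply; the
#' day-family terms remain in the denominators because time is random.
#'
#' @inheritParams reliability_dyadic
#' @param level `"BP"` or `"WPD"`.
#' @param terms Term set; defaults to the daily non-dyadic design.
#' @export
reliability_nondyadic <- function(components, reps, level = c("BP", "WPD"),
                                  terms = enumerate_terms(
                                    esm_facets(dyadic = FALSE,
                                               moments = FALSE))) {
  level <- match.arg(level)
  spec <- build_reliability_spec(terms, level, reps)
  eval_rel_spec(spec, as_component_vector(components))
}

#' Reliabilities at all aggregation levels
#'
#' @inheritParams reliability_dyadic
#' @param levels Which levels to compute.
#' @param na_on_undefined Return `NA` (with a warning) instead of an error
#'   for levels whose denominator is zero.
#' @return A tibble `level`, `reliability`.
#' @export
reliability_table <- function(components, reps, levels = .levels_dyadic,
                              terms = enumerate_terms(esm_facets()),
                              na_on_undefined = FALSE) {
  comp <- as_component_vector(components)
  tibble(level = levels,
         reliability = purrr::map_dbl(levels, function(lv) {
           spec <- build_reliability_spec(terms, lv, reps)
           if (na_on_undefined) {
             tryCatch(eval_rel_spec(spec, comp), error = function(e) {
               warn(paste0("reliability undefined at level ", lv))
               NA_real_
             })
           } else {
             eval_rel_spec(spec, comp)
           }
         }))
}

#' Audit breakdown of one reliability coefficient
#'
#' @inheritParams reliability_dyadic
#' @return The reliability spec with a `contribution` column
#'   (`sigma2 / divisor`) and the resulting value as attribute
#'   `"reliability"`.
#' @export
reliability_breakdown <- function(components, reps, level = .levels_dyadic,
                                  terms = enumerate_terms(esm_facets())) {
  level <- match.arg(level)
  comp <- as_component_vector(components)
  spec <- build_reliability_spec(terms, level, reps)
  x <- comp[spec$term]
  x[is.na(x)] <- 0
  spec$sigma2 <- unname(x)
  spec$contribution <- spec$sigma2 / spec$divisor
  attr(spec, "reliability") <- eval_rel_spec(spec, comp)
  spec
}

#' Bounds on a plug-in reliability from rounded inputs
#'
#' When variance components are read from a table printed to 2 decimals,
#' each printed cell represents an interval of half-width 0.005 and each
#' blank cell the interval `[0, 0.005)`. A reliability ratio is increasing
#' in every numerator component and decreasing in every denominator-only
#' component, so interval propagation gives exact attainable bounds on the
#' coefficient. Use this to judge how precisely rounded published variances
#' determine a reliability.
#'
#' @inheritParams reliability_dyadic
#' @param rounding Half-width of the rounding interval of printed cells.
#' @return A tibble with `level`, `lower`, `point`, `upper`, `half_width`.
#' @export
reliability_bounds <- function(components, reps, level = .levels_dyadic,
                               terms = enumerate_terms(esm_facets()),
                               rounding = 0.005) {
  level <- match.arg(level)
  comp <- as_component_vector(components)
  spec <- build_reliability_spec(terms, level, reps)
  x <- comp[spec$term]
  x[is.na(x)] <- 0
  lo <- pmax(x - rounding, 0)
  hi <- x + rounding
  num <- spec$in_numerator
  r_at <- function(xnum, xden) {
    nn <- sum(xnum[num] / spec$divisor[num])
    dd <- nn + sum(xden[!num] / spec$divisor[!num])
    if (dd <= 0) return(NA_real_)
    nn / dd
  }
  upper <- r_at(hi, lo)
  lower <- r_at(lo, hi)
  point <- eval_rel_spec(spec, comp)
  tibble(level = level, lower = lower, point = point, upper = upper,
         half_width = (upper - lower) / 2)
}

#' @export
print.esm_rel_spec <- function(x, ...) {
  cat(sprintf("<reliability spec: level %s, focal %s>\n",
              attr(x, "level"), attr(x, "focal")))
  df <- as.data.frame(x)
  df$where <- ifelse(df$in_numerator, "num+den", "den")
  print(df[c("term", "where", "divisor_facets", "divisor")],
        row.names = FALSE)
  invisible(x)
}
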