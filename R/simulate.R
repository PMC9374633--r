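#' Specify a synthetic dyadic experience-sampling study
#'
#' Describes a study to be generated from the additive variance-component
#' model: `n_couples` couples of two indistinguishable partners, answering
#' `n_items` items at `n_moments` scheduled surveys on each of `n_days`
#' days. One independent normal effect is drawn per level combination of
#' each variance term — effects of shared terms (day, moment, and their
#' interactions) are drawn once and reused across persons, which is what
#' makes them shared — and composed additively with residual noise.
#' Whole surveys are then deleted completely at random with probability
#' `missing_rate`, emulating skipped surveys.
#'
#' The default dimensions and variances mirror a two-week couple study with
#' five daily surveys, a four-item scale measured in z-score units, and the
#' observed survey response rate of about 83%.
#'
#' @param n_couples,n_days,n_moments,n_items Design dimensions (all >= 1).
#' @param mu Grand mean.
#' @param sigma2 Named numeric vector of per-term variances (names from the
#'   22-term dyadic set; unnamed terms are 0). Defaults to the communal
#'   motivation column of [esm_reference_components()], sample S1.
#' @param sigma2_e Residual variance.
#' @param missing_rate Survey-level missingness probability in `[0, 1)`.
#' @param item_missing_rate Additional item-level missingness within
#'   answered surveys (partial surveys), default 0.
#' @param seed Integer seed; generation is fully reproducible
#'   (Mersenne-Twister, inversion normals).
#' @param scale_id Label of the generated scale.
#' @return An `esm_sim_spec` object.
#' @export
sim_spec <- function(n_couples = 65, n_days = 14, n_moments = 5,
                     n_items = 4, mu = 0, sigma2 = NULL, sigma2_e = 0.27,
                     missing_rate = 0.17, item_missing_rate = 0,
                     seed = 1L, scale_id = "scale_1") {
  dims <- c(n_couples = n_couples, n_days = n_days, n_moments = n_moments,
            n_items = n_items)
  if (any(dims < 1) || any(dims != round(dims))) {
    abort("design dimensions must be positive integers")
  }
  if (is.null(sigma2)) {
    ref <- filter(esm_reference_components(),
                  .data$sample == "S1", .data$scale == "communal",
                  .data$term != "e")
    sigma2 <- setNames(ref$sigma2, ref$term)
  }
  all_terms <- enumerate_terms(esm_facets())$term
  bad <- setdiff(names(sigma2), all_terms)
  if (length(bad)) {
    abort(paste0("unknown term(s) in sigma2: ", paste(bad, collapse = ", ")))
  }
  full <- setNames(numeric(length(all_terms)), all_terms)
  full[names(sigma2)] <- sigma2
  if (any(!is.finite(full)) || any(full < 0) || !is.finite(sigma2_e) ||
      sigma2_e < 0) {
    abort("variances must be finite and nonnegative")
  }
  if (missing_rate < 0 || missing_rate >= 1 ||
      item_missing_rate < 0 || item_missing_rate >= 1) {
    abort("missingness rates must lie in [0, 1)")
  }
  structure(list(n_couples = as.integer(n_couples),
                 n_days = as.integer(n_days),
                 n_moments = as.integer(n_moments),
                 n_items = as.integer(n_items),
                 mu = mu, sigma2 = full, sigma2_e = sigma2_e,
                 missing_rate = missing_rate,
                 item_missing_rate = item_missing_rate,
                 seed = as.integer(seed), scale_id = scale_id,
                 rng = "Mersenne-Twister/Inversion"),
            class = "esm_sim_spec")
}

#' @export
print.esm_sim_spec <- function(x, ...) {
  cat(sprintf(paste0("<sim spec: %d couples x %d days x %d moments x %d ",
                     "items; missing %.0f%%; seed %d>\n"),
              x$n_couples, x$n_days, x$n_moments, x$n_items,
              100 * x$missing_rate, x$seed))
  invisible(x)
}

sim_grid <- function(spec, item_prefix = "i") {
  g <- tidyr::expand_grid(
    couple_id = sprintf("c%03d", seq_len(spec$n_couples)),
    member = 1:2,
    day = seq_len(spec$n_days),
    moment = seq_len(spec$n_moments),
    item = paste0(item_prefix, seq_len(spec$n_items)))
  g$person_id <- sprintf("%s_p%d", g$couple_id, g$member)
  select(g, all_of(c("couple_id", "person_id", "day", "moment", "item")))
}

# add the per-term random effects of one scale to a response vector
compose_effects <- function(grid, terms, facets, sigma2,
                            shared_draws = NULL) {
  y <- numeric(nrow(grid))
  for (i in seq_len(nrow(terms))) {
    tt <- terms$term[i]
    s2 <- sigma2[[tt]]
    if (is.null(s2) || s2 == 0) next
    idx <- group_index_for(grid, terms$closure[[i]], facets)
    draws <- if (!is.null(shared_draws) && !is.null(shared_draws[[tt]])) {
      shared_draws[[tt]]
    } else {
      rnorm(attr(idx, "n_groups"), 0, sqrt(s2))
    }
    y <- y + draws[idx]
  }
  y
}

apply_missingness <- function(data, missing_rate, item_missing_rate) {
  if (missing_rate > 0) {
    surveys <- distinct(data, .data$person_id, .data$day, .data$moment)
    surveys$.keep <- runif(nrow(surveys)) >= missing_rate
    data <- filter(left_join(data, surveys,
                             by = c("person_id", "day", "moment")),
                   .data$.keep)
    data$.keep <- NULL
  }
  if (item_missing_rate > 0) {
    data <- filter(data, runif(nrow(data)) >= item_missing_rate)
  }
  data
}

#' Generate a synthetic dyadic experience-sampling dataset
#'
#' @param spec An [sim_spec()].
#' @return A validated dataset (tibble with design attributes) in the long
#'   format used throughout the package, with the generating specification
#'   attached as attribute `sim_spec`.
#' @examples
#' d <- simulate_esm(sim_spec(n_couples = 4, n_days = 3, n_moments = 2,
#'                            n_items = 2, seed = 42))
#' @export
simulate_esm <- function(spec) {
  stopifnot(inherits(spec, "esm_sim_spec"))
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  terms <- enumerate_terms(esm_facets())
  facets <- attr(terms, "design")
  grid <- sim_grid(spec)
  grid$value <- spec$mu +
    compose_effects(grid, terms, facets, spec$sigma2) +
    rnorm(nrow(grid), 0, sqrt(spec$sigma2_e))
  grid <- apply_missingness(grid, spec$missing_rate, spec$item_missing_rate)
  out <- esm_dataset(grid,
                     scales = scale_def(spec$scale_id,
                                        paste0("i", seq_len(spec$n_items))),
                     n_days = spec$n_days, n_moments = spec$n_moments,
                     dyadic = TRUE)
  attr(out, "sim_spec") <- spec
  out
}

#' Generate two scales with latent correlations at chosen levels
#'
#' Draws the couple (C), person (P), person-day (PD) and person-day-moment
#' (PDM) effects of two scales from bivariate normal distributions with the
#' requested correlations, holding each scale's marginal variances; all
#' other (nuisance and shared-time) effects, and the residuals, are drawn
#' independently per scale. The two scales share the survey grid and
#' missingness pattern, as when both are asked in the same survey.
#'
#' @param spec Specification of the first scale (items `a1..`).
#' @param rho Named correlations, e.g. `c(C = .2, P = .4, PD = .4, PDM = 0)`;
#'   omitted levels default to 0.
#' @param spec2 Specification of the second scale (defaults to `spec` with
#'   scale id `scale_2`); must share the design dimensions, seed and
#'   missingness of `spec`.
#' @return A dataset containing both scales' item responses (items `a*` and
#'   `b*`), with both scale definitions attached.
#' @export
simulate_esm_bivariate <- function(spec, rho = c(C = 0, P = 0, PD = 0,
                                                 PDM = 0),
                                   spec2 = NULL) {
  stopifnot(inherits(spec, "esm_sim_spec"))
  if (is.null(spec2)) {
    spec2 <- spec
    spec2$scale_id <- "scale_2"
  }
  same <- c("n_couples", "n_days", "n_moments", "n_items", "missing_rate",
            "item_missing_rate", "seed")
  if (!identical(spec[same], spec2[same])) {
    abort("the two scale specs must share dimensions, missingness and seed")
  }
  rho_full <- c(C = 0, P = 0, PD = 0, PDM = 0)
  rho_full[names(rho)] <- rho
  if (any(abs(rho_full) > 1)) abort("correlations must lie in [-1, 1]")
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  terms <- enumerate_terms(esm_facets())
  facets <- attr(terms, "design")
  grid_a <- sim_grid(spec, item_prefix = "a")
  grid_b <- sim_grid(spec2, item_prefix = "b")
  shared_a <- shared_b <- list()
  for (tt in names(rho_full)) {
    s2a <- spec$sigma2[[tt]]; s2b <- spec2$sigma2[[tt]]
    idx <- group_index_for(grid_a, terms$closure[[match(tt, terms$term)]],
                           facets)
    ng <- attr(idx, "n_groups")
    r <- rho_full[[tt]]
    z1 <- rnorm(ng); z2 <- rnorm(ng)
    shared_a[[tt]] <- sqrt(s2a) * z1
    shared_b[[tt]] <- sqrt(s2b) * (r * z1 + sqrt(1 - r^2) * z2)
  }
  grid_a$value <- spec$mu +
    compose_effects(grid_a, terms, facets, spec$sigma2, shared_a) +
    rnorm(nrow(grid_a), 0, sqrt(spec$sigma2_e))
  grid_b$value <- spec2$mu +
    compose_effects(grid_b, terms, facets, spec2$sigma2, shared_b) +
    rnorm(nrow(grid_b), 0, sqrt(spec2$sigma2_e))
  both <- bind_rows(grid_a, grid_b)
  surveys <- distinct(both, .data$person_id, .data$day, .data$moment)
  surveys$.keep <- runif(nrow(surveys)) >= spec$missing_rate
  both <- filter(left_join(both, surveys,
                           by = c("person_id", "day", "moment")), .data$.keep)
  both$.keep <- NULL
  if (spec$item_missing_rate > 0) {
    both <- filter(both, runif(nrow(both)) >= spec$item_missing_rate)
  }
  out <- esm_dataset(
    both,
    scales = list(scale_def(spec$scale_id, paste0("a", seq_len(spec$n_items))),
                  scale_def(spec2$scale_id, paste0("b", seq_len(spec2$n_items)))),
    n_days = spec$n_days, n_moments = spec$n_moments, dyadic = TRUE)
  attr(out, "sim_spec") <- list(spec, spec2, rho = rho_full)
  out
}

#' Write a dataset to the standard long CSV, and a spec to YAML
#'
#' @param data A dataset.
#' @param path Output CSV path.
#' @param spec_path Optional path to serialize the generating spec (YAML),
#'   when the dataset carries one.
#' @return `path`, invisibly.
#' @export
write_esm_csv <- function(data, path, spec_path = NULL) {
  out <- rename(data, !!!setNames(unname(.esm_cols), names(.esm_cols)))
  readr::write_csv(out[names(.esm_cols)], path)
  spec <- attr(data, "sim_spec")
  if (!is.null(spec_path) && !is.null(spec)) {
    ser <- function(s) {
      s <- unclass(s)
      s$sigma2 <- as.list(s$sigma2)
      s
    }
    obj <- if (inherits(spec, "esm_sim_spec")) ser(spec) else {
      list(scale_1 = ser(spec[[1]]), scale_2 = ser(spec[[2]]),
           rho = as.list(spec$rho))
    }
    yaml::write_yaml(obj, spec_path)
  }
  invisible(path)
}
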