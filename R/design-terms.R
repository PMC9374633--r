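#' Declare the measurement facets of an experience-sampling design
#'
#' A facet is one factor of the measurement design: couple, person, day,
#' moment, or item. Each facet is declared `random` (its levels are a sample
#' from a larger universe, e.g. days) or `fixed` (the levels exhaust the
#' universe of interest, e.g. the item set), and may be nested in another
#' facet (persons are nested in couples in the dyadic design). Facet roles
#' drive which variance components count as "true score" variance in the
#' reliability formulas; nesting drives which interaction terms are estimable.
#'
#' @param dyadic Include the couple facet with persons nested in it?
#' @param moments Include the within-day moment facet? Set to `FALSE` for
#'   daily-diary designs with a single survey per day.
#' @param items Include the item facet? Almost always `TRUE`.
#' @return A tibble with one row per facet: `facet` (single-letter label),
#'   `column` (the data column holding its levels), `role`
#'   (`"random"`/`"fixed"`), and `nested_in` (parent facet or `NA`).
#' @examples
#' esm_facets()                    # the full dyadic design: C, P, D, M, I
#' esm_facets(dyadic = FALSE, moments = FALSE)  # single daily measurement
#' @export
esm_facets <- function(dyadic = TRUE, moments = TRUE, items = TRUE) {
  fac <- tibble(
    facet     = c("C", "P", "D", "M", "I"),
    column    = c("couple_id", "person_id", "day", "moment", "item"),
    role      = c("random", "random", "random", "fixed", "fixed"),
    nested_in = c(NA, if (dyadic) "C" else NA, NA, NA, NA)
  )
  keep <- c(if (dyadic) "C", "P", "D", if (moments) "M", if (items) "I")
  fac <- fac[fac$facet %in% keep, ]
  class(fac) <- c("esm_facets", class(fac))
  fac
}

# facet subset closure under nesting: a term containing a nested facet is
# implicitly grouped by its ancestors as well (P-groups are unique across
# couples, so any P-term is refined by C)
facet_closure <- function(subset, facets) {
  parents <- setNames(facets$nested_in, facets$facet)
  out <- subset
  repeat {
    add <- stats::na.omit(unique(parents[out]))
    add <- setdiff(add, out)
    if (!length(add)) break
    out <- c(out, add)
  }
  sort_facets(out)
}

sort_facets <- function(x) {
  known <- intersect(.facet_order, x)
  c(known, sort(setdiff(x, .facet_order)))
}

term_label <- function(subset) paste(sort_facets(subset), collapse = "")

#' Enumerate the estimable variance terms of a crossed/nested design
#'
#' Builds the set of random-effect terms of the additive variance
#' decomposition model: one term per non-empty facet subset, excluding
#' (i) subsets that contain both a nested facet and one of its ancestors
#' (persons are nested in couples, so no couple-by-person interaction can
#' exist), and (ii) the maximal subset, whose interaction has no replicate
#' observations in a one-observation-per-cell design and is therefore
#' confounded with the residual. For the five-facet dyadic design this yields
#' exactly 22 terms plus the residual; for a non-dyadic daily design with
#' facets P, D, I it yields P, D, I, PD, PI, DI plus the residual.
#'
#' @param facets A facet declaration from [esm_facets()].
#' @param drop_confounded Drop the maximal (replication-free) subset?
#'   Ignored for single-facet designs, where replicate observations within
#'   the facet's cells make the single term estimable.
#' @return A tibble of class `esm_terms` with columns `term` (canonical
#'   label, e.g. `"PDM"`), `facets` (list of facet letters), and `closure`
#'   (list; facet letters including nesting ancestors, which define the
#'   grouping of observations). The residual is implicit.
#' @examples
#' nrow(enumerate_terms(esm_facets()))  # 22
#' enumerate_terms(esm_facets(dyadic = FALSE, moments = FALSE))$term
#' @export
enumerate_terms <- function(facets, drop_confounded = TRUE) {
  if (!nrow(facets)) abort("empty design: declare at least one facet")
  f <- facets$facet
  subsets <- purrr::map(seq_len(2^length(f) - 1), function(m) {
    f[bitwAnd(m, 2^(seq_along(f) - 1)) > 0]
  })
  # (i) drop subsets containing a facet together with one of its ancestors
  ok <- purrr::map_lgl(subsets, function(s) {
    anc <- setdiff(facet_closure(s, facets), s)
    all(!purrr::map_lgl(s, function(x) {
      any(setdiff(facet_closure(x, facets), x) %in% s)
    }))
  })
  subsets <- subsets[ok]
  # (ii) drop the maximal subset: its closure covers every facet, so its
  # groups have a single observation each and it is confounded with error
  if (drop_confounded && length(f) > 1L) {
    maximal <- purrr::map_lgl(subsets, function(s) {
      setequal(facet_closure(s, facets), f)
    })
    subsets <- subsets[!maximal]
  }
  labels <- purrr::map_chr(subsets, term_label)
  ord <- order(lengths(subsets), match(purrr::map_chr(subsets, 1), .facet_order),
               labels)
  closures <- purrr::map(subsets[ord], facet_closure, facets = facets)
  out <- tibble(term = labels[ord], facets = subsets[ord],
                closure = closures)
  attr(out, "design") <- facets
  class(out) <- c("esm_terms", class(out))
  out
}

#' Group observations by the levels of one variance term
#'
#' Maps every observation to the integer index of its level combination for
#' a term, using the term's closure (a person-day term groups by couple,
#' person and day). Group indices are assigned in a canonical sorted order,
#' so they do not depend on row order.
#'
#' @param data A long-format dataset with the facet columns declared in the
#'   design (`couple_id`, `person_id`, `day`, `moment`, `item`).
#' @param term A term label (e.g. `"PDM"`) or one row of an
#'   [enumerate_terms()] table.
#' @param facets The facet declaration; defaults to the design stored in
#'   `terms`, or the full dyadic design.
#' @return An integer vector of group indices with attribute `n_groups`.
#' @examples
#' toy <- simulate_esm(sim_spec(n_couples = 2, n_days = 2, n_moments = 2,
#'                              n_items = 2, seed = 1))
#' g <- build_group_labels(toy, "PD")
#' attr(g, "n_groups")  # 4 persons x 2 days = 8
#' @export
build_group_labels <- function(data, term, facets = esm_facets()) {
  if (is.character(term)) {
    letters_ <- strsplit(term, "")[[1]]
  } else {
    letters_ <- term$facets[[1]]
  }
  missing_f <- setdiff(letters_, facets$facet)
  if (length(missing_f)) {
    abort(paste0("term references undeclared facet(s): ",
                 paste(missing_f, collapse = ", ")))
  }
  cls <- facet_closure(letters_, facets)
  cols <- facets$column[match(cls, facets$facet)]
  missing_c <- setdiff(cols, names(data))
  if (length(missing_c)) {
    abort(paste0("data lacks column(s): ", paste(missing_c, collapse = ", ")))
  }
  key <- do.call(paste, c(unname(as.list(data[cols])), sep = "\r"))
  lev <- sort(unique(key))
  idx <- match(key, lev)
  attr(idx, "n_groups") <- length(lev)
  idx
}

#' @export
format.esm_terms <- function(x, ...) {
  c(sprintf("<esm_terms: %d terms + residual>", nrow(x)),
    paste(x$term, collapse = " "))
}

#' @export
print.esm_terms <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Serialize a term set to JSON
#'
#' @param terms An [enumerate_terms()] table.
#' @param data Optional dataset; when given, per-term group counts are
#'   included.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return JSON (invisibly, when written to `path`).
#' @export
terms_to_json <- function(terms, data = NULL, path = NULL) {
  facets <- attr(terms, "design")
  obj <- list(terms = purrr::map2(terms$term, terms$facets, function(lab, fs) {
    entry <- list(label = lab, facets = fs)
    if (!is.null(data)) {
      entry$n_groups <- attr(build_group_labels(data, lab, facets), "n_groups")
    }
    entry
  }), residual = "e")
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
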