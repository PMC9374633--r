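#' Decompose scale scores into four hierarchical levels
#'
#' Sequentially centers per-survey scale scores so that correlations can be
#' computed at each conceptual level without confounding from the levels
#' above: (a) couple scores are the means over all observed surveys of both
#' partners; (b) person scores are the person means of the couple-centered
#' residuals; (c) person-day scores are the day means of the couple- and
#' person-centered residuals; (d) moment scores are the remaining residuals.
#' The four components add back to the raw score exactly for every observed
#' survey. With complete data the residuals at each level average to zero
#' within their parent unit; with missing surveys the means are taken over
#' observed values only, so those sums are only approximately zero.
#'
#' @param scores Per-survey scale scores from [compute_scale_scores()]
#'   (columns `couple_id`, `person_id`, `day`, `moment`, `scale`, `score`).
#' @return An `esm_levels` list of four tibbles: `couple` (`couple_id`,
#'   scale columns), `person`, `person_day`, `person_day_moment`, each wide
#'   by scale, plus `survey` holding the per-survey component breakdown.
#' @export
center_to_levels <- function(scores) {
  need <- c("couple_id", "person_id", "day", "moment", "scale", "score")
  missing_cols <- setdiff(need, names(scores))
  if (length(missing_cols)) {
    abort(paste0("scores lack column(s): ", paste(missing_cols, collapse = ", ")))
  }
  dec <- scores %>%
    group_by(.data$scale, .data$couple_id) %>%
    mutate(couple_comp = mean(.data$score)) %>%
    group_by(.data$scale, .data$couple_id, .data$person_id) %>%
    mutate(person_comp = mean(.data$score - .data$couple_comp)) %>%
    group_by(.data$scale, .data$couple_id, .data$person_id, .data$day) %>%
    mutate(day_comp = mean(.data$score - .data$couple_comp -
                             .data$person_comp)) %>%
    ungroup() %>%
    mutate(moment_comp = .data$score - .data$couple_comp -
             .data$person_comp - .data$day_comp)
  wide <- function(df, keys, value) {
    tidyr::pivot_wider(distinct(df, across(all_of(c(keys, "scale", value)))),
                       names_from = "scale", values_from = all_of(value))
  }
  out <- list(
    couple = wide(dec, "couple_id", "couple_comp"),
    person = wide(dec, c("couple_id", "person_id"), "person_comp"),
    person_day = wide(dec, c("couple_id", "person_id", "day"), "day_comp"),
    person_day_moment = wide(dec, c("couple_id", "person_id", "day",
                                    "moment"), "moment_comp"),
    survey = dec
  )
  class(out) <- "esm_levels"
  out
}

#' @export
print.esm_levels <- function(x, ...) {
  cat(sprintf(paste0("<esm_levels: %d couples, %d persons, %d person-days, ",
                     "%d surveys; scales: %s>\n"),
              nrow(x$couple), nrow(x$person), nrow(x$person_day),
              nrow(x$person_day_moment),
              paste(unique(x$survey$scale), collapse = ", ")))
  invisible(x)
}

#' Scale intercorrelations at each aggregation level
#'
#' Pearson correlations between scales, computed separately at the couple,
#' person, person-day, and moment level, pooling all units of a level as
#' rows and using pairwise-complete observations (scales may cover
#' different surveys). Correlations are not corrected for unreliability.
#'
#' @param levels An [center_to_levels()] result.
#' @param min_units Minimum units required at a level (default 2); levels
#'   with fewer are flagged `NA`.
#' @return A tibble `level`, `scale_a`, `scale_b`, `r`, `n` (pairwise
#'   units). Zero-variance scales yield `NA` with a warning.
#' @export
correlate_at_levels <- function(levels, min_units = 2L) {
  stopifnot(inherits(levels, "esm_levels"))
  lvl_names <- c("couple", "person", "person_day", "person_day_moment")
  out <- purrr::map(lvl_names, function(lv) {
    tab <- levels[[lv]]
    keys <- intersect(c("couple_id", "person_id", "day", "moment"),
                      names(tab))
    scales_ <- setdiff(names(tab), keys)
    if (length(scales_) < 2L) {
      abort("need scores for at least 2 scales to correlate")
    }
    pairs <- utils::combn(scales_, 2L)
    purrr::map(seq_len(ncol(pairs)), function(ip) {
      a <- tab[[pairs[1, ip]]]; b <- tab[[pairs[2, ip]]]
      ok <- stats::complete.cases(a, b)
      n_ok <- sum(ok)
      r <- if (n_ok < min_units || sd(a[ok]) == 0 || sd(b[ok]) == 0) {
        if (n_ok >= min_units) {
          warn(paste0("zero variance for a scale at level ", lv,
                      "; correlation undefined"))
        }
        NA_real_
      } else {
        cor(a[ok], b[ok])
      }
      tibble(level = lv, scale_a = pairs[1, ip], scale_b = pairs[2, ip],
             r = r, n = n_ok)
    }) %>% bind_rows()
  })
  out <- bind_rows(out)
  class(out) <- c("esm_level_cors", class(out))
  out
}

#' Correlation matrix of one level
#'
#' @param cors A [correlate_at_levels()] result.
#' @param level One of `"couple"`, `"person"`, `"person_day"`,
#'   `"person_day_moment"`.
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
level_cor_matrix <- function(cors, level) {
  sub <- filter(cors, .data$level == !!level)
  scales_ <- sort(unique(c(sub$scale_a, sub$scale_b)))
  m <- diag(length(scales_))
  dimnames(m) <- list(scales_, scales_)
  for (i in seq_len(nrow(sub))) {
    m[sub$scale_a[i], sub$scale_b[i]] <- sub$r[i]
    m[sub$scale_b[i], sub$scale_a[i]] <- sub$r[i]
  }
  m
}
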