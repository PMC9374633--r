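#' Define a scale: its items, and any reverse-coded items
#'
#' @param scale_id Scale label.
#' @param items Character vector of item ids, in order.
#' @param reverse Character vector (subset of `items`) of reverse-coded
#'   items.
#' @param bounds Named list giving `c(min, max)` response bounds for each
#'   reverse-coded item (required when `reverse` is non-empty).
#' @return A `scale_def` object.
#' @examples
#' scale_def("relsat", c("RS-3", "RS-4"),
#'           reverse = "RS-4", bounds = list(`RS-4` = c(1, 7)))
#' @export
scale_def <- function(scale_id, items, reverse = character(), bounds = NULL) {
  stopifnot(is.character(scale_id), length(scale_id) == 1L)
  if (!length(items)) abort("a scale needs at least one item")
  if (anyDuplicated(items)) abort("duplicate item ids in scale definition")
  if (!all(reverse %in% items)) {
    abort("reverse-coded items must be a subset of the scale's items")
  }
  for (it in reverse) {
    b <- bounds[[it]]
    if (is.null(b) || length(b) != 2L || !is.numeric(b) || b[1] >= b[2]) {
      abort(paste0("reverse-coded item '", it,
                   "' needs bounds = c(min, max) with min < max"))
    }
  }
  structure(list(scale_id = scale_id, items = as.character(items),
                 reverse = as.character(reverse), bounds = bounds),
            class = "scale_def")
}

#' @export
print.scale_def <- function(x, ...) {
  cat(sprintf("<scale '%s': %d items%s>\n", x$scale_id, length(x$items),
              if (length(x$reverse))
                paste0(", reversed: ", paste(x$reverse, collapse = ", "))
              else ""))
  invisible(x)
}

.esm_cols <- c(couple_uid = "couple_id", person_uid = "person_id",
               studyday_id = "day", moment_id = "moment",
               item = "item", value = "value")

#' Read a long-format experience-sampling table from CSV
#'
#' The expected layout is one row per response: columns `couple_uid`,
#' `person_uid`, `studyday_id`, `moment_id`, `item`, `value` (UTF-8,
#' comma-separated, header row). Rows with a missing `value` are dropped and
#' counted in the load report. Internally the index columns are renamed to
#' `couple_id`, `person_id`, `day`, `moment`.
#'
#' @param path Path to the CSV file.
#' @param config Optional parsed configuration (see [read_esm_config()]);
#'   when given, its scales and declared dimensions are attached and the
#'   dataset is validated.
#' @return A tibble of observations with attributes `scales`, `n_days`,
#'   `n_moments`, `dyadic`, `standardized` and `load_report` (rows read,
#'   rows dropped).
#' @export
read_esm_csv <- function(path, config = NULL) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  missing_cols <- setdiff(names(.esm_cols), names(raw))
  if (length(missing_cols)) {
    abort(paste0("format error: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  raw <- rename(raw, !!!setNames(names(.esm_cols), unname(.esm_cols)))
  val <- suppressWarnings(as.numeric(raw$value))
  bad <- which(!is.na(raw$value) & raw$value != "" & is.na(val))
  if (length(bad)) {
    abort(paste0("unparseable value(s) at data line(s): ",
                 paste(head(bad, 5L) + 1L, collapse = ", ")))
  }
  for (cn in c("day", "moment")) {
    iv <- suppressWarnings(as.numeric(raw[[cn]]))
    if (anyNA(iv) || any(iv != round(iv)) || any(iv < 1)) {
      abort(paste0("column '", cn, "' must hold positive integer indices"))
    }
    raw[[cn]] <- as.integer(iv)
  }
  raw$value <- val
  n_read <- nrow(raw)
  out <- filter(raw, !is.na(.data$value))
  n_dropped <- n_read - nrow(out)
  if (n_read == 0L) warn(paste0("empty input: ", path))
  out <- select(out, all_of(unname(.esm_cols)))
  esm_dataset(
    out,
    scales    = if (!is.null(config)) config$scales else list(),
    n_days    = if (!is.null(config)) config$n_days else max(out$day, 0L),
    n_moments = if (!is.null(config)) config$n_moments else max(out$moment, 0L),
    dyadic    = if (!is.null(config)) isTRUE(config$dyadic) else TRUE,
    load_report = list(rows_read = n_read, rows_dropped_missing = n_dropped)
  )
}

#' Assemble and validate an experience-sampling dataset
#'
#' Checks the structural invariants of the long-format data: unique
#' (person, day, moment, item) keys, each person belonging to exactly one
#' couple, indices within the declared bounds, and (in dyadic mode) exactly
#' two persons per couple.
#'
#' @param data A data frame with columns `couple_id`, `person_id`, `day`,
#'   `moment`, `item`, `value`.
#' @param scales A list of [scale_def()] objects.
#' @param n_days,n_moments Declared numbers of study days and of scheduled
#'   surveys per day.
#' @param dyadic Enforce two persons per couple?
#' @param standardized Have item responses already been z-standardized?
#' @param load_report Optional load report to attach.
#' @return The data as a validated tibble carrying the design attributes.
#' @export
esm_dataset <- function(data, scales = list(), n_days = max(data$day, 0L),
                        n_moments = max(data$moment, 0L), dyadic = TRUE,
                        standardized = FALSE, load_report = NULL) {
  data <- as_tibble(data)
  need <- unname(.esm_cols)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("format error: missing required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (inherits(scales, "scale_def")) scales <- list(scales)
  key <- paste(data$person_id, data$day, data$moment, data$item, sep = "\r")
  if (anyDuplicated(key)) {
    d <- key[duplicated(key)][1L]
    abort(paste0("duplicate observation key (person, day, moment, item): ",
                 gsub("\r", " / ", d, fixed = TRUE)))
  }
  pc <- distinct(data, .data$person_id, .data$couple_id)
  if (anyDuplicated(pc$person_id)) {
    abort(paste0("person(s) mapped to more than one couple: ",
                 paste(unique(pc$person_id[duplicated(pc$person_id)]),
                       collapse = ", ")))
  }
  if (nrow(data) && (any(data$day > n_days) || any(data$moment > n_moments))) {
    abort("day or moment index exceeds the declared design bounds")
  }
  if (dyadic && nrow(data)) {
    sizes <- count(pc, .data$couple_id)
    bad <- sizes$couple_id[sizes$n != 2L]
    if (length(bad)) {
      abort(paste0("dyadic design violated: couple(s) without exactly 2 ",
                   "persons: ", paste(bad, collapse = ", ")))
    }
  }
  attr(data, "scales") <- scales
  attr(data, "n_days") <- as.integer(n_days)
  attr(data, "n_moments") <- as.integer(n_moments)
  attr(data, "dyadic") <- isTRUE(dyadic)
  attr(data, "standardized") <- isTRUE(standardized)
  if (!is.null(load_report)) attr(data, "load_report") <- load_report
  data
}

#' Summarise the structure and completeness of a dataset
#'
#' @param data A dataset from [esm_dataset()] or [read_esm_csv()].
#' @param dyadic Require two persons per couple? Defaults to the dataset's
#'   declared mode. A violation raises a structural error naming the couple.
#' @return A list of class `esm_validation`: counts, persons per couple,
#'   per-person survey response rates (share of the `n_days * n_moments`
#'   scheduled surveys with at least one observed response), and the overall
#'   response rate.
#' @export
validate_esm <- function(data, dyadic = attr(data, "dyadic") %||% TRUE) {
  n_days <- attr(data, "n_days") %||% max(data$day, 0L)
  n_moments <- attr(data, "n_moments") %||% max(data$moment, 0L)
  pc <- count(distinct(data, .data$person_id, .data$couple_id),
              .data$couple_id, name = "n_persons")
  if (dyadic && any(pc$n_persons != 2L)) {
    bad <- pc$couple_id[pc$n_persons != 2L]
    abort(paste0("dyadic design violated: couple(s) without exactly 2 ",
                 "persons: ", paste(bad, collapse = ", ")))
  }
  surveys <- distinct(data, .data$person_id, .data$day, .data$moment)
  per_person <- count(surveys, .data$person_id, name = "n_answered")
  per_person$response_rate <- per_person$n_answered / (n_days * n_moments)
  oob <- sum(data$day > n_days | data$moment > n_moments)
  structure(list(
    n_observations = nrow(data),
    n_couples = nrow(pc),
    n_persons = sum(pc$n_persons),
    persons_per_couple = pc,
    out_of_bounds = oob,
    person_response = as_tibble(per_person),
    response_rate = if (nrow(per_person))
      sum(per_person$n_answered) / (nrow(per_person) * n_days * n_moments)
    else NA_real_,
    violations = 0L
  ), class = "esm_validation")
}

#' @export
print.esm_validation <- function(x, ...) {
  cat(sprintf(paste0("<esm validation: %d observations, %d couples, ",
                     "%d persons, response rate %.3f, %d index violations>\n"),
              x$n_observations, x$n_couples, x$n_persons,
              x$response_rate, x$out_of_bounds + x$violations))
  invisible(x)
}

#' Recode reverse-keyed items
#'
#' Replaces each reverse-coded response by `min + max - value`, using the
#' bounds declared in the scale definition. Applying the function twice
#' restores the original values.
#'
#' @param data An experience-sampling dataset.
#' @param scale A [scale_def()] with `reverse` items and their `bounds`.
#' @return The dataset with reversed values.
#' @export
reverse_code <- function(data, scale) {
  stopifnot(inherits(scale, "scale_def"))
  for (it in scale$reverse) {
    b <- scale$bounds[[it]]
    sel <- data$item == it
    v <- data$value[sel]
    if (any(v < b[1] | v > b[2], na.rm = TRUE)) {
      abort(paste0("range error: item '", it, "' has values outside [",
                   b[1], ", ", b[2], "]"))
    }
    data$value[sel] <- b[1] + b[2] - v
  }
  data
}

#' z-standardize every item across all observations
#'
#' Each item is centered at its grand mean and scaled by its grand standard
#' deviation (denominator `n - 1`), computed over all observations of that
#' item: both partners, all days and moments. Standardizing before averaging
#' puts items with different response formats on a common metric.
#'
#' @param data An experience-sampling dataset.
#' @return The dataset with standardized values and the `standardized`
#'   attribute set.
#' @export
zstandardize_items <- function(data) {
  stats_ <- summarise(group_by(data, .data$item),
                      m = mean(.data$value), s = sd(.data$value),
                      k = n_distinct(.data$value), .groups = "drop")
  const <- stats_$item[stats_$k < 2L | stats_$s == 0]
  if (length(const)) {
    abort(paste0("zero-variance item(s), cannot standardize: ",
                 paste(const, collapse = ", ")))
  }
  i <- match(data$item, stats_$item)
  data$value <- (data$value - stats_$m[i]) / stats_$s[i]
  attr(data, "standardized") <- TRUE
  data
}

#' Average item responses into per-survey scale scores
#'
#' For every answered survey (person by day by moment) the scale score is
#' the mean of the scale's observed item values; partially answered surveys
#' use the available items, and the number of contributing items is kept.
#'
#' @param data A (typically standardized) experience-sampling dataset.
#' @param scale A [scale_def()], a list of them, or `NULL` to use the
#'   dataset's attached scales.
#' @return A tibble with one row per survey and scale: `couple_id`,
#'   `person_id`, `day`, `moment`, `scale`, `score`, `n_items`.
#' @export
compute_scale_scores <- function(data, scale = NULL) {
  scales <- scale %||% attr(data, "scales")
  if (inherits(scales, "scale_def")) scales <- list(scales)
  if (!length(scales)) abort("no scale definitions given or attached")
  out <- purrr::map(scales, function(sc) {
    sub <- filter(data, .data$item %in% sc$items)
    if (!nrow(sub)) {
      abort(paste0("scale '", sc$scale_id, "': none of its items observed"))
    }
    summarise(group_by(sub, .data$couple_id, .data$person_id,
                       .data$day, .data$moment),
              score = mean(.data$value), n_items = n(), .groups = "drop") %>%
      mutate(scale = sc$scale_id)
  })
  arrange(select(bind_rows(out), all_of(c("couple_id", "person_id", "day",
                                          "moment", "scale", "score",
                                          "n_items"))),
          .data$scale, .data$couple_id, .data$person_id, .data$day,
          .data$moment)
}
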