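#' @title Variance-component estimation for crossed/nested ESM designs
#' @description
#' The measurement model is an additive random-intercept decomposition of
#' item responses: for person p in couple c answering item i at moment m of
#' day d,
#' \deqn{y = \mu + \sum_f u_{f,\,group_f(c,p,d,m,i)} + e,\qquad
#'       u_f \sim N(0, \sigma^2_f),\ e \sim N(0, \sigma^2_e),}
#' with one independent normal effect per level combination of each term f
#' (the 22 terms of the dyadic design, or the 6 terms of a non-dyadic daily
#' design). All effects are mutually independent; the partners of a couple
#' are indistinguishable and share only the couple-level intercepts.
#' @name variance_model
NULL

# ---- internal: design geometry ------------------------------------------

# per-facet level counts; nested facets report levels per parent (must be
# constant across parents for a balanced design)
facet_sizes <- function(data, facets) {
  out <- numeric(nrow(facets))
  names(out) <- facets$facet
  for (i in seq_len(nrow(facets))) {
    col <- facets$column[i]
    parent <- facets$nested_in[i]
    if (is.na(parent)) {
      out[i] <- n_distinct(data[[col]])
    } else {
      pcol <- facets$column[facets$facet == parent]
      tab <- distinct(data, .data[[pcol]], .data[[col]])
      sizes <- table(tab[[pcol]])
      out[i] <- if (length(unique(sizes)) == 1L) unname(sizes[1]) else NA_real_
    }
  }
  out
}

group_index_for <- function(data, letters_, facets) {
  if (!length(letters_)) {
    idx <- rep(1L, nrow(data)); attr(idx, "n_groups") <- 1L
    return(idx)
  }
  cols <- facets$column[match(sort_facets(letters_), facets$facet)]
  key <- do.call(paste, c(unname(as.list(data[cols])), sep = "\r"))
  lev <- sort(unique(key))
  idx <- match(key, lev)
  attr(idx, "n_groups") <- length(lev)
  idx
}

# complete balanced design: full crossing (respecting nesting) is present
# and every cell holds the same number of observations (>= 1 replicate)
is_balanced_design <- function(data, facets) {
  if (!nrow(data)) return(FALSE)
  sz <- facet_sizes(data, facets)
  if (anyNA(sz)) return(FALSE)
  full <- group_index_for(data, facets$facet, facets)
  cnt <- tabulate(full, attr(full, "n_groups"))
  if (length(unique(cnt)) != 1L) return(FALSE)
  nested <- facets$facet[!is.na(facets$nested_in)]
  n_cells <- prod(sz[is.na(facets$nested_in)]) * prod(sz[nested])
  isTRUE(all.equal(n_cells, attr(full, "n_groups")))
}

# Moebius complement rule: dropping a nested facet from a subset leaves its
# ancestors as the margin over which the effect is defined
mobius_group <- function(sub, full, facets) {
  dropped <- setdiff(full, sub)
  anc <- unlist(purrr::map(dropped, function(f) {
    setdiff(facet_closure(f, facets), f)
  }))
  facet_closure(union(sub, anc), facets)
}

# ANOVA geometry of a balanced design: per-term sums of squares, degrees of
# freedom, observations-per-group constants, and the stratum containment
# relation (which terms' variances enter which stratum's expected mean
# square / likelihood eigenvalue)
strata_decompose <- function(data, terms, facets, y = data$value) {
  N <- nrow(data)
  labels <- terms$term
  gidx <- purrr::map(terms$closure, group_index_for, data = data, facets = facets)
  names(gidx) <- labels
  ucache <- new.env(parent = emptyenv())
  uval <- function(letters_) {
    key <- paste0("u_", paste(letters_, collapse = ""))
    got <- ucache[[key]]
    if (!is.null(got)) return(got)
    if (!length(letters_)) {
      v <- sum(y)^2 / N
    } else {
      idx <- group_index_for(data, letters_, facets)
      sums <- rowsum(y, idx)
      cnt <- tabulate(idx)
      v <- sum(sums^2 / cnt)
    }
    ucache[[key]] <- v
    v
  }
  gcount <- function(letters_) {
    if (!length(letters_)) return(1L)
    attr(group_index_for(data, letters_, facets), "n_groups")
  }
  ss <- df <- numeric(length(labels))
  for (t in seq_along(labels)) {
    s <- terms$facets[[t]]
    nf <- length(s)
    for (m in 0:(2^nf - 1)) {
      sub <- s[bitwAnd(m, 2^(seq_len(nf) - 1)) > 0]
      g <- mobius_group(sub, s, facets)
      sgn <- (-1)^(nf - length(sub))
      ss[t] <- ss[t] + sgn * uval(g)
      df[t] <- df[t] + sgn * gcount(g)
    }
  }
  ss_tot <- sum(y^2) - uval(character(0))
  ss_e <- ss_tot - sum(ss)
  df_e <- N - 1 - sum(df)
  cT <- N / purrr::map_dbl(gidx, attr, "n_groups")
  closures <- terms$closure
  contains <- purrr::map(closures, function(cS) {
    which(purrr::map_lgl(closures, function(cT_) all(cS %in% cT_)))
  })
  list(N = N, labels = labels, ss = ss, df = df, ss_e = max(ss_e, 0),
       df_e = df_e, cT = cT, contains = contains, ybar = mean(y))
}

# -2 log likelihood (ML) or REML criterion from the stratum decomposition;
# exact for balanced complete designs
strata_n2ll <- function(sig2, sig2_e, geo, reml = FALSE) {
  lam <- purrr::map_dbl(seq_along(geo$labels), function(S) {
    idx <- geo$contains[[S]]
    sig2_e + sum(geo$cT[idx] * sig2[idx])
  })
  lam0 <- sig2_e + sum(geo$cT * sig2)
  if (any(lam <= 0) || sig2_e <= 0) return(Inf)
  v <- sum(geo$df * log(lam)) + sum(geo$ss / lam) +
    geo$df_e * log(sig2_e) + geo$ss_e / sig2_e
  if (reml) {
    v + (geo$N - 1) * log(2 * pi) + log(geo$N)
  } else {
    v + geo$N * log(2 * pi) + log(lam0)
  }
}

strata_n2ll_grad <- function(lsig, geo, reml = FALSE) {
  s2 <- exp(lsig)
  k <- length(lsig)
  sig2 <- s2[-k]; sig2_e <- s2[k]
  lam <- purrr::map_dbl(seq_along(geo$labels), function(S) {
    idx <- geo$contains[[S]]
    sig2_e + sum(geo$cT[idx] * sig2[idx])
  })
  lam0 <- sig2_e + sum(geo$cT * sig2)
  inner <- geo$df / lam - geo$ss / lam^2
  g <- numeric(k)
  for (t in seq_len(k - 1)) {
    strata_t <- purrr::map_lgl(geo$contains, function(idx) t %in% idx)
    g[t] <- geo$cT[t] * sum(inner[strata_t])
    if (!reml) g[t] <- g[t] + geo$cT[t] / lam0
  }
  g[k] <- sum(inner) + geo$df_e / sig2_e - geo$ss_e / sig2_e^2
  if (!reml) g[k] <- g[k] + 1 / lam0
  g * s2
}

# method-of-moments starting values via the EMS equations, floored
strata_mom_start <- function(geo, floor_at = 1e-4) {
  ms <- c(geo$ss / pmax(geo$df, 1), geo$ss_e / max(geo$df_e, 1))
  k <- length(geo$labels)
  A <- matrix(0, k + 1, k + 1)
  for (S in seq_len(k)) {
    idx <- geo$contains[[S]]
    A[S, idx] <- geo$cT[idx]
  }
  A[, k + 1] <- 1
  A[k + 1, k + 1] <- 1
  est <- tryCatch(solve(A, ms), error = function(e) rep(NA_real_, k + 1))
  if (anyNA(est)) est <- rep(ms[k + 1], k + 1)
  pmax(est, floor_at)
}

# ---- fitting -------------------------------------------------------------

#' Estimate the variance components of the decomposition model
#'
#' Fits the Gaussian random-intercept model with one variance component per
#' term by maximum likelihood (default, as in the reliability model this
#' package implements) or REML. Two engines are available: for complete
#' balanced designs, an exact closed-form stratum likelihood (the design's
#' ANOVA orthogonal-block structure turns the log-likelihood into a sum over
#' strata of `df * log(lambda) + SS / lambda`), optimized over the log
#' variances with analytic gradients; for unbalanced data, [lme4::lmer()]
#' with one scalar random intercept per term. Nonnegativity is enforced by
#' optimizing on the log scale with a floor of 1e-10; estimates below 1e-6
#' are reported as boundary zeros.
#'
#' @param data A long-format dataset (one row per item response). To analyse
#'   one scale, filter to its items (or pass `scale`).
#' @param terms A term set from [enumerate_terms()]; defaults to the full
#'   dyadic five-facet design.
#' @param scale Optional [scale_def()]; rows are filtered to its items.
#' @param method `"ML"` (default) or `"REML"`.
#' @param engine `"auto"` (stratum likelihood when the design is complete
#'   and balanced, otherwise lmer), `"strata"`, or `"lmer"`.
#' @param tol Convergence tolerance on the relative change of the -2
#'   log-likelihood.
#' @param max_iter Iteration cap.
#' @param start Optional named starting values for the variances.
#' @return An object of class `esm_vc`: components tibble (`term`, `sigma2`,
#'   `n_groups`, `boundary`), `sigma2_e`, `mu`, `minus2loglik`, `method`,
#'   `engine`, `converged`, `iterations`.
#' @seealso [anova_balanced()] for the method-of-moments oracle,
#'   [neg_loglik()] for direct likelihood evaluation.
#' @export
fit_components <- function(data, terms = NULL, scale = NULL,
                           method = c("ML", "REML"),
                           engine = c("auto", "strata", "lmer"),
                           tol = 1e-8, max_iter = 500, start = NULL) {
  method <- match.arg(method)
  engine <- match.arg(engine)
  if (!is.null(scale)) data <- filter(data, .data$item %in% scale$items)
  if (!nrow(data)) abort("no observations to fit")
  terms <- terms %||% enumerate_terms(esm_facets())
  facets <- attr(terms, "design")
  single <- purrr::map_lgl(terms$closure, function(cl) {
    attr(group_index_for(data, cl, facets), "n_groups") < 2L
  })
  if (any(single)) {
    abort(paste0("term(s) with a single group, not estimable: ",
                 paste(terms$term[single], collapse = ", ")))
  }
  if (engine == "auto") {
    engine <- if (is_balanced_design(data, facets)) "strata" else "lmer"
  }
  fit <- switch(engine,
    strata = fit_strata(data, terms, facets, method, tol, max_iter, start),
    lmer   = fit_lmer(data, terms, facets, method, tol, max_iter, start))
  n_groups <- purrr::map_int(terms$closure, function(cl) {
    attr(group_index_for(data, cl, facets), "n_groups")
  })
  sig2 <- fit$sig2
  boundary <- sig2 < 1e-6
  sig2[boundary] <- 0
  out <- list(
    components = tibble(term = terms$term, sigma2 = unname(sig2),
                        n_groups = n_groups, boundary = unname(boundary)),
    sigma2_e = fit$sig2_e,
    mu = fit$mu,
    minus2loglik = fit$n2ll,
    method = method,
    engine = engine,
    converged = fit$converged,
    iterations = fit$iterations,
    n_obs = nrow(data),
    terms = terms
  )
  class(out) <- "esm_vc"
  check_dyadic_covariance(out, data, facets)
  out
}

fit_strata <- function(data, terms, facets, method, tol, max_iter, start) {
  if (!is_balanced_design(data, facets)) {
    abort("the stratum-likelihood engine needs a complete balanced design; use engine = \"lmer\"")
  }
  geo <- strata_decompose(data, terms, facets)
  reml <- method == "REML"
  k <- nrow(terms) + 1L
  if (is.null(start)) {
    s0 <- strata_mom_start(geo)
  } else {
    s0 <- pmax(c(start[terms$term], start[["e"]] %||% var(data$value) / 2),
               1e-4)
  }
  obj <- function(lsig) {
    s2 <- exp(lsig)
    strata_n2ll(s2[-k], s2[k], geo, reml = reml)
  }
  grad <- function(lsig) strata_n2ll_grad(lsig, geo, reml = reml)
  opt <- nlminb(log(s0), obj, gradient = grad,
                lower = log(1e-10), upper = log(1e6),
                control = list(iter.max = max_iter, eval.max = 4L * max_iter,
                               rel.tol = tol))
  s2 <- exp(opt$par)
  list(sig2 = setNames(s2[-k], terms$term), sig2_e = s2[k],
       mu = geo$ybar, n2ll = opt$objective,
       converged = opt$convergence == 0 ||
         grepl("relative convergence|both X|singular convergence",
               opt$message %||% ""),
       iterations = opt$iterations)
}

fit_lmer <- function(data, terms, facets, method, tol, max_iter, start) {
  d <- as.data.frame(data)
  for (i in seq_len(nrow(terms))) {
    idx <- group_index_for(d, terms$closure[[i]], facets)
    d[[paste0(".g_", terms$term[i])]] <- factor(idx)
  }
  fml <- stats::as.formula(paste(
    "value ~ 1 +",
    paste(sprintf("(1 | .g_%s)", terms$term), collapse = " + ")))
  ctrl <- lme4::lmerControl(
    check.nobs.vs.nRE = "ignore", check.nobs.vs.nlev = "ignore",
    check.nlev.gtr.1 = "stop", calc.derivs = FALSE,
    optCtrl = list(maxfun = 50L * max_iter))
  m <- withCallingHandlers(
    lme4::lmer(fml, data = d, REML = method == "REML", control = ctrl),
    message = function(m) invokeRestart("muffleMessage"),
    warning = function(w) {
      if (grepl("singular|converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  vc <- as.data.frame(lme4::VarCorr(m))
  grp <- sub("^\\.g_", "", vc$grp)
  sig2 <- setNames(vc$vcov[match(terms$term, grp)], terms$term)
  conv <- m@optinfo$conv$opt == 0
  list(sig2 = sig2, sig2_e = vc$vcov[vc$grp == "Residual"],
       mu = unname(lme4::fixef(m)[1]),
       n2ll = as.numeric(-2 * logLik(m)),
       converged = isTRUE(conv),
       iterations = m@optinfo$feval %||% NA_integer_)
}

# the model carries no partner covariance beyond the shared couple
# intercept; negative within-couple dependence would bias the decomposition,
# so flag it when the person means are negatively correlated within couples
check_dyadic_covariance <- function(vc, data, facets) {
  if (!"C" %in% facets$facet) return(invisible(NULL))
  pm <- summarise(group_by(data, .data$couple_id, .data$person_id),
                  m = mean(.data$value), .groups = "drop")
  pm <- filter(group_by(pm, .data$couple_id), n() == 2L)
  pm <- summarise(pm, a = .data$m[1], b = .data$m[2], .groups = "drop")
  if (nrow(pm) >= 8L) {
    r <- suppressWarnings(cor(pm$a, pm$b))
    if (is.finite(r) && r < -0.1) {
      warn(sprintf(paste0("within-couple correlation of person means is ",
                          "negative (r = %.2f); the shared-intercept model ",
                          "cannot represent negative dyadic covariance and ",
                          "variance estimates may be biased"), r))
    }
  }
  invisible(NULL)
}

# ---- likelihood kernel ---------------------------------------------------

#' Evaluate the -2 log-likelihood of the variance-component model
#'
#' Computes the exact Gaussian -2 log-likelihood of the random-intercept
#' model at given variance components, for arbitrary (balanced or not)
#' data. The marginal covariance `V = sigma2_e I + sum_f sigma2_f Z_f Z_f'`
#' is never formed densely: the Woodbury identity reduces the computation to
#' one sparse Cholesky factorization of a q x q system, q the total number
#' of random-effect levels.
#'
#' @param components An `esm_vc` fit, or a named numeric vector of variances
#'   with one entry per term label plus `"e"` for the residual.
#' @param data The dataset.
#' @param terms Term set (defaults to the one stored in an `esm_vc`, else
#'   the full dyadic design).
#' @param mu Fixed grand mean; defaults to the fit's mean or the sample mean.
#' @return The value of -2 log L (a length-1 numeric). `Inf`, with a
#'   warning, when `sigma2_e` is 0 but residual variation is present.
#' @export
neg_loglik <- function(components, data, terms = NULL, mu = NULL) {
  if (inherits(components, "esm_vc")) {
    terms <- terms %||% components$terms
    mu <- mu %||% components$mu
    sig2 <- setNames(components$components$sigma2, components$components$term)
    sig2_e <- components$sigma2_e
  } else {
    stopifnot(is.numeric(components), !is.null(names(components)))
    sig2_e <- components[["e"]]
    sig2 <- components[setdiff(names(components), "e")]
  }
  terms <- terms %||% enumerate_terms(esm_facets())
  facets <- attr(terms, "design")
  mu <- mu %||% mean(data$value)
  if (!all(is.finite(c(sig2, sig2_e))) || any(c(sig2, sig2_e) < 0)) {
    abort("variance components must be finite and nonnegative")
  }
  r <- data$value - mu
  n <- length(r)
  active <- names(sig2)[sig2 > 0]
  if (sig2_e == 0) {
    warn("sigma2_e = 0 with residual variation present: -2logL is infinite")
    return(Inf)
  }
  if (!length(active)) {
    return(n * log(2 * pi) + n * log(sig2_e) + sum(r^2) / sig2_e)
  }
  blocks <- purrr::map(active, function(tt) {
    cl <- terms$closure[[match(tt, terms$term)]]
    idx <- group_index_for(data, cl, facets)
    list(idx = idx, q = attr(idx, "n_groups"), s = sqrt(sig2[[tt]]))
  })
  offs <- cumsum(c(0, purrr::map_dbl(blocks, "q")))
  q <- offs[length(offs)]
  ii <- rep(seq_len(n), times = length(blocks))
  jj <- unlist(purrr::map2(blocks, offs[-length(offs)],
                           function(b, o) b$idx + o))
  xx <- unlist(purrr::map(blocks, function(b) rep(b$s, n)))
  S <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, q))
  A <- Matrix::Diagonal(q) + Matrix::crossprod(S) / sig2_e
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(A), LDL = FALSE, perm = TRUE)
  logdetA <- 2 * Matrix::determinant(ch, logarithm = TRUE, sqrt = TRUE)$modulus
  u <- Matrix::crossprod(S, r)
  quad <- (sum(r^2) - as.numeric(Matrix::crossprod(u, Matrix::solve(ch, u))) /
             sig2_e) / sig2_e
  as.numeric(n * log(2 * pi) + n * log(sig2_e) + logdetA + quad)
}

# ---- EMS oracle ----------------------------------------------------------

#' Closed-form ANOVA (expected-mean-squares) variance components
#'
#' Method-of-moments estimator for complete balanced designs: computes the
#' ANOVA sum of squares of every term, equates each observed mean square to
#' its expectation (a linear combination of the variance components), and
#' solves the resulting triangular system. On balanced data with an interior
#' optimum this coincides with REML; it serves as an independent oracle for
#' [fit_components()]. Negative solutions are reported both raw and
#' truncated at zero.
#'
#' @inheritParams fit_components
#' @return A tibble with columns `term` (incl. `"e"`), `df`, `mean_square`,
#'   `sigma2_raw`, `sigma2` (truncated at 0).
#' @export
anova_balanced <- function(data, terms = NULL, scale = NULL) {
  if (!is.null(scale)) data <- filter(data, .data$item %in% scale$items)
  terms <- terms %||% enumerate_terms(esm_facets())
  facets <- attr(terms, "design")
  if (!is_balanced_design(data, facets)) {
    abort("design is unbalanced or incomplete; use fit_components() instead")
  }
  geo <- strata_decompose(data, terms, facets)
  k <- length(geo$labels)
  ms <- c(geo$ss / geo$df, geo$ss_e / geo$df_e)
  A <- matrix(0, k + 1, k + 1)
  for (S in seq_len(k)) A[S, geo$contains[[S]]] <- geo$cT[geo$contains[[S]]]
  A[, k + 1] <- 1
  A[k + 1, k + 1] <- 1
  raw <- solve(A, ms)
  tibble(term = c(geo$labels, "e"),
         df = c(geo$df, geo$df_e),
         mean_square = ms,
         sigma2_raw = raw,
         sigma2 = pmax(raw, 0))
}

# ---- reporting -----------------------------------------------------------

#' Relative shares of the systematic variance
#'
#' Expresses every non-error component as a percentage of the summed
#' systematic (non-error) variance; the residual is excluded from numerator
#' and denominator.
#'
#' @param components An `esm_vc` fit or a tidy components tibble with
#'   columns `term` and `sigma2` (a row `term == "e"` is ignored).
#' @return A tibble `term`, `sigma2`, `share` (percent, summing to 100).
#' @export
relative_shares <- function(components) {
  comp <- if (inherits(components, "esm_vc")) {
    components$components
  } else {
    filter(as_tibble(components), .data$term != "e")
  }
  tot <- sum(comp$sigma2)
  if (tot <= 0) abort("all systematic components are zero; shares undefined")
  mutate(select(comp, all_of(c("term", "sigma2"))),
         share = 100 * .data$sigma2 / tot)
}

#' @export
print.esm_vc <- function(x, digits = 3, ...) {
  cat(sprintf("<esm_vc: %s (%s engine), %d terms + residual, n = %d>\n",
              x$method, x$engine, nrow(x$components), x$n_obs))
  cat(sprintf("  mu = %.4f  sigma2_e = %.4f  -2logL = %.2f  converged: %s\n",
              x$mu, x$sigma2_e, x$minus2loglik, x$converged))
  nz <- filter(x$components, .data$sigma2 > 0)
  cat("  nonzero components:\n")
  print(as.data.frame(mutate(nz, sigma2 = round(.data$sigma2, digits))),
        row.names = FALSE)
  invisible(x)
}

#' @rdname fit_components
#' @param x An `esm_vc` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.esm_vc <- function(x, ...) {
  bind_rows(select(x$components, all_of(c("term", "sigma2", "boundary"))),
            tibble(term = "e", sigma2 = x$sigma2_e, boundary = FALSE))
}

#' @rdname fit_components
#' @exportS3Method generics::glance
glance.esm_vc <- function(x, ...) {
  tibble(n_obs = x$n_obs, n_terms = nrow(x$components),
         method = x$method, engine = x$engine,
         minus2loglik = x$minus2loglik, converged = x$converged,
         iterations = x$iterations,
         n_boundary = sum(x$components$boundary))
}

#' Export a fit as a two-column variance table
#'
#' @param x An `esm_vc` fit.
#' @param path_csv,path_json Optional output paths (CSV rounded to 2
#'   decimals, JSON at full precision).
#' @return A tibble `term`, `sigma2`, `share`.
#' @export
component_table <- function(x, path_csv = NULL, path_json = NULL) {
  shares <- relative_shares(x)
  out <- bind_rows(shares,
                   tibble(term = "e", sigma2 = x$sigma2_e, share = NA_real_))
  if (!is.null(path_csv)) {
    readr::write_csv(mutate(out, sigma2 = round(.data$sigma2, 2),
                            share = round(.data$share)), path_csv)
  }
  if (!is.null(path_json)) {
    jsonlite::write_json(list(mu = x$mu, sigma2_e = x$sigma2_e,
                              components = out),
                         path_json, auto_unbox = TRUE, digits = NA)
  }
  out
}
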