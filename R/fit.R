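#' Optimizer settings for BDI model fits
#'
#' @param n_starts Number of optimization starts (a fixed heuristic start
#'   plus stratified random starts in log-rate space).
#' @param lower,upper Rate bounds (per Myr) applied on the log scale.
#' @param maxit Iteration cap per start (L-BFGS-B).
#' @param factr,pgtol Convergence tolerances passed to [stats::optim()];
#'   the defaults resolve log-likelihoods far below the Delta-AIC scale
#'   used for model calls.
#' @return A `fit_control` list.
#' @export
fit_control <- function(n_starts = 5L, lower = 1e-8, upper = 10,
                        maxit = 100L, factr = 1e8, pgtol = 1e-5) {
  structure(
    list(
      n_starts = as.integer(n_starts), lower = lower, upper = upper,
      maxit = as.integer(maxit), factr = factr, pgtol = pgtol
    ),
    class = "fit_control"
  )
}

# overflow-safe stationary distribution of the truncated chain
.stationary_prior <- function(r, n_max) {
  k <- seq_len(n_max)
  lpi <- c(0, cumsum(log((k - 1) * r[1] + r[3]) - log(k * r[2])))
  if (any(!is.finite(lpi))) return(rep(1 / (n_max + 1), n_max + 1))
  p <- exp(lpi - max(lpi))
  p / sum(p)
}

# deterministic stratified starts in log-rate space for one fit;
# two fixed heuristic starts (slow-turnover and moderate-turnover) plus
# stratified random draws
.fit_starts <- function(n_par, control, seed) {
  s1 <- rep(log(0.01), n_par)
  s2 <- rep(log(c(0.1, 0.05, 0.02)), n_par / 3)
  if (control$n_starts <= 1) return(list(s1))
  if (control$n_starts == 2) return(list(s1, s2))
  old <- .save_seed()
  on.exit(.restore_seed(old))
  set.seed(seed)
  lo <- log(1e-4)
  hi <- log(0.3)
  n_rand <- control$n_starts - 2L
  extra <- lapply(seq_len(n_rand), function(i) {
    # stratified: start i drawn from slice i of the log-rate range
    a <- lo + (hi - lo) * (i - 1) / n_rand
    b <- lo + (hi - lo) * i / n_rand
    stats::runif(n_par, a, b)
  })
  c(list(s1, s2), extra)
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.restore_seed <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}

#' Fit a GR or SR rate model to one orthogroup by maximum likelihood
#'
#' Bounded multi-start maximization of [bdi_loglik()] over log rates. The GR
#' model fits one rate class for all branches; the SR model fits one rate
#' set per branch class in `classes` (background plus foreground).
#'
#' @param tree Labelled `phylo`.
#' @param counts Tip counts (named by tip label, or in tip order).
#' @param kind `"GR"` or `"SR"`.
#' @param classes Branch-class assignment (see [branch_classes()]); required
#'   for `"SR"`, must include at least one non-background branch.
#' @param og Orthogroup id carried through to the result.
#' @param n_max Truncation bound; default [default_n_max()].
#' @param control A [fit_control()].
#' @param seed Seed for the random starts.
#' @param extra_starts Optional list of extra start vectors (log rates),
#'   e.g. a warm start from a GR fit.
#' @param prior Root prior used during fitting: `"stationary"` (default;
#'   the stationary distribution of the proposed chain, recomputed per
#'   evaluation -- a flat prior loads most mass onto large ancestral
#'   counts and biases death rates upward) or `"uniform"`.
#' @return A `bdi_fit` object: fitted [rate_model()], `loglik`,
#'   `n_free_parameters`, `AIC`, convergence info.
#' @export
fit_bdi <- function(tree, counts, kind = c("GR", "SR"), classes = NULL,
                    og = NA_character_, n_max = NULL, control = fit_control(),
                    seed = 1L, extra_starts = NULL,
                    prior = c("stationary", "uniform")) {
  prior <- match.arg(prior)
  kind <- match.arg(kind)
  counts <- .tip_counts(tree, counts)
  if (is.null(n_max)) n_max <- max(default_n_max(max(counts)), max(counts) + 5L)
  idx <- tree_index(tree, if (kind == "GR") NULL else classes)
  if (kind == "SR" && length(idx$class_levels) < 2) {
    rlang::abort("SR fit needs >= 2 branch classes (>= 1 foreground branch)",
      class = "famdyn_validation_error"
    )
  }
  n_class <- length(idx$class_levels)
  n_par <- 3L * n_class
  unif <- rep(1 / (n_max + 1), n_max + 1)
  # the root belongs to the background class (GR: the only class)
  root_class <- match("background", idx$class_levels)
  if (is.na(root_class)) root_class <- 1L
  tipstate <- as.integer(c(counts, rep(-1L, tree$Nnode)))

  negll <- function(logr) {
    rmat <- matrix(exp(logr), nrow = n_class, ncol = 3, byrow = TRUE)
    pr <- if (prior == "stationary") {
      .stationary_prior(rmat[root_class, ], n_max)
    } else {
      unif
    }
    ll <- bdi_loglik_cpp(
      idx$edge, idx$elen, idx$eclass, rmat, tipstate,
      idx$root, pr, as.integer(n_max)
    )
    if (!is.finite(ll) || ll > 1e-6) 1e10 else -ll
  }

  # large families carry sharply peaked likelihoods (lots of data per
  # family); the multi-start machinery exists for flat small-count surfaces,
  # so only the fixed heuristic starts (plus warm starts) are used here
  ctl <- control
  if (max(counts) > 30L) ctl$n_starts <- min(ctl$n_starts, 2L)
  starts <- c(.fit_starts(n_par, ctl, seed), extra_starts)
  lo <- rep(log(control$lower), n_par)
  hi <- rep(log(control$upper), n_par)
  # soft bounds for the simplex phase; the polish phase enforces them
  negll_pen <- function(logr) {
    pen <- sum(pmax(logr - hi, 0)^2) + sum(pmax(lo - logr, 0)^2)
    negll(pmin(pmax(logr, lo), hi)) + 100 * pen
  }
  # phase 1: cheap simplex screen of every start; phase 2: refine the winner
  best <- NULL
  best_start <- NA_integer_
  for (si in seq_along(starts)) {
    st <- pmin(pmax(starts[[si]], lo), hi)
    res <- tryCatch(
      stats::optim(st, negll_pen,
        method = "Nelder-Mead",
        control = list(maxit = 10L * n_par, reltol = 1e-5)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      best_start <- si
    }
  }
  if (!is.null(best)) {
    refine <- tryCatch(
      stats::optim(best$par, negll_pen,
        method = "Nelder-Mead",
        control = list(maxit = 40L * n_par, reltol = 1e-7)
      ),
      error = function(e) NULL
    )
    if (!is.null(refine) && refine$value <= best$value) best <- refine
  }
  n_conv <- 0L
  if (!is.null(best)) {
    polish <- tryCatch(
      stats::optim(pmin(pmax(best$par, lo), hi), negll,
        method = "L-BFGS-B", lower = lo, upper = hi,
        control = list(
          maxit = min(control$maxit, 15L), factr = control$factr,
          pgtol = control$pgtol
        )
      ),
      error = function(e) NULL
    )
    if (!is.null(polish) && polish$value <= best$value) best <- polish
    n_conv <- 1L
  }
  converged <- !is.null(best) && n_conv > 0 && best$value < 1e9
  if (is.null(best)) {
    best <- list(par = rep(log(control$lower), n_par), value = 1e10)
  }
  rates <- lapply(seq_len(n_class), function(ci) {
    v <- exp(best$par[(3 * ci - 2):(3 * ci)])
    bdi_rates(v[1], v[2], v[3])
  })
  names(rates) <- idx$class_levels
  model <- rate_model(rates, kind = kind)
  ll <- -best$value
  structure(
    list(
      og = og, kind = kind, model = model, loglik = ll,
      n_free_parameters = n_par, AIC = 2 * n_par - 2 * ll,
      converged = converged, n_starts = length(starts),
      best_start = best_start, n_max = n_max,
      log_par = best$par, prior = prior
    ),
    class = "bdi_fit"
  )
}

#' @export
print.bdi_fit <- function(x, ...) {
  cat(sprintf(
    "<bdi_fit %s%s> logLik %.3f, k %d, AIC %.3f, converged %s\n",
    x$kind, if (is.na(x$og)) "" else paste0(" ", x$og),
    x$loglik, x$n_free_parameters, x$AIC, x$converged
  ))
  invisible(x)
}

#' @rdname tidy
#' @param x A `bdi_fit`.
#' @param ... Unused.
#' @export
tidy.bdi_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$model$rates), function(cl) {
    r <- x$model$rates[[cl]]
    tibble::tibble(
      og = x$og, kind = x$kind, class = cl,
      birth = r[["birth"]], death = r[["death"]],
      innovation = r[["innovation"]], net = r[["birth"]] - r[["death"]]
    )
  }))
}

#' @rdname glance
#' @param x A `bdi_fit`.
#' @param ... Unused.
#' @export
glance.bdi_fit <- function(x, ...) {
  tibble::tibble(
    og = x$og, kind = x$kind, logLik = x$loglik,
    n_free_parameters = x$n_free_parameters, AIC = x$AIC,
    converged = x$converged, n_starts = x$n_starts, best_start = x$best_start
  )
}

#' Compare a GR and an SR fit of the same orthogroup by AIC
#'
#' The best model minimizes AIC; the shift is called significant when
#' `AIC_SR + threshold <= AIC_GR`. Direction and magnitude come from the SR
#' fit's foreground-minus-background net rates (net = birth - death).
#'
#' @param gr,sr `bdi_fit` objects for the same orthogroup.
#' @param threshold Delta-AIC call threshold (default 2; 0 reproduces plain
#'   arg-min model choice).
#' @param foreground Name of the foreground class in the SR fit; default the
#'   single non-background class.
#' @return One-row tibble: `og`, `best_model`, `delta_aic`, `significant`,
#'   `direction` ("expanded", "contracted" or "none"), `magnitude`.
#' @export
compare_models <- function(gr, sr, threshold = 2, foreground = NULL) {
  if (!identical(gr$og, sr$og)) {
    rlang::abort("GR and SR fits are for different orthogroups",
      class = "famdyn_validation_error"
    )
  }
  cls <- names(sr$model$rates)
  if (is.null(foreground)) {
    fg <- setdiff(cls, "background")
    if (length(fg) != 1) {
      rlang::abort("cannot infer foreground class; pass `foreground`",
        class = "famdyn_validation_error"
      )
    }
    foreground <- fg
  }
  bg_cls <- setdiff(cls, foreground)[1]
  net <- function(r) r[["birth"]] - r[["death"]]
  magnitude <- net(sr$model$rates[[foreground]]) - net(sr$model$rates[[bg_cls]])
  delta <- gr$AIC - sr$AIC
  significant <- (sr$AIC + threshold <= gr$AIC) && gr$converged && sr$converged
  tibble::tibble(
    og = gr$og,
    best_model = if (sr$AIC < gr$AIC) "SR" else "GR",
    loglik_gr = gr$loglik, loglik_sr = sr$loglik,
    aic_gr = gr$AIC, aic_sr = sr$AIC,
    delta_aic = delta,
    significant = significant,
    direction = if (!significant) "none" else if (magnitude > 0) "expanded" else "contracted",
    magnitude = magnitude,
    converged = gr$converged && sr$converged
  )
}

#' Fit GR and SR models to every orthogroup of a count table
#'
#' Runs [fit_bdi()] for both model kinds on each orthogroup, compares them
#' with [compare_models()], and returns one row per orthogroup. The SR fit
#' always includes the GR solution among its starts, so `loglik_sr >=
#' loglik_gr` up to optimizer noise.
#'
#' @param tree Labelled `phylo`.
#' @param counts Count tibble (column `og` + taxon columns).
#' @param classes Branch-class assignment with at least one foreground class.
#' @param threshold Delta-AIC significance threshold.
#' @param control A [fit_control()].
#' @param seed Integer; per-orthogroup fit seeds are derived from it.
#' @param keep_fits Attach the `bdi_fit` objects as list columns.
#' @return Tibble of significance calls plus fitted rates per orthogroup
#'   (`gr_*` rates, `bg_*`/`fg_*` SR rates).
#' @export
fit_all <- function(tree, counts, classes, threshold = 2,
                    control = fit_control(), seed = 1L, keep_fits = FALSE) {
  counts <- validate_counts(counts, tree)
  if (nrow(counts) == 0) {
    return(tibble::tibble(
      og = character(0), best_model = character(0), loglik_gr = numeric(0),
      loglik_sr = numeric(0), aic_gr = numeric(0), aic_sr = numeric(0),
      delta_aic = numeric(0), significant = logical(0),
      direction = character(0), magnitude = numeric(0), converged = logical(0)
    ))
  }
  m <- counts_matrix(counts)[, tree$tip.label, drop = FALSE]
  cls <- branch_classes(tree, classes)
  fg_levels <- setdiff(unique(cls), "background")
  if (length(fg_levels) == 0) {
    rlang::abort("classes must mark at least one foreground branch",
      class = "famdyn_validation_error"
    )
  }
  # identical count patterns yield identical fits: fit each pattern once
  pattern <- apply(m, 1, paste, collapse = ",")
  first_of <- match(unique(pattern), pattern)
  rows <- vector("list", length(first_of))
  fits <- if (keep_fits) vector("list", length(first_of)) else NULL
  for (u in seq_along(first_of)) {
    g <- first_of[u]
    og <- rownames(m)[g]
    fit_seed <- (seed + 7L * g) %% .Machine$integer.max
    gr <- fit_bdi(tree, m[g, ],
      kind = "GR", og = og,
      control = control, seed = fit_seed
    )
    warm <- list(rep(gr$log_par, length(fg_levels) + 1L))
    sr <- fit_bdi(tree, m[g, ],
      kind = "SR", classes = classes, og = og,
      control = control, seed = fit_seed, extra_starts = warm
    )
    cmp <- compare_models(gr, sr, threshold = threshold)
    rates <- c(
      stats::setNames(unclass(gr$model$rates[[1]])[1:3], c("gr_birth", "gr_death", "gr_innovation")),
      stats::setNames(
        unclass(sr$model$rates[["background"]])[1:3],
        c("bg_birth", "bg_death", "bg_innovation")
      ),
      stats::setNames(
        unclass(sr$model$rates[[setdiff(names(sr$model$rates), "background")[1]]])[1:3],
        c("fg_birth", "fg_death", "fg_innovation")
      )
    )
    rows[[u]] <- dplyr::bind_cols(cmp, tibble::as_tibble(as.list(rates)))
    if (keep_fits) fits[[u]] <- list(gr = gr, sr = sr)
  }
  uniq <- dplyr::bind_rows(rows)
  if (keep_fits) uniq$fits <- fits
  out <- uniq[match(pattern, pattern[first_of]), , drop = FALSE]
  out$og <- rownames(m)
  out
}

#' Summarize significance calls
#'
#' The headline quantities of a rate-shift screen: how many orthogroups are
#' significant under the branch-specific model, and the expanded/contracted
#' split among them.
#'
#' @param calls Output of [fit_all()].
#' @return One-row tibble with counts and percentages.
#' @export
summarize_calls <- function(calls) {
  sig <- calls[calls$significant, , drop = FALSE]
  tibble::tibble(
    n_og = nrow(calls),
    n_converged = sum(calls$converged),
    n_significant = nrow(sig),
    pct_significant = 100 * nrow(sig) / max(1, nrow(calls)),
    n_expanded = sum(sig$direction == "expanded"),
    n_contracted = sum(sig$direction == "contracted"),
    pct_expanded = 100 * mean(sig$direction == "expanded") * (nrow(sig) > 0),
    pct_contracted = 100 * mean(sig$direction == "contracted") * (nrow(sig) > 0)
  )
}
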