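#' Birth-death-innovation rate set
#'
#' Rates of the copy-number Markov process for one branch class: per-gene
#' birth rate `birth`, per-gene death rate `death`, and per-family innovation
#' (gain-from-zero) rate `innovation`, all per Myr. The chain moves up from
#' state n at rate `n * birth + innovation` and down at rate `n * death`.
#'
#' @param birth,death,innovation Nonnegative finite rates (per Myr).
#' @return A named numeric vector of class `bdi_rates`.
#' @export
bdi_rates <- function(birth, death, innovation) {
  r <- c(birth = birth, death = death, innovation = innovation)
  if (any(!is.finite(r)) || any(r < 0)) {
    rlang::abort("rates must be finite and >= 0", class = "famdyn_validation_error")
  }
  structure(r, class = "bdi_rates")
}

#' Branch-class rate model
#'
#' A global-rates (GR) model has a single class covering every branch; a
#' branch-specific (SR) model assigns separate rates to two or more classes
#' (typically `"background"` plus a foreground such as `"subterranean"`).
#'
#' @param ... Named [bdi_rates()], one per branch class.
#' @param kind `"GR"` or `"SR"`; inferred from the number of classes when
#'   omitted.
#' @return An object of class `rate_model` with fields `rates` (named list),
#'   `kind`, and `n_free_parameters` (3 per class).
#' @export
rate_model <- function(..., kind = NULL) {
  rates <- list(...)
  if (length(rates) == 1 && is.list(rates[[1]]) && !inherits(rates[[1]], "bdi_rates")) {
    rates <- rates[[1]]
  }
  stopifnot(length(rates) >= 1, !is.null(names(rates)), all(names(rates) != ""))
  if (is.null(kind)) kind <- if (length(rates) == 1) "GR" else "SR"
  if (kind == "GR" && length(rates) != 1) {
    rlang::abort("GR model must have exactly one class", class = "famdyn_validation_error")
  }
  if (kind == "SR" && length(rates) < 2) {
    rlang::abort("SR model needs >= 2 classes", class = "famdyn_validation_error")
  }
  structure(
    list(rates = rates, kind = kind, n_free_parameters = 3L * length(rates)),
    class = "rate_model"
  )
}

#' @export
print.rate_model <- function(x, ...) {
  cat(sprintf("<rate_model %s> %d classes, k = %d\n", x$kind, length(x$rates), x$n_free_parameters))
  for (nm in names(x$rates)) {
    r <- x$rates[[nm]]
    cat(sprintf("  %s: birth %.4g death %.4g innovation %.4g\n", nm, r[1], r[2], r[3]))
  }
  invisible(x)
}

#' Default state-space truncation for an orthogroup
#'
#' Three times the largest observed count for small families, bounded by a
#' square-root buffer for large ones (copy-number fluctuations scale with
#' the square root of the count, so mass far above the observed maximum is
#' negligible and tripling a large state space only slows the likelihood).
#'
#' @param max_count Largest observed tip count.
#' @param floor_count Minimum pre-scaling count (default 5).
#' @param factor Multiplier (default 3).
#' @param cap Hard upper bound on `n_max`.
#' @return Integer `n_max`.
#' @export
default_n_max <- function(max_count, floor_count = 5L, factor = 3L, cap = 120L) {
  m <- max(max_count, floor_count)
  min(cap, factor * m, m + ceiling(3 * sqrt(m)) + 10L)
}

#' BDI transition probability matrix on a branch
#'
#' Probability of moving between copy-number states 0..`n_max` over `t` Myr,
#' computed by uniformization of the truncated tridiagonal generator
#' (with scaling-and-squaring for long intervals). The
#' truncation boundary leaks: rows sum to 1 minus the leaked mass, and the
#' leak is checked on the start states in `check_states`.
#'
#' @param rates A [bdi_rates()].
#' @param t Branch length in Myr (>= 0).
#' @param n_max Largest count state retained.
#' @param tol Maximum tolerated leaked mass on checked rows.
#' @param check_states Start states whose leak is checked; default
#'   `0:(n_max %/% 3)`, consistent with the default truncation
#'   `n_max = 3 * max(observed, 5)`.
#' @return `(n_max + 1) x (n_max + 1)` matrix, rows = start state.
#' @export
transition_matrix <- function(rates, t, n_max, tol = 1e-6,
                              check_states = NULL) {
  stopifnot(t >= 0, n_max >= 1)
  P <- bdi_pmat_cpp(
    rates[["birth"]], rates[["death"]], rates[["innovation"]],
    t, as.integer(n_max)
  )
  dimnames(P) <- list(0:n_max, 0:n_max)
  if (is.null(check_states)) check_states <- 0:(n_max %/% 3)
  leak <- 1 - rowSums(P)[check_states + 1]
  if (any(leak >= tol)) {
    rlang::abort(
      sprintf(
        "truncation leak %.3g >= tol %.3g on state %d; increase n_max (currently %d)",
        max(leak), tol, check_states[which.max(leak)], n_max
      ),
      class = "famdyn_truncation_error"
    )
  }
  P
}

#' Root-state prior over 0..n_max
#'
#' @param kind `"uniform"` (flat, the default) or `"stationary"` (normalized
#'   stationary mass of the truncated chain; requires positive death and
#'   innovation rates, otherwise falls back to uniform).
#' @param n_max State-space bound.
#' @param rates Rates used for the stationary option.
#' @return Probability vector of length `n_max + 1`.
#' @export
root_prior <- function(kind = c("uniform", "stationary"), n_max, rates = NULL) {
  kind <- match.arg(kind)
  n <- n_max + 1
  if (kind == "uniform" || is.null(rates) ||
    rates[["death"]] <= 0 || rates[["innovation"]] <= 0) {
    return(rep(1 / n, n))
  }
  lpi <- numeric(n)
  for (k in seq_len(n_max)) {
    up <- (k - 1) * rates[["birth"]] + rates[["innovation"]]
    dn <- k * rates[["death"]]
    lpi[k + 1] <- lpi[k] + log(up) - log(dn)
  }
  p <- exp(lpi - max(lpi))
  p / sum(p)
}

#' Phylogenetic log-likelihood of one orthogroup's tip counts
#'
#' Felsenstein pruning over discrete copy-number states: tip partials are
#' indicator vectors, each branch applies its class's transition matrix, and
#' the root combines with `prior`. Rescaled per node to avoid underflow.
#'
#' @param tree Labelled `phylo`.
#' @param counts Named integer vector of tip counts (names = tip labels), or
#'   unnamed in tip order.
#' @param model A [rate_model()] covering every branch class in `classes`.
#' @param classes Branch-class assignment (see [branch_classes()]).
#' @param prior Root prior vector over 0..`n_max`; default uniform.
#' @param n_max Truncation bound; default [default_n_max()] of the counts.
#' @return Log-likelihood (<= 0 for proper priors).
#' @export
bdi_loglik <- function(tree, counts, model, classes = NULL, prior = NULL,
                       n_max = NULL) {
  idx <- tree_index(tree, classes)
  missing_cls <- setdiff(idx$class_levels, names(model$rates))
  if (length(missing_cls) > 0) {
    rlang::abort(
      paste0("model lacks rates for class(es): ", paste(missing_cls, collapse = ", ")),
      class = "famdyn_validation_error"
    )
  }
  counts <- .tip_counts(tree, counts)
  if (is.null(n_max)) n_max <- max(default_n_max(max(counts)), max(counts) + 5L)
  if (is.null(prior)) prior <- rep(1 / (n_max + 1), n_max + 1)
  if (length(prior) != n_max + 1 || any(prior < 0) || sum(prior) <= 0) {
    rlang::abort("invalid root prior", class = "famdyn_validation_error")
  }
  rmat <- do.call(rbind, lapply(idx$class_levels, function(cl) unclass(model$rates[[cl]])[1:3]))
  tipstate <- c(counts, rep(-1L, tree$Nnode))
  bdi_loglik_cpp(
    idx$edge, idx$elen, idx$eclass, rmat, as.integer(tipstate),
    idx$root, prior, as.integer(n_max)
  )
}

.tip_counts <- function(tree, counts) {
  if (!is.null(names(counts))) {
    missing <- setdiff(tree$tip.label, names(counts))
    if (length(missing) > 0) {
      rlang::abort(
        paste0("counts missing for tips: ", paste(missing, collapse = ", ")),
        class = "famdyn_validation_error"
      )
    }
    counts <- counts[tree$tip.label]
  } else if (length(counts) != length(tree$tip.label)) {
    rlang::abort("counts length != number of tips", class = "famdyn_validation_error")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    rlang::abort("tip counts must be nonnegative integers", class = "famdyn_validation_error")
  }
  as.integer(counts)
}
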