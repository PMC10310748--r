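#' Marginal ancestral reconstruction of one orthogroup's copy numbers
#'
#' Computes the marginal posterior distribution over count states at every
#' node by an up-down (inside-outside) pass under the given rate model, and
#' reports the max-marginal state per node (ties broken toward the smaller
#' count). Tip entries equal the observed counts.
#'
#' @param tree Labelled `phylo`.
#' @param counts Tip counts (named by tip label, or in tip order).
#' @param model A [rate_model()] covering every class in `classes`.
#' @param classes Branch-class assignment (see [branch_classes()]).
#' @param prior Root prior over 0..`n_max`: a probability vector, the
#'   string `"stationary"` (stationary distribution of the model's
#'   background-class rates, matching the fitting default), or `NULL` for
#'   uniform.
#' @param n_max Truncation bound; default [default_n_max()].
#' @param og Orthogroup id carried through to the result.
#' @return Tibble `og`, `node`, `state`, `posterior` (marginal mass of the
#'   reported state), one row per node.
#' @export
reconstruct_ancestral <- function(tree, counts, model, classes = NULL,
                                  prior = NULL, n_max = NULL,
                                  og = NA_character_) {
  idx <- tree_index(tree, classes)
  counts <- .tip_counts(tree, counts)
  if (is.null(n_max)) n_max <- max(default_n_max(max(counts)), max(counts) + 5L)
  n <- n_max + 1
  if (is.null(prior)) prior <- rep(1 / n, n)
  if (identical(prior, "stationary")) {
    rc <- model$rates[["background"]] %||% model$rates[[1]]
    prior <- .stationary_prior(unclass(rc)[1:3], n_max)
  }
  rmat <- do.call(rbind, lapply(
    idx$class_levels,
    function(cl) unclass(model$rates[[cl]])[1:3]
  ))
  n_node <- length(idx$labels)
  n_edge <- nrow(idx$edge)
  apply_edge <- function(e, v, transpose) {
    r <- rmat[idx$eclass[e], ]
    bdi_expmv_cpp(r[1], r[2], r[3], idx$elen[e], as.integer(n_max), v,
      transpose = transpose
    )$v
  }

  # inside pass (postorder), columns rescaled to max 1
  L <- matrix(1, n, n_node)
  for (tp in seq_len(idx$n_tip)) {
    L[, tp] <- 0
    L[counts[tp] + 1, tp] <- 1
  }
  msg <- matrix(0, n, n_edge) # message from child edge e to its parent
  for (e in seq_len(n_edge)) {
    child <- idx$edge[e, 2]
    v <- apply_edge(e, L[, child], transpose = FALSE)
    m <- max(v)
    if (m <= 0) {
      rlang::abort("zero likelihood during reconstruction",
        class = "famdyn_numeric_error"
      )
    }
    msg[, e] <- v / m
    L[, idx$edge[e, 1]] <- L[, idx$edge[e, 1]] * msg[, e]
  }

  # outside pass (preorder = reversed postorder)
  children_edges <- split(seq_len(n_edge), idx$edge[, 1])
  O <- matrix(0, n, n_node)
  O[, idx$root] <- prior
  for (e in rev(seq_len(n_edge))) {
    p <- idx$edge[e, 1]
    child <- idx$edge[e, 2]
    sib <- setdiff(children_edges[[as.character(p)]], e)
    w <- O[, p]
    for (s in sib) w <- w * msg[, s]
    v <- apply_edge(e, w, transpose = TRUE)
    m <- max(v)
    if (m <= 0) {
      rlang::abort("zero outside mass during reconstruction",
        class = "famdyn_numeric_error"
      )
    }
    O[, child] <- v / m
  }

  post <- O * L
  cs <- colSums(post)
  if (any(cs <= 0)) {
    rlang::abort("posterior underflow during reconstruction",
      class = "famdyn_numeric_error"
    )
  }
  post <- sweep(post, 2, cs, "/")
  state <- apply(post, 2, function(p) {
    m <- max(p)
    min(which(p >= m - 1e-12)) - 1L
  })
  tibble::tibble(
    og = og,
    node = idx$labels,
    state = as.integer(state),
    posterior = post[cbind(state + 1L, seq_len(n_node))]
  )
}

# rebuild the best model of one fit_all row
.call_model <- function(row, fg_class) {
  if (row$best_model == "GR") {
    rate_model(background = bdi_rates(row$gr_birth, row$gr_death, row$gr_innovation))
  } else {
    args <- list(
      bdi_rates(row$bg_birth, row$bg_death, row$bg_innovation),
      bdi_rates(row$fg_birth, row$fg_death, row$fg_innovation)
    )
    names(args) <- c("background", fg_class)
    rate_model(args, kind = "SR")
  }
}

#' Ancestral states for every orthogroup under its best-fitting model
#'
#' Applies [reconstruct_ancestral()] per orthogroup, using each orthogroup's
#' AIC-best model (GR or SR rates) from a [fit_all()] table. Non-converged
#' orthogroups are skipped and reported via the `"skipped"` attribute.
#'
#' @param tree Labelled `phylo`.
#' @param counts Count tibble.
#' @param calls [fit_all()] output.
#' @param classes Branch-class assignment used for the SR fits (exactly one
#'   foreground class).
#' @return Tibble `og`, `node`, `state`, `posterior`.
#' @export
ancestral_states <- function(tree, counts, calls, classes) {
  counts <- validate_counts(counts, tree)
  m <- counts_matrix(counts)[, tree$tip.label, drop = FALSE]
  cls <- branch_classes(tree, classes)
  fg <- setdiff(unique(cls), "background")
  if (length(fg) != 1) {
    rlang::abort("ancestral_states expects exactly one foreground class",
      class = "famdyn_validation_error"
    )
  }
  skipped <- character(0)
  rows <- vector("list", nrow(calls))
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    if (!isTRUE(row$converged)) {
      skipped <- c(skipped, row$og)
      next
    }
    model <- .call_model(row, fg)
    use_classes <- if (row$best_model == "GR") NULL else classes
    rows[[i]] <- reconstruct_ancestral(
      tree, m[row$og, ], model,
      classes = use_classes, prior = "stationary", og = row$og
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "skipped") <- skipped
  out
}

#' Per-branch copy-number changes per orthogroup
#'
#' For every branch (identified by its child node) and orthogroup, the
#' change `delta = state(child) - state(parent)` between reconstructed (or
#' observed, at tips) states, with the event flags used throughout:
#' `expanded` (delta > 0), `contracted` (delta < 0), `og_gained`
#' (parent 0, child > 0) and `og_lost` (parent > 0, child 0).
#'
#' @param states Tibble `og`, `node`, `state` (from [ancestral_states()] or
#'   simulation truth).
#' @param tree Labelled `phylo`.
#' @return Tibble with one row per (branch, og) with `delta != 0`:
#'   `branch`, `og`, `parent_state`, `child_state`, `delta`, flags.
#' @export
branch_changes <- function(states, tree) {
  tb <- tree_branches(tree)
  st <- states[, c("og", "node", "state")]
  ch <- st %>%
    dplyr::rename(branch = "node", child_state = "state") %>%
    dplyr::inner_join(tb[, c("branch", "parent")], by = "branch") %>%
    dplyr::inner_join(
      dplyr::rename(st, parent = "node", parent_state = "state"),
      by = c("og", "parent")
    ) %>%
    dplyr::mutate(
      delta = .data$child_state - .data$parent_state,
      expanded = .data$delta > 0,
      contracted = .data$delta < 0,
      og_gained = .data$parent_state == 0 & .data$child_state > 0,
      og_lost = .data$parent_state > 0 & .data$child_state == 0
    ) %>%
    dplyr::filter(.data$delta != 0) %>%
    dplyr::select(
      "branch", "og", "parent_state", "child_state", "delta",
      "expanded", "contracted", "og_gained", "og_lost"
    ) %>%
    dplyr::arrange(.data$branch, .data$og)
  ch
}

#' Per-branch event totals
#'
#' Aggregates a [branch_changes()] table into the per-branch quantities
#' plotted in repertoire-evolution summaries: total gene gains and losses,
#' numbers of expanded/contracted/gained/lost orthogroups, and duplication
#' events (gene gains on branches where the family already existed).
#'
#' @param changes [branch_changes()] output.
#' @param tree Labelled `phylo`; every branch appears in the result, with
#'   zeros where nothing changed.
#' @return Tibble, one row per branch.
#' @export
branch_summary <- function(changes, tree) {
  tb <- tree_branches(tree)
  agg <- changes %>%
    dplyr::group_by(.data$branch) %>%
    dplyr::summarise(
      gene_gains = sum(pmax(.data$delta, 0)),
      gene_losses = sum(pmax(-.data$delta, 0)),
      n_expanded = sum(.data$expanded),
      n_contracted = sum(.data$contracted),
      n_gained = sum(.data$og_gained),
      n_lost = sum(.data$og_lost),
      n_duplications = sum(pmax(.data$delta, 0)[.data$parent_state > 0])
    )
  tb %>%
    dplyr::select("branch") %>%
    dplyr::left_join(agg, by = "branch") %>%
    dplyr::mutate(dplyr::across(-"branch", ~ tidyr::replace_na(.x, 0)))
}

#' Orthogroup lists per branch and event category
#'
#' @param changes [branch_changes()] output.
#' @param branches Branch ids (child node labels) of interest.
#' @param tree Labelled `phylo`, used to validate the branch ids (the root
#'   is not a branch).
#' @return Tibble `branch`, `category` (expanded / contracted / gained /
#'   lost), `og`. Gained lists are subsets of expanded, lost of contracted.
#' @export
branch_og_lists <- function(changes, branches, tree) {
  valid <- tree_branches(tree)$branch
  bad <- setdiff(branches, valid)
  if (length(bad) > 0) {
    rlang::abort(
      paste0(
        "not a branch (unknown or root): ",
        paste(bad, collapse = ", ")
      ),
      class = "famdyn_validation_error"
    )
  }
  ch <- changes[changes$branch %in% branches, , drop = FALSE]
  dplyr::bind_rows(
    ch %>% dplyr::filter(.data$expanded) %>%
      dplyr::transmute(.data$branch, category = "expanded", .data$og),
    ch %>% dplyr::filter(.data$contracted) %>%
      dplyr::transmute(.data$branch, category = "contracted", .data$og),
    ch %>% dplyr::filter(.data$og_gained) %>%
      dplyr::transmute(.data$branch, category = "gained", .data$og),
    ch %>% dplyr::filter(.data$og_lost) %>%
      dplyr::transmute(.data$branch, category = "lost", .data$og)
  ) %>%
    dplyr::arrange(.data$branch, .data$category, .data$og)
}
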