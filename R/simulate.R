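#' Simulation configuration
#'
#' Bundles everything the synthetic-data generator needs: a tree (fixed
#' Newick text or a sampled pure-birth tree), the number of orthogroups,
#' background BDI rates, optional per-class multiplicative foreground shifts,
#' the root-count distribution, and the seed that fixes all randomness.
#'
#' @param n_og Number of orthogroups (>= 1).
#' @param tree A `phylo` to reuse, or `NULL` to sample a pure-birth tree.
#' @param n_tips Tips of the sampled tree when `tree` is `NULL`.
#' @param tree_height Height (Myr) the sampled tree is rescaled to.
#' @param rates Background [bdi_rates()].
#' @param classes Branch-class assignment passed to [branch_classes()].
#' @param shift Named list `class -> multiplicative factors`, each a numeric
#'   vector of length 3 (birth, death, innovation multipliers) or length 1
#'   (applied to birth only); classes not listed evolve at background rates.
#' @param shifted_ogs Which orthogroups the shifts apply to: `NULL` (all, the
#'   default), or a named list `class -> integer indices of shifted OGs`,
#'   letting different orthogroups carry shifts on different branch classes.
#' @param root_mean Mean of the truncated geometric root-count distribution.
#' @param root_max Truncation of the root-count distribution.
#' @param root_min Smallest root count with positive mass (default 0; set 1
#'   to restrict to families present in the clade ancestor).
#' @param seed Integer seed; fixes all randomness.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_og = 100L, tree = NULL, n_tips = 12L, tree_height = 50,
                       rates = bdi_rates(0.05, 0.05, 0.02), classes = NULL,
                       shift = NULL, shifted_ogs = NULL,
                       root_mean = 2, root_max = 10L, root_min = 0L, seed = 1L) {
  stopifnot(n_og >= 1, is.null(tree) || inherits(tree, "phylo"))
  stopifnot(root_min >= 0, root_min <= root_max)
  structure(
    list(
      n_og = as.integer(n_og), tree = tree, n_tips = as.integer(n_tips),
      tree_height = tree_height, rates = rates, classes = classes,
      shift = shift, shifted_ogs = shifted_ogs,
      root_mean = root_mean, root_max = as.integer(root_max),
      root_min = as.integer(root_min),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

# geometric root-count distribution with the given mean, truncated at
# root_max and renormalized; positive mass at small counts, long-ish tail --
# a rough stand-in for orthogroup size distributions
.root_dist <- function(root_mean, root_max, root_min = 0L) {
  p <- 1 / (1 + root_mean) # geometric on 0,1,2,... with mean root_mean
  k <- 0:root_max
  w <- p * (1 - p)^k
  w[k < root_min] <- 0
  w / sum(w)
}

#' Simulate one branch of the BDI jump process (exact Gillespie)
#'
#' @param n0 Start count.
#' @param rates A [bdi_rates()] (or numeric vector birth, death, innovation).
#' @param t Branch duration (Myr).
#' @return End count after time `t`.
#' @export
sim_branch <- function(n0, rates, t) {
  b <- rates[[1]]; d <- rates[[2]]; i <- rates[[3]]
  n <- n0
  time <- 0
  repeat {
    up <- n * b + i
    dn <- n * d
    tot <- up + dn
    if (tot <= 0) return(n)
    time <- time + stats::rexp(1, tot)
    if (time > t) return(n)
    n <- if (stats::runif(1) < up / tot) n + 1L else n - 1L
  }
}

#' Simulate orthogroup counts on a tree under the BDI process
#'
#' For every orthogroup a root count is drawn from a truncated geometric
#' distribution, then evolved along each branch by exact stochastic
#' simulation of the jump process with rates `n*birth + innovation` (up) and
#' `n*death` (down). Branch classes named in `config$shift` evolve at
#' background rates multiplied by their shift factors, for the orthogroups
#' selected in `config$shifted_ogs`.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_dataset` with elements `tree`, `counts`
#'   (tibble, column `og` + one column per tip), `node_states` (tibble
#'   `og`, `node`, `count` for every node incl. tips), `og_truth` (tibble
#'   `og`, `model` ("GR" or the shifted class labels)), and `config`.
#' @export
simulate_counts <- function(config) {
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rphylo(config$n_tips, birth = 0.1, death = 0)
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree)) *
      config$tree_height
    tree$tip.label <- sprintf("t%02d", seq_len(config$n_tips))
    tree$node.label <- NULL
  }
  tree <- label_internal_nodes(validate_tree(tree))
  idx <- tree_index(tree, config$classes)
  labs <- idx$labels
  n_node <- length(labs)
  rootw <- .root_dist(config$root_mean, config$root_max, config$root_min %||% 0L)

  bg <- unclass(config$rates)[1:3]
  # per-class rate table; shifts multiply background
  class_rates <- lapply(idx$class_levels, function(cl) {
    f <- config$shift[[cl]]
    if (is.null(f)) return(bg)
    if (length(f) == 1) f <- c(f, 1, 1)
    bg * f
  })
  names(class_rates) <- idx$class_levels
  shifted_idx <- config$shifted_ogs
  shifted_classes <- names(config$shift)

  og_ids <- sprintf("OG%06d", seq_len(config$n_og))
  states <- matrix(0L, nrow = config$n_og, ncol = n_node,
    dimnames = list(og_ids, labs)
  )
  # preorder = reversed postorder edges
  pre <- idx$edge[rev(seq_len(nrow(idx$edge))), , drop = FALSE]
  elen <- rev(idx$elen)
  ecls <- rev(idx$eclass)
  og_model <- rep("GR", config$n_og)

  for (g in seq_len(config$n_og)) {
    st <- integer(n_node)
    st[idx$root] <- sample(0:config$root_max, 1, prob = rootw)
    for (e in seq_len(nrow(pre))) {
      cl <- idx$class_levels[ecls[e]]
      use_shift <- cl %in% shifted_classes &&
        (is.null(shifted_idx) || g %in% shifted_idx[[cl]])
      r <- if (use_shift) class_rates[[cl]] else bg
      st[pre[e, 2]] <- sim_branch(st[pre[e, 1]], r, elen[e])
    }
    states[g, ] <- st
    active <- shifted_classes[vapply(shifted_classes, function(cl) {
      is.null(shifted_idx) || g %in% shifted_idx[[cl]]
    }, TRUE)]
    if (length(active) > 0) og_model[g] <- paste(sort(active), collapse = "+")
  }

  counts <- tibble::as_tibble(states[, tree$tip.label, drop = FALSE])
  counts <- dplyr::bind_cols(tibble::tibble(og = og_ids), counts)
  node_states <- tibble::as_tibble(as.table(states), .name_repair = "minimal")
  names(node_states) <- c("og", "node", "count")
  node_states$count <- as.integer(node_states$count)
  structure(
    list(
      tree = tree, counts = counts,
      node_states = tibble::as_tibble(node_states),
      og_truth = tibble::tibble(og = og_ids, model = og_model),
      config = config
    ),
    class = "sim_dataset"
  )
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf(
    "<sim_dataset> %d orthogroups x %d tips (seed %d)\n",
    nrow(x$counts), length(x$tree$tip.label), x$config$seed
  ))
  invisible(x)
}

#' Simulate a themed ontology
#'
#' One root plus `n_themes` disjoint subtrees ("themes"): theme level `d`
#' (1..`depth`) holds `branching^d` terms, each level-1 term attached to the
#' root by an `is_a` edge. Term ids are deterministic, so a given geometry
#' always yields the same ontology.
#'
#' @param n_themes Number of themes (>= 1).
#' @param depth Levels per theme (>= 2).
#' @param branching Children per term.
#' @param seed Unused (construction is deterministic); kept so all
#'   generators share one signature.
#' @return An [ontology]; theme membership is recoverable from the ids
#'   (`T<theme>.<level>.<index>`).
#' @export
simulate_ontology <- function(n_themes, depth, branching, seed = 1L) {
  stopifnot(n_themes >= 1, depth >= 2, branching >= 1)
  terms <- tibble::tibble(
    id = "ROOT", name = "root process", namespace = "biological_process"
  )
  edges <- NULL
  for (th in seq_len(n_themes)) {
    for (d in seq_len(depth)) {
      n_lvl <- branching^d
      ids <- sprintf("T%d.%d.%03d", th, d, seq_len(n_lvl))
      terms <- dplyr::bind_rows(terms, tibble::tibble(
        id = ids,
        name = sprintf("theme %d process %d.%d", th, d, seq_len(n_lvl)),
        namespace = "biological_process"
      ))
      parent <- if (d == 1) {
        rep("ROOT", n_lvl)
      } else {
        sprintf("T%d.%d.%03d", th, d - 1, ceiling(seq_len(n_lvl) / branching))
      }
      edges <- dplyr::bind_rows(edges, tibble::tibble(
        child = ids, parent = parent, relation = "is_a"
      ))
    }
  }
  ontology(terms, edges)
}

#' Terms belonging to one theme of a simulated ontology
#'
#' @param ont Ontology from [simulate_ontology()].
#' @param theme Theme number.
#' @return Character vector of term ids.
#' @export
theme_terms <- function(ont, theme) {
  grep(sprintf("^T%d\\.", theme), ont$terms$id, value = TRUE)
}

#' Simulate orthogroup annotations with planted functional themes
#'
#' Each orthogroup draws `n_terms_per_og` terms uniformly from its assigned
#' theme's subtree; every drawn term is then replaced, with probability
#' `noise_rate`, by a uniform draw from the whole ontology.
#'
#' @param ont Ontology from [simulate_ontology()].
#' @param og_ids Orthogroup ids.
#' @param theme_assignment Integer vector (same length as `og_ids`) of theme
#'   numbers.
#' @param n_terms_per_og Terms drawn per orthogroup.
#' @param noise_rate Per-term replacement probability in [0, 1].
#' @param seed Integer seed.
#' @return Long tibble `og`, `term` (distinct pairs).
#' @export
simulate_annotations <- function(ont, og_ids, theme_assignment,
                                 n_terms_per_og = 5L, noise_rate = 0.05,
                                 seed = 1L) {
  stopifnot(length(og_ids) == length(theme_assignment))
  set.seed(seed)
  all_terms <- setdiff(ont$terms$id, ont$roots)
  rows <- lapply(seq_along(og_ids), function(i) {
    pool <- theme_terms(ont, theme_assignment[i])
    tms <- sample(pool, n_terms_per_og, replace = TRUE)
    noisy <- stats::runif(n_terms_per_og) < noise_rate
    if (any(noisy)) tms[noisy] <- sample(all_terms, sum(noisy), replace = TRUE)
    tibble::tibble(og = og_ids[i], term = tms)
  })
  dplyr::distinct(dplyr::bind_rows(rows))
}

#' Write a simulated dataset to a directory
#'
#' Emits `tree.nwk`, `counts.tsv`, `annotations.tsv` (if present),
#' `ontology.obo` (if present) and `truth.tsv` (ancestral states + generating
#' model labels).
#'
#' @param sim A `sim_dataset`, optionally with `$annotations`, `$ontology`,
#'   `$themes` attached.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_newick(sim$tree, file.path(dir, "tree.nwk"))
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  truth <- dplyr::left_join(sim$node_states, sim$og_truth, by = "og")
  .write_tsv_stamped(truth, file.path(dir, "truth.tsv"))
  if (!is.null(sim$annotations)) {
    write_annotations(sim$annotations, file.path(dir, "annotations.tsv"))
  }
  if (!is.null(sim$ontology)) write_obo(sim$ontology, file.path(dir, "ontology.obo"))
  invisible(dir)
}
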