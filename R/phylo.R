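#' Read a rooted time tree from a Newick file
#'
#' Parses a Newick tree (branch lengths in Myr), validates it, and assigns
#' deterministic labels (`"N1"`, `"N2"`, ... in postorder) to any unlabelled
#' internal nodes so that every branch can be identified by its child node
#' label across runs.
#'
#' @param path Path to a Newick file (or a string containing Newick text via
#'   `text`).
#' @param text Newick text, used instead of `path` when supplied.
#' @return An [ape::read.tree()] `phylo` object with complete node labels.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path, warn = FALSE), collapse = "")
  .check_newick_balance(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    rlang::abort("failed to parse Newick text", class = "famdyn_format_error")
  }
  validate_tree(tree)
  label_internal_nodes(tree)
}

# cheap balance scan so format errors can name a byte offset
.check_newick_balance <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L) {
      rlang::abort(
        sprintf("unbalanced ')' at byte offset %d", i),
        class = "famdyn_format_error"
      )
    }
  }
  if (depth != 0L) {
    rlang::abort(
      sprintf("unbalanced '(' (depth %d at end of input)", depth),
      class = "famdyn_format_error"
    )
  }
  invisible(TRUE)
}

#' Validate a phylogeny
#'
#' Checks the invariants assumed throughout: rooted, connected binary-or-not
#' topology with unique tip labels and nonnegative branch lengths.
#'
#' @param tree A `phylo` object.
#' @return The tree, invisibly.
#' @export
validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    rlang::abort(
      paste0("duplicate tip labels: ", paste(dup, collapse = ", ")),
      class = "famdyn_validation_error"
    )
  }
  if (!ape::is.rooted(tree)) {
    rlang::abort("tree must be rooted", class = "famdyn_validation_error")
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    rlang::abort("negative branch lengths", class = "famdyn_validation_error")
  }
  invisible(tree)
}

#' Assign deterministic postorder labels to unlabelled internal nodes
#'
#' @param tree A `phylo` object.
#' @return The tree with every internal node labelled; existing labels are
#'   kept, empty ones become `"N1"`, `"N2"`, ... in postorder.
#' @export
label_internal_nodes <- function(tree) {
  n_tip <- length(tree$tip.label)
  labs <- tree$node.label
  if (is.null(labs)) labs <- rep("", tree$Nnode)
  labs[is.na(labs)] <- ""
  po <- ape::reorder.phylo(tree, "postorder")$edge
  # internal nodes in the order their subtrees complete
  seen <- integer(0)
  for (nd in po[, 1]) if (!(nd %in% seen)) seen <- c(seen, nd)
  counter <- 0L
  for (nd in seen) {
    j <- nd - n_tip
    if (labs[j] == "") {
      counter <- counter + 1L
      labs[j] <- paste0("N", counter)
    }
  }
  if (anyDuplicated(c(tree$tip.label, labs))) {
    rlang::abort("duplicate node labels after labelling",
      class = "famdyn_validation_error"
    )
  }
  tree$node.label <- labs
  tree
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

# all node labels indexed by ape node number (tips first)
node_labels <- function(tree) c(tree$tip.label, tree$node.label)

#' Branch table of a tree
#'
#' Every branch is identified by its child node label. Optionally attaches a
#' rate-class label per branch (default `"background"`).
#'
#' @param tree A labelled `phylo` object.
#' @param classes Optional named character vector `child label -> class`, or a
#'   named list `class -> character vector of child labels`; branches not
#'   mentioned get `"background"`.
#' @return A tibble with columns `branch` (child label), `parent`, `length`,
#'   `class`.
#' @export
tree_branches <- function(tree, classes = NULL) {
  labs <- node_labels(tree)
  tb <- tibble::tibble(
    branch = labs[tree$edge[, 2]],
    parent = labs[tree$edge[, 1]],
    length = if (is.null(tree$edge.length)) NA_real_ else tree$edge.length
  )
  tb$class <- branch_classes(tree, classes)[tb$branch]
  tb
}

#' Resolve branch-class labels
#'
#' @inheritParams tree_branches
#' @return Named character vector over all branches (child labels).
#' @export
branch_classes <- function(tree, classes = NULL) {
  labs <- node_labels(tree)
  branches <- labs[tree$edge[, 2]]
  cls <- stats::setNames(rep("background", length(branches)), branches)
  if (is.null(classes)) return(cls)
  if (is.list(classes)) {
    flat <- unlist(lapply(names(classes), function(nm) {
      stats::setNames(rep(nm, length(classes[[nm]])), classes[[nm]])
    }))
    classes <- flat
  }
  unknown <- setdiff(names(classes), branches)
  if (length(unknown) > 0) {
    rlang::abort(
      paste0("branch labels not in tree: ", paste(unknown, collapse = ", ")),
      class = "famdyn_validation_error"
    )
  }
  cls[names(classes)] <- unname(classes)
  cls
}

# Internal: indexing used by the likelihood core.
# Returns postorder edge matrix (parent, child) in ape node numbers, edge
# lengths, per-edge class index, class level names, root number, labels.
tree_index <- function(tree, classes = NULL) {
  po <- ape::reorder.phylo(tree, "postorder")
  labs <- node_labels(tree)
  cls <- branch_classes(tree, classes)
  ecls <- cls[labs[po$edge[, 2]]]
  lev <- sort(unique(ecls))
  list(
    edge = po$edge,
    elen = po$edge.length,
    eclass = match(ecls, lev),
    class_levels = lev,
    root = length(tree$tip.label) + 1L,
    labels = labs,
    n_tip = length(tree$tip.label)
  )
}

#' Restrict a tree to a subset of tips (analysis scope)
#'
#' Used to rerun the rate analysis on a clade only (e.g. the aquatic or the
#' terrestrial subtree).
#'
#' @param tree A labelled `phylo`.
#' @param tips Tip labels to keep.
#' @return The pruned, relabelled tree.
#' @export
prune_tree <- function(tree, tips) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0) {
    rlang::abort(
      paste0("tips not in tree: ", paste(missing, collapse = ", ")),
      class = "famdyn_validation_error"
    )
  }
  pruned <- ape::keep.tip(tree, tips)
  validate_tree(pruned)
  label_internal_nodes(pruned)
}
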