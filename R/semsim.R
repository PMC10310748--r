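#' Wang-style semantic-similarity parameters
#'
#' @param weights Named edge-weight vector for the semantic-contribution
#'   recursion (defaults `is_a` 0.8, `part_of` 0.6, both in (0, 1)).
#' @return A `sim_params` list.
#' @export
sim_params <- function(weights = c(is_a = 0.8, part_of = 0.6)) {
  if (any(weights <= 0) || any(weights >= 1)) {
    rlang::abort("edge weights must lie in (0, 1)", class = "famdyn_validation_error")
  }
  structure(list(weights = weights), class = "sim_params")
}

# S-values of `term`: named vector over {term} + ancestors, S(term) = 1 and
# S(a) = max over paths term -> a of the product of edge weights.
# Ancestors are relaxed in decreasing-depth order (parents are always
# shallower under longest-path depth), so one sweep suffices.
wang_svalues <- function(ont, term, params = sim_params()) {
  anc <- term_ancestors(ont, term)
  nodes <- c(term, anc)
  s <- stats::setNames(rep(-Inf, length(nodes)), nodes)
  s[term] <- 1
  ord <- nodes[order(ont$depth[nodes], decreasing = TRUE)]
  for (x in ord) {
    pe <- ont$parents[[x]]
    if (is.null(pe) || length(pe$parent) == 0) next
    w <- unname(params$weights[pe$relation])
    w[is.na(w)] <- min(params$weights)
    for (j in seq_along(pe$parent)) {
      p <- pe$parent[j]
      if (p %in% nodes) s[p] <- max(s[p], s[x] * w[j])
    }
  }
  s[is.finite(s)]
}

#' Semantic similarity of two ontology terms (Wang measure)
#'
#' The similarity is the summed semantic contributions of the common
#' ancestors of both terms, `sum(S1[a] + S2[a])`, divided by the total
#' semantic values `SV(t1) + SV(t2)`.
#'
#' @param ont An [ontology].
#' @param t1,t2 Term ids.
#' @param params [sim_params()].
#' @return Similarity in [0, 1].
#' @export
term_similarity <- function(ont, t1, t2, params = sim_params()) {
  s1 <- wang_svalues(ont, t1, params)
  s2 <- wang_svalues(ont, t2, params)
  common <- intersect(names(s1), names(s2))
  if (length(common) == 0) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# term x term similarity matrix with cached S-values
.term_sim_matrix <- function(ont, terms, params = sim_params()) {
  terms <- unique(terms)
  sv <- lapply(terms, wang_svalues, ont = ont, params = params)
  names(sv) <- terms
  tot <- vapply(sv, sum, 0)
  n <- length(terms)
  S <- diag(1, n)
  dimnames(S) <- list(terms, terms)
  if (n < 2) return(S)
  for (i in 1:(n - 1)) {
    si <- sv[[i]]
    for (j in (i + 1):n) {
      sj <- sv[[j]]
      common <- intersect(names(si), names(sj))
      val <- if (length(common) == 0) 0 else {
        sum(si[common] + sj[common]) / (tot[i] + tot[j])
      }
      S[i, j] <- val
      S[j, i] <- val
    }
  }
  S
}

# best-match average of a term-similarity block
.bma <- function(block) {
  (mean(apply(block, 1, max)) + mean(apply(block, 2, max))) / 2
}

#' Functional similarity of two orthogroups (best-match average)
#'
#' Mean over each orthogroup's terms of the best Wang similarity in the
#' other orthogroup's term set, averaged over both directions.
#'
#' @param annotations Long tibble `og`, `term`.
#' @param og1,og2 Orthogroup ids; both must be annotated.
#' @param ont An [ontology].
#' @param params [sim_params()].
#' @return Similarity in [0, 1].
#' @export
og_similarity <- function(annotations, og1, og2, ont, params = sim_params()) {
  t1 <- unique(annotations$term[annotations$og == og1])
  t2 <- unique(annotations$term[annotations$og == og2])
  if (length(t1) == 0 || length(t2) == 0) {
    rlang::abort(
      paste0("unannotated orthogroup: ", if (length(t1) == 0) og1 else og2),
      class = "famdyn_validation_error"
    )
  }
  S <- .term_sim_matrix(ont, union(t1, t2), params)
  .bma(S[t1, t2, drop = FALSE])
}

#' Pairwise orthogroup similarity matrix
#'
#' Wang/best-match-average similarity for every pair of annotated
#' orthogroups; unannotated ones are excluded and listed in the
#' `"excluded"` attribute rather than silently scored 0.
#'
#' @param annotations Long tibble `og`, `term`.
#' @param ogs Orthogroup ids to include.
#' @param ont An [ontology].
#' @param params [sim_params()].
#' @return Symmetric numeric matrix in [0, 1] with unit diagonal, row and
#'   column names = annotated orthogroups.
#' @export
og_similarity_matrix <- function(annotations, ogs, ont, params = sim_params()) {
  ogs <- unique(ogs)
  ann <- annotations[annotations$og %in% ogs, , drop = FALSE]
  annotated <- intersect(ogs, unique(ann$og))
  excluded <- setdiff(ogs, annotated)
  term_sets <- split(ann$term, ann$og)[annotated]
  term_sets <- lapply(term_sets, unique)
  S <- .term_sim_matrix(ont, unique(unlist(term_sets)), params)
  n <- length(annotated)
  M <- diag(1, n)
  dimnames(M) <- list(annotated, annotated)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        v <- .bma(S[term_sets[[i]], term_sets[[j]], drop = FALSE])
        M[i, j] <- v
        M[j, i] <- v
      }
    }
  }
  attr(M, "excluded") <- excluded
  M
}

#' Single representative term for an orthogroup's annotation set
#'
#' Two steps: keep the three deepest terms (depth = longest path to a root,
#' ties broken by term id; sets of fewer than three terms are kept whole),
#' then greedily merge terms whose pairwise Wang similarity is at least
#' `threshold` and return the representative of the largest group -- its
#' deepest member, ties broken toward the lexicographically smallest id.
#'
#' @param terms Non-empty character vector of term ids.
#' @param ont An [ontology].
#' @param threshold Similarity merge threshold (default 0.95).
#' @param params [sim_params()].
#' @return A single term id.
#' @export
reduced_term <- function(terms, ont, threshold = 0.95, params = sim_params()) {
  terms <- unique(terms)
  if (length(terms) == 0) {
    rlang::abort("empty term set", class = "famdyn_validation_error")
  }
  bad <- setdiff(terms, ont$terms$id)
  if (length(bad) > 0) {
    rlang::abort(paste0("unknown terms: ", paste(bad, collapse = ", ")),
      class = "famdyn_validation_error"
    )
  }
  ord <- terms[order(-ont$depth[terms], terms)]
  keep <- utils::head(ord, 3)
  if (length(keep) == 1) return(keep)
  S <- .term_sim_matrix(ont, keep, params)
  # greedy single-linkage grouping at the threshold
  group <- seq_along(keep)
  for (i in 1:(length(keep) - 1)) {
    for (j in (i + 1):length(keep)) {
      if (S[keep[i], keep[j]] >= threshold) {
        group[group == group[j]] <- group[i]
      }
    }
  }
  sizes <- table(group)
  best_groups <- as.integer(names(sizes)[sizes == max(sizes)])
  rep_of <- function(g) {
    members <- keep[group == g]
    members[order(-ont$depth[members], members)][1]
  }
  reps <- vapply(best_groups, rep_of, "")
  sort(reps)[1]
}
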