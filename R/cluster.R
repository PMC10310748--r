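#' Similarity-to-distance transform
#'
#' @param sim Symmetric similarity matrix in [0, 1].
#' @return Distance matrix `1 - sim` with zero diagonal.
#' @export
to_distance <- function(sim) {
  d <- 1 - sim
  diag(d) <- 0
  d
}

#' Classical (metric) multidimensional scaling
#'
#' Double-centers `-0.5 * D^2`, eigendecomposes, and returns the top-`dims`
#' coordinates scaled by the square roots of the eigenvalues (negative
#' eigenvalues from non-Euclidean distances are clamped to zero with a
#' warning). Thin wrapper over [stats::cmdscale()].
#'
#' @param dist Square symmetric distance matrix with zero diagonal.
#' @param dims Embedding dimension (default 2; must be < n).
#' @return An `mds_embedding`: list with `coords` tibble (`item`, `x`, `y`,
#'   ...), `eigenvalues` (descending), and `variance_fraction` explained by
#'   the retained axes.
#' @export
mds_embed <- function(dist, dims = 2) {
  n <- nrow(dist)
  if (dims > n - 1) {
    rlang::abort("dims must be <= n - 1", class = "famdyn_validation_error")
  }
  fit <- stats::cmdscale(stats::as.dist(dist), k = dims, eig = TRUE)
  ev <- sort(fit$eig, decreasing = TRUE)
  if (any(ev < -1e-8 * max(abs(ev), 1e-300))) {
    rlang::warn("negative eigenvalues clamped to zero (non-Euclidean distances)")
  }
  pts <- fit$points
  if (ncol(pts) < dims) { # degenerate configurations
    pts <- cbind(pts, matrix(0, n, dims - ncol(pts)))
  }
  axis_names <- paste0("dim", seq_len(dims))
  axis_names[1] <- "x"
  if (dims >= 2) axis_names[2] <- "y"
  coords <- tibble::as_tibble(pts, .name_repair = ~axis_names)
  coords <- dplyr::bind_cols(
    tibble::tibble(item = rownames(dist) %||% as.character(seq_len(n))),
    coords
  )
  pos <- pmax(ev, 0)
  structure(
    list(
      coords = coords,
      eigenvalues = ev,
      variance_fraction = if (sum(pos) > 0) sum(pos[seq_len(dims)]) / sum(pos) else 0
    ),
    class = "mds_embedding"
  )
}

#' Affinity-propagation clustering
#'
#' Standard responsibility/availability message passing on a similarity
#' matrix with damping. Exemplars are the points whose self
#' responsibility + availability is positive at convergence; every point is
#' assigned to its most similar exemplar (ties broken by index). Fully
#' deterministic: no symmetry-breaking noise is added.
#'
#' @param sim Square similarity matrix.
#' @param preference Per-point preference (diagonal of the working
#'   similarity); scalar or vector. Default: median off-diagonal similarity.
#' @param damping Damping factor in [0.5, 1).
#' @param max_iter Iteration cap.
#' @param convergence_window Iterations the exemplar set must stay unchanged.
#' @return An `ap_result`: tibble `assignment` (`item`, `cluster`,
#'   `exemplar`, `is_exemplar`), `exemplars`, `converged`, `iterations`,
#'   `net_similarity`.
#' @export
affinity_propagation <- function(sim, preference = NULL, damping = 0.9,
                                 max_iter = 1000L, convergence_window = 100L) {
  n <- nrow(sim)
  items <- rownames(sim) %||% as.character(seq_len(n))
  if (n == 1) {
    return(structure(
      list(
        assignment = tibble::tibble(
          item = items, cluster = 1L, exemplar = items, is_exemplar = TRUE
        ),
        exemplars = items, converged = TRUE, iterations = 0L,
        net_similarity = if (is.null(preference)) 0 else preference[1]
      ),
      class = "ap_result"
    ))
  }
  S <- sim
  offdiag <- S[row(S) != col(S)]
  if (is.null(preference)) preference <- stats::median(offdiag)
  # deterministic index-based tie-break: perfectly symmetric inputs (e.g.
  # identical points) otherwise cancel all messages; an infinitesimal
  # preference advantage for earlier indices replaces the random noise the
  # original algorithm uses, keeping results reproducible
  jit <- 1e-9 * max(1e-3, diff(range(S)))
  diag(S) <- rep(preference, length.out = n) + jit * (n:1)

  R <- matrix(0, n, n)
  A <- matrix(0, n, n)
  stable <- 0L
  prev_ex <- integer(0)
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # responsibilities
    AS <- A + S
    max1 <- apply(AS, 1, max)
    which1 <- max.col(AS, ties.method = "first")
    AS2 <- AS
    AS2[cbind(seq_len(n), which1)] <- -Inf
    max2 <- apply(AS2, 1, max)
    Rnew <- S - max1
    Rnew[cbind(seq_len(n), which1)] <- S[cbind(seq_len(n), which1)] - max2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    colsum <- colSums(Rp)
    Anew <- matrix(colsum, n, n, byrow = TRUE) - Rp
    dAnew <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dAnew
    A <- damping * A + (1 - damping) * Anew

    ex <- which(diag(A) + diag(R) > 0)
    if (identical(ex, prev_ex) && length(ex) > 0) {
      stable <- stable + 1L
      if (stable >= convergence_window) break
    } else {
      stable <- 0L
    }
    prev_ex <- ex
  }
  converged <- stable >= convergence_window
  ex <- which(diag(A) + diag(R) > 0)
  if (length(ex) == 0) ex <- which.max(diag(A) + diag(R))
  # assignment to the most similar exemplar (ties -> lowest index)
  assign_idx <- vapply(seq_len(n), function(i) {
    if (i %in% ex) return(i)
    ex[which.max(S[i, ex])]
  }, 0L)
  cluster <- match(assign_idx, sort(unique(assign_idx)))
  net <- sum(S[cbind(seq_len(n), assign_idx)])
  structure(
    list(
      assignment = tibble::tibble(
        item = items, cluster = as.integer(cluster),
        exemplar = items[assign_idx], is_exemplar = seq_len(n) %in% ex
      ),
      exemplars = items[sort(unique(assign_idx))],
      converged = converged, iterations = iter, net_similarity = net
    ),
    class = "ap_result"
  )
}

#' @export
print.ap_result <- function(x, ...) {
  cat(sprintf(
    "<ap_result> %d items, %d clusters, converged %s (%d iterations)\n",
    nrow(x$assignment), length(x$exemplars), x$converged, x$iterations
  ))
  invisible(x)
}

#' Functional-convergence clusters of lineage-exclusive orthogroups
#'
#' The machinery behind "constellation" views of convergent evolution:
#' lineage-exclusive orthogroups are scored for pairwise functional
#' similarity (Wang / best-match average), clustered by affinity
#' propagation on the similarity matrix, labelled by the exemplar's
#' [reduced_term()], and embedded in 2-D with classical MDS on `1 - sim`
#' for display.
#'
#' @param exclusive Named list `lineage -> orthogroup ids` (typically the
#'   `exclusive` field of an [overlap_report()]).
#' @param annotations Long tibble `og`, `term`.
#' @param ont An [ontology].
#' @param changes Optional [branch_changes()] table used to attach total
#'   gains/losses per orthogroup and to apply `min_gains`.
#' @param min_gains Keep only orthogroups with more than `min_gains` total
#'   gene gains (`NULL` keeps all); mirrors restricting a large expanded
#'   set to multi-gain families.
#' @param params [sim_params()].
#' @param preference,damping Passed to [affinity_propagation()]. The
#'   default preference here is `min(sim) - 2 * diff(range(sim))` (over
#'   off-diagonal similarities): functional-convergence clusters are broad
#'   thematic units, and the median-preference convention splits them into
#'   sub-theme fragments.
#' @return A `functional_clusters` object: tibbles `clusters` (`og`,
#'   `lineage`, `cluster`, `is_exemplar`, `representative_term`,
#'   `term_name`, `gains`, `losses`, `x`, `y`), `stats` (per cluster), the
#'   `embedding`, the `ap` result, and `excluded` (unannotated orthogroups).
#' @export
build_clusters <- function(exclusive, annotations, ont, changes = NULL,
                           min_gains = NULL, params = sim_params(),
                           preference = NULL, damping = 0.9) {
  lineage_of <- dplyr::bind_rows(lapply(names(exclusive), function(l) {
    tibble::tibble(og = exclusive[[l]], lineage = l)
  }))
  ogs <- lineage_of$og
  gl <- NULL
  if (!is.null(changes)) {
    gl <- changes %>%
      dplyr::filter(.data$og %in% ogs) %>%
      dplyr::group_by(.data$og) %>%
      dplyr::summarise(
        gains = sum(pmax(.data$delta, 0)),
        losses = sum(pmax(-.data$delta, 0))
      )
    if (!is.null(min_gains)) {
      keep <- gl$og[gl$gains > min_gains]
      ogs <- intersect(ogs, keep)
    }
  }
  annotated <- intersect(ogs, unique(annotations$og))
  if (length(annotated) == 0) {
    rlang::warn("no annotated orthogroups to cluster")
    return(structure(
      list(
        clusters = tibble::tibble(), stats = tibble::tibble(),
        embedding = NULL, ap = NULL, excluded = ogs
      ),
      class = "functional_clusters"
    ))
  }
  M <- og_similarity_matrix(annotations, annotated, ont, params)
  if (is.null(preference) && nrow(M) > 1) {
    # broad-theme granularity: the cost of an extra exemplar must scale
    # with typical cluster size, so the preference drops linearly with n
    # (calibrated on planted-theme fixtures of 16..100 orthogroups)
    off <- M[row(M) != col(M)]
    preference <- min(off) - max(0.4, nrow(M) / 30) * diff(range(off))
  }
  ap <- affinity_propagation(M, preference = preference, damping = damping)
  emb <- mds_embed(to_distance(M), dims = min(2, nrow(M) - 1))

  reps <- vapply(ap$exemplars, function(og) {
    reduced_term(unique(annotations$term[annotations$og == og]), ont, params = params)
  }, "")
  rep_tbl <- tibble::tibble(exemplar = ap$exemplars, representative_term = reps) %>%
    dplyr::left_join(
      dplyr::select(ont$terms, representative_term = "id", term_name = "name"),
      by = "representative_term"
    )
  clusters <- ap$assignment %>%
    dplyr::rename(og = "item") %>%
    dplyr::left_join(rep_tbl, by = "exemplar") %>%
    dplyr::left_join(lineage_of, by = "og") %>%
    dplyr::left_join(emb$coords, by = c(og = "item"))
  if (!is.null(gl)) clusters <- dplyr::left_join(clusters, gl, by = "og")
  stats <- clusters %>%
    dplyr::group_by(.data$cluster, .data$exemplar, .data$representative_term) %>%
    dplyr::summarise(n_og = dplyr::n(), n_lineages = dplyr::n_distinct(.data$lineage), .groups = "drop")
  structure(
    list(
      clusters = clusters, stats = stats, embedding = emb, ap = ap,
      excluded = c(setdiff(lineage_of$og, ogs), setdiff(ogs, annotated)),
      n_clusters = length(ap$exemplars),
      ogs_per_cluster = nrow(clusters) / max(1L, length(ap$exemplars))
    ),
    class = "functional_clusters"
  )
}

#' @export
print.functional_clusters <- function(x, ...) {
  cat(sprintf(
    "<functional_clusters> %d orthogroups in %d clusters (%.1f per cluster)\n",
    nrow(x$clusters), x$n_clusters, x$ogs_per_cluster
  ))
  invisible(x)
}

#' @rdname glance
#' @param x A `functional_clusters` object.
#' @export
glance.functional_clusters <- function(x, ...) {
  tibble::tibble(
    n_og = nrow(x$clusters), n_clusters = x$n_clusters,
    ogs_per_cluster = x$ogs_per_cluster,
    converged = if (is.null(x$ap)) NA else x$ap$converged
  )
}

#' Constellation plot of functional clusters
#'
#' @param object A `functional_clusters` object.
#' @param ... Unused.
#' @return A ggplot: MDS coordinates, points sized by total gains + losses
#'   where available, coloured by cluster, exemplars highlighted.
#' @export
autoplot.functional_clusters <- function(object, ...) {
  cl <- object$clusters
  if (nrow(cl) == 0) return(ggplot2::ggplot())
  if (!"gains" %in% names(cl)) cl$gains <- 0
  if (!"losses" %in% names(cl)) cl$losses <- 0
  cl$events <- cl$gains + cl$losses
  ggplot2::ggplot(cl, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(
      colour = factor(.data$cluster),
      size = .data$events
    ), alpha = 0.7) +
    ggplot2::geom_point(
      data = cl[cl$is_exemplar, ],
      shape = 5, size = 4, stroke = 1
    ) +
    ggplot2::labs(
      x = "MDS 1", y = "MDS 2", colour = "cluster", size = "gains + losses"
    ) +
    ggplot2::theme_minimal()
}

#' Adjusted Rand index between two labelings
#'
#' Used to score recovery of planted functional themes by the clustering.
#'
#' @param a,b Equal-length label vectors.
#' @return The adjusted Rand index (1 = identical partitions, ~0 = chance).
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
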