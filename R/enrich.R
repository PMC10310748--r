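#' Two-tailed Fisher exact test p-value for a 2x2 table
#'
#' Sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (the standard two-sided Fisher test, via [stats::fisher.test()]).
#'
#' @param a,b,c,d Nonnegative integer cell counts: `a` query hits, `b` query
#'   misses, `c` background-minus-query hits, `d` its misses.
#' @return p-value in [0, 1].
#' @export
fisher_two_tailed <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    rlang::abort("cell counts must be nonnegative integers",
      class = "famdyn_validation_error"
    )
  }
  p <- stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
  min(max(p, 0), 1) # guard rounding slightly outside [0, 1]
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment `q_(i) = min_{j >= i} (m * p_(j) / j)`, returned
#' in the input order (via [stats::p.adjust()]).
#'
#' @param pvals Vector of p-values in [0, 1].
#' @return q-values in [0, 1], same order as the input.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    rlang::abort("p-values must lie in [0, 1]", class = "famdyn_validation_error")
  }
  stats::p.adjust(pvals, method = "BH")
}

# propagate annotations to all ancestors (true-path rule)
propagate_annotations <- function(annotations, ont) {
  anc_cache <- new.env(parent = emptyenv())
  get_anc <- function(term) {
    if (!is.null(anc_cache[[term]])) return(anc_cache[[term]])
    a <- term_ancestors(ont, term)
    anc_cache[[term]] <- a
    a
  }
  extra <- lapply(unique(annotations$term), function(t) {
    a <- get_anc(t)
    if (length(a) == 0) return(NULL)
    tibble::tibble(term = t, ancestor = a)
  })
  extra <- dplyr::bind_rows(extra)
  up <- if (is.null(extra) || nrow(extra) == 0) {
    annotations[0, ]
  } else {
    annotations %>%
      dplyr::inner_join(extra, by = "term", relationship = "many-to-many") %>%
      dplyr::transmute(.data$og, term = .data$ancestor)
  }
  dplyr::distinct(dplyr::bind_rows(annotations, up))
}

#' GO-term enrichment of a query orthogroup list
#'
#' Two-tailed Fisher tests of every term against a background set, with
#' true-path propagation of annotations to ancestor terms before counting
#' and Benjamini-Hochberg correction across all tested terms. Terms with
#' fewer than `min_count` query hits are not tested.
#'
#' @param query Orthogroup ids (must be a subset of `background`, non-empty).
#' @param background Orthogroup ids forming the branch-specific background
#'   (e.g. families present at the branch that carry annotations).
#' @param annotations Long tibble `og`, `term`.
#' @param ont An [ontology].
#' @param q_cut Significance cutoff on the q-value (default 0.01).
#' @param min_count Minimum query hits for a term to be tested (default 2).
#' @param propagate Apply the true-path rule (default TRUE).
#' @return Tibble: `term`, `name`, `a`, `b`, `c`, `d`, `p`, `q`,
#'   `direction` ("over"/"under"), `significant`, sorted by `q`.
#' @export
go_enrichment <- function(query, background, annotations, ont,
                          q_cut = 0.01, min_count = 2L, propagate = TRUE) {
  query <- unique(query)
  background <- unique(background)
  if (length(query) == 0) {
    rlang::abort("empty query set", class = "famdyn_validation_error")
  }
  if (length(setdiff(query, background)) > 0) {
    rlang::abort("query must be a subset of the background",
      class = "famdyn_validation_error"
    )
  }
  ann <- annotations[annotations$og %in% background, , drop = FALSE]
  if (propagate) ann <- propagate_annotations(ann, ont)
  n_query <- length(query)
  n_bg <- length(background)
  counts <- ann %>%
    dplyr::group_by(.data$term) %>%
    dplyr::summarise(
      a = sum(unique(.data$og) %in% query),
      hits_bg = dplyr::n_distinct(.data$og)
    ) %>%
    dplyr::filter(.data$a >= min_count)
  if (nrow(counts) == 0) {
    return(tibble::tibble(
      term = character(0), name = character(0), a = integer(0), b = integer(0),
      c = integer(0), d = integer(0), p = numeric(0), q = numeric(0),
      direction = character(0), significant = logical(0)
    ))
  }
  counts <- counts %>%
    dplyr::mutate(
      b = n_query - .data$a,
      c = .data$hits_bg - .data$a,
      d = (n_bg - n_query) - .data$c
    )
  counts$p <- vapply(seq_len(nrow(counts)), function(i) {
    fisher_two_tailed(counts$a[i], counts$b[i], counts$c[i], counts$d[i])
  }, 0)
  counts$q <- bh_adjust(counts$p)
  counts %>%
    dplyr::mutate(
      direction = ifelse(
        .data$a / n_query >= .data$hits_bg / n_bg, "over", "under"
      ),
      significant = .data$q <= q_cut
    ) %>%
    dplyr::left_join(dplyr::select(ont$terms, term = "id", "name"), by = "term") %>%
    dplyr::select(
      "term", "name", "a", "b", "c", "d", "p", "q", "direction", "significant"
    ) %>%
    dplyr::arrange(.data$q, .data$p, .data$term)
}
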