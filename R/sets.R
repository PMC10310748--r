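#' Venn-style overlap report across lineage orthogroup sets
#'
#' Exact finite-set algebra over two or more named orthogroup sets: every
#' non-empty Venn cell, per-lineage set sizes, per-lineage exclusive sets,
#' and the "parallel" set (orthogroups shared by two or more lineages).
#'
#' @param sets Named list (>= 2 entries) of character vectors of orthogroup
#'   ids.
#' @param category Optional label carried through (e.g. `"expanded"`).
#' @return An `overlap_report`: list with tibbles `cells` (`combination` in
#'   lexicographic lineage order, `n_lineages`, `n`, list column `ogs`),
#'   `sizes`, `membership` (`og`, `lineages`, `n_lineages`, `parallel`),
#'   `exclusive` and `parallel`.
#' @export
overlap_report <- function(sets, category = NA_character_) {
  if (length(sets) < 2 || is.null(names(sets)) || any(names(sets) == "")) {
    rlang::abort("overlap_report needs >= 2 named lineage sets",
      class = "famdyn_validation_error"
    )
  }
  lin <- sort(names(sets))
  sets <- lapply(sets[lin], unique)
  universe <- sort(unique(unlist(sets)))
  memb <- vapply(lin, function(l) universe %in% sets[[l]], logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, lin))
  combo <- apply(memb, 1, function(r) paste(lin[r], collapse = "&"))
  n_lin <- rowSums(memb)
  membership <- tibble::tibble(
    og = universe, lineages = combo, n_lineages = as.integer(n_lin),
    parallel = n_lin >= 2
  )
  cells <- membership %>%
    dplyr::group_by(combination = .data$lineages) %>%
    dplyr::summarise(
      n_lineages = .data$n_lineages[1],
      n = dplyr::n(),
      ogs = list(sort(.data$og)),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$combination)
  sizes <- tibble::tibble(
    lineage = lin,
    n = vapply(sets, length, 0L),
    n_exclusive = vapply(lin, function(l) {
      sum(memb[, l] & n_lin == 1)
    }, 0L)
  )
  exclusive <- lapply(lin, function(l) sort(universe[memb[, l] & n_lin == 1]))
  names(exclusive) <- lin
  structure(
    list(
      category = category, cells = cells, sizes = sizes,
      membership = membership, exclusive = exclusive,
      parallel = sort(universe[n_lin >= 2]),
      all_shared = sort(universe[n_lin == length(lin)])
    ),
    class = "overlap_report"
  )
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "<overlap_report%s> %d lineages, %d orthogroups, %d parallel (>=2), %d shared by all\n",
    if (is.na(x$category)) "" else paste0(" ", x$category),
    nrow(x$sizes), nrow(x$membership), length(x$parallel), length(x$all_shared)
  ))
  print(x$cells[, c("combination", "n")])
  invisible(x)
}

#' @rdname tidy
#' @param x An `overlap_report`.
#' @export
tidy.overlap_report <- function(x, ...) {
  dplyr::select(x$cells, "combination", "n_lineages", "n")
}

#' Parallel-evolution report for one event category
#'
#' Builds the per-lineage orthogroup sets for `category` from per-branch
#' lists, runs [overlap_report()], and annotates every parallel orthogroup
#' (shared by two or more lineages) with its representative GO term when an
#' annotation map and ontology are supplied.
#'
#' @param og_lists [branch_og_lists()] output.
#' @param lineages Tibble with columns `lineage`, `branch` (one or more
#'   branches per lineage) and optionally `habitat`.
#' @param category One of `"expanded"`, `"contracted"`, `"gained"`, `"lost"`.
#' @param annotations Optional long annotation tibble (`og`, `term`).
#' @param ont Optional [ontology] for [reduced_term()] labels.
#' @return An `overlap_report` with an extra tibble `parallel_annotated`.
#' @export
parallel_report <- function(og_lists, lineages, category,
                            annotations = NULL, ont = NULL) {
  ok <- c("expanded", "contracted", "gained", "lost")
  if (!category %in% ok) {
    rlang::abort(
      paste0("unknown category '", category, "'"),
      class = "famdyn_validation_error"
    )
  }
  if (length(unique(lineages$lineage)) < 2) {
    rlang::abort("parallel evolution needs >= 2 lineages",
      class = "famdyn_validation_error"
    )
  }
  sets <- lapply(split(lineages$branch, lineages$lineage), function(brs) {
    unique(og_lists$og[og_lists$branch %in% brs & og_lists$category == category])
  })
  rep <- overlap_report(sets, category = category)
  ann <- tibble::tibble(og = rep$parallel)
  if (length(rep$parallel) > 0 && !is.null(annotations) && !is.null(ont)) {
    ann$reduced_term <- vapply(ann$og, function(og) {
      tms <- annotations$term[annotations$og == og]
      if (length(tms) == 0) NA_character_ else reduced_term(tms, ont)
    }, "")
    ann <- dplyr::left_join(ann,
      dplyr::select(ont$terms, reduced_term = "id", term_name = "name"),
      by = "reduced_term"
    )
  }
  rep$parallel_annotated <- dplyr::left_join(
    ann,
    dplyr::select(rep$membership, "og", "lineages", "n_lineages"),
    by = "og"
  )
  rep
}
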