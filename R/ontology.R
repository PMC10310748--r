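#' Construct an ontology object
#'
#' A lightweight directed-acyclic-graph representation of a Gene Ontology
#' style vocabulary: terms with names and namespaces, typed child-to-parent
#' edges (`is_a`, `part_of`), and one or more roots.
#'
#' @param terms Tibble with columns `id`, `name`, `namespace`.
#' @param edges Tibble with columns `child`, `parent`, `relation`.
#' @return An object of class `ontology` with precomputed parent lists,
#'   `depth` (longest path to a root) per term, and `roots`.
#' @export
ontology <- function(terms, edges) {
  terms <- tibble::as_tibble(terms)
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("id", "name", "namespace") %in% names(terms)))
  if (nrow(edges) > 0) {
    stopifnot(all(c("child", "parent", "relation") %in% names(edges)))
    bad <- setdiff(c(edges$child, edges$parent), terms$id)
    if (length(bad) > 0) {
      rlang::abort(
        paste0("edge references unknown terms: ", paste(bad, collapse = ", ")),
        class = "famdyn_validation_error"
      )
    }
  }
  ord <- .topo_sort(terms$id, edges)
  parents <- split(seq_len(nrow(edges)), factor(edges$child, levels = terms$id))
  parents <- lapply(parents, function(idx) {
    list(parent = edges$parent[idx], relation = edges$relation[idx])
  })
  roots <- terms$id[!terms$id %in% edges$child]
  depth <- stats::setNames(rep(0L, nrow(terms)), terms$id)
  for (id in ord) { # roots first
    p <- parents[[id]]$parent
    if (length(p) > 0) depth[id] <- max(depth[p]) + 1L
  }
  structure(
    list(
      terms = terms, edges = edges, parents = parents,
      roots = roots, depth = depth, topo = ord
    ),
    class = "ontology"
  )
}

#' @export
print.ontology <- function(x, ...) {
  cat(sprintf(
    "<ontology> %d terms, %d edges, %d root(s), max depth %d\n",
    nrow(x$terms), nrow(x$edges), length(x$roots), max(c(0L, x$depth))
  ))
  invisible(x)
}

# Kahn topological sort, roots first; cycle -> validation error naming one.
.topo_sort <- function(ids, edges) {
  outdeg <- stats::setNames(rep(0L, length(ids)), ids) # edges to parents
  for (p in edges$parent) outdeg[p] <- outdeg[p] # touch
  children <- split(edges$child, factor(edges$parent, levels = ids))
  n_parents <- stats::setNames(rep(0L, length(ids)), ids)
  tab <- table(factor(edges$child, levels = ids))
  n_parents[names(tab)] <- as.integer(tab)
  queue <- ids[n_parents == 0L]
  ord <- character(0)
  np <- n_parents
  while (length(queue) > 0) {
    id <- queue[1]
    queue <- queue[-1]
    ord <- c(ord, id)
    for (ch in children[[id]]) {
      np[ch] <- np[ch] - 1L
      if (np[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(ord) < length(ids)) {
    cyc <- setdiff(ids, ord)
    rlang::abort(
      paste0(
        "ontology contains a cycle involving: ",
        paste(utils::head(cyc, 5), collapse = " -> ")
      ),
      class = "famdyn_validation_error"
    )
  }
  ord
}

#' All ancestors of a term (excluding itself)
#'
#' @param ont An [ontology].
#' @param term Term id.
#' @return Character vector of ancestor ids.
#' @export
term_ancestors <- function(ont, term) {
  if (!term %in% ont$terms$id) {
    rlang::abort(paste0("unknown term: ", term), class = "famdyn_validation_error")
  }
  anc <- character(0)
  frontier <- term
  while (length(frontier) > 0) {
    ps <- unique(unlist(lapply(frontier, function(t) ont$parents[[t]]$parent)))
    ps <- setdiff(ps, anc)
    anc <- c(anc, ps)
    frontier <- ps
  }
  anc
}

#' Read a minimal OBO 1.2 ontology
#'
#' Supports `[Term]` stanzas with `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of` and `is_obsolete`; obsolete terms are dropped and
#' all other tags are ignored (a count of ignored tags is reported).
#'
#' @param path OBO file path.
#' @param namespace Keep only this namespace (default
#'   `"biological_process"`); `NULL` keeps everything.
#' @return An [ontology].
#' @export
read_obo <- function(path, namespace = "biological_process") {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- list()
  n_ignored <- 0L
  flush <- function(cur, terms) {
    if (!is.null(cur) && !isTRUE(cur$obsolete) && !is.null(cur$id)) {
      terms[[cur$id]] <- cur
    }
    terms
  }
  for (ln in lines) {
    ln <- sub("!.*$", "", ln)
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[", ln)) {
      terms <- flush(cur, terms)
      in_term <- identical(ln, "[Term]")
      cur <- if (in_term) list(is_a = character(0), part_of = character(0)) else NULL
      next
    }
    if (!in_term) next
    kv <- regmatches(ln, regexec("^([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) < 3) next
    key <- kv[2]
    val <- kv[3]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, trimws(val))
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "relationship") {
      parts <- strsplit(trimws(val), "\\s+")[[1]]
      if (length(parts) >= 2 && parts[1] == "part_of") {
        cur$part_of <- c(cur$part_of, parts[2])
      } else {
        n_ignored <- n_ignored + 1L
      }
    } else {
      n_ignored <- n_ignored + 1L
    }
  }
  terms <- flush(cur, terms)
  if (n_ignored > 0) message(sprintf("read_obo: ignored %d unsupported tags", n_ignored))

  tt <- tibble::tibble(
    id = unname(vapply(terms, function(t) t$id, "")),
    name = unname(vapply(terms, function(t) t$name %||% t$id, "")),
    namespace = unname(vapply(terms, function(t) t$namespace %||% "", ""))
  )
  if (!is.null(namespace)) tt <- tt[tt$namespace == namespace, ]
  keep <- tt$id
  ee <- dplyr::bind_rows(lapply(terms, function(t) {
    if (!(t$id %in% keep)) return(NULL)
    dplyr::bind_rows(
      if (length(t$is_a) > 0) {
        tibble::tibble(child = t$id, parent = t$is_a, relation = "is_a")
      },
      if (length(t$part_of) > 0) {
        tibble::tibble(child = t$id, parent = t$part_of, relation = "part_of")
      }
    )
  }))
  if (is.null(ee) || nrow(ee) == 0) {
    ee <- tibble::tibble(child = character(0), parent = character(0), relation = character(0))
  } else {
    ee <- ee[ee$parent %in% keep, ]
  }
  ontology(tt, ee)
}

#' Write an ontology in the minimal OBO dialect
#'
#' @param ont An [ontology].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(ont$terms))) {
    id <- ont$terms$id[i]
    writeLines("[Term]", con)
    writeLines(paste0("id: ", id), con)
    writeLines(paste0("name: ", ont$terms$name[i]), con)
    writeLines(paste0("namespace: ", ont$terms$namespace[i]), con)
    pe <- ont$parents[[id]]
    if (!is.null(pe) && length(pe$parent) > 0) {
      for (j in seq_along(pe$parent)) {
        if (pe$relation[j] == "is_a") {
          writeLines(paste0("is_a: ", pe$parent[j]), con)
        } else {
          writeLines(paste0("relationship: ", pe$relation[j], " ", pe$parent[j]), con)
        }
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
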