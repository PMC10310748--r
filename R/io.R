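#' Read an orthogroup-by-taxon count table
#'
#' Expects a TSV with a header row of taxon ids and a first column of
#' orthogroup ids; all cells must be nonnegative integers.
#'
#' @param path TSV file path.
#' @param tree Optional `phylo`; when given, the taxon set must exactly match
#'   the tree's tips.
#' @return A tibble with column `og` followed by one integer column per taxon.
#' @export
read_counts <- function(path, tree = NULL) {
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  names(tb)[1] <- "og"
  tb$og <- as.character(tb$og)
  validate_counts(tb, tree)
}

#' Validate a count table
#'
#' @param counts Tibble with `og` column plus taxon columns.
#' @inheritParams read_counts
#' @return The validated tibble with integer count columns.
#' @export
validate_counts <- function(counts, tree = NULL) {
  if (names(counts)[1] != "og") names(counts)[1] <- "og"
  if (anyDuplicated(counts$og)) {
    rlang::abort("duplicate orthogroup ids", class = "famdyn_validation_error")
  }
  taxa <- names(counts)[-1]
  for (tx in taxa) {
    v <- counts[[tx]]
    if (!is.numeric(v) || any(is.na(v)) || any(v < 0) || any(v != floor(v))) {
      rlang::abort(
        paste0("counts for taxon '", tx, "' must be nonnegative integers"),
        class = "famdyn_validation_error"
      )
    }
    counts[[tx]] <- as.integer(v)
  }
  if (!is.null(tree)) {
    extra <- setdiff(taxa, tree$tip.label)
    missing <- setdiff(tree$tip.label, taxa)
    if (length(extra) > 0 || length(missing) > 0) {
      rlang::abort(
        paste0(
          "taxon/tip mismatch; only in counts: [",
          paste(extra, collapse = ", "), "], only in tree: [",
          paste(missing, collapse = ", "), "]"
        ),
        class = "famdyn_validation_error"
      )
    }
  }
  counts
}

#' Write a count table
#'
#' @inheritParams validate_counts
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  .write_tsv_stamped(counts, path)
}

# integer matrix (og x taxon) view of a counts tibble
counts_matrix <- function(counts) {
  m <- as.matrix(counts[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- counts$og
  m
}

#' Read orthogroup GO annotations
#'
#' Format: `og<TAB>comma-separated term ids`, one row per orthogroup; rows
#' with an empty term field are allowed and yield no annotation rows.
#'
#' @param path TSV path.
#' @param ontology Optional [ontology] object; when given, term ids are
#'   checked against it.
#' @return A long tibble with columns `og`, `term`.
#' @export
read_annotations <- function(path, ontology = NULL) {
  tb <- readr::read_tsv(path,
    comment = "#", col_names = c("og", "terms"),
    col_types = "cc"
  )
  if (nrow(tb) > 0 && identical(tolower(tb$og[1]), "og")) tb <- tb[-1, ]
  out <- tb %>%
    dplyr::filter(!is.na(.data$terms), .data$terms != "") %>%
    dplyr::mutate(term = strsplit(.data$terms, ",[ ]*")) %>%
    tidyr::unnest("term") %>%
    dplyr::distinct(.data$og, .data$term)
  if (!is.null(ontology)) {
    bad <- setdiff(out$term, ontology$terms$id)
    if (length(bad) > 0) {
      rlang::abort(
        paste0("unknown ontology terms: ", paste(utils::head(bad, 5), collapse = ", ")),
        class = "famdyn_validation_error"
      )
    }
  }
  out
}

#' Write orthogroup GO annotations
#'
#' @param annotations Long tibble with columns `og`, `term`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  wide <- annotations %>%
    dplyr::group_by(.data$og) %>%
    dplyr::summarise(terms = paste(sort(unique(.data$term)), collapse = ","))
  .write_tsv_stamped(wide, path, col_names = FALSE)
}

# all result writers stamp a comment line with tool version + config hash
.write_tsv_stamped <- function(x, path, col_names = TRUE, config_hash = NULL) {
  ver <- as.character(utils::packageVersion("famdyn"))
  hash <- if (is.null(config_hash)) "none" else config_hash
  writeLines(sprintf("# famdyn %s config_hash=%s", ver, hash), path)
  readr::write_tsv(x, path, append = TRUE, col_names = col_names)
  invisible(path)
}
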