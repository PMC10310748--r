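#' Pipeline configuration
#'
#' Everything needed to run the repertoire-dynamics analysis end to end on
#' one dataset: the inputs (in memory or as paths), the branch-class and
#' lineage structure, per-stage parameters, and one global seed from which
#' all per-stage seeds are derived by fixed offsets.
#'
#' @param tree `phylo` or path to a Newick file.
#' @param counts Count tibble or TSV path.
#' @param annotations Long annotation tibble or TSV path (optional; the
#'   similarity/enrichment stages need it).
#' @param ont [ontology] or OBO path (optional, as above).
#' @param fit_classes Branch-class assignment for the SR fits (exactly one
#'   foreground class, e.g. `list(subterranean = c(...))`).
#' @param lineages Tibble `lineage`, `branch`, optional `habitat` mapping
#'   each independent transition to its branch(es).
#' @param scope_tips Optional tip subset: prune the tree (and counts) to
#'   this clade before any analysis.
#' @param threshold Delta-AIC significance threshold.
#' @param control [fit_control()] for the per-orthogroup fits.
#' @param q_cut,min_count Enrichment parameters.
#' @param min_gains Multi-gain restriction applied before clustering
#'   (`NULL` = keep all).
#' @param seed Global integer seed.
#' @param truth Optional list with simulation truth (`og_truth`,
#'   `node_states`, `themes`) enabling recovery metrics in the run report.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(tree, counts, annotations = NULL, ont = NULL,
                            fit_classes, lineages, scope_tips = NULL,
                            threshold = 2, control = fit_control(),
                            q_cut = 0.01, min_count = 2L, min_gains = NULL,
                            seed = 1L, truth = NULL) {
  if (is.character(tree)) tree <- read_newick(tree)
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(annotations)) annotations <- read_annotations(annotations)
  if (is.character(ont)) ont <- read_obo(ont)
  cfg <- structure(
    list(
      tree = tree, counts = counts, annotations = annotations, ont = ont,
      fit_classes = fit_classes, lineages = tibble::as_tibble(lineages),
      scope_tips = scope_tips, threshold = threshold, control = control,
      q_cut = q_cut, min_count = min_count, min_gains = min_gains,
      seed = as.integer(seed), truth = truth
    ),
    class = "pipeline_config"
  )
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration before any computation
#'
#' @param config A `pipeline_config`.
#' @return The config, invisibly usable; errors on unresolved branch ids or
#'   taxon mismatches.
#' @export
validate_pipeline_config <- function(config) {
  tree <- config$tree
  counts <- config$counts
  if (!is.null(config$scope_tips)) {
    tree <- prune_tree(tree, config$scope_tips)
    missing <- setdiff(tree$tip.label, names(counts))
    if (length(missing) > 0) {
      rlang::abort(
        paste0("counts lack scope taxa: ", paste(missing, collapse = ", ")),
        class = "famdyn_validation_error"
      )
    }
    counts <- counts[, c("og", tree$tip.label)]
  }
  branch_classes(tree, config$fit_classes) # errors on unknown branches
  valid <- tree_branches(tree)$branch
  bad <- setdiff(config$lineages$branch, valid)
  if (length(bad) > 0) {
    rlang::abort(
      paste0("lineage branch ids not in tree: ", paste(bad, collapse = ", ")),
      class = "famdyn_validation_error"
    )
  }
  validate_counts(counts, tree)
  config
}

# stage seeds fan out from the global seed by fixed offsets
.stage_seed <- function(seed, stage) {
  offs <- c(simulate = 101L, fit = 211L, ancestral = 307L, converge = 401L)
  (seed + offs[[stage]]) %% .Machine$integer.max
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: per-orthogroup GR/SR fits and significance
#' calls; ancestral reconstruction and per-branch change parsing; parallel
#' overlap reports across lineages; functional-convergence clustering of
#' lineage-exclusive orthogroups; GO enrichment per lineage branch. Each
#' stage's tables are written to `out_dir` as TSV when given, and a run
#' report of the headline quantities is produced. When the config carries
#' simulation truth, recovery metrics (power, false-positive rate, parallel
#' recall, theme adjusted Rand index) are added to the report.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for the stage tables.
#' @return A `famdyn_pipeline` list: `calls`, `call_summary`, `states`,
#'   `changes`, `summary` (per branch), `og_lists`, `overlaps` (per
#'   category), `clusters` (expanded and contracted), `enrichment`,
#'   `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  config <- validate_pipeline_config(config)
  tree <- config$tree
  counts <- config$counts
  if (!is.null(config$scope_tips)) {
    tree <- prune_tree(tree, config$scope_tips)
    counts <- counts[, c("og", tree$tip.label)]
    keep <- rowSums(counts[, -1]) > 0
    counts <- counts[keep, , drop = FALSE]
  }
  hash <- substr(rlang::hash(config[setdiff(names(config), "truth")]), 1, 12)
  emit <- function(x, name) {
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      .write_tsv_stamped(x, file.path(out_dir, name), config_hash = hash)
    }
    x
  }

  # -- fit --------------------------------------------------------------
  calls <- fit_all(tree, counts, config$fit_classes,
    threshold = config$threshold, control = config$control,
    seed = .stage_seed(config$seed, "fit")
  )
  emit(calls, "calls.tsv")
  call_summary <- emit(summarize_calls(calls), "call_summary.tsv")

  # -- ancestral --------------------------------------------------------
  states <- ancestral_states(tree, counts, calls, config$fit_classes)
  emit(states, "ancestral_states.tsv")
  changes <- emit(branch_changes(states, tree), "branch_changes.tsv")
  summary_tbl <- emit(branch_summary(changes, tree), "branch_summary.tsv")
  og_lists <- emit(
    branch_og_lists(changes, unique(config$lineages$branch), tree),
    "og_lists.tsv"
  )

  # -- compare (parallel vs exclusive) ----------------------------------
  overlaps <- list()
  for (cat in c("expanded", "contracted")) {
    overlaps[[cat]] <- parallel_report(
      og_lists, config$lineages, cat,
      annotations = config$annotations, ont = config$ont
    )
    emit(tidy(overlaps[[cat]]), paste0("overlap_", cat, ".tsv"))
  }

  # -- converge ---------------------------------------------------------
  clusters <- list()
  if (!is.null(config$annotations) && !is.null(config$ont)) {
    for (cat in c("expanded", "contracted")) {
      excl <- overlaps[[cat]]$exclusive
      if (sum(lengths(excl)) >= 2) {
        clusters[[cat]] <- build_clusters(
          excl, config$annotations, config$ont,
          changes = changes, min_gains = config$min_gains
        )
        if (nrow(clusters[[cat]]$clusters) > 0) {
          emit(clusters[[cat]]$clusters, paste0("clusters_", cat, ".tsv"))
          emit(clusters[[cat]]$stats, paste0("cluster_stats_", cat, ".tsv"))
        }
      }
    }
  }

  # -- enrich -----------------------------------------------------------
  enrichment <- NULL
  if (!is.null(config$annotations) && !is.null(config$ont)) {
    annotated <- unique(config$annotations$og)
    present <- states %>%
      dplyr::filter(.data$state > 0) %>%
      dplyr::select("og", "node")
    enr <- list()
    for (i in seq_len(nrow(config$lineages))) {
      br <- config$lineages$branch[i]
      lin <- config$lineages$lineage[i]
      bg <- intersect(present$og[present$node == br], annotated)
      for (cat in c("expanded", "contracted")) {
        q <- intersect(
          og_lists$og[og_lists$branch == br & og_lists$category == cat], bg
        )
        if (length(q) == 0) next
        res <- go_enrichment(q, bg, config$annotations, config$ont,
          q_cut = config$q_cut, min_count = config$min_count
        )
        if (nrow(res) > 0) {
          enr[[paste(lin, cat, sep = "_")]] <- dplyr::bind_cols(
            tibble::tibble(
              lineage = lin, branch = br, category = cat
            )[rep(1, nrow(res)), ], res
          )
        }
      }
    }
    enrichment <- dplyr::bind_rows(enr)
    if (!is.null(enrichment) && nrow(enrichment) > 0) emit(enrichment, "enrichment.tsv")
  }

  report <- .pipeline_report(config, calls, call_summary, overlaps, clusters)
  emit(report, "run_report.tsv")

  structure(
    list(
      tree = tree, calls = calls, call_summary = call_summary,
      states = states, changes = changes, summary = summary_tbl,
      og_lists = og_lists, overlaps = overlaps, clusters = clusters,
      enrichment = enrichment, report = report, config_hash = hash
    ),
    class = "famdyn_pipeline"
  )
}

# headline quantities + truth-recovery metrics when truth is available
.pipeline_report <- function(config, calls, call_summary, overlaps, clusters) {
  rep <- call_summary
  for (cat in names(overlaps)) {
    ov <- overlaps[[cat]]
    rep[[paste0("n_parallel_", cat)]] <- length(ov$parallel)
    rep[[paste0("n_exclusive_", cat)]] <- sum(lengths(ov$exclusive))
  }
  for (cat in names(clusters)) {
    cl <- clusters[[cat]]
    rep[[paste0("n_clusters_", cat)]] <- cl$n_clusters
    rep[[paste0("ogs_per_cluster_", cat)]] <- cl$ogs_per_cluster
  }
  tr <- config$truth
  if (!is.null(tr) && !is.null(tr$og_truth)) {
    joined <- dplyr::left_join(calls, tr$og_truth, by = "og")
    shifted <- joined$model == "all_foreground"
    null_og <- joined$model == "GR"
    if (any(shifted)) {
      tp <- joined$significant & shifted
      rep$power <- sum(tp) / sum(shifted)
      rep$direction_accuracy <- if (sum(tp) > 0) {
        mean(joined$direction[tp] == "expanded")
      } else {
        NA_real_
      }
      if (!is.null(overlaps$expanded)) {
        rep$parallel_recall <- mean(
          joined$og[shifted] %in% overlaps$expanded$parallel
        )
      }
    }
    if (any(null_og)) rep$fpr <- mean(joined$significant[null_og])
    if (!is.null(tr$themes) && length(clusters) > 0) {
      # theme recovery per category (expanded / contracted clustered
      # separately, as in the analysis), pooled as a size-weighted mean
      aris <- ns <- numeric(0)
      for (x in clusters) {
        cl <- x$clusters
        if (is.null(cl) || nrow(cl) < 2) next
        th <- tr$themes$theme[match(cl$og, tr$themes$og)]
        ok <- !is.na(th)
        if (sum(ok) > 1) {
          aris <- c(aris, adjusted_rand_index(cl$cluster[ok], th[ok]))
          ns <- c(ns, sum(ok))
        }
      }
      if (length(aris) > 0) rep$theme_ari <- sum(aris * ns) / sum(ns)
    }
  }
  rep
}

#' @export
print.famdyn_pipeline <- function(x, ...) {
  cat("<famdyn_pipeline>\n")
  print(as.data.frame(x$report))
  invisible(x)
}

#' Fixed species tree of the synthetic demo study
#'
#' A 12-tip ultrametric tree of height 20 Myr shaped like a three-tribe
#' beetle phylogeny: tribe B (tips B1, Bs1, B2, Bs2) and tribe H (H1,
#' Hs1, Hs2) are the aquatic clade, tribe L (L1, Ls1, L2, L3, Ls2) the
#' terrestrial one. Tips named without an "s" are the six independent
#' subterranean transitions; their terminal branches (10 Myr, except L3
#' at 6 Myr) are the natural foreground class.
#'
#' @return A labelled `phylo` object.
#' @export
demo_tree <- function() {
  txt <- paste0(
    "(((B1:10,Bs1:10):4,(B2:10,Bs2:10):4):6,",
    "((H1:10,(Hs1:6,Hs2:6):4):7,",
    "((L1:10,Ls1:10):4,(L2:10,(L3:6,Ls2:6):4):4):3):3);"
  )
  read_newick(text = txt)
}

#' Synthetic end-to-end demo configuration
#'
#' Builds a complete simulated study emulating a multi-lineage subterranean
#' transition design on the fixed 20-Myr tree of [demo_tree()]: three
#' clades ("tribes") holding six subterranean transition tips -- B1, B2
#' and H1 (aquatic), L1, L2 and L3 (terrestrial) -- whose terminal
#' branches form the foreground class. Orthogroup counts evolve under
#' background BDI rates (0.05, 0.05, 0.02)/Myr with a `shift`-fold birth
#' shift planted either on all six foreground branches (parallel set,
#' `frac_parallel` of families) or on a single lineage (exclusive sets);
#' root counts are drawn from the truncated geometric restricted to 2..4
#' -- families with at least two ancestral copies, since a single-copy
#' family frequently loses its only copy before a birth-rate shift can
#' act on it. A four-theme ontology and theme-planted annotations (5 terms
#' per family, 5% noise) complete the dataset; truth labels for recovery
#' metrics ride along in the config.
#'
#' @param seed Global seed.
#' @param n_og Number of orthogroups (default 200, a desk-scale stand-in
#'   for genome-wide repertoires).
#' @param shift Foreground birth multiplier (default 5).
#' @param frac_parallel Fraction of families shifted on all foreground
#'   branches (default 0.2).
#' @param n_exclusive_per_lineage Families shifted on a single lineage's
#'   branch (default `n_og %/% 20`; background turnover reclassifies a
#'   sizable share of them as parallel, so the exclusive sets that feed
#'   the convergence clustering need headroom).
#' @param control [fit_control()] used downstream.
#' @return A [pipeline_config()] with `truth` attached.
#' @export
demo_config <- function(seed = 1L, n_og = 200L, shift = 5,
                        frac_parallel = 0.2,
                        n_exclusive_per_lineage = max(1L, n_og %/% 20L),
                        control = fit_control()) {
  sim_seed <- .stage_seed(seed, "simulate")
  tree <- demo_tree()
  fg_tips <- c("B1", "B2", "H1", "L1", "L2", "L3")
  lineages <- tibble::tibble(
    lineage = fg_tips,
    branch = fg_tips,
    habitat = c(rep("aquatic", 3), rep("terrestrial", 3))
  )
  sim_classes <- stats::setNames(as.list(fg_tips), lineages$lineage)

  n_par <- round(frac_parallel * n_og)
  n_excl <- n_exclusive_per_lineage
  par_idx <- seq_len(n_par)
  excl_idx <- lapply(1:6, function(j) n_par + (j - 1) * n_excl + seq_len(n_excl))
  shifted <- lapply(1:6, function(j) c(par_idx, excl_idx[[j]]))
  names(shifted) <- lineages$lineage

  sim <- simulate_counts(sim_config(
    n_og = n_og, tree = tree, rates = bdi_rates(0.05, 0.05, 0.02),
    classes = sim_classes,
    shift = stats::setNames(rep(list(c(shift, 1, 1)), 6), lineages$lineage),
    shifted_ogs = shifted, root_min = 2L, root_max = 4L, seed = sim_seed
  ))
  # truth labels: shifted on every foreground branch / one lineage / none
  model <- rep("GR", n_og)
  model[par_idx] <- "all_foreground"
  for (j in 1:6) model[excl_idx[[j]]] <- lineages$lineage[j]
  og_truth <- tibble::tibble(og = sim$counts$og, model = model)

  ont <- simulate_ontology(n_themes = 4, depth = 3, branching = 3)
  theme <- (seq_len(n_og) - 1L) %% 4L + 1L
  for (j in 1:6) theme[excl_idx[[j]]] <- (j - 1L) %% 4L + 1L
  annotations <- simulate_annotations(
    ont, sim$counts$og, theme,
    n_terms_per_og = 5L, noise_rate = 0.05, seed = sim_seed + 1L
  )

  pipeline_config(
    tree = sim$tree, counts = sim$counts, annotations = annotations,
    ont = ont,
    fit_classes = list(subterranean = fg_tips),
    lineages = lineages, control = control, seed = seed,
    truth = list(
      og_truth = og_truth,
      node_states = sim$node_states,
      themes = tibble::tibble(og = sim$counts$og, theme = theme)
    )
  )
}
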