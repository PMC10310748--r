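# shared small fixture: 6-tip tree, two foreground branches
fit_fixture <- local({
  tr <- read_newick(text = "(((A:2,B:2):3,(C:2,D:2):3):4,(E:5,F:5):4);")
  list(tree = tr, classes = list(subterranean = c("A", "C")))
})

test_that("AIC identity and comparison formula", {
  # direct formula check: AIC = 2k - 2 lnL
  gr <- structure(
    list(
      og = "x", kind = "GR", loglik = -100, n_free_parameters = 3L,
      AIC = 2 * 3 - 2 * (-100), converged = TRUE,
      model = rate_model(background = bdi_rates(.1, .1, .1))
    ),
    class = "bdi_fit"
  )
  sr_model <- rate_model(
    background = bdi_rates(.1, .1, .01),
    subterranean = bdi_rates(.3, .1, .01)
  )
  sr <- structure(
    list(
      og = "x", kind = "SR", loglik = -95, n_free_parameters = 6L,
      AIC = 2 * 6 - 2 * (-95), converged = TRUE, model = sr_model
    ),
    class = "bdi_fit"
  )
  expect_equal(gr$AIC, 206)
  expect_equal(sr$AIC, 202)
  cmp <- compare_models(gr, sr, threshold = 2)
  expect_equal(cmp$best_model, "SR")
  expect_true(cmp$significant)
  expect_equal(cmp$delta_aic, 4)
  expect_equal(cmp$direction, "expanded")
  expect_equal(cmp$magnitude, (.3 - .1) - (.1 - .1))

  # identical likelihoods: GR wins on the parameter penalty
  sr2 <- sr
  sr2$loglik <- -100
  sr2$AIC <- 2 * 6 + 200
  cmp2 <- compare_models(gr, sr2)
  expect_equal(cmp2$best_model, "GR")
  expect_false(cmp2$significant)
  expect_equal(cmp2$direction, "none")

  # mismatched orthogroups are rejected
  sr3 <- sr
  sr3$og <- "y"
  expect_error(compare_models(gr, sr3), class = "famdyn_validation_error")
})

test_that("degenerate constant counts drive rates to the lower bound", {
  tr <- fit_fixture$tree
  cts <- stats::setNames(rep(2L, 6), tr$tip.label)
  fit <- fit_bdi(tr, cts,
    kind = "GR", control = fit_control(n_starts = 3),
    prior = "uniform"
  )
  expect_true(fit$converged)
  r <- fit$model$rates$background
  expect_lt(max(r), 1e-4)
  n_max <- fit$n_max
  expect_equal(fit$loglik, log(1 / (n_max + 1)), tolerance = 1e-4)
  # AIC identity holds on the result
  expect_equal(fit$AIC, 2 * fit$n_free_parameters - 2 * fit$loglik)
  # the stationary-prior default can only explain constant data better
  fit2 <- fit_bdi(tr, cts, kind = "GR", control = fit_control(n_starts = 3))
  expect_gte(fit2$loglik, fit$loglik - 1e-8)
})

test_that("optimizer beats a log-rate grid search", {
  tr <- fit_fixture$tree
  sim <- simulate_counts(sim_config(
    n_og = 3, tree = tr, rates = bdi_rates(0.06, 0.04, 0.02), seed = 31
  ))
  for (g in 1:3) {
    cts <- unlist(sim$counts[g, tr$tip.label])
    fit <- fit_bdi(tr, cts, kind = "GR", seed = 2, prior = "uniform")
    model_at <- function(b, d, i) {
      rate_model(background = bdi_rates(b, d, i))
    }
    grid <- expand.grid(
      b = 10^seq(-4, 0, length.out = 5),
      d = 10^seq(-4, 0, length.out = 5),
      i = 10^seq(-4, 0, length.out = 5)
    )
    grid_ll <- max(apply(grid, 1, function(p) {
      bdi_loglik(tr, cts, model_at(p[1], p[2], p[3]), n_max = fit$n_max)
    }))
    expect_gte(fit$loglik, grid_ll - 1e-3)
  }
})

test_that("GR parameter recovery on pooled medians (reduced size)", {
  # deliberately smaller than the headline experiment (40 families, looser
  # bands for the extra median noise); the full-size run lives in the
  # acceptance suite
  sim <- simulate_counts(sim_config(
    n_og = 40, n_tips = 10, tree_height = 200,
    rates = bdi_rates(0.05, 0.05, 0.02),
    root_mean = 2, root_min = 1, root_max = 6, seed = 41
  ))
  ests <- t(sapply(seq_len(40), function(g) {
    cts <- unlist(sim$counts[g, -1])
    unclass(fit_bdi(sim$tree, cts, kind = "GR", seed = g)$model$rates$background)[1:3]
  }))
  med <- apply(ests, 2, median)
  expect_lt(abs(med[1] - 0.05) / 0.05, 0.5)
  expect_lt(abs(med[2] - 0.05) / 0.05, 0.5)
  expect_lt(abs(med[3] - 0.02) / 0.02, 0.8)
})

test_that("fit_all output is order-invariant and complete", {
  sim <- simulate_counts(sim_config(
    n_og = 8, tree = fit_fixture$tree, seed = 51
  ))
  calls <- fit_all(sim$tree, sim$counts, fit_fixture$classes, seed = 9)
  expect_equal(nrow(calls), 8)
  expect_true(all(calls$converged))
  # AIC identities
  expect_equal(calls$aic_gr, 2 * 3 - 2 * calls$loglik_gr, tolerance = 1e-10)
  expect_equal(calls$aic_sr, 2 * 6 - 2 * calls$loglik_sr, tolerance = 1e-10)
  # SR nests GR
  expect_true(all(calls$loglik_sr >= calls$loglik_gr - 0.5))

  # permuting orthogroup rows and taxon columns leaves calls unchanged
  perm <- sim$counts[sample(8), c("og", sample(sim$tree$tip.label))]
  calls2 <- fit_all(sim$tree, perm, fit_fixture$classes, seed = 9)
  j <- dplyr::inner_join(
    calls[, c("og", "significant", "best_model")],
    calls2[, c("og", "significant", "best_model")],
    by = "og"
  )
  expect_equal(j$significant.x, j$significant.y)
  expect_equal(j$best_model.x, j$best_model.y)
})

test_that("empty count table yields an empty call table", {
  counts <- tibble::tibble(
    og = character(0), A = integer(0), B = integer(0), C = integer(0),
    D = integer(0), E = integer(0), F = integer(0)
  )
  calls <- fit_all(fit_fixture$tree, counts, fit_fixture$classes)
  expect_equal(nrow(calls), 0)
})

test_that("power grows with the foreground shift magnitude", {
  # small-n version of the power curve; monotone non-decreasing calls
  tr <- read_newick(text = "(((A:8,B:8):4,(C:8,D:8):4):4,(E:12,F:12):4);")
  classes <- list(subterranean = c("A", "C"))
  shifts <- c(1, 5, 10)
  rate <- sapply(shifts, function(s) {
    sim <- simulate_counts(sim_config(
      n_og = 15, tree = tr, rates = bdi_rates(0.05, 0.05, 0.02),
      classes = classes, shift = list(subterranean = c(s, 1, 1)),
      root_min = 1, seed = 61
    ))
    calls <- fit_all(tr, sim$counts, classes, seed = 6)
    mean(calls$significant)
  })
  expect_lte(rate[1], rate[2] + 0.15)
  expect_lte(rate[2], rate[3] + 0.15)
  expect_gt(rate[3], rate[1])
})

test_that("tidy and glance methods expose fit fields", {
  tr <- fit_fixture$tree
  cts <- stats::setNames(c(1L, 2L, 1L, 0L, 2L, 1L), tr$tip.label)
  fit <- fit_bdi(tr, cts, kind = "GR", og = "OG1", control = fit_control(n_starts = 2))
  td <- tidy(fit)
  expect_equal(td$class, "background")
  expect_equal(td$net, td$birth - td$death)
  gl <- glance(fit)
  expect_equal(gl$AIC, fit$AIC)
})
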