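test_that("similarity-to-distance transform is the exact complement", {
  set.seed(61)
  S <- matrix(runif(25), 5, 5)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  D <- to_distance(S)
  expect_equal(unname(diag(D)), rep(0, 5))
  off <- row(S) != col(S)
  expect_equal(D[off] + S[off], rep(1, sum(off)))
  expect_equal(to_distance(matrix(1, 2, 2))[1, 2], 0)
  expect_equal(to_distance(diag(1, 2))[1, 2], 1)
})

test_that("classical MDS reproduces an exact 2-D configuration", {
  pts <- rbind(c(0, 0), c(3, 0), c(0, 4))
  D <- as.matrix(dist(pts))
  emb <- mds_embed(D, dims = 2)
  got <- as.matrix(dist(emb$coords[, c("x", "y")]))
  expect_lt(max(abs(got - D)), 1e-8)
  expect_equal(order(emb$eigenvalues, decreasing = TRUE), seq_along(emb$eigenvalues))

  # equidistant points embed as a regular simplex
  De <- matrix(1, 4, 4)
  diag(De) <- 0
  embe <- mds_embed(De, dims = 3)
  d3 <- as.matrix(dist(embe$coords[, c("x", "y", "dim3")]))
  off <- row(d3) != col(d3)
  expect_lt(diff(range(d3[off])), 1e-8)

  expect_error(mds_embed(De, dims = 4), class = "famdyn_validation_error")
})

test_that("double-centered rank matches the generating dimension", {
  set.seed(67)
  pts <- matrix(rnorm(12), 6, 2)
  D <- as.matrix(dist(pts))
  emb <- mds_embed(D, dims = 2)
  ev <- emb$eigenvalues
  expect_lt(abs(ev[3]), 1e-8 * ev[1])
  expect_gt(emb$variance_fraction, 1 - 1e-8)
})

test_that("affinity propagation separates two clear blocks", {
  S <- matrix(0.1, 10, 10)
  S[1:5, 1:5] <- 0.9
  S[6:10, 6:10] <- 0.9
  diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("p", 1:10)
  ap <- affinity_propagation(S)
  expect_true(ap$converged)
  expect_equal(length(ap$exemplars), 2)
  cl <- ap$assignment$cluster
  expect_equal(length(unique(cl[1:5])), 1)
  expect_equal(length(unique(cl[6:10])), 1)
  expect_false(cl[1] == cl[6])
  # exemplars belong to their clusters
  for (e in ap$exemplars) {
    row <- ap$assignment[ap$assignment$item == e, ]
    expect_equal(row$exemplar, e)
  }
})

test_that("affinity propagation finds k blocks for k in 2..5", {
  for (k in 2:5) {
    n_per <- 3
    n <- k * n_per
    S <- matrix(0.05, n, n)
    for (b in seq_len(k)) {
      idx <- ((b - 1) * n_per + 1):(b * n_per)
      S[idx, idx] <- 0.85
    }
    diag(S) <- 1
    ap <- affinity_propagation(S)
    expect_equal(length(ap$exemplars), k)
  }
})

test_that("single point is its own exemplar", {
  ap <- affinity_propagation(matrix(1, 1, 1, dimnames = list("a", "a")))
  expect_equal(ap$assignment$cluster, 1L)
  expect_true(ap$assignment$is_exemplar)
})

test_that("AP net similarity is near the exhaustive optimum for n <= 8", {
  set.seed(71)
  for (rep in 1:6) {
    n <- sample(4:8, 1)
    S <- matrix(runif(n * n, 0, 1), n, n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    rownames(S) <- colnames(S) <- paste0("x", seq_len(n))
    pref <- median(S[row(S) != col(S)])
    ap <- affinity_propagation(S, preference = pref)
    net <- ap_net(S, pref, ap$assignment)
    best <- ap_exhaustive(S, pref)
    expect_gte(net, best - 0.05 * abs(best) - 1e-9)
  }
})

test_that("cluster assignment is always a partition", {
  set.seed(73)
  S <- matrix(runif(400), 20, 20)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  rownames(S) <- colnames(S) <- paste0("g", 1:20)
  ap <- affinity_propagation(S)
  a <- ap$assignment
  expect_setequal(a$item, rownames(S))
  expect_equal(anyDuplicated(a$item), 0)
  expect_true(all(a$exemplar %in% a$item[a$is_exemplar]))
})

test_that("build_clusters recovers planted themes", {
  ont <- simulate_ontology(n_themes = 4, depth = 3, branching = 3)
  n_per <- 25
  ogs <- sprintf("OG%03d", 1:(4 * n_per))
  themes <- rep(1:4, each = n_per)
  ann <- simulate_annotations(ont, ogs, themes,
    n_terms_per_og = 5, noise_rate = 0.05, seed = 79
  )
  exclusive <- split(ogs, rep(c("L1", "L2"), length.out = length(ogs)))
  fc <- build_clusters(exclusive, ann, ont)
  expect_equal(nrow(fc$clusters), length(ogs))
  # partition invariant
  expect_equal(anyDuplicated(fc$clusters$og), 0)
  # every exemplar is a member of its own cluster
  ex <- fc$clusters[fc$clusters$is_exemplar, ]
  expect_true(all(ex$exemplar == ex$og))
  ari <- adjusted_rand_index(fc$clusters$cluster, themes[match(fc$clusters$og, ogs)])
  expect_gte(ari, 0.8)
})

test_that("one orthogroup per theme still forms valid clusters", {
  ont <- simulate_ontology(n_themes = 4, depth = 2, branching = 2)
  ogs <- sprintf("OG%d", 1:4)
  ann <- simulate_annotations(ont, ogs, 1:4,
    n_terms_per_og = 3, noise_rate = 0, seed = 83
  )
  fc <- build_clusters(list(L1 = ogs), ann, ont)
  expect_gte(fc$n_clusters, 1)
  ex <- fc$clusters[fc$clusters$is_exemplar, ]
  expect_true(all(ex$og == ex$exemplar))
})

test_that("the multi-gain restriction filters the cluster input exactly", {
  ont <- simulate_ontology(n_themes = 2, depth = 2, branching = 2)
  ogs <- sprintf("OG%d", 1:6)
  ann <- simulate_annotations(ont, ogs, rep(1:2, 3),
    n_terms_per_og = 3, noise_rate = 0, seed = 89
  )
  changes <- tibble::tibble(
    branch = "b1", og = ogs,
    parent_state = 1L, child_state = c(2L, 3L, 4L, 2L, 5L, 2L),
    delta = c(1L, 2L, 3L, 1L, 4L, 1L),
    expanded = TRUE, contracted = FALSE, og_gained = FALSE, og_lost = FALSE
  )
  fc <- build_clusters(list(L1 = ogs), ann, ont,
    changes = changes, min_gains = 1
  )
  expect_setequal(fc$clusters$og, c("OG2", "OG3", "OG5"))
})

test_that("unannotated input produces an empty result with a warning", {
  ont <- simulate_ontology(n_themes = 2, depth = 2, branching = 2)
  ann <- tibble::tibble(og = character(0), term = character(0))
  expect_warning(
    fc <- build_clusters(list(L1 = c("OGa", "OGb")), ann, ont),
    "no annotated"
  )
  expect_equal(nrow(fc$clusters), 0)
})

test_that("adjusted Rand index behaves at its reference points", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 7, 7)), 1)
  set.seed(97)
  a <- sample(1:4, 400, replace = TRUE)
  b <- sample(1:4, 400, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.1)
})
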