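# hand DAG: chain B is_a A is_a root, weight 0.8
chain_ont <- ontology(
  tibble::tibble(
    id = c("root", "A", "B"),
    name = c("root", "a", "b"),
    namespace = "biological_process"
  ),
  tibble::tibble(child = c("A", "B"), parent = c("root", "A"), relation = "is_a")
)

test_that("Wang similarity reproduces the hand-computed chain value", {
  # S_B = {B:1, A:0.8, root:0.64}, S_A = {A:1, root:0.8}
  # sim = (1 + 0.8 + 0.8 + 0.64) / (2.44 + 1.8) = 3.24 / 4.24
  expect_equal(term_similarity(chain_ont, "A", "B"), 3.24 / 4.24,
    tolerance = 1e-12
  )
  expect_equal(term_similarity(chain_ont, "B", "A"), 3.24 / 4.24,
    tolerance = 1e-12
  )
})

test_that("similarity is an identity-1, symmetric measure on random DAGs", {
  ont <- simulate_ontology(n_themes = 3, depth = 3, branching = 2)
  ids <- setdiff(ont$terms$id, ont$roots)
  set.seed(47)
  for (i in 1:15) {
    t1 <- sample(ids, 1)
    t2 <- sample(ids, 1)
    s12 <- term_similarity(ont, t1, t2)
    expect_gte(s12, 0)
    expect_lte(s12, 1)
    expect_equal(s12, term_similarity(ont, t2, t1), tolerance = 1e-12)
  }
  for (t in sample(ids, 5)) {
    expect_equal(term_similarity(ont, t, t), 1)
  }
  # distinct terms on a tree-shaped ontology are strictly below 1
  expect_lt(term_similarity(ont, ids[1], ids[2]), 1)
  expect_error(
    term_similarity(ont, "nope", ids[1]),
    class = "famdyn_validation_error"
  )
})

test_that("orthogroup similarity: BMA hand value and identities", {
  ann <- tibble::tibble(
    og = c("O1", "O1", "O2", "O2"),
    term = c("A", "B", "A", "root")
  )
  # pairwise Wang values on the chain: sim(A,A)=1, sim(A,root), sim(B,A), sim(B,root)
  s_ar <- term_similarity(chain_ont, "A", "root")
  s_ba <- term_similarity(chain_ont, "B", "A")
  s_br <- term_similarity(chain_ont, "B", "root")
  # row bests: A -> 1, B -> max(s_ba, s_br); col bests: A -> 1, root -> max(s_ar, s_br)
  hand <- (mean(c(1, max(s_ba, s_br))) + mean(c(1, max(s_ar, s_br)))) / 2
  expect_equal(og_similarity(ann, "O1", "O2", chain_ont), hand, tolerance = 1e-12)

  expect_equal(og_similarity(ann, "O1", "O1", chain_ont), 1)
  # term listing order does not matter
  ann_rev <- ann[c(2, 1, 4, 3), ]
  expect_equal(
    og_similarity(ann_rev, "O1", "O2", chain_ont),
    og_similarity(ann, "O1", "O2", chain_ont)
  )
  expect_error(
    og_similarity(ann, "O1", "O9", chain_ont),
    class = "famdyn_validation_error"
  )
})

test_that("disjoint root subtrees of a forest ontology score zero", {
  forest <- ontology(
    tibble::tibble(
      id = c("r1", "r2", "a", "b"),
      name = c("r1", "r2", "a", "b"),
      namespace = "biological_process"
    ),
    tibble::tibble(
      child = c("a", "b"), parent = c("r1", "r2"), relation = "is_a"
    )
  )
  expect_equal(term_similarity(forest, "a", "b"), 0)
})

test_that("similarity matrix is symmetric with unit diagonal, exclusions listed", {
  ont <- simulate_ontology(n_themes = 2, depth = 3, branching = 2)
  ogs <- sprintf("OG%02d", 1:10)
  ann <- simulate_annotations(ont, ogs[1:8], rep(1:2, 4),
    n_terms_per_og = 3, noise_rate = 0, seed = 5
  )
  M <- og_similarity_matrix(ann, ogs, ont)
  expect_equal(rownames(M), ogs[1:8])
  expect_setequal(attr(M, "excluded"), ogs[9:10])
  expect_lt(max(abs(M - t(M))), 1e-12)
  expect_equal(unname(diag(M)), rep(1, 8))
  expect_true(all(M >= 0 & M <= 1))
  # same-theme orthogroups are more similar than cross-theme ones
  expect_gt(mean(M[c(1, 3, 5, 7), c(1, 3, 5, 7)]), mean(M[c(1, 3, 5, 7), c(2, 4, 6, 8)]))
})

test_that("adding a shared unrelated noise term moves BMA by a bounded amount", {
  # the bound 1/min(set size) holds when the added term is unrelated to the
  # existing annotations (it contributes one perfect pair and nothing else);
  # a *related* noise term can lift every best-match and move BMA further
  ont <- simulate_ontology(n_themes = 3, depth = 3, branching = 2)
  set.seed(53)
  terms1 <- sample(theme_terms(ont, 1), 4)
  terms2 <- sample(theme_terms(ont, 2), 4)
  ann <- dplyr::bind_rows(
    tibble::tibble(og = "O1", term = terms1),
    tibble::tibble(og = "O2", term = terms2)
  )
  base <- og_similarity(ann, "O1", "O2", ont)
  noise <- theme_terms(ont, 3)[1] # disjoint subtree from both term sets
  ann2 <- dplyr::bind_rows(ann, tibble::tibble(og = c("O1", "O2"), term = noise))
  with_noise <- og_similarity(ann2, "O1", "O2", ont)
  expect_lte(abs(with_noise - base), 1 / 5 + 0.05)
})

test_that("reduced_term follows depth and tie-break rules", {
  ont <- simulate_ontology(n_themes = 2, depth = 3, branching = 2)
  # singleton set: that term
  expect_equal(reduced_term("T1.2.001", ont), "T1.2.001")
  # all pairwise sims < 0.95 at equal depth: lexicographically smallest id
  picks <- c("T1.3.001", "T1.3.008", "T2.3.001")
  expect_equal(
    reduced_term(picks, ont),
    sort(picks)[1]
  )
  # deepest terms are kept first: a shallow term is never chosen over 3 deeper
  mix <- c("T1.1.001", "T1.3.001", "T1.3.002", "T2.3.005")
  got <- reduced_term(mix, ont)
  expect_true(got %in% setdiff(mix, "T1.1.001"))
  expect_error(reduced_term(character(0), ont), class = "famdyn_validation_error")
})

test_that("planted-theme annotations reduce into the theme subtree", {
  ont <- simulate_ontology(n_themes = 4, depth = 3, branching = 3)
  ogs <- sprintf("OG%03d", 1:40)
  themes <- rep(1:4, each = 10)
  ann <- simulate_annotations(ont, ogs, themes,
    n_terms_per_og = 5, noise_rate = 0, seed = 59
  )
  inside <- vapply(seq_along(ogs), function(i) {
    rt <- reduced_term(ann$term[ann$og == ogs[i]], ont)
    rt %in% theme_terms(ont, themes[i])
  }, TRUE)
  expect_gte(mean(inside), 0.95)
})
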