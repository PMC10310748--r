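test_that("zero rates reconstruct constant counts exactly", {
  tr <- read_newick(text = "((A:1,B:1):2,C:3);")
  model <- rate_model(background = bdi_rates(0, 0, 0))
  prof <- reconstruct_ancestral(tr, c(A = 3, B = 3, C = 3), model, n_max = 6)
  expect_true(all(prof$state == 3))
  expect_true(all(abs(prof$posterior - 1) < 1e-12))
})

test_that("marginals equal exhaustive enumeration on a 3-tip tree", {
  tr <- read_newick(text = "((A:1,B:1):2,C:3);")
  set.seed(17)
  for (i in 1:6) {
    rates <- c(runif(1, 0.01, 0.4), runif(1, 0.01, 0.4), runif(1, 0.01, 0.2))
    cts <- c(A = sample(0:3, 1), B = sample(0:3, 1), C = sample(0:3, 1))
    model <- rate_model(background = bdi_rates(rates[1], rates[2], rates[3]))
    prof <- reconstruct_ancestral(tr, cts, model, n_max = 4)
    oracle <- enum_marginals(tr, cts, list(background = rates), nmax = 4)
    for (nd in colnames(oracle)) {
      st <- prof$state[prof$node == nd]
      expect_equal(
        unname(prof$posterior[prof$node == nd]),
        unname(oracle[st + 1, nd]),
        tolerance = 1e-10
      )
      # reported state is the argmax of the enumerated posterior
      expect_equal(
        unname(oracle[st + 1, nd]), unname(max(oracle[, nd])),
        tolerance = 1e-10
      )
    }
  }
})

test_that("posterior mass of the reported state is a valid probability", {
  sim <- simulate_counts(sim_config(n_og = 5, n_tips = 6, seed = 23))
  model <- rate_model(background = bdi_rates(0.05, 0.05, 0.02))
  for (g in 1:5) {
    cts <- unlist(sim$counts[g, sim$tree$tip.label])
    prof <- reconstruct_ancestral(sim$tree, cts, model, og = sim$counts$og[g])
    expect_true(all(prof$posterior > 0 & prof$posterior <= 1 + 1e-12))
    # tips reproduce their observed counts
    tips <- prof$state[match(sim$tree$tip.label, prof$node)]
    expect_equal(tips, unname(cts))
  }
})

test_that("simulation recovery: reconstructed states mostly match truth", {
  # exact-state recovery is count-scale dependent: with the default root
  # distribution (mostly 0-3 copies) and modest drift, max-marginal
  # reconstruction should recover most internal states exactly
  sim <- simulate_counts(sim_config(
    n_og = 30, n_tips = 12, tree_height = 15,
    rates = bdi_rates(0.05, 0.05, 0.02), seed = 29
  ))
  model <- rate_model(background = bdi_rates(0.05, 0.05, 0.02))
  hit <- unlist(lapply(1:30, function(g) {
    cts <- unlist(sim$counts[g, sim$tree$tip.label])
    prof <- reconstruct_ancestral(sim$tree, cts, model,
      prior = "stationary", og = sim$counts$og[g]
    )
    truth <- sim$node_states[sim$node_states$og == sim$counts$og[g], ]
    internal <- setdiff(truth$node, sim$tree$tip.label)
    prof$state[match(internal, prof$node)] ==
      truth$count[match(internal, truth$node)]
  }))
  expect_gte(mean(hit), 0.7)
})

test_that("branch change flags follow the definitions", {
  tr <- read_newick(text = "((A:1,B:1):1,C:2);")
  # postorder labelling: the (A,B) node completes first ("N1"), root is "N2"
  # hand profile: root N2 = 2; internal N1 = 0; tips A=3, B=0, C=0
  states <- tibble::tibble(
    og = "OG1",
    node = c("A", "B", "C", "N1", "N2"),
    state = c(3L, 0L, 0L, 0L, 2L)
  )
  ch <- branch_changes(states, tr)
  # N2 -> N1: 2 -> 0 is an orthogroup loss contributing 2 gene losses
  r <- ch[ch$branch == "N1", ]
  expect_equal(r$delta, -2)
  expect_true(r$og_lost && r$contracted)
  expect_false(r$expanded || r$og_gained)
  # N1 -> A: 0 -> 3 is an origination with 3 gains and no duplication
  r <- ch[ch$branch == "A", ]
  expect_equal(r$delta, 3)
  expect_true(r$og_gained && r$expanded)
  # N2 -> C: 2 -> 0 loss; B: 0 -> 0 absent
  expect_false("B" %in% ch$branch)

  summ <- branch_summary(ch, tr)
  expect_equal(summ$gene_gains[summ$branch == "A"], 3)
  expect_equal(summ$gene_losses[summ$branch == "N1"], 2)
  expect_equal(summ$n_duplications[summ$branch == "A"], 0) # parent was 0
  expect_equal(sum(summ$n_lost), 2) # N1 and C
  # flag consistency invariants
  expect_true(all(!ch$og_gained | ch$expanded))
  expect_true(all(!ch$og_lost | ch$contracted))
})

test_that("hand-tallied 4-tip fixture matches branch_summary", {
  tr <- read_newick(text = "(((A:1,B:1):1,C:2):1,D:3);")
  # N labels postorder: (A,B)->N1, ((A,B),C)->N2, root N3
  states <- tibble::tibble(
    og = rep(c("OG1", "OG2"), each = 7),
    node = rep(c("A", "B", "C", "D", "N1", "N2", "N3"), 2),
    state = c(
      2L, 1L, 1L, 1L, 1L, 1L, 1L, # OG1: one gain on A
      0L, 2L, 2L, 3L, 2L, 2L, 2L  # OG2: loss on A branch, gain on D
    )
  )
  ch <- branch_changes(states, tr)
  summ <- branch_summary(ch, tr)
  expect_equal(summ$gene_gains[summ$branch == "A"], 1)
  expect_equal(summ$gene_losses[summ$branch == "A"], 2)
  expect_equal(summ$n_lost[summ$branch == "A"], 1)
  expect_equal(summ$gene_gains[summ$branch == "D"], 1)
  expect_equal(summ$n_duplications[summ$branch == "A"], 1) # OG1 parent 1 -> 2
  expect_equal(summ$n_duplications[summ$branch == "D"], 1) # OG2 parent 2 -> 3
  # totals equal sums over rows
  expect_equal(sum(summ$gene_gains), sum(pmax(ch$delta, 0)))
  expect_equal(sum(summ$gene_losses), sum(pmax(-ch$delta, 0)))

  lists <- branch_og_lists(ch, c("A", "D"), tr)
  expect_setequal(
    lists$og[lists$branch == "A" & lists$category == "expanded"], "OG1"
  )
  expect_setequal(
    lists$og[lists$branch == "A" & lists$category == "contracted"], "OG2"
  )
  expect_setequal(
    lists$og[lists$branch == "A" & lists$category == "lost"], "OG2"
  )
  expect_equal(sum(lists$branch == "D" & lists$category == "gained"), 0)
})

test_that("gained/lost lists are subsets of expanded/contracted", {
  sim <- simulate_counts(sim_config(n_og = 40, n_tips = 8, seed = 37))
  ch <- branch_changes(
    dplyr::rename(sim$node_states, state = "count"), sim$tree
  )
  summ <- branch_summary(ch, sim$tree)
  expect_true(all(summ$n_gained <= summ$n_expanded))
  expect_true(all(summ$n_lost <= summ$n_contracted))
  # orthogroup-order invariance of totals
  ch2 <- branch_changes(
    dplyr::rename(sim$node_states, state = "count")[sample(nrow(sim$node_states)), ],
    sim$tree
  )
  expect_equal(
    dplyr::arrange(branch_summary(ch2, sim$tree), branch),
    dplyr::arrange(summ, branch)
  )
})

test_that("zero-rate data produce an empty change table", {
  tr <- read_newick(text = "((A:1,B:1):2,C:3);")
  states <- tibble::tibble(
    og = rep(c("OG1", "OG2"), each = 5),
    node = rep(c("A", "B", "C", "N2", "N1"), 2),
    state = rep(c(2L, 2L, 2L, 2L, 2L), 2)
  )
  ch <- branch_changes(states, tr)
  expect_equal(nrow(ch), 0)
})

test_that("requesting the root as a branch is an error", {
  tr <- read_newick(text = "((A:1,B:1):2,C:3);")
  root_label <- setdiff(tr$node.label, tree_branches(tr)$branch)
  ch <- tibble::tibble(
    branch = "A", og = "OG1", parent_state = 1L, child_state = 2L,
    delta = 1L, expanded = TRUE, contracted = FALSE,
    og_gained = FALSE, og_lost = FALSE
  )
  expect_error(
    branch_og_lists(ch, root_label, tr),
    class = "famdyn_validation_error"
  )
  # a branch with no changes yields empty lists, not an error
  lists <- branch_og_lists(ch, "B", tr)
  expect_equal(nrow(lists), 0)
})
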