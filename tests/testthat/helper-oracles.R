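# Independent oracles used across the suite. These deliberately avoid the
# package's own numerical routes: dense Taylor series with scaling and
# squaring for the matrix exponential, exhaustive enumeration for
# likelihoods/posteriors/Fisher tables, and bitmask tallies for set algebra.

# dense matrix exponential by scaling-and-squaring Taylor series
expm_taylor <- function(A) {
  nrm <- max(rowSums(abs(A)))
  s <- max(0L, ceiling(log2(max(nrm, 1e-300))))
  As <- A / 2^s
  P <- diag(nrow(A))
  Tm <- diag(nrow(A))
  for (k in 1:80) {
    Tm <- Tm %*% As / k
    P <- P + Tm
  }
  for (k in seq_len(s)) P <- P %*% P
  P
}

# truncated BDI generator with leaking boundary (matches the package spec)
bdi_generator <- function(b, d, i, nmax) {
  n <- nmax + 1
  Q <- matrix(0, n, n)
  for (k in 0:nmax) {
    up <- k * b + i
    dn <- k * d
    Q[k + 1, k + 1] <- -(up + dn)
    if (k < nmax) Q[k + 1, k + 2] <- up
    if (k > 0) Q[k + 1, k] <- dn
  }
  Q
}

oracle_pmat <- function(b, d, i, t, nmax) expm_taylor(bdi_generator(b, d, i, nmax) * t)

# Exhaustive-enumeration log-likelihood over all internal-state assignments.
# Works for any labelled rooted tree with <= a handful of internal nodes.
enum_loglik <- function(tree, counts, rates_by_class, classes = NULL,
                        nmax, prior = NULL) {
  labs <- c(tree$tip.label, tree$node.label)
  cls <- famdyn::branch_classes(tree, classes)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (is.null(prior)) prior <- rep(1 / (nmax + 1), nmax + 1)
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    r <- rates_by_class[[cls[labs[tree$edge[e, 2]]]]]
    oracle_pmat(r[1], r[2], r[3], tree$edge.length[e], nmax)
  })
  internals <- (n_tip + 1):n_node
  grid <- do.call(expand.grid, rep(list(0:nmax), length(internals)))
  counts <- counts[tree$tip.label]
  tot <- 0
  for (gi in seq_len(nrow(grid))) {
    st <- integer(n_node)
    st[internals] <- as.integer(grid[gi, ])
    st[1:n_tip] <- counts
    p <- prior[st[n_tip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * P[[e]][st[tree$edge[e, 1]] + 1, st[tree$edge[e, 2]] + 1]
      if (p == 0) break
    }
    tot <- tot + p
  }
  log(tot)
}

# exhaustive marginal posteriors at internal nodes (same enumeration)
enum_marginals <- function(tree, counts, rates_by_class, classes = NULL,
                           nmax, prior = NULL) {
  labs <- c(tree$tip.label, tree$node.label)
  cls <- famdyn::branch_classes(tree, classes)
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  if (is.null(prior)) prior <- rep(1 / (nmax + 1), nmax + 1)
  P <- lapply(seq_len(nrow(tree$edge)), function(e) {
    r <- rates_by_class[[cls[labs[tree$edge[e, 2]]]]]
    oracle_pmat(r[1], r[2], r[3], tree$edge.length[e], nmax)
  })
  internals <- (n_tip + 1):n_node
  grid <- do.call(expand.grid, rep(list(0:nmax), length(internals)))
  counts <- counts[tree$tip.label]
  post <- matrix(0, nmax + 1, length(internals))
  for (gi in seq_len(nrow(grid))) {
    st <- integer(n_node)
    st[internals] <- as.integer(grid[gi, ])
    st[1:n_tip] <- counts
    p <- prior[st[n_tip + 1] + 1]
    for (e in seq_len(nrow(tree$edge))) {
      p <- p * P[[e]][st[tree$edge[e, 1]] + 1, st[tree$edge[e, 2]] + 1]
      if (p == 0) break
    }
    for (j in seq_along(internals)) {
      post[st[internals[j]] + 1, j] <- post[st[internals[j]] + 1, j] + p
    }
  }
  post <- sweep(post, 2, colSums(post), "/")
  colnames(post) <- labs[internals]
  post
}

# two-sided Fisher p by explicit hypergeometric enumeration in log space
fisher_enum <- function(a, b, c, d) {
  m <- a + b # row 1 total (query)
  n <- c + d
  k <- a + c # column 1 total (term hits)
  lp <- function(x) {
    lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  }
  xs <- max(0, k - n):min(k, m)
  lps <- lp(xs)
  obs <- lp(a)
  sum(exp(lps[lps <= obs + 1e-7]))
}

# brute-force Venn cells via membership bit vectors
venn_bitmask <- function(sets) {
  lin <- sort(names(sets))
  universe <- sort(unique(unlist(sets)))
  key <- vapply(universe, function(x) {
    paste(lin[vapply(lin, function(l) x %in% sets[[l]], TRUE)], collapse = "&")
  }, "")
  table(key)
}

# exhaustive best exemplar set: maximize sum of preferences of exemplars plus
# similarity of each non-exemplar to its nearest exemplar
ap_exhaustive <- function(S, preference) {
  n <- nrow(S)
  Sp <- S
  diag(Sp) <- preference
  best <- -Inf
  for (mask in 1:(2^n - 1)) {
    ex <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    val <- sum(diag(Sp)[ex])
    for (i in setdiff(1:n, ex)) val <- val + max(S[i, ex])
    if (val > best) best <- val
  }
  best
}

# net similarity actually achieved by an AP result
ap_net <- function(S, preference, assignment) {
  Sp <- S
  diag(Sp) <- preference
  idx <- match(assignment$exemplar, assignment$item)
  sum(Sp[cbind(seq_len(nrow(S)), idx)])
}
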