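# Independent brute-force oracles: direct enumeration over all node-state
# assignments. Deliberately naive and separate from the package's pruning,
# DP and enumeration code paths.

# All states each node can take: observed tips are fixed, missing tips and
# internal nodes range over the full alphabet.
bf_node_domains <- function(tree, states, alphabet) {
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  doms <- vector("list", n_node)
  for (i in seq_len(n_tip)) {
    s <- states[tree$tip.label[i]]
    doms[[i]] <- if (is.na(s)) alphabet else s
  }
  for (v in (n_tip + 1):n_node) doms[[v]] <- alphabet
  doms
}

# total likelihood by summation over every assignment of states to nodes
bf_loglik <- function(tree, states, Q, prior, alphabet) {
  doms <- bf_node_domains(tree, states, alphabet)
  edge <- tree$edge
  Pt <- lapply(seq_len(nrow(edge)), function(e)
    transition_probability(Q, tree$edge.length[e]))
  root <- length(tree$tip.label) + 1
  grid <- expand.grid(doms, stringsAsFactors = FALSE)
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    asg <- match(unlist(grid[r, ]), alphabet)
    p <- prior[asg[root]]
    for (e in seq_len(nrow(edge))) {
      p <- p * Pt[[e]][asg[edge[e, 1]], asg[edge[e, 2]]]
    }
    tot <- tot + p
  }
  log(tot)
}

# marginal state probabilities at one node, by the same enumeration
bf_marginal <- function(tree, states, Q, prior, alphabet, node) {
  doms <- bf_node_domains(tree, states, alphabet)
  edge <- tree$edge
  Pt <- lapply(seq_len(nrow(edge)), function(e)
    transition_probability(Q, tree$edge.length[e]))
  root <- length(tree$tip.label) + 1
  grid <- expand.grid(doms, stringsAsFactors = FALSE)
  acc <- setNames(numeric(length(alphabet)), alphabet)
  for (r in seq_len(nrow(grid))) {
    lab <- unlist(grid[r, ])
    asg <- match(lab, alphabet)
    p <- prior[asg[root]]
    for (e in seq_len(nrow(edge))) {
      p <- p * Pt[[e]][asg[edge[e, 1]], asg[edge[e, 2]]]
    }
    acc[lab[node]] <- acc[lab[node]] + p
  }
  acc / sum(acc)
}

# minimum parsimony length and per-node MPR sets by enumeration
bf_parsimony <- function(tree, states, alphabet, cost = NULL) {
  k <- length(alphabet)
  if (is.null(cost)) cost <- matrix(1, k, k) - diag(k)
  doms <- bf_node_domains(tree, states, alphabet)
  edge <- tree$edge
  grid <- expand.grid(doms, stringsAsFactors = FALSE)
  lens <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    asg <- match(unlist(grid[r, ]), alphabet)
    lens[r] <- sum(cost[cbind(asg[edge[, 1]], asg[edge[, 2]])])
  }
  best <- min(lens)
  opt <- grid[abs(lens - best) < 1e-9, , drop = FALSE]
  sets <- lapply(seq_len(ncol(opt)), function(v) sort(unique(opt[, v])))
  list(length = best, sets = sets)
}

# independent count of rate-class models: canonical signatures of all
# labelled maps params -> {zero, class1..classn}, deduplicated
bf_count_models <- function(n) {
  labels <- 0:n
  grid <- do.call(expand.grid, rep(list(labels), n))
  sigs <- apply(grid, 1, function(a) {
    a <- as.integer(a)
    if (all(a == 0)) return(NA_character_)
    nz <- a != 0
    a[nz] <- match(a[nz], unique(a[nz]))
    paste(a, collapse = ",")
  })
  length(unique(sigs[!is.na(sigs)]))
}
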