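#' Simulate an ultrametric Yule tree
#'
#' Pure-birth simulation conditioned on the tip count: the process starts
#' with two lineages at the root, waits an Exp(k * birth_rate) epoch while
#' k lineages exist, splits a uniformly chosen lineage, and stops after the
#' Exp(n * birth_rate) epoch following the appearance of the n-th lineage.
#' Expected root age is therefore `sum(1/(k*birth_rate))` for k in 2..n.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate per lineage per unit time (> 0).
#' @param seed optional RNG seed.
#' @return an ultrametric `phylo` with tips `t1..tn`.
#' @examples
#' simulate_yule_tree(5, 1, seed = 1)
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  if (n_tips < 2 || birth_rate <= 0) {
    stop("need n_tips >= 2 and birth_rate > 0", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n_tips)
  # grow forward in time; record (birth time, parent lineage) per lineage
  birth_t <- c(0, 0)          # lineages 1..k alive, birth times
  parent_lin <- c(0L, 0L)
  split_of <- integer(0)
  t_now <- 0
  k <- 2L
  events <- list()
  while (k < n) {
    t_now <- t_now + rexp(1, k * birth_rate)
    j <- sample.int(k, 1)
    # lineage j splits: continues as j, spawns lineage k+1
    events[[length(events) + 1]] <- list(time = t_now, lineage = j)
    birth_t <- c(birth_t, t_now)
    parent_lin <- c(parent_lin, j)
    k <- k + 1L
  }
  t_now <- t_now + rexp(1, k * birth_rate)   # final epoch, no split observed

  # build the phylo: each split event creates an internal node
  n_node <- n - 1L
  edge <- matrix(0L, 2 * n - 2, 2)
  edge_len <- numeric(2 * n - 2)
  # lineage -> current tree node carrying it, and that node's start time
  root <- n + 1L
  lin_node <- c(root, root)
  lin_start <- c(0, 0)
  next_node <- root + 1L
  ei <- 0L
  for (ev in events) {
    j <- ev$lineage
    new_lin <- length(lin_node) + 1L
    node <- next_node; next_node <- next_node + 1L
    ei <- ei + 1L
    edge[ei, ] <- c(lin_node[j], node)
    edge_len[ei] <- ev$time - lin_start[j]
    lin_node[j] <- node; lin_start[j] <- ev$time
    lin_node[new_lin] <- node; lin_start[new_lin] <- ev$time
  }
  for (j in seq_len(n)) {
    ei <- ei + 1L
    edge[ei, ] <- c(lin_node[j], j)
    edge_len[ei] <- t_now - lin_start[j]
  }
  tr <- structure(list(edge = edge, edge.length = edge_len,
                       tip.label = paste0("t", seq_len(n)),
                       Nnode = n_node), class = "phylo")
  stats::reorder(ape::read.tree(text = ape::write.tree(tr)), "cladewise")
}

#' Simulate a discrete character on a tree
#'
#' Forward simulation of the CTMC along every branch by exponential
#' waiting times (Gillespie-style event sampling), so the full event log
#' is available. States at every node, including the root, are recorded.
#'
#' @param tree a `phylo` with branch lengths.
#' @param Q generator matrix (dimnames give the state alphabet).
#' @param root_prior probability vector over states (default flat), or a
#'   single state label to pin the root.
#' @param seed optional RNG seed.
#' @return a `sim_character`: `tip_states` (named vector), `node_states`
#'   (all nodes), `events` tibble (edge, time, from, to), alphabet, seed.
#' @export
simulate_character <- function(tree, Q, root_prior = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tree <- stats::reorder(tree, "cladewise")   # parents before children
  k <- nrow(Q)
  alphabet <- rownames(Q) %||% as.character(0:(k - 1))
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  root <- n_tip + 1L

  state <- integer(n_node)
  if (is.character(root_prior) && length(root_prior) == 1) {
    state[root] <- match(root_prior, alphabet)
  } else {
    p <- root_prior %||% rep(1 / k, k)
    state[root] <- sample.int(k, 1, prob = p)
  }

  ev <- list()
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    s <- state[par]
    t_left <- tree$edge.length[e]
    t_pos <- 0
    repeat {
      out_rate <- -Q[s, s]
      if (out_rate <= 0) break
      w <- rexp(1, out_rate)
      if (w > t_left) break
      t_left <- t_left - w
      t_pos <- t_pos + w
      s_new <- sample.int(k, 1, prob = pmax(Q[s, ], 0) *
                            (seq_len(k) != s))
      ev[[length(ev) + 1]] <- list(edge = e, time = t_pos,
                                   from = alphabet[s], to = alphabet[s_new])
      s <- s_new
    }
    state[ch] <- s
  }
  events <- if (length(ev)) dplyr::bind_rows(lapply(ev, tibble::as_tibble))
    else tibble::tibble(edge = integer(), time = numeric(),
                        from = character(), to = character())
  tips <- setNames(alphabet[state[seq_len(n_tip)]], tree$tip.label)
  structure(list(tip_states = tips,
                 node_states = setNames(alphabet[state], c(tree$tip.label,
                   paste0("node", (n_tip + 1L):n_node))),
                 events = events, alphabet = alphabet, tree = tree),
            class = "sim_character")
}

#' Simulate a pair of binary characters on the combined chain
#'
#' Simulates the 4-state combined chain (00, 01, 10, 11; dual transitions
#' structurally zero) and returns the two marginal binary columns together
#' with the true combined node states and the event log (which can be
#' checked for the absence of dual transitions).
#'
#' @param tree a `phylo`.
#' @param spec a pair model from [build_pair_model()], or `rates` given a
#'   `rate_partition`-style assignment via `Q`.
#' @param rates rates for `spec`'s classes.
#' @param Q alternatively, a 4x4 combined generator with zero dual rates.
#' @param root_prior over combined states (default flat).
#' @param seed optional RNG seed.
#' @return a `sim_pair`: `statesA`, `statesB` (named binary vectors),
#'   `combined` (`sim_character`).
#' @export
simulate_pair <- function(tree, spec = NULL, rates = NULL, Q = NULL,
                          root_prior = NULL, seed = NULL) {
  if (is.null(Q)) {
    stopifnot(inherits(spec, "mk_model"), isTRUE(spec$pair))
    Q <- build_rate_matrix(spec, rates)
  }
  stopifnot(nrow(Q) == 4)
  if (Q[1, 4] != 0 || Q[4, 1] != 0 || Q[2, 3] != 0 || Q[3, 2] != 0) {
    stop("dual transition rates must be zero", call. = FALSE)
  }
  rownames(Q) <- colnames(Q) <- c("00", "01", "10", "11")
  sim <- simulate_character(tree, Q, root_prior = root_prior, seed = seed)
  sa <- substr(sim$tip_states, 1, 1)
  sb <- substr(sim$tip_states, 2, 2)
  structure(list(statesA = setNames(sa, names(sim$tip_states)),
                 statesB = setNames(sb, names(sim$tip_states)),
                 combined = sim),
            class = "sim_pair")
}

#' Mask cells of a trait matrix as missing or inapplicable
#'
#' Masks cells independently at `missing_rate`; of the masked cells, a
#' fraction `inapplicable_share` receives the inapplicable code instead of
#' the missing code. The mask is recorded for bookkeeping.
#'
#' @param matrix a `trait_matrix`.
#' @param missing_rate overall masking probability, in [0, 1).
#' @param inapplicable_share share of masked cells coded inapplicable.
#' @param seed optional RNG seed.
#' @return a `trait_matrix` with attribute `mask` (logical matrix).
#' @export
inject_missing <- function(matrix, missing_rate, inapplicable_share = 0,
                           seed = NULL) {
  if (missing_rate >= 1 || missing_rate < 0) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  mc <- attr(matrix, "missing_code"); ic <- attr(matrix, "inapplicable_code")
  chars <- setdiff(names(matrix), "species")
  mask <- matrix(runif(nrow(matrix) * length(chars)) < missing_rate,
                 nrow(matrix), length(chars), dimnames = list(NULL, chars))
  inap <- matrix(runif(nrow(matrix) * length(chars)) < inapplicable_share,
                 nrow(matrix), length(chars))
  out <- matrix
  for (j in seq_along(chars)) {
    v <- out[[chars[j]]]
    v[mask[, j]] <- ifelse(inap[mask[, j], j], ic, mc)
    out[[chars[j]]] <- v
  }
  res <- trait_matrix(out, mc, ic)
  attr(res, "mask") <- mask
  res
}

#' Jittered pseudo-posterior tree sample
#'
#' Emulates a Bayesian posterior sample around a base chronogram: node
#' ages are jittered multiplicatively (relative sd `time_jitter`) while
#' preserving parent-older-than-child ordering, tip ages stay at zero
#' (ultrametricity preserved), and up to `topo_moves` random
#' nearest-neighbour interchanges are applied where node ages permit.
#'
#' @param base an ultrametric `phylo`.
#' @param n_trees number of trees.
#' @param time_jitter relative standard deviation of node-age jitter.
#' @param topo_moves NNI moves attempted per tree.
#' @param seed optional RNG seed.
#' @return a `tree_sample`.
#' @export
perturb_tree_sample <- function(base, n_trees, time_jitter = 0.05,
                                topo_moves = 0, seed = NULL) {
  stopifnot(n_trees >= 1)
  if (!is.null(seed)) set.seed(seed)
  trees <- lapply(seq_len(n_trees), function(i) {
    tr <- base
    if (topo_moves > 0) tr <- random_nni(tr, topo_moves)
    if (time_jitter > 0) tr <- jitter_ages(tr, time_jitter)
    tr
  })
  tree_sample(trees, label = "pseudo-posterior")
}

# node ages from tip-depth; tips at age 0
node_ages <- function(tree) {
  d <- ape::node.depth.edgelength(tree)
  max(d) - d
}

jitter_ages <- function(tree, rel_sd) {
  n_tip <- length(tree$tip.label)
  age <- node_ages(tree)
  age[seq_len(n_tip)] <- 0
  idx <- (n_tip + 1):max(tree$edge)
  for (tries in 1:100) {
    a2 <- age
    a2[idx] <- age[idx] * exp(rnorm(length(idx), 0, rel_sd))
    el <- a2[tree$edge[, 1]] - a2[tree$edge[, 2]]
    if (all(el > 0)) {
      tree$edge.length <- el
      return(tree)
    }
  }
  # fall back: order-preserving shrink toward original ages
  tree
}

# NNI on internal edges where node ages allow the swap (keeps the tree a
# valid chronogram: only topology changes, ages are untouched)
random_nni <- function(tree, moves) {
  n_tip <- length(tree$tip.label)
  for (m in seq_len(moves)) {
    age <- node_ages(tree)
    edge <- tree$edge
    internal <- which(edge[, 2] > n_tip)
    if (!length(internal)) break
    for (try in sample(internal)) {
      p <- edge[try, 1]; cnode <- edge[try, 2]
      sibs <- setdiff(edge[edge[, 1] == p, 2], cnode)
      kids <- edge[edge[, 1] == cnode, 2]
      if (!length(sibs) || length(kids) < 2) next
      x <- sibs[1]; y <- kids[1]
      if (age[x] >= age[cnode]) next       # x must fit under cnode
      ex <- which(edge[, 1] == p & edge[, 2] == x)
      ey <- which(edge[, 1] == cnode & edge[, 2] == y)
      edge[ex, ] <- c(cnode, x)
      edge[ey, ] <- c(p, y)
      tree$edge <- edge
      tree$edge.length <- age[tree$edge[, 1]] - age[tree$edge[, 2]]
      tree <- stats::reorder(tree, "cladewise")
      tree <- ape::read.tree(text = ape::write.tree(tree))
      break
    }
  }
  tree
}

#' Paper-shaped synthetic benchmark data set
#'
#' Generates a full synthetic study: a Yule chronogram, a mixed set of
#' binary and ordered multistate characters evolved under known rate
#' matrices, and a missingness mask. Default dimensions mirror a large
#' empirical floral-trait study (792 tips, 27 characters, 27\% missing);
#' pass smaller values for desk-scale work.
#'
#' @param n_tips,n_chars,missing_rate study dimensions.
#' @param rate mean evolutionary rate for the generating models.
#' @param seed RNG seed (drives every stage).
#' @return list: `tree`, `matrix` (`trait_matrix` with mask applied),
#'   `truth` (list of `sim_character` records), `generating` tibble.
#' @export
simulate_study <- function(n_tips = 792, n_chars = 27, missing_rate = 0.27,
                           rate = 0.05, seed = 1) {
  set.seed(seed)
  tree <- simulate_yule_tree(n_tips, 1)
  tree$edge.length <- tree$edge.length / max(node_ages(tree))  # unit depth
  truth <- list()
  gen <- list()
  df <- tibble::tibble(species = tree$tip.label)
  for (j in seq_len(n_chars)) {
    k <- sample(c(2, 2, 2, 3, 4), 1)       # mostly binary, some multistate
    nm <- sprintf("char%02d", j)
    spec <- mk_model(if (k == 2) "ER" else "SYM", k)
    rates <- rexp(spec$K, 1 / rate) * 5 + rate  # spread of regimes
    Q <- build_rate_matrix(spec, rates)
    sim <- simulate_character(tree, Q)
    truth[[nm]] <- sim
    gen[[nm]] <- tibble::tibble(character = nm, k = k, model = spec$name,
                                rates = paste(signif(rates, 3), collapse = ","))
    df[[nm]] <- unname(sim$tip_states[df$species])
  }
  mat <- inject_missing(trait_matrix(df), missing_rate,
                        inapplicable_share = 0.3)
  list(tree = tree, matrix = mat, truth = truth,
       generating = dplyr::bind_rows(gen))
}
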