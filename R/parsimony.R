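#' Sankoff parsimony score of a character on a tree
#'
#' Minimum total transition cost over all internal-node labelings, by
#' Sankoff dynamic programming (generalizes to polytomies directly).
#' Unit (Fitch) costs by default; `"ordered"` uses cost `|i - j|` over the
#' state order. Missing and inapplicable tips contribute zero cost for
#' every state, so adding a missing tip never changes the length.
#'
#' @param tree a `phylo` (branch lengths ignored).
#' @param states named character vector of tip states (`NA` = no signal).
#' @param costs `"unit"`, `"ordered"`, or a k x k cost matrix.
#' @param alphabet optional state alphabet (inferred from the data).
#' @return parsimony length (numeric; integer-valued for unit costs).
#' @examples
#' tr <- read_trees("((A:1,B:1):1,(C:1,D:1):1);")$trees[[1]]
#' parsimony_score(tr, c(A = "0", B = "0", C = "1", D = "1"))
#' @export
parsimony_score <- function(tree, states, costs = "unit", alphabet = NULL) {
  sk <- sankoff_down(tree, states, costs, alphabet)
  min(sk$down[root_node(tree), ])
}

#' Most-parsimonious reconstruction (MPR) state sets
#'
#' For every node, the set of states that appear in at least one
#' most-parsimonious labeling of the tree, from the Sankoff down-pass
#' combined with an up-pass carrying the cost of the rest of the tree.
#' Nodes whose set has more than one state are reported as equivocal.
#'
#' @inheritParams parsimony_score
#' @return an `mpr_result`: tibble with `node`, `states` (sorted,
#'   `"|"`-separated), `equivocal`; parsimony length in `attr(, "length")`.
#' @export
mpr_state_sets <- function(tree, states, costs = "unit", alphabet = NULL) {
  sk <- sankoff_down(tree, states, costs, alphabet)
  tree <- sk$tree
  D <- sk$down; cost <- sk$cost; k <- ncol(D)
  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  n_node <- max(edge)
  root <- root_node(tree)

  # U[v, s]: minimal cost of the tree outside v's subtree, given v = s
  U <- matrix(0, n_node, k)
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in rev(seq_len(nrow(edge)))) {        # preorder
    p <- edge[e, 1]; ch <- edge[e, 2]
    sib <- setdiff(kids[[as.character(p)]], e)
    # cost at p excluding child ch's subtree, for each parent state sp
    base <- U[p, ]
    for (s in sib) {
      cc <- edge[s, 2]
      base <- base + apply(cost + rep(D[cc, ], each = k), 1, min)
    }
    U[ch, ] <- apply(cost + rep(base, k), 2, min)  # min over sp of base[sp]+cost[sp,s]
  }

  total <- min(D[root, ])
  rows <- purrr::map_dfr(seq_len(n_node), function(v) {
    g <- D[v, ] + U[v, ]
    set <- sk$alphabet[abs(g - total) < 1e-9]
    tibble::tibble(node = v, states = paste(sort(set), collapse = "|"),
                   equivocal = length(set) > 1)
  })
  structure(rows, class = c("mpr_result", class(rows)), length = total,
            alphabet = sk$alphabet)
}

# Shared Sankoff down-pass. Returns per-node minimal subtree costs.
sankoff_down <- function(tree, states, costs = "unit", alphabet = NULL) {
  tree <- stats::reorder(ape::collapse.singles(tree), "postorder")
  states <- normalize_states(states)
  obs <- states[tree$tip.label]
  if (all(is.na(obs))) stop("all tips missing", call. = FALSE)
  if (is.null(alphabet)) alphabet <- infer_alphabet(obs)
  k <- length(alphabet)
  cost <- if (is.matrix(costs)) {
    stopifnot(nrow(costs) == k, ncol(costs) == k)
    costs
  } else if (identical(costs, "unit")) {
    matrix(1, k, k) - diag(k)
  } else if (identical(costs, "ordered")) {
    abs(outer(seq_len(k), seq_len(k), "-"))
  } else stop("unknown cost scheme", call. = FALSE)

  edge <- tree$edge
  n_tip <- length(tree$tip.label)
  n_node <- max(edge)
  D <- matrix(0, n_node, k)
  big <- 1e9
  for (i in seq_len(n_tip)) {
    s <- obs[[i]]
    if (!is.na(s)) {
      j <- match(s, alphabet)
      if (is.na(j)) stop("state '", s, "' not in alphabet", call. = FALSE)
      D[i, ] <- big
      D[i, j] <- 0
    }
  }
  for (e in seq_len(nrow(edge))) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    D[p, ] <- D[p, ] + apply(cost + rep(D[ch, ], each = k), 1, min)
  }
  list(tree = tree, down = D, cost = cost, alphabet = alphabet)
}
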