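#' Mk log-likelihood of a character on a chronogram
#'
#' Felsenstein pruning over the tree: the probability of the observed tip
#' states under the CTMC defined by `spec` and `rates`, integrating over
#' all internal-node states with the chosen root prior. Missing and
#' inapplicable tips enter as all-ones partial likelihoods, which yields
#' exactly the likelihood of the tree with those tips pruned. Polytomies
#' are handled natively by the product over children.
#'
#' @param tree a `phylo` chronogram.
#' @param states named character vector of tip states (`NA` = no signal),
#'   names matching tip labels.
#' @param spec an [mk_model()] specification.
#' @param rates one positive rate per free class of `spec`.
#' @param root_prior `NULL` (use the spec's mode), `"flat"`,
#'   `"equilibrium"`, or a length-k probability vector.
#' @return log-likelihood (scalar).
#' @examples
#' tr <- read_trees("(A:1,B:1);")$trees[[1]]
#' log_likelihood(tr, c(A = "0", B = "1"), mk_model("ER", 2), 0.5)
#' @export
log_likelihood <- function(tree, states, spec, rates, root_prior = NULL) {
  tree <- prep_tree(tree)
  states <- normalize_states(states)
  if (all(is.na(states[tree$tip.label]))) {
    stop("all tips missing: no observed states", call. = FALSE)
  }
  Q <- build_rate_matrix(spec, rates)
  tp <- tip_partials(tree, states, spec$alphabet)
  prior <- resolve_root_prior(spec, Q, root_prior)
  mk_loglik_cpp(tree$edge, tree$edge.length, length(tree$tip.label), tp, Q, prior)
}

# log-likelihood from precomputed pieces (hot path for fitting/MCMC)
loglik_raw <- function(ptree, tp, Q, prior) {
  mk_loglik_cpp(ptree$edge, ptree$edge.length, length(ptree$tip.label), tp, Q, prior)
}

#' Small-sample Akaike information criterion
#'
#' `AICc = -2 lnL + 2K + 2K(K+1)/(n - K - 1)`.
#'
#' @param lnL log-likelihood.
#' @param K number of free parameters.
#' @param n effective sample size (here: tips with observed states).
#' @return AICc value; error when `n - K - 1 <= 0`.
#' @export
aicc <- function(lnL, K, n) {
  if (n - K - 1 <= 0) {
    stop("AICc undefined: n - K - 1 <= 0 (n = ", n, ", K = ", K, ")", call. = FALSE)
  }
  -2 * lnL + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' Akaike weights from information-criterion values
#'
#' @param ic vector of AIC/AICc values for a candidate set.
#' @return weights proportional to `exp(-delta/2)`, summing to 1.
#' @export
akaike_weights <- function(ic) {
  d <- ic - min(ic)
  w <- exp(-d / 2)
  w / sum(w)
}

#' Fit an Mk model by maximum likelihood
#'
#' Optimizes the free rates on the log scale (bounds `[1e-9, 100]` per
#' rate) with L-BFGS-B from several start points: a parsimony-informed
#' start (observed changes divided by total tree length) plus fixed
#' pseudo-random multistarts. Non-convergence after the multistart budget
#' is flagged, never silent.
#'
#' @inheritParams log_likelihood
#' @param n_starts number of additional multistarts (default 5).
#' @param bounds rate bounds, default `c(1e-9, 100)`.
#' @return an `mk_fit`: spec, fitted `rates`, `lnL`, `K`, `n` (tips with
#'   observed states), `AICc`, `convergence` flag.
#' @export
fit_ml <- function(tree, states, spec, root_prior = NULL,
                   n_starts = 5, bounds = c(1e-9, 100)) {
  tree <- prep_tree(tree)
  states <- normalize_states(states)
  obs <- states[tree$tip.label]
  n_obs <- sum(!is.na(obs))
  if (n_obs == 0) stop("all tips missing", call. = FALSE)
  tp <- tip_partials(tree, states, spec$alphabet)
  K <- spec$K
  lb <- log(bounds[1]); ub <- log(bounds[2])

  nll <- function(logr) {
    Q <- build_rate_matrix(spec, exp(logr))
    prior <- resolve_root_prior(spec, Q, root_prior)
    ll <- loglik_raw(tree, tp, Q, prior)
    if (!is.finite(ll)) 1e10 else -ll
  }

  # parsimony-informed start: changes per unit tree time
  p_len <- tryCatch(parsimony_score(tree, states), error = function(e) 1)
  q0 <- max(p_len, 0.5) / sum(tree$edge.length)
  q0 <- min(max(q0, bounds[1] * 10), bounds[2] / 10)
  starts <- list(rep(log(q0), K))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(20231101L)  # fixed multistart seeds: fits are deterministic
  for (i in seq_len(n_starts)) {
    starts[[i + 1]] <- pmin(pmax(log(q0) + rnorm(K, 0, 1.5), lb), ub)
  }

  best <- NULL
  conv <- FALSE
  for (s in starts) {
    o <- tryCatch(
      optim(s, nll, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(o)) next
    if (is.null(best) || o$value < best$value) {
      best <- o
      conv <- conv || o$convergence == 0
    } else {
      conv <- conv || o$convergence == 0
    }
  }
  if (is.null(best)) stop("optimization failed from every start", call. = FALSE)

  rates <- exp(best$par)
  lnL <- -best$value
  structure(
    list(spec = spec, model = spec$name, rates = rates, lnL = lnL, K = K,
         n = n_obs,
         AICc = tryCatch(aicc(lnL, K, n_obs), error = function(e) NA_real_),
         root_prior = root_prior %||% spec$root_prior,
         convergence = conv, tree = tree, states = states),
    class = "mk_fit")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible()
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("<mk_fit> ", x$model, ": lnL = ", format(x$lnL, digits = 6),
      ", K = ", x$K, ", AICc = ", format(x$AICc, digits = 6),
      if (!x$convergence) " [NOT CONVERGED]", "\n", sep = "")
  invisible(x)
}

#' Default candidate model sets
#'
#' Binary characters get \{ER, ARD, ARDeq, UNI01, UNI10\}; unordered
#' multistate characters get \{ER, SYM, SYMeq, ARD, ARDeq\}; ordered
#' multistate characters add the ordered family \{ORD, ORDeq, ORDSYM,
#' ORDSYMeq, ORDER\}. ER and ORDER have no `eq` variant (equilibrium equals
#' flat); the unidirectional models have the root implied.
#'
#' @param k number of states.
#' @param ordered is the character ordered (count-derived)?
#' @return character vector of model names.
#' @export
default_candidates <- function(k, ordered = FALSE) {
  if (k == 2) return(c("ER", "ARD", "ARDeq", "UNI01", "UNI10"))
  base <- c("ER", "SYM", "SYMeq", "ARD", "ARDeq")
  if (ordered) c(base, "ORD", "ORDeq", "ORDSYM", "ORDSYMeq", "ORDER") else base
}

#' Fit and rank a candidate model set by AICc
#'
#' @inheritParams fit_ml
#' @param candidates model names (default from [default_candidates()]).
#' @param ordered is the character ordered? (affects the default set)
#' @return a `model_selection`: tibble ranked by AICc with columns `model`,
#'   `K`, `lnL`, `AICc`, `delta`, `weight`; the fitted objects in
#'   `attr(, "fits")`; the best fit is `attr(, "best")`.
#' @export
model_select <- function(tree, states, candidates = NULL, ordered = FALSE, ...) {
  states <- normalize_states(states)
  alpha <- infer_alphabet(states)
  k <- length(alpha)
  if (k < 2) stop("character is constant: no model comparison possible", call. = FALSE)
  if (is.null(candidates)) candidates <- default_candidates(k, ordered)
  fits <- purrr::map(candidates, function(nm) {
    fit_ml(tree, states, mk_model(nm, k, alphabet = alpha), ...)
  })
  names(fits) <- candidates
  tab <- purrr::map_dfr(fits, function(f) {
    tibble::tibble(model = f$model, K = f$K, lnL = f$lnL, AICc = f$AICc,
                   converged = f$convergence)
  })
  if (anyNA(tab$AICc)) {
    stop("AICc undefined (n - K - 1 <= 0) for model(s): ",
         paste(tab$model[is.na(tab$AICc)], collapse = ", "), call. = FALSE)
  }
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  tab <- dplyr::arrange(tab, .data$AICc)
  structure(tab, class = c("model_selection", class(tab)),
            fits = fits, best = fits[[tab$model[1]]])
}

#' Marginal ancestral state probabilities
#'
#' For every internal node, the marginal posterior distribution over states
#' under the fitted model: the normalized product of the node's downward
#' partial likelihood and the likelihood flowing from the rest of the tree
#' (computed by a root-to-tip message pass; valid for non-reversible
#' models). Ties in the modal state (probability gap < 1e-9) are reported
#' as ties.
#'
#' @param tree,states as in [log_likelihood()]; taken from `fit` when omitted.
#' @param fit an `mk_fit`.
#' @return a `marginal_recon` tibble: `node`, `state`, `prob`, `modal`,
#'   `tie`.
#' @export
marginal_ancestral <- function(fit, tree = NULL, states = NULL) {
  stopifnot(inherits(fit, "mk_fit"))
  tree <- prep_tree(tree %||% fit$tree)
  states <- normalize_states(states %||% fit$states)
  spec <- fit$spec
  Q <- build_rate_matrix(spec, fit$rates)
  prior <- resolve_root_prior(spec, Q, fit$root_prior)
  out <- node_marginals(tree, states, spec, Q, prior)
  structure(out, class = c("marginal_recon", class(out)))
}

# Two-pass marginal computation shared by ML and Bayesian samplers.
node_marginals <- function(tree, states, spec, Q, prior, nodes = NULL) {
  k <- spec$k
  n_tip <- length(tree$tip.label)
  tp <- tip_partials(tree, states, spec$alphabet)
  parts <- mk_partials_cpp(tree$edge, tree$edge.length, n_tip, tp, Q)
  D <- parts$partials
  P <- parts$P
  edge <- tree$edge
  n_node <- max(edge)
  root <- root_node(tree)

  # messages from parent side, preorder over edges
  A <- matrix(NA_real_, n_node, k)
  A[root, ] <- prior
  ord <- rev(seq_len(nrow(edge)))  # postorder reversed = valid preorder
  # per-edge downward message child -> parent: m_e[i] = sum_j P_e[i,j] D_child[j]
  msg <- matrix(NA_real_, nrow(edge), k)
  for (e in seq_len(nrow(edge))) {
    msg[e, ] <- P[, , e] %*% D[edge[e, 2], ]
  }
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  for (e in ord) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    sib <- setdiff(kids[[as.character(p)]], e)
    above <- A[p, ]
    for (s in sib) above <- above * msg[s, ]
    m <- as.numeric(above %*% P[, , e])   # sum_i above[i] P_e[i,j]
    if (max(m) > 0) m <- m / max(m)
    A[ch, ] <- m
  }

  wanted <- nodes %||% (n_tip + 1):n_node
  purrr::map_dfr(wanted, function(v) {
    pr <- A[v, ] * D[v, ]
    pr <- pr / sum(pr)
    modal <- pr >= max(pr) - 1e-9
    tibble::tibble(node = v, state = spec$alphabet, prob = pr,
                   modal = modal, tie = sum(modal) > 1)
  })
}

#' Most recent common ancestor of a taxon set
#'
#' @param tree a `phylo`.
#' @param taxa taxon labels; at least two must be present in the tree.
#' @return one-row tibble: `node`, `monophyletic` (TRUE iff the node's
#'   descendant tip set equals the query set), `n_found`.
#' @export
mrca_node <- function(tree, taxa) {
  present <- intersect(taxa, tree$tip.label)
  if (length(present) < 2) {
    stop("fewer than 2 query taxa present in tree", call. = FALSE)
  }
  node <- ape::getMRCA(tree, present)
  desc <- tree$tip.label[unlist(phangorn_free_descendants(tree, node))]
  tibble::tibble(node = node,
                 monophyletic = setequal(desc, present),
                 n_found = length(present))
}

# descendant tips of a node without a phangorn dependency
phangorn_free_descendants <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  edge <- tree$edge
  out <- integer(0)
  stack <- node
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    ch <- edge[edge[, 1] == v, 2]
    out <- c(out, ch[ch <= n_tip])
    stack <- c(stack, ch[ch > n_tip])
  }
  out
}
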