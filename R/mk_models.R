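#' Mk-family model specifications
#'
#' Build a model specification for a k-state continuous-time Markov (Mk)
#' model of discrete character evolution. A specification is a pattern of
#' equality constraints and forced zeros over the off-diagonal entries of
#' the rate matrix, together with a root-prior mode.
#'
#' Available single-character models:
#' \describe{
#'   \item{ER}{equal rates: a single transition rate.}
#'   \item{SYM}{symmetric: one rate per unordered state pair.}
#'   \item{ARD}{all rates different: one rate per ordered pair.}
#'   \item{ORD, ORDSYM, ORDER}{ordered models for characters derived from
#'     counts: transitions between non-adjacent states are forced to zero;
#'     ORD keeps a distinct rate per direction per adjacent pair, ORDSYM is
#'     the symmetric version, ORDER uses a single rate.}
#'   \item{UNI01, UNI10}{unidirectional binary models: UNI01 forces the
#'     1-to-0 rate to zero (change only away from state 0), UNI10 forces
#'     the 0-to-1 rate to zero. The root state is implied by the model
#'     (the source state of the remaining transition).}
#' }
#' An `eq` suffix (for example `"ARDeq"`) requests the equilibrium
#' (stationary) root prior instead of the flat prior; it changes nothing
#' else. Pair (combined two-trait) models are built with
#' [build_pair_model()].
#'
#' @param name model name, e.g. `"ER"`, `"ARDeq"`, `"ORDSYM"`.
#' @param k number of states (2 for UNI models).
#' @param alphabet optional state labels (defaults to `0:(k-1)`).
#' @return an object of class `mk_model`: name, `k`, `K` (free parameters),
#'   `class_id` (k x k matrix; 0 = forced zero, positive integers = equality
#'   classes), root-prior mode and alphabet.
#' @examples
#' mk_model("ER", 2)
#' mk_model("ORD", 4)
#' @export
mk_model <- function(name, k, alphabet = NULL) {
  stopifnot(is.character(name), length(name) == 1, k >= 2)
  eq <- grepl("eq$", name) && !name %in% c("ER", "ORDER")
  base <- if (eq) sub("eq$", "", name) else name
  if (is.null(alphabet)) alphabet <- as.character(0:(k - 1))
  stopifnot(length(alphabet) == k)

  cid <- matrix(0L, k, k)
  implied_root <- NA_integer_
  pairs_upper <- which(upper.tri(cid), arr.ind = TRUE)
  adj <- function(i, j) abs(i - j) == 1

  if (base == "ER") {
    cid[row(cid) != col(cid)] <- 1L
  } else if (base == "SYM") {
    cls <- 0L
    for (p in seq_len(nrow(pairs_upper))) {
      i <- pairs_upper[p, 1]; j <- pairs_upper[p, 2]
      cls <- cls + 1L
      cid[i, j] <- cls; cid[j, i] <- cls
    }
  } else if (base == "ARD") {
    cls <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j) { cls <- cls + 1L; cid[i, j] <- cls }  # row-major: 0->1 first
    }
  } else if (base == "ORD") {
    cls <- 0L
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i != j && adj(i, j)) { cls <- cls + 1L; cid[i, j] <- cls }
    }
  } else if (base == "ORDSYM") {
    cls <- 0L
    for (i in seq_len(k - 1)) {
      cls <- cls + 1L
      cid[i, i + 1] <- cls; cid[i + 1, i] <- cls
    }
  } else if (base == "ORDER") {
    for (i in seq_len(k - 1)) { cid[i, i + 1] <- 1L; cid[i + 1, i] <- 1L }
  } else if (base == "UNI01") {
    if (k != 2) stop("UNI models are binary-only", call. = FALSE)
    cid[1, 2] <- 1L            # 0 -> 1 free; 1 -> 0 forced zero
    implied_root <- 1L
  } else if (base == "UNI10") {
    if (k != 2) stop("UNI models are binary-only", call. = FALSE)
    cid[2, 1] <- 1L            # 1 -> 0 free; 0 -> 1 forced zero
    implied_root <- 2L
  } else {
    stop("unknown model name: ", name, call. = FALSE)
  }

  root_prior <- if (!is.na(implied_root)) "implied" else if (eq) "equilibrium" else "flat"
  structure(
    list(name = name, k = k, K = max(cid), class_id = cid,
         root_prior = root_prior, implied_root = implied_root,
         alphabet = alphabet, pair = FALSE),
    class = "mk_model"
  )
}

#' @export
print.mk_model <- function(x, ...) {
  cat("<mk_model> ", x$name, ": k = ", x$k, ", K = ", x$K,
      ", root prior = ", x$root_prior, "\n", sep = "")
  invisible(x)
}

#' Build a rate matrix from a model specification
#'
#' Fills the equality-class pattern of `spec` with one positive rate per
#' free class and sets the diagonal to minus the row sum, yielding a valid
#' CTMC generator Q (expected transitions per unit branch time).
#'
#' @param spec an [mk_model()] specification.
#' @param rates numeric vector, one value per free rate class (`spec$K`).
#' @return k x k generator matrix with zero row sums.
#' @examples
#' build_rate_matrix(mk_model("ER", 2), 0.5)
#' @export
build_rate_matrix <- function(spec, rates) {
  stopifnot(inherits(spec, "mk_model"))
  if (length(rates) != spec$K) {
    stop("expected ", spec$K, " rate(s), got ", length(rates), call. = FALSE)
  }
  if (any(rates < 0)) stop("rates must be nonnegative", call. = FALSE)
  k <- spec$k
  Q <- matrix(0, k, k)
  off <- spec$class_id > 0
  Q[off] <- rates[spec$class_id[off]]
  diag(Q) <- -rowSums(Q)
  dimnames(Q) <- list(spec$alphabet, spec$alphabet)
  Q
}

#' Stationary distribution of a rate matrix
#'
#' Returns the limiting state distribution of the chain started from the
#' flat distribution: for irreducible Q this is the usual stationary
#' distribution solving pi Q = 0; for reducible chains (e.g. unidirectional
#' models) it is the limiting distribution concentrated on the absorbing
#' class. Computed by repeated squaring of P(t) until the rows converge.
#'
#' @param Q generator matrix.
#' @param tol convergence tolerance on the transition-matrix rows.
#' @return probability vector summing to 1.
#' @export
stationary_distribution <- function(Q, tol = 1e-13) {
  k <- nrow(Q)
  scale <- max(abs(Q))
  if (scale == 0) return(rep(1 / k, k))
  P <- expm_cpp(Q, 1 / scale)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  for (i in 1:80) {
    P2 <- P %*% P
    # keep the iterate stochastic: squaring accumulates rounding drift
    P2[P2 < 0] <- 0
    P2 <- P2 / rowSums(P2)
    if (max(abs(P2 - P)) < tol) { P <- P2; break }
    P <- P2
  }
  pi <- colMeans(P)         # flat start
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' @param Q generator matrix.
#' @param t branch time, `t >= 0`.
#' @return stochastic matrix of state-to-state probabilities over time t.
#' @examples
#' transition_probability(build_rate_matrix(mk_model("ER", 2), 0.5), 1)
#' @export
transition_probability <- function(Q, t) {
  if (t < 0) stop("t must be nonnegative", call. = FALSE)
  P <- expm_cpp(Q, t)
  P[P < 0] <- 0
  P
}

#' Enumerate rate-class partition models
#'
#' A rate-class model over `n_params` free transition parameters assigns
#' each parameter either to the distinguished zero class (rate exactly 0)
#' or to one of a set of unlabeled positive-rate classes; parameters in the
#' same class share one rate. The all-zero model is excluded. The number of
#' such models is Bell(n+1) - 1, e.g. 21,146 for the 8 parameters of a
#' combined two-binary-trait model and 51 for the 4 parameters of its
#' independent submodel.
#'
#' @param n_params number of free transition parameters (>= 1).
#' @param include_zero_class if `FALSE`, enumerate plain set partitions
#'   (no zero class), giving Bell(n) models.
#' @return a `model_space` object: `n_params`, `count`, and `assignments`,
#'   a count x n_params integer matrix (0 = zero class, positive integers =
#'   rate classes numbered by first occurrence).
#' @examples
#' enumerate_rate_class_models(2)$count # 4
#' @export
enumerate_rate_class_models <- function(n_params, include_zero_class = TRUE) {
  if (n_params < 1) stop("n_params must be >= 1", call. = FALSE)
  key <- paste0("space_", n_params, "_", include_zero_class)
  if (!is.null(.mktraits_env[[key]])) return(.mktraits_env[[key]])

  if (include_zero_class) {
    idx <- seq_len(n_params)
    rows <- list()
    for (zn in 0:n_params) {
      zsets <- if (zn == 0) list(integer(0)) else
        apply(combn(n_params, zn), 2, identity, simplify = FALSE)
      sub <- if (zn == n_params) NULL else enumerate_set_partitions(n_params - zn)
      for (zs in zsets) {
        keep <- setdiff(idx, zs)
        if (length(keep) == 0) next  # all-zero model excluded
        for (r in seq_len(nrow(sub))) {
          a <- integer(n_params)
          a[keep] <- sub[r, seq_along(keep)]
          rows[[length(rows) + 1]] <- a
        }
      }
    }
    assignments <- do.call(rbind, rows)
  } else {
    assignments <- enumerate_set_partitions(n_params)
  }
  out <- structure(
    list(n_params = n_params, count = nrow(assignments),
         include_zero_class = include_zero_class, assignments = assignments),
    class = "model_space"
  )
  .mktraits_env[[key]] <- out
  out
}

# All set partitions of n elements as canonical restricted-growth strings.
enumerate_set_partitions <- function(n) {
  if (n == 0) return(matrix(integer(0), nrow = 1, ncol = 0))
  acc <- list()
  rec <- function(a, i, mx) {
    if (i > n) { acc[[length(acc) + 1]] <<- a; return(invisible()) }
    for (cls in seq_len(mx + 1)) {
      a[i] <- cls
      rec(a, i + 1, max(mx, cls))
    }
  }
  rec(integer(n), 1L, 0L)
  do.call(rbind, acc)
}

#' @export
print.model_space <- function(x, ...) {
  cat("<model_space> ", x$n_params, " parameters, ", x$count, " models",
      if (x$include_zero_class) " (with zero class)", "\n", sep = "")
  invisible(x)
}

# Canonical signature string for a zero/class assignment vector.
partition_signature <- function(a) paste(a, collapse = ",")

# Canonicalize an assignment vector: nonzero classes renumbered by first
# occurrence, zero class kept as 0.
canonicalize_assignment <- function(a) {
  nz <- a != 0
  if (!any(nz)) return(a)
  lev <- unique(a[nz])
  a[nz] <- match(a[nz], lev)
  a
}

# Row-major layout of the k(k-1) free parameters of an all-rates-different
# chain: parameter 1 is the first off-diagonal entry of row 1 (0 -> 1).
ard_param_layout <- function(k) {
  ids <- matrix(0L, k, k)
  cls <- 0L
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j) { cls <- cls + 1L; ids[i, j] <- cls }
  }
  ids
}

# Layout of the 8 free parameters of a combined two-binary-trait model
# with dual transitions excluded. Combined states are (00, 01, 10, 11)
# with trait 1 the high bit. Parameter order:
#   1 q(00->01)  2 q(01->00)  [trait-2 gain/loss when trait 1 = 0]
#   3 q(00->10)  4 q(10->00)  [trait-1 gain/loss when trait 2 = 0]
#   5 q(01->11)  6 q(11->01)  [trait-1 gain/loss when trait 2 = 1]
#   7 q(10->11)  8 q(11->10)  [trait-2 gain/loss when trait 1 = 1]
pair_param_layout <- function() {
  id <- matrix(0L, 4, 4)
  tr <- rbind(c(1, 2, 1L), c(2, 1, 2L), c(1, 3, 3L), c(3, 1, 4L),
              c(2, 4, 5L), c(4, 2, 6L), c(3, 4, 7L), c(4, 3, 8L))
  for (r in seq_len(nrow(tr))) id[tr[r, 1], tr[r, 2]] <- tr[r, 3]
  id
}

# Independence: each trait's gain and loss rates must not depend on the
# state of the other trait, i.e. parameter pairs (1,7), (2,8), (3,5), (4,6)
# each share a class (the zero class counts as shared).
pair_independence_pairs <- function() list(c(1L, 7L), c(2L, 8L), c(3L, 5L), c(4L, 6L))

# TRUE iff a zero/class assignment over the 8 pair parameters describes an
# independent (uncorrelated) model.
is_independent_assignment <- function(a) {
  all(vapply(pair_independence_pairs(), function(p) a[p[1]] == a[p[2]], logical(1)))
}

#' Combined two-trait model space with dependent/independent counts
#'
#' Enumerates the rate-class models over the 8 transition parameters of a
#' combined two-binary-trait chain (dual transitions excluded) and
#' classifies each as dependent or independent. A model is independent when
#' each trait's gain and loss rates are identical across the other trait's
#' states.
#'
#' @return a `model_space` with extra fields `independent` (logical vector)
#'   and counts `n_independent`, `n_dependent`.
#' @examples
#' \donttest{
#' sp <- pair_model_space()
#' c(sp$count, sp$n_independent) # 21146, 51
#' }
#' @export
pair_model_space <- function() {
  key <- "pair_space"
  if (!is.null(.mktraits_env[[key]])) return(.mktraits_env[[key]])
  sp <- enumerate_rate_class_models(8)
  ind <- apply(sp$assignments, 1, is_independent_assignment)
  sp$independent <- ind
  sp$n_independent <- sum(ind)
  sp$n_dependent <- sum(!ind)
  .mktraits_env[[key]] <- sp
  sp
}

#' Build a combined two-binary-trait model
#'
#' Constructs a 4-state Mk model over the combined states (00, 01, 10, 11)
#' of two binary traits, with the four dual transitions (both traits
#' changing at once) forced to zero, as in pairwise correlated-evolution
#' tests. Models:
#' \describe{
#'   \item{ERnodual}{a single rate for all 8 allowed transitions (independent).}
#'   \item{UNCORRnodual}{4 rates: each trait's gain and loss, shared across
#'     the other trait's states (the most general independent model).}
#'   \item{SYMnodual}{4 rates: forward = backward for each allowed
#'     transition pair (dependent).}
#'   \item{ARDnodual}{8 distinct rates (dependent).}
#' }
#' The `eq` suffix selects the equilibrium root prior.
#'
#' @param name one of the names above, optionally with `eq` suffix.
#' @return an `mk_model` with `pair = TRUE` and an `independent` flag.
#' @examples
#' build_pair_model("UNCORRnodual")$independent
#' @export
build_pair_model <- function(name) {
  eq <- grepl("eq$", name)
  base <- sub("eq$", "", name)
  layout <- pair_param_layout()
  cls <- switch(base,
    ERnodual     = rep(1L, 8),
    UNCORRnodual = c(1L, 2L, 3L, 4L, 3L, 4L, 1L, 2L),
    SYMnodual    = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
    ARDnodual    = 1:8,
    stop("unknown pair model: ", name, call. = FALSE)
  )
  cid <- matrix(0L, 4, 4)
  cid[layout > 0] <- cls[layout[layout > 0]]
  alphabet <- c("00", "01", "10", "11")
  structure(
    list(name = name, k = 4L, K = max(cls), class_id = cid,
         root_prior = if (eq) "equilibrium" else "flat",
         implied_root = NA_integer_, alphabet = alphabet, pair = TRUE,
         independent = is_independent_assignment(cls)),
    class = "mk_model"
  )
}

#' Summary counts for a pair-model space
#'
#' @param space a `model_space`, typically [pair_model_space()].
#' @return one-row tibble with total, independent and dependent model counts.
#' @export
model_space_info <- function(space = pair_model_space()) {
  tibble::tibble(
    n_params = space$n_params,
    n_models = space$count,
    n_independent = if (!is.null(space$n_independent)) space$n_independent else NA_integer_,
    n_dependent = if (!is.null(space$n_dependent)) space$n_dependent else NA_integer_
  )
}
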