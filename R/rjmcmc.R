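#' MCMC settings for reversible-jump runs
#'
#' Defaults follow common practice for large empirical analyses: 10M
#' generations, sampling every 100, the first 1M discarded as burn-in, and
#' an exponential prior on class rates whose mean is itself uniform on
#' (0, 1) (a weak hyperprior). Desk-scale runs should pass much smaller
#' values explicitly.
#'
#' @param generations total generations.
#' @param sample_interval record every this many generations (post burn-in).
#' @param burn_in generations discarded before sampling starts.
#' @param seed RNG seed; chains are reproducible bit-for-bit.
#' @param move_weights proposal mix: `rate` (multiplicative log-normal rate
#'   update), `local` (move one parameter to another rate class, including
#'   the zero class, with affected class rates drawn from the conditional
#'   prior), `global` (independence jump: redraw the whole model and all
#'   rates from the prior), `tree` (switch to a tree drawn uniformly from
#'   the sample), `hyper` (redraw the hyperprior mean).
#' @param rate_sd standard deviation of the log-normal rate proposal.
#' @return an `rj_settings` list.
#' @export
rj_settings <- function(generations = 1e7, sample_interval = 100,
                        burn_in = 1e6, seed = 1L,
                        move_weights = c(rate = 0.40, local = 0.35,
                                         global = 0.10, tree = 0.10,
                                         hyper = 0.05),
                        rate_sd = 0.6) {
  stopifnot(burn_in < generations, sample_interval >= 1)
  mw <- move_weights / sum(move_weights)
  structure(list(generations = as.integer(generations),
                 sample_interval = as.integer(sample_interval),
                 burn_in = as.integer(burn_in), seed = as.integer(seed),
                 move_weights = mw, rate_sd = rate_sd),
            class = "rj_settings")
}

#' A rate-class partition model state
#'
#' @param assignment integer vector over the free transition parameters:
#'   0 for the zero class, positive canonical class indices otherwise.
#' @param rates one positive rate per nonzero class.
#' @return a `rate_partition`.
#' @export
rate_partition <- function(assignment, rates) {
  a <- canonicalize_assignment(as.integer(assignment))
  if (!any(a != 0)) stop("all parameters in the zero class", call. = FALSE)
  if (length(rates) != max(a)) {
    stop("need ", max(a), " rate(s), got ", length(rates), call. = FALSE)
  }
  if (any(rates <= 0)) stop("class rates must be positive", call. = FALSE)
  structure(list(assignment = a, rates = as.numeric(rates)),
            class = "rate_partition")
}

# Build a generator matrix from a template (param-id layout) and partition.
partition_Q <- function(template, a, r) {
  Q <- matrix(0, template$k, template$k)
  ids <- template$param_id
  pos <- which(ids > 0)
  vals <- numeric(template$n_params)
  nz <- a != 0
  vals[nz] <- r[a[nz]]
  Q[pos] <- vals[ids[pos]]
  diag(Q) <- -rowSums(Q)
  Q
}

# Valid local moves from assignment a: (param, target) pairs where target
# is 0 (zero class), an existing other class, or -1 (new singleton class).
# Moves emptying every nonzero class are excluded.
local_move_targets <- function(a, i) {
  ncls <- max(a)
  cur <- a[i]
  if (cur == 0L) return(c(seq_len(ncls), -1L))
  n_nonzero <- sum(a != 0L)
  size <- sum(a == cur)
  c(if (n_nonzero > 1L) 0L, setdiff(seq_len(ncls), cur), if (size > 1L) -1L)
}

count_local_moves <- function(a) {
  n <- length(a)
  ncls <- max(a)
  n_nonzero <- sum(a != 0L)
  sizes <- tabulate(a[a != 0L], nbins = ncls)
  total <- 0L
  per <- integer(n)
  for (i in seq_len(n)) {
    cur <- a[i]
    per[i] <- if (cur == 0L) ncls + 1L else
      (ncls - 1L) + (n_nonzero > 1L) + (sizes[cur] > 1L)
  }
  list(total = sum(per), per = per)
}

sample_local_move <- function(a, counts) {
  i <- sample.int(length(a), 1, prob = counts$per)
  targets <- local_move_targets(a, i)
  c(i, targets[sample.int(length(targets), 1)])
}

# Apply a local move; returns new canonical assignment, rates and a flag
# list describing births/deaths (for the Hastings bookkeeping done by the
# caller via prior draws that cancel).
apply_local_move <- function(a, r, move, m) {
  i <- move[1]; target <- move[2]
  cur <- a[i]
  a2 <- a
  r2 <- r
  if (target == -1L) {               # birth of a singleton class
    a2[i] <- max(a) + 1L
    r2 <- c(r, rexp(1, rate = 1 / m))
  } else {
    a2[i] <- target
  }
  if (cur != 0L && sum(a2 == cur) == 0L) {  # class died
    r2 <- r2[-cur]
    a2[a2 > cur] <- a2[a2 > cur] - 1L
  }
  # canonical renumbering by first occurrence, rates permuted alongside
  nzpos <- which(a2 != 0)
  lev <- unique(a2[nzpos])
  a3 <- a2
  a3[nzpos] <- match(a2[nzpos], lev)
  r3 <- r2[lev]
  list(a = a3, r = r3)
}

#' Run a reversible-jump MCMC over rate-class models
#'
#' Samples jointly over (model, rates, hyperprior mean, tree) for one
#' discrete character: the model is a partition of the free transition
#' parameters into unlabeled rate classes plus a distinguished zero class
#' (uniform prior over the enumerated space), class rates carry an
#' exponential prior with mean `m`, and `m` is uniform on (0, 1).
#' Tree uncertainty is integrated by Metropolis moves over the supplied
#' tree sample. Marginal ancestral-state probability vectors are recorded
#' for each focal node at every sampled generation.
#'
#' @param trees a `tree_sample` or single `phylo`.
#' @param states named character vector of tip states (`NA` = no signal).
#' @param settings an [rj_settings()].
#' @param focal_nodes named list of taxon-label vectors; the MRCA of each
#'   set is tracked (flagged when non-monophyletic in the current tree).
#' @param alphabet optional state alphabet.
#' @param root_prior `"flat"` (default) or `"equilibrium"`.
#' @param template internal: parameter layout (defaults to the all-rates
#'   layout over `k` states; [run_pair_rjmcmc()] supplies the combined
#'   two-trait layout).
#' @return an `rjmcmc_fit`: `trace` tibble (generation, lnL, tree index,
#'   class counts, hyperprior mean, model signature, focal-node state
#'   probabilities), `model_freq`, `summary` (per node and state: mean,
#'   95% CI, ESS), `acceptance`, and the settings.
#' @export
run_rjmcmc <- function(trees, states, settings = rj_settings(),
                       focal_nodes = NULL, alphabet = NULL,
                       root_prior = c("flat", "equilibrium"),
                       template = NULL) {
  root_prior <- match.arg(root_prior)
  if (inherits(trees, "phylo")) trees <- tree_sample(trees)
  states <- normalize_states(states)
  if (is.null(alphabet)) {
    alphabet <- tryCatch(infer_alphabet(states), error = function(e) c("0", "1"))
  }
  k <- length(alphabet)
  if (is.null(template)) {
    template <- list(k = k, n_params = k * (k - 1L),
                     param_id = ard_param_layout(k), alphabet = alphabet)
  }
  spec_like <- list(k = template$k, alphabet = template$alphabet,
                    root_prior = root_prior, implied_root = NA_integer_)
  class(spec_like) <- "mk_model"
  rj_engine(trees, states, template, settings, focal_nodes, spec_like)
}

# Uniform draw from the rate-class model space without enumeration:
# Stam's urn method samples a uniform set partition of the n parameters
# plus the zero marker; the marker's block is the zero class. The all-zero
# partition is rejected, leaving the uniform distribution on the space.
sample_uniform_assignment <- function(n_params) {
  m <- n_params + 1L
  u_max <- m + 60L
  lw <- m * log(seq_len(u_max)) - lgamma(seq_len(u_max) + 1)
  w <- exp(lw - max(lw))
  repeat {
    u <- sample.int(u_max, 1, prob = w)
    urn <- sample.int(u, m, replace = TRUE)
    a <- integer(n_params)
    zero_urn <- urn[m]
    par_urn <- urn[seq_len(n_params)]
    nz <- par_urn != zero_urn
    if (!any(nz)) next                      # all-zero model excluded
    a[nz] <- match(par_urn[nz], unique(par_urn[nz]))
    return(a)
  }
}

rj_engine <- function(trees, states, template, settings, focal_nodes, spec_like) {
  set.seed(settings$seed)
  n_par <- template$n_params
  # full enumeration is cheap up to ~10 parameters (Bell(11) models);
  # beyond that the global jump samples the space uniformly instead
  use_enum <- n_par <= 10
  space <- if (use_enum) enumerate_rate_class_models(n_par) else
    structure(list(n_params = n_par, count = NA_integer_,
                   include_zero_class = TRUE, assignments = NULL),
              class = "model_space")
  ptrees <- lapply(trees$trees, prep_tree)
  tparts <- lapply(ptrees, function(tr) tip_partials(tr, states, template$alphabet))
  all_missing <- all(vapply(tparts, function(tp) all(tp == 1), logical(1)))

  # focal node resolution per tree (MRCA + monophyly), cached
  focal <- focal_nodes %||% list()
  fmap <- lapply(ptrees, function(tr) {
    lapply(focal, function(tx) {
      res <- tryCatch(mrca_node(tr, tx), error = function(e) NULL)
      if (is.null(res)) list(node = NA_integer_, mono = NA) else
        list(node = res$node, mono = res$monophyletic)
    })
  })
  if (length(focal)) {
    unresolved <- vapply(seq_along(focal), function(j) {
      mean(vapply(fmap, function(f) is.na(f[[j]]$node), logical(1)))
    }, numeric(1))
    if (any(unresolved > 0.5)) {
      stop("focal clade unresolvable in more than half of the trees: ",
           paste(names(focal)[unresolved > 0.5], collapse = ", "), call. = FALSE)
    }
  }

  flat_prior <- rep(1 / template$k, template$k)
  lnL_of <- function(a, r, ti) {
    if (all_missing) return(0)
    Q <- partition_Q(template, a, r)
    prior <- if (spec_like$root_prior == "equilibrium")
      stationary_distribution(Q) else flat_prior
    loglik_raw(ptrees[[ti]], tparts[[ti]], Q, prior)
  }

  # initial state: single shared rate class, prior draws
  m <- runif(1)
  a <- rep(1L, n_par)
  r <- rexp(1, 1 / m)
  ti <- sample.int(length(ptrees), 1)
  lnL <- lnL_of(a, r, ti)
  if (!is.finite(lnL)) stop("non-finite initial log-likelihood", call. = FALSE)

  G <- settings$generations; B <- settings$burn_in; S <- settings$sample_interval
  n_samp <- floor((G - B) / S)
  mw <- settings$move_weights
  move_names <- names(mw)
  prop_count <- acc_count <- setNames(numeric(length(mw)), move_names)

  sig_v <- character(n_samp)
  gen_v <- integer(n_samp); lnL_v <- numeric(n_samp); tree_v <- integer(n_samp)
  ncls_v <- integer(n_samp); zero_v <- integer(n_samp); m_v <- numeric(n_samp)
  fprob <- if (length(focal))
    matrix(NA_real_, n_samp, length(focal) * template$k) else NULL
  fmono <- if (length(focal)) matrix(NA, n_samp, length(focal)) else NULL
  si <- 0L

  for (gen in seq_len(G)) {
    mv <- move_names[sample.int(length(mw), 1, prob = mw)]
    prop_count[mv] <- prop_count[mv] + 1
    if (mv == "rate") {
      cls <- sample.int(length(r), 1)
      r2 <- r
      r2[cls] <- r[cls] * exp(rnorm(1, 0, settings$rate_sd))
      lnL2 <- lnL_of(a, r2, ti)
      la <- (lnL2 - lnL) + (r[cls] - r2[cls]) / m + log(r2[cls] / r[cls])
      if (is.finite(la) && log(runif(1)) < la) {
        r <- r2; lnL <- lnL2; acc_count[mv] <- acc_count[mv] + 1
      }
    } else if (mv == "local") {
      counts <- count_local_moves(a)
      Tm <- counts$total
      prop <- apply_local_move(a, r, sample_local_move(a, counts), m)
      Tm2 <- count_local_moves(prop$a)$total
      lnL2 <- lnL_of(prop$a, prop$r, ti)
      la <- (lnL2 - lnL) + log(Tm) - log(Tm2)
      if (is.finite(la) && log(runif(1)) < la) {
        a <- prop$a; r <- prop$r; lnL <- lnL2
        acc_count[mv] <- acc_count[mv] + 1
      }
    } else if (mv == "global") {
      a2 <- if (use_enum) space$assignments[sample.int(space$count, 1), ]
        else sample_uniform_assignment(n_par)
      r2 <- rexp(max(a2), 1 / m)
      lnL2 <- lnL_of(a2, r2, ti)
      la <- lnL2 - lnL
      if (is.finite(la) && log(runif(1)) < la) {
        a <- a2; r <- r2; lnL <- lnL2
        acc_count[mv] <- acc_count[mv] + 1
      }
    } else if (mv == "tree") {
      if (length(ptrees) > 1) {
        tj <- sample.int(length(ptrees), 1)
        lnL2 <- lnL_of(a, r, tj)
        if (is.finite(lnL2) && log(runif(1)) < lnL2 - lnL) {
          ti <- tj; lnL <- lnL2; acc_count[mv] <- acc_count[mv] + 1
        }
      }
    } else if (mv == "hyper") {
      m2 <- runif(1)
      la <- sum(dexp(r, 1 / m2, log = TRUE) - dexp(r, 1 / m, log = TRUE))
      if (log(runif(1)) < la) {
        m <- m2; acc_count[mv] <- acc_count[mv] + 1
      }
    }

    if (gen > B && (gen - B) %% S == 0L) {
      si <- si + 1L
      gen_v[si] <- gen; lnL_v[si] <- lnL; tree_v[si] <- ti
      ncls_v[si] <- max(a); zero_v[si] <- sum(a == 0); m_v[si] <- m
      sig_v[si] <- partition_signature(a)
      if (length(focal)) {
        Q <- partition_Q(template, a, r)
        prior <- if (spec_like$root_prior == "equilibrium")
          stationary_distribution(Q) else flat_prior
        for (j in seq_along(focal)) {
          fm <- fmap[[ti]][[j]]
          if (is.na(fm$node)) next
          if (all_missing && fm$node == root_node(ptrees[[ti]])) {
            # no data: the root marginal is exactly the root prior
            fprob[si, ((j - 1) * template$k + 1):(j * template$k)] <- prior
          } else {
            marg <- node_marginals(ptrees[[ti]], states, spec_like, Q, prior,
                                   nodes = fm$node)
            fprob[si, ((j - 1) * template$k + 1):(j * template$k)] <- marg$prob
          }
          fmono[si, j] <- fm$mono
        }
      }
    }
  }

  trace <- tibble::tibble(generation = gen_v, lnL = lnL_v, tree = tree_v,
                          n_classes = ncls_v, zero_size = zero_v,
                          hyper_mean = m_v, signature = sig_v)
  if (length(focal)) {
    cn <- as.vector(t(outer(names(focal), template$alphabet, paste, sep = ".P")))
    colnames(fprob) <- cn
    trace <- dplyr::bind_cols(trace, tibble::as_tibble(fprob))
  }

  model_freq <- trace |>
    dplyr::count(.data$signature, name = "visits") |>
    dplyr::mutate(freq = .data$visits / sum(.data$visits)) |>
    dplyr::arrange(dplyr::desc(.data$visits))

  summ <- NULL
  if (length(focal)) {
    summ <- purrr::map_dfr(seq_along(focal), function(j) {
      purrr::map_dfr(seq_len(template$k), function(s) {
        p <- fprob[, (j - 1) * template$k + s]
        p <- p[!is.na(p)]
        ci <- credibility_interval(p)
        tibble::tibble(node = names(focal)[j], state = template$alphabet[s],
                       mean = mean(p), ci_lower = ci[1], ci_upper = ci[2],
                       ess = effective_sample_size(p)$ess,
                       monophyly_fraction = mean(fmono[, j], na.rm = TRUE))
      })
    })
  }

  structure(list(trace = trace, model_freq = model_freq, summary = summ,
                 acceptance = tibble::tibble(move = move_names,
                                             proposed = as.numeric(prop_count),
                                             accepted = as.numeric(acc_count),
                                             rate = ifelse(prop_count > 0,
                                                           acc_count / prop_count, NA)),
                 settings = settings, space = space,
                 alphabet = template$alphabet, focal = names(focal)),
            class = "rjmcmc_fit")
}

#' @export
print.rjmcmc_fit <- function(x, ...) {
  cat("<rjmcmc_fit> ", nrow(x$trace), " samples, ",
      nrow(x$model_freq), " models visited\n", sep = "")
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

#' Equal-tailed credibility interval
#'
#' @param samples numeric draws (e.g. a node-state probability across MCMC
#'   samples).
#' @param level interval mass, in (0, 1); default 0.95.
#' @return numeric length-2 vector (lower, upper).
#' @export
credibility_interval <- function(samples, level = 0.95) {
  if (level <= 0 || level >= 1) stop("level must be in (0,1)", call. = FALSE)
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  alpha <- (1 - level) / 2
  unname(quantile(samples, c(alpha, 1 - alpha)))
}

#' Effective sample size of an MCMC trace
#'
#' `ESS = n / (1 + 2 * sum(rho_k))` with the autocorrelation sum truncated
#' by Geyer's initial-positive-sequence rule (stop when a consecutive pair
#' of autocorrelations turns nonpositive). Values below 200 are flagged,
#' following the usual convergence guideline.
#'
#' @param trace numeric vector of post-burn-in samples (>= 10).
#' @return one-row tibble: `ess`, `flag` (`"ok"`, `"low"`, or
#'   `"undefined"` for a zero-variance trace).
#' @export
effective_sample_size <- function(trace) {
  n <- length(trace)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  if (stats::var(trace) == 0) {
    return(tibble::tibble(ess = NA_real_, flag = "undefined"))
  }
  rho <- as.numeric(acf(trace, lag.max = min(n - 1, 2000),
                        plot = FALSE, demean = TRUE)$acf)[-1]
  s <- 0
  i <- 1
  while (i <= length(rho)) {
    pair <- rho[i] + if (i + 1 <= length(rho)) rho[i + 1] else 0
    if (pair <= 0) break
    s <- s + rho[i] + if (i + 1 <= length(rho)) rho[i + 1] else 0
    i <- i + 2
  }
  ess <- n / (1 + 2 * s)
  tibble::tibble(ess = ess, flag = if (ess < 200) "low" else "ok")
}

#' Ancestral-state draw or marginal under a fixed rate-class model
#'
#' Computes the marginal posterior state distribution at one node under a
#' given partition model, tree and character, and optionally draws a state
#' from it.
#'
#' @param tree a `phylo`.
#' @param states named tip-state vector.
#' @param partition a [rate_partition()].
#' @param node internal node id (e.g. from [mrca_node()]).
#' @param alphabet state alphabet.
#' @param root_prior `"flat"` or `"equilibrium"`.
#' @param draw if `TRUE`, return a single sampled state; otherwise the
#'   marginal probability tibble.
#' @export
sample_ancestral_state <- function(tree, states, partition, node,
                                   alphabet = NULL, root_prior = "flat",
                                   draw = FALSE) {
  stopifnot(inherits(partition, "rate_partition"))
  states <- normalize_states(states)
  if (is.null(alphabet)) alphabet <- infer_alphabet(states)
  k <- length(alphabet)
  template <- list(k = k, n_params = k * (k - 1L),
                   param_id = ard_param_layout(k), alphabet = alphabet)
  if (length(partition$assignment) != template$n_params) {
    stop("partition has ", length(partition$assignment),
         " parameters; expected ", template$n_params, call. = FALSE)
  }
  Q <- partition_Q(template, partition$assignment, partition$rates)
  spec_like <- structure(list(k = k, alphabet = alphabet,
                              root_prior = root_prior,
                              implied_root = NA_integer_), class = "mk_model")
  prior <- if (root_prior == "equilibrium") stationary_distribution(Q) else rep(1 / k, k)
  marg <- node_marginals(prep_tree(tree), states, spec_like, Q, prior, nodes = node)
  if (!draw) return(marg)
  sample(alphabet, 1, prob = marg$prob)
}
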