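# Combined two-trait machinery: each pair of binary characters is analysed
# on the 4 combined states (00, 01, 10, 11), trait 1 the high bit, with
# dual transitions (both traits changing at once) forced to zero.

pair_model_names <- function() {
  c("ARDnodual", "ARDnodualeq", "SYMnodual", "SYMnodualeq",
    "ERnodual", "UNCORRnodual", "UNCORRnodualeq")
}
correlated_model_names <- function() {
  c("ARDnodual", "ARDnodualeq", "SYMnodual", "SYMnodualeq")
}

# Combined tip partial rows: p[(a,b)] = pA[a] * pB[b]; a missing trait
# contributes a flat factor, so partially observed tips keep their signal.
combined_partials <- function(tree, statesA, statesB) {
  pa <- tip_partials(tree, statesA, c("0", "1"))
  pb <- tip_partials(tree, statesB, c("0", "1"))
  out <- matrix(0, nrow(pa), 4)
  for (a in 0:1) for (b in 0:1) {
    out[, 2 * a + b + 1] <- pa[, a + 1] * pb[, b + 1]
  }
  out
}

check_binary <- function(states, label) {
  if (all(is.na(states))) return(invisible(TRUE))  # prior-only runs
  alpha <- infer_alphabet(states)
  if (!all(alpha %in% c("0", "1")) || length(alpha) > 2) {
    stop("character '", label, "' is not binary (states ",
         paste(alpha, collapse = ","), ")", call. = FALSE)
  }
}

# log-likelihood of a pair model given precomputed combined partials
pair_loglik <- function(ptree, cp, spec, rates) {
  Q <- build_rate_matrix(spec, rates)
  prior <- resolve_root_prior(spec, Q)
  loglik_raw(ptree, cp, Q, prior)
}

#' ML correlated-evolution test for a pair of binary characters
#'
#' Fits the seven combined 4-state models — four correlated (ARDnodual,
#' ARDnodualeq, SYMnodual, SYMnodualeq) and three uncorrelated (ERnodual,
#' UNCORRnodual, UNCORRnodualeq) — ranks them by AICc, and reports the
#' cumulative Akaike weight of the correlated models as the measure of
#' support for correlation.
#'
#' @param tree a `phylo`.
#' @param matrix a `trait_matrix` of binary characters.
#' @param charA,charB character (column) names.
#' @param n_starts multistarts per fit.
#' @return a `pair_fit`: tibble of the 7 fits (`model`, `K`, `lnL`, `AICc`,
#'   `delta`, `weight`, `correlated`), with `cum_correlated_weight`,
#'   `best_model` and the pair recorded as attributes.
#' @export
fit_pair_ml <- function(tree, matrix, charA, charB, n_starts = 3) {
  sa <- trait_states(matrix, charA)
  sb <- trait_states(matrix, charB)
  check_binary(sa, charA); check_binary(sb, charB)
  ptree <- prep_tree(tree)
  cp <- combined_partials(ptree, sa, sb)
  n_obs <- sum(!(is.na(sa[ptree$tip.label]) & is.na(sb[ptree$tip.label])))

  fits <- purrr::map(pair_model_names(), function(nm) {
    spec <- build_pair_model(nm)
    K <- spec$K
    lb <- log(1e-9); ub <- log(100)
    nll <- function(logr) {
      ll <- pair_loglik(ptree, cp, spec, exp(logr))
      if (!is.finite(ll)) 1e10 else -ll
    }
    q0 <- log(min(max(2 / sum(ptree$edge.length), 1e-6), 1))
    old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(20231102L)
    starts <- c(list(rep(q0, K)),
                lapply(seq_len(n_starts), function(i)
                  pmin(pmax(q0 + rnorm(K, 0, 1.5), lb), ub)))
    best <- NULL
    for (s in starts) {
      o <- tryCatch(optim(s, nll, method = "L-BFGS-B", lower = lb, upper = ub,
                          control = list(maxit = 500)),
                    error = function(e) NULL)
      if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
    }
    if (is.null(best)) stop("pair fit failed for ", nm, call. = FALSE)
    tibble::tibble(model = nm, K = K, lnL = -best$value,
                   AICc = aicc(-best$value, K, n_obs),
                   correlated = nm %in% correlated_model_names())
  })
  tab <- dplyr::bind_rows(fits)
  tab$delta <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$AICc)
  tab <- dplyr::arrange(tab, .data$AICc)
  structure(tab, class = c("pair_fit", class(tab)),
            pair = c(charA, charB), n = n_obs,
            cum_correlated_weight = sum(tab$weight[tab$correlated]),
            best_model = tab$model[1])
}

#' Bayes factor for dependent versus independent evolution
#'
#' `BF_DI = [P(M_D|D)/P(M_I|D)] / [(N - N_I)/N_I]`: the posterior odds of
#' dependent over independent models (their reversible-jump sampling
#' frequencies) divided by the prior odds implied by the model counts of
#' the combined space (21,146 models, of which 51 are independent, for two
#' binary traits).
#'
#' @param freqD,freqI sampling frequencies of dependent and independent
#'   models; must sum to 1.
#' @param space a `model_space` with dependent/independent counts
#'   (default [pair_model_space()]), or a list with `count` and
#'   `n_independent`.
#' @return one-row tibble: `bf`, `freqD`, `freqI`, `prior_odds`, `flag`
#'   (`"ok"`, `"infinite"`, or `"zero"`).
#' @examples
#' bf_dependent_independent(0.5, 0.5,
#'   space = list(count = 21146, n_independent = 51))
#' @export
bf_dependent_independent <- function(freqD, freqI, space = pair_model_space()) {
  if (abs(freqD + freqI - 1) > 1e-9) {
    stop("freqD + freqI must equal 1", call. = FALSE)
  }
  n_total <- space$count
  n_ind <- space$n_independent
  prior_odds <- (n_total - n_ind) / n_ind
  if (freqI == 0) {
    return(tibble::tibble(bf = Inf, freqD = freqD, freqI = freqI,
                          prior_odds = prior_odds, flag = "infinite"))
  }
  bf <- (freqD / freqI) / prior_odds
  tibble::tibble(bf = bf, freqD = freqD, freqI = freqI,
                 prior_odds = prior_odds,
                 flag = if (freqD == 0) "zero" else "ok")
}

#' Reversible-jump correlated-evolution test for a pair of binary characters
#'
#' Runs the rjMCMC sampler over the full combined model space (the 21,146
#' rate-class models over the 8 allowed transitions), classifies every
#' sampled model as dependent or independent, and reports the Bayes factor
#' [bf_dependent_independent()] together with combined-state ancestral
#' summaries at the focal nodes.
#'
#' @inheritParams fit_pair_ml
#' @param trees a `tree_sample` or `phylo`.
#' @param settings an [rj_settings()].
#' @param focal_nodes named list of taxon sets.
#' @return a `pair_rj`: the underlying `rjmcmc_fit` plus `freqD`, `freqI`,
#'   `bf` tibble, and the pair name.
#' @export
run_pair_rjmcmc <- function(trees, matrix, charA, charB,
                            settings = rj_settings(), focal_nodes = NULL) {
  sa <- trait_states(matrix, charA)
  sb <- trait_states(matrix, charB)
  check_binary(sa, charA); check_binary(sb, charB)
  if (inherits(trees, "phylo")) trees <- tree_sample(trees)

  # combined pseudo-states: observed pairs become a single combined state,
  # partially observed tips stay partially informative via the template
  comb <- combine_binary_states(sa, sb)
  template <- list(k = 4L, n_params = 8L, param_id = pair_param_layout(),
                   alphabet = c("00", "01", "10", "11"))
  fit <- run_rjmcmc(trees, comb, settings = settings,
                    focal_nodes = focal_nodes,
                    alphabet = template$alphabet, template = template)

  ind <- vapply(strsplit(fit$model_freq$signature, ","), function(s)
    is_independent_assignment(as.integer(s)), logical(1))
  fit$model_freq$independent <- ind
  freqD <- sum(fit$model_freq$freq[!ind])
  freqI <- sum(fit$model_freq$freq[ind])
  bf <- bf_dependent_independent(freqD, freqI)
  structure(list(fit = fit, pair = c(charA, charB),
                 freqD = freqD, freqI = freqI, bf = bf),
            class = "pair_rj")
}

# Merge two binary tip vectors into combined-state codes; a tip missing
# both traits is NA. Tips observed for only one trait keep partial signal:
# encoded via ambiguity handled in tip partials below.
combine_binary_states <- function(sa, sb) {
  taxa <- union(names(sa), names(sb))
  out <- setNames(rep(NA_character_, length(taxa)), taxa)
  for (tx in taxa) {
    a <- unname(sa[tx])
    b <- unname(sb[tx])
    if (is.na(a) && is.na(b)) next
    if (is.na(a)) { out[tx] <- paste0("?", b); next }
    if (is.na(b)) { out[tx] <- paste0(a, "?"); next }
    out[tx] <- paste0(a, b)
  }
  out
}

#' @export
print.pair_rj <- function(x, ...) {
  cat("<pair_rj> ", paste(x$pair, collapse = " ~ "),
      ": P(M_D|D) = ", format(x$freqD, digits = 4),
      ", BF_DI = ", format(x$bf$bf, digits = 4), "\n", sep = "")
  invisible(x)
}

#' All pairwise correlation tests
#'
#' Runs [fit_pair_ml()] (and optionally [run_pair_rjmcmc()]) for every
#' unordered pair of binary characters and summarizes significance calls:
#' cumulative correlated Akaike weight above `w_threshold` for the ML
#' route, Bayes factor above `bf_threshold` for the Bayesian route.
#'
#' @param matrix a binary `trait_matrix`.
#' @param trees a `phylo` (ML) or `tree_sample` (Bayesian route uses all).
#' @param methods any of `"ml"`, `"rjmcmc"`.
#' @param settings rjMCMC settings (Bayesian route).
#' @param w_threshold,bf_threshold significance cutoffs (defaults 0.5, 3).
#' @param ... passed to [fit_pair_ml()].
#' @return an `all_pairs_result` tibble: one row per pair with the support
#'   measures and significance calls; summary fractions in attributes
#'   `frac_ml` / `frac_bf`.
#' @export
all_pairs <- function(matrix, trees, methods = "ml",
                      settings = rj_settings(), w_threshold = 0.5,
                      bf_threshold = 3, ...) {
  chars <- setdiff(names(matrix), "species")
  if (length(chars) < 2) stop("need at least 2 binary characters", call. = FALSE)
  tree1 <- if (inherits(trees, "tree_sample")) trees$trees[[1]] else trees
  prs <- combn(chars, 2)
  rows <- purrr::map_dfr(seq_len(ncol(prs)), function(i) {
    ca <- prs[1, i]; cb <- prs[2, i]
    out <- tibble::tibble(charA = ca, charB = cb)
    if ("ml" %in% methods) {
      f <- fit_pair_ml(tree1, matrix, ca, cb, ...)
      out$cum_correlated_weight <- attr(f, "cum_correlated_weight")
      out$best_model <- attr(f, "best_model")
      out$sig_ml <- out$cum_correlated_weight > w_threshold
    }
    if ("rjmcmc" %in% methods) {
      st <- settings
      st$seed <- settings$seed + i   # per-pair substream
      rj <- run_pair_rjmcmc(trees, matrix, ca, cb, settings = st)
      out$freqD <- rj$freqD
      out$bf <- rj$bf$bf
      out$sig_bf <- out$bf > bf_threshold
    }
    out
  })
  structure(rows, class = c("all_pairs_result", class(rows)),
            n_pairs = ncol(prs),
            frac_ml = if ("ml" %in% methods) mean(rows$sig_ml) else NA,
            frac_bf = if ("rjmcmc" %in% methods) mean(rows$sig_bf) else NA)
}

#' Symmetric pair-support matrix
#'
#' Square layout mirroring a correlation table: upper triangle = Bayes
#' factors, lower triangle = cumulative correlated Akaike weights.
#'
#' @param pairs an `all_pairs_result`.
#' @return a character-dimnamed numeric matrix.
#' @export
pair_matrix <- function(pairs) {
  chars <- sort(unique(c(pairs$charA, pairs$charB)))
  m <- matrix(NA_real_, length(chars), length(chars),
              dimnames = list(chars, chars))
  has_bf <- "bf" %in% names(pairs)
  has_w <- "cum_correlated_weight" %in% names(pairs)
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$charA[i]; b <- pairs$charB[i]
    lo <- min(a, b); hi <- max(a, b)
    if (has_bf) m[lo, hi] <- pairs$bf[i]
    if (has_w) m[hi, lo] <- pairs$cum_correlated_weight[i]
  }
  m
}
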