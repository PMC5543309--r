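test_that("the ML pair test fits exactly the seven named models", {
  set.seed(21)
  tr <- simulate_yule_tree(40, 1, seed = 21)
  pr <- simulate_pair(tr, build_pair_model("UNCORRnodual"),
                      rates = c(0.2, 0.2, 0.2, 0.2), seed = 22)
  m <- trait_matrix(tibble::tibble(species = tr$tip.label,
                                   a = unname(pr$statesA[tr$tip.label]),
                                   b = unname(pr$statesB[tr$tip.label])))
  f <- fit_pair_ml(tr, m, "a", "b", n_starts = 2)
  expect_setequal(f$model, c("ARDnodual", "ARDnodualeq", "SYMnodual",
                             "SYMnodualeq", "ERnodual", "UNCORRnodual",
                             "UNCORRnodualeq"))
  expect_equal(sum(f$weight), 1)
  expect_equal(attr(f, "cum_correlated_weight"),
               sum(f$weight[f$correlated]))
  expect_error(fit_pair_ml(tr, trait_matrix(tibble::tibble(
    species = tr$tip.label, a = unname(pr$statesA[tr$tip.label]),
    b = sample(c("0", "1", "2"), length(tr$tip.label), replace = TRUE))),
    "a", "b"), "not binary")
})

test_that("independent-model likelihood factorizes into single-trait parts", {
  tr <- tree4()
  m <- small_binary_matrix()
  # UNCORRnodual with trait-specific rates equals the sum of two ARD fits
  spec <- build_pair_model("UNCORRnodual")
  # classes: 1 = trait-2 gain, 2 = trait-2 loss, 3 = trait-1 gain, 4 = loss
  rates <- c(0.4, 0.7, 0.2, 0.9)
  cp <- mktraits:::combined_partials(mktraits:::prep_tree(tr),
                                     trait_states(m, "x"),
                                     trait_states(m, "y"))
  Q <- build_rate_matrix(spec, rates)
  lnL_pair <- mktraits:::loglik_raw(mktraits:::prep_tree(tr), cp, Q,
                                    rep(0.25, 4))
  # single-trait ARD layout is row-major: rate 1 is 0->1 (gain), rate 2 loss
  lnL_x <- log_likelihood(tr, trait_states(m, "x"), mk_model("ARD", 2),
                          c(0.2, 0.9))
  lnL_y <- log_likelihood(tr, trait_states(m, "y"), mk_model("ARD", 2),
                          c(0.4, 0.7))
  expect_equal(lnL_pair, lnL_x + lnL_y, tolerance = 1e-10)
})

test_that("the Bayes factor formula reproduces its worked values", {
  sp <- list(count = 21146, n_independent = 51)
  b1 <- bf_dependent_independent(0.5, 0.5, space = sp)
  expect_equal(b1$bf, 51 / 21095, tolerance = 1e-9)
  expect_equal(b1$bf, 0.0024176, tolerance = 1e-4)

  b2 <- bf_dependent_independent(0, 1, space = sp)
  expect_equal(b2$bf, 0)
  expect_equal(b2$flag, "zero")

  b3 <- bf_dependent_independent(1, 0, space = sp)
  expect_true(is.infinite(b3$bf))
  expect_equal(b3$flag, "infinite")

  # inversion: BF = 1 exactly at freqD/freqI = 21095/51
  fD <- (21095 / 51) / (1 + 21095 / 51)
  expect_equal(fD, 0.997589, tolerance = 1e-6)
  expect_equal(bf_dependent_independent(fD, 1 - fD, space = sp)$bf, 1,
               tolerance = 1e-9)

  expect_error(bf_dependent_independent(0.6, 0.6, space = sp), "equal 1")

  # monotone in freqD
  bfs <- vapply(c(0.2, 0.5, 0.8, 0.95), function(f)
    bf_dependent_independent(f, 1 - f, space = sp)$bf, numeric(1))
  expect_true(all(diff(bfs) > 0))
})

test_that("the enumerated combined space backs the printed prior odds", {
  sp <- pair_model_space()
  expect_equal(sp$count, 21146)
  expect_equal(sp$n_independent, 51)
  expect_equal(sp$n_dependent, 21095)
  # the named models classify as documented
  expect_true(build_pair_model("ERnodual")$independent)
  expect_true(build_pair_model("UNCORRnodual")$independent)
  expect_false(build_pair_model("ARDnodual")$independent)
  expect_false(build_pair_model("SYMnodual")$independent)
})

test_that("a prior-only pair chain samples dependent models at the prior rate", {
  tr <- tree4()
  m <- trait_matrix(tibble::tibble(species = c("A", "B", "C", "D"),
                                   a = rep("?", 4), b = rep("?", 4)))
  rj <- run_pair_rjmcmc(tr, m, "a", "b",
                        settings = rj_settings(generations = 30000,
                                               sample_interval = 2,
                                               burn_in = 1000, seed = 41))
  # prior probability of a dependent model is 21095/21146 = 0.99759
  expect_equal(rj$freqD, 21095 / 21146, tolerance = 0.005)
  # the Bayes factor sits near 1 under the prior; the independent share is
  # rare (0.24%), so its Monte-Carlo error allows a factor-scale check only
  expect_gt(rj$bf$bf, 0.4)
  expect_lt(rj$bf$bf, 2.5)
})

test_that("dependent simulations earn larger Bayes factors than independent ones", {
  bf_for <- function(dep, seed) {
    tr <- simulate_yule_tree(80, 1, seed = seed)
    # dependent regime: trait-2 rates an order of magnitude higher when
    # trait 1 is in state 1 than in state 0
    rates <- if (dep) c(0.02, 0.02, 0.2, 0.2, 0.2, 0.2, 1.0, 1.0)
      else rep(0.15, 4)
    spec <- if (dep) build_pair_model("ARDnodual") else build_pair_model("UNCORRnodual")
    pr <- simulate_pair(tr, spec, rates = rates, seed = seed + 1)
    m <- trait_matrix(tibble::tibble(species = tr$tip.label,
                                     a = unname(pr$statesA[tr$tip.label]),
                                     b = unname(pr$statesB[tr$tip.label])))
    rj <- run_pair_rjmcmc(tr, m, "a", "b",
                          settings = rj_settings(generations = 20000,
                                                 sample_interval = 20,
                                                 burn_in = 2000, seed = seed + 2))
    rj$bf$bf
  }
  bf_dep <- vapply(1:3, function(i) bf_for(TRUE, 5200 + 10 * i), numeric(1))
  bf_ind <- vapply(1:3, function(i) bf_for(FALSE, 6200 + 10 * i), numeric(1))
  expect_gt(median(bf_dep), median(bf_ind))
  expect_gt(median(bf_dep), 1)
  expect_lt(median(bf_ind), 2.5)
})

test_that("all_pairs enumerates unordered pairs with significance calls", {
  tr <- simulate_yule_tree(40, 1, seed = 88)
  set.seed(89)
  m <- trait_matrix(tibble::tibble(
    species = tr$tip.label,
    x = sample(c("0", "1"), 40, replace = TRUE),
    y = sample(c("0", "1"), 40, replace = TRUE),
    z = sample(c("0", "1", "?"), 40, replace = TRUE)))
  res <- all_pairs(m, tr, methods = "ml", n_starts = 1)
  expect_equal(nrow(res), 3)
  expect_equal(attr(res, "n_pairs"), 3)
  expect_true(all(c("cum_correlated_weight", "sig_ml") %in% names(res)))
  pm <- pair_matrix(res)
  expect_equal(dim(pm), c(3, 3))
  expect_false(is.na(pm["y", "x"]))   # lower triangle holds ML weights
  expect_error(all_pairs(trait_matrix(tibble::tibble(
    species = c("A", "B"), only = c("0", "1"))), tr), "at least 2")
})
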