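test_that("yule trees have the right shape and are reproducible", {
  tr <- simulate_yule_tree(5, 1, seed = 9)
  expect_equal(length(tr$tip.label), 5)
  expect_equal(tr$Nnode, 4)
  expect_true(check_ultrametric(tr, rel_tol = 1e-9)$pass)
  tr2 <- simulate_yule_tree(5, 1, seed = 9)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  expect_error(simulate_yule_tree(1, 1), "n_tips")
  expect_error(simulate_yule_tree(5, -1), "birth_rate")
})

test_that("yule root ages match the analytic expectation", {
  set.seed(123)
  ages <- vapply(1:400, function(i) {
    tr <- simulate_yule_tree(50, 1)
    max(ape::node.depth.edgelength(tr))
  }, numeric(1))
  expect_equal(mean(ages), sum(1 / (2:50)), tolerance = 0.15)
})

test_that("character simulation respects the generating chain", {
  tr <- tree4()
  # zero rates: everything inherits the root state
  Q0 <- build_rate_matrix(mk_model("ER", 2), 0)
  sim0 <- simulate_character(tr, Q0, root_prior = "1", seed = 3)
  expect_true(all(sim0$tip_states == "1"))
  expect_true(all(sim0$node_states == "1"))
  expect_equal(nrow(sim0$events), 0)

  # single branch of length 1 under ER q=0.5: P(different) = 0.31606
  br <- read_trees("(A:1,B:1e-9);")$trees[[1]]
  Q <- build_rate_matrix(mk_model("ER", 2), 0.5)
  set.seed(4)
  flips <- vapply(1:20000, function(i) {
    s <- simulate_character(br, Q, root_prior = "0")
    s$tip_states[["A"]] != "0"
  }, logical(1))
  expect_equal(mean(flips), (1 - exp(-1)) / 2, tolerance = 0.01)

  # high rate reaches equilibrium tip frequencies
  yt <- simulate_yule_tree(300, 1, seed = 5)
  simh <- simulate_character(yt, build_rate_matrix(mk_model("ARD", 2), c(2, 4)),
                             seed = 6)
  expect_equal(mean(simh$tip_states == "1"), 1 / 3, tolerance = 0.12)
})

test_that("pair simulation never produces dual transitions", {
  tr <- simulate_yule_tree(80, 1, seed = 31)
  pr <- simulate_pair(tr, build_pair_model("ARDnodual"),
                      rates = c(0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3, 0.3),
                      seed = 32)
  ev <- pr$combined$events
  if (nrow(ev) > 0) {
    both_change <- substr(ev$from, 1, 1) != substr(ev$to, 1, 1) &
      substr(ev$from, 2, 2) != substr(ev$to, 2, 2)
    expect_false(any(both_change))
  }
  expect_setequal(unique(c(pr$statesA, pr$statesB)), c("0", "1"))
  expect_error(simulate_pair(tr, Q = matrix(1, 4, 4)), "dual")
})

test_that("independent pairs are uncorrelated at the tips", {
  phis <- vapply(1:25, function(i) {
    tr <- simulate_yule_tree(200, 1, seed = 7000 + i)
    pr <- simulate_pair(tr, build_pair_model("UNCORRnodual"),
                        rates = c(0.5, 0.5, 0.5, 0.5), seed = 7100 + i)
    a <- as.integer(pr$statesA); b <- as.integer(pr$statesB)
    if (sd(a) == 0 || sd(b) == 0) return(0)
    cor(a, b)
  }, numeric(1))
  # shared phylogeny inflates the tip association even for independent
  # traits, so the bound is looser than the i.i.d. expectation
  expect_lt(mean(abs(phis)), 0.12)

  # a strongly dependent regime shows association
  phis_dep <- vapply(1:10, function(i) {
    tr <- simulate_yule_tree(200, 1, seed = 7500 + i)
    pr <- simulate_pair(tr, build_pair_model("ARDnodual"),
                        rates = c(0.05, 0.5, 0.05, 0.5, 0.5, 0.05, 0.5, 0.05),
                        seed = 7600 + i)
    a <- as.integer(pr$statesA); b <- as.integer(pr$statesB)
    if (sd(a) == 0 || sd(b) == 0) return(0)
    abs(cor(a, b))
  }, numeric(1))
  expect_gt(mean(phis_dep), mean(abs(phis)))
})

test_that("missingness injection hits its target rate deterministically", {
  df <- tibble::tibble(species = paste0("s", 1:792))
  for (j in 1:27) df[[paste0("c", j)]] <- "0"
  m <- trait_matrix(df)
  expect_equal(as.data.frame(inject_missing(m, 0))[, -1],
               as.data.frame(m)[, -1])
  mm <- inject_missing(m, 0.27, inapplicable_share = 0.3, seed = 8)
  frac <- missing_fraction(mm)
  tot <- frac[frac$character == ".total", ]
  expect_equal(tot$no_signal, 0.27, tolerance = 0.01)
  expect_gt(tot$inapplicable, 0)
  mm2 <- inject_missing(m, 0.27, inapplicable_share = 0.3, seed = 8)
  expect_equal(as.data.frame(mm), as.data.frame(mm2))
  expect_error(inject_missing(m, 1), "missing_rate")
})

test_that("pseudo-posterior samples stay ultrametric and close to the base", {
  skip_if_not_installed("phangorn")
  base <- simulate_yule_tree(50, 1, seed = 61)
  same <- perturb_tree_sample(base, 3, time_jitter = 0, topo_moves = 0)
  expect_identical(ape::write.tree(same$trees[[2]]), ape::write.tree(base))

  ts <- perturb_tree_sample(base, 50, time_jitter = 0.05, seed = 62)
  for (tr in ts$trees) {
    expect_true(check_ultrametric(tr, rel_tol = 1e-6)$pass)
  }

  tsm <- perturb_tree_sample(base, 20, time_jitter = 0, topo_moves = 2,
                             seed = 63)
  for (tr in tsm$trees) {
    rf <- phangorn::RF.dist(tr, base)
    expect_lte(rf, 4)
    expect_true(check_ultrametric(tr, rel_tol = 1e-6)$pass)
  }
})

test_that("end-to-end recovery improves with slower evolution", {
  acc_for <- function(q) {
    hits <- vapply(1:15, function(i) {
      tr <- simulate_yule_tree(120, 1, seed = 9000 + i)
      sim <- simulate_character(tr, build_rate_matrix(mk_model("ER", 2), q),
                                seed = 9100 + i)
      truth <- sim$node_states[[length(tr$tip.label) + 1]]
      fit <- fit_ml(tr, sim$tip_states, mk_model("ER", 2), n_starts = 2)
      marg <- marginal_ancestral(fit)
      root <- marg[marg$node == length(tr$tip.label) + 1, ]
      root$state[which.max(root$prob)] == truth
    }, logical(1))
    mean(hits)
  }
  expect_gte(acc_for(0.02), acc_for(1.5) - 0.05)
})
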