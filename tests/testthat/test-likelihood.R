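test_that("log-likelihood matches closed forms on two-tip trees", {
  tr <- tree2()
  spec <- mk_model("ER", 2)
  # rates ~ 0, all tips in one state: only the root prior contributes
  expect_equal(log_likelihood(tr, c(A = "0", B = "0"), spec, 1e-12),
               log(0.5), tolerance = 1e-6)
  # A=0, B=1, q=0.5: L = P_same(1) * P_diff(1)
  p_same <- (1 + exp(-1)) / 2
  expect_equal(log_likelihood(tr, c(A = "0", B = "1"), spec, 0.5),
               log(p_same * (1 - p_same)), tolerance = 1e-10)
  expect_error(log_likelihood(tr, c(A = NA, B = NA), spec, 0.5), "missing")
})

test_that("a missing tip is equivalent to pruning it", {
  tr <- read_trees("(((A:1,B:1):1,C:2):1,D:3);")$trees[[1]]
  spec <- mk_model("ARD", 2)
  rates <- c(0.3, 0.6)
  full <- log_likelihood(tr, c(A = "0", B = NA, C = "1", D = "0"), spec, rates)
  pruned <- log_likelihood(ape::drop.tip(tr, "B"),
                           c(A = "0", C = "1", D = "0"), spec, rates)
  expect_equal(full, pruned, tolerance = 1e-10)
})

test_that("pruning equals brute-force summation across trees, states and rates", {
  rate_settings <- list(0.5, 2, 0.08)
  for (tr in small_trees()) {
    for (k in 2:4) {
      alphabet <- as.character(0:(k - 1))
      states <- random_states(tr, alphabet, seed = 100 * k + length(tr$tip.label))
      for (ri in seq_along(rate_settings)) {
        spec <- mk_model("ER", k)
        Q <- build_rate_matrix(spec, rate_settings[[ri]])
        got <- log_likelihood(tr, states, spec, rate_settings[[ri]])
        want <- bf_loglik(tr, states, Q, rep(1 / k, k), alphabet)
        expect_equal(got, want, tolerance = 1e-10)
      }
      # an asymmetric model too
      specA <- mk_model("ARD", k)
      set.seed(k)
      rts <- rexp(specA$K, 2)
      QA <- build_rate_matrix(specA, rts)
      expect_equal(log_likelihood(tr, states, specA, rts),
                   bf_loglik(tr, states, QA, rep(1 / k, k), alphabet),
                   tolerance = 1e-10)
    }
  }
})

test_that("likelihood is invariant to tip ordering", {
  tr <- tree4()
  st <- c(A = "0", B = "1", C = "1", D = "0")
  l1 <- log_likelihood(tr, st, mk_model("ER", 2), 0.4)
  l2 <- log_likelihood(tr, st[c("D", "B", "A", "C")], mk_model("ER", 2), 0.4)
  expect_equal(l1, l2)
})

test_that("AICc arithmetic and Akaike weights match hand values", {
  expect_equal(aicc(-100, 2, 50), 204.2553, tolerance = 1e-4)
  expect_error(aicc(-100, 49, 50), "undefined")
  w <- akaike_weights(c(100, 102))
  expect_equal(w, c(0.73106, 0.26894), tolerance = 1e-5)
  expect_equal(sum(akaike_weights(c(3, 9, 2, 5))), 1)
  # AICc converges to AIC for large n
  expect_equal(aicc(-100, 3, 1e6), -2 * (-100) + 2 * 3, tolerance = 1e-6)
})

test_that("ML fitting recovers boundary and nesting behaviour", {
  tr <- tree4()
  # constant character: likelihood maximized as q -> 0
  f0 <- fit_ml(tr, c(A = "0", B = "0", C = "0", D = "0"), mk_model("ER", 2))
  expect_lt(f0$rates, 1e-6)
  # nesting: ARD can never fit worse than ER
  st <- c(A = "0", B = "1", C = "1", D = "0")
  fer <- fit_ml(tr, st, mk_model("ER", 2))
  fard <- fit_ml(tr, st, mk_model("ARD", 2))
  expect_gte(fard$lnL, fer$lnL - 1e-6)
})

test_that("simulated rates are recovered within a factor of two", {
  hits <- vapply(1:20, function(i) {
    tr <- simulate_yule_tree(300, 1, seed = 5000 + i)
    sim <- simulate_character(tr, build_rate_matrix(mk_model("ER", 2), 0.1),
                              seed = 6000 + i)
    q <- fit_ml(tr, sim$tip_states, mk_model("ER", 2), n_starts = 2)$rates
    q >= 0.05 && q <= 0.2
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("candidate sets follow character type", {
  expect_setequal(default_candidates(2),
                  c("ER", "ARD", "ARDeq", "UNI01", "UNI10"))
  expect_true(all(c("ORD", "ORDSYM", "ORDER") %in%
                    default_candidates(3, ordered = TRUE)))
  expect_false(any(grepl("UNI", default_candidates(3))))
})

test_that("model selection ranks by AICc with weights summing to one", {
  set.seed(11)
  tr <- simulate_yule_tree(60, 1, seed = 11)
  sim <- simulate_character(tr, build_rate_matrix(mk_model("ER", 2), 0.3),
                            seed = 12)
  sel <- model_select(tr, sim$tip_states, n_starts = 2)
  expect_equal(nrow(sel), 5)
  expect_equal(sum(sel$weight), 1)
  expect_true(!is.unsorted(sel$AICc))
  expect_s3_class(attr(sel, "best"), "mk_fit")
})

test_that("marginal reconstructions match closed form and brute force", {
  # symmetric configuration: root marginal is (1/2, 1/2)
  tr <- tree4()
  fit <- structure(list(spec = mk_model("ER", 2), model = "ER", rates = 0.5,
                        lnL = 0, K = 1, n = 4, AICc = 0, root_prior = "flat",
                        convergence = TRUE, tree = tr,
                        states = c(A = "0", B = "0", C = "1", D = "1")),
                   class = "mk_fit")
  m <- marginal_ancestral(fit)
  root <- m[m$node == 5, ]
  expect_equal(root$prob, c(0.5, 0.5), tolerance = 1e-9)
  expect_true(all(root$tie))

  # two-tip worked case: P(root=0 | A=B=0)
  tr2 <- tree2()
  fit2 <- fit; fit2$tree <- tr2; fit2$states <- c(A = "0", B = "0")
  m2 <- marginal_ancestral(fit2)
  p_same <- (1 + exp(-1)) / 2
  expect_equal(m2$prob[m2$state == "0"],
               p_same^2 / (p_same^2 + (1 - p_same)^2), tolerance = 1e-9)
  expect_equal(m2$prob[m2$state == "0"], 0.82403, tolerance = 1e-5)

  # per-node sums are 1 and values agree with enumeration
  for (tr in small_trees()[c(2, 4, 5)]) {
    alphabet <- c("0", "1", "2")
    states <- random_states(tr, alphabet, seed = 77)
    spec <- mk_model("ARD", 3)
    set.seed(3); rts <- rexp(spec$K, 1)
    Q <- build_rate_matrix(spec, rts)
    fitx <- structure(list(spec = spec, model = "ARD", rates = rts, lnL = 0,
                           K = 6, n = 4, AICc = 0, root_prior = "flat",
                           convergence = TRUE, tree = tr, states = states),
                      class = "mk_fit")
    marg <- marginal_ancestral(fitx)
    sums <- as.numeric(tapply(marg$prob, marg$node, sum))
    expect_equal(sums, rep(1, length(sums)), tolerance = 1e-9)
    n_tip <- length(tr$tip.label)
    for (v in (n_tip + 1):(n_tip + tr$Nnode)) {
      want <- bf_marginal(tr, states, Q, rep(1 / 3, 3), alphabet, v)
      expect_equal(marg$prob[marg$node == v], unname(want), tolerance = 1e-10)
    }
  }
})

test_that("MRCA lookup reports monophyly", {
  tr <- tree4()
  r1 <- mrca_node(tr, c("A", "B"))
  expect_equal(r1$node, 6)
  expect_true(r1$monophyletic)
  r2 <- mrca_node(tr, c("A", "C"))
  expect_equal(r2$node, 5)
  expect_false(r2$monophyletic)
  expect_error(mrca_node(tr, "A"), "fewer than 2")
})
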