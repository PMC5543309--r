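---
title: "Models and methods behind mktraits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mktraits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mktraits)
```

mktraits reconstructs the evolution of discrete morphological traits on
time-calibrated phylogenies (chronograms) with three complementary methods —
Sankoff parsimony, maximum likelihood under the Mk model family, and a
reversible-jump Bayesian sampler over rate-class models — and tests pairs of
binary traits for correlated evolution. This vignette explains the models,
the tunable parameters, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## The Mk model family

A k-state discrete character evolves as a continuous-time Markov chain with
generator $Q$: off-diagonal $q_{ij} \ge 0$ is the instantaneous rate of
change from state $i$ to $j$ (per unit branch time), and rows sum to zero.
Named models are equality/zero patterns over the off-diagonal entries:

* **ER** — one shared rate; **SYM** — one rate per unordered state pair;
  **ARD** — one rate per ordered pair (row-major parameter order, so the
  first rate of a binary ARD model is the 0→1 gain).
* **ORD / ORDSYM / ORDER** — ordered variants for count-derived characters:
  non-adjacent transitions are forced to zero, with per-direction, symmetric,
  or single rates.
* **UNI01 / UNI10** — unidirectional binary models with the 1→0 (resp. 0→1)
  rate forced to zero. Their root prior is the point mass on the source
  state, since any other root state has zero probability of generating
  both observed states.

The root prior is flat by default; the `eq` suffix requests the stationary
distribution of the fitted $Q$ instead. For reducible chains "equilibrium"
means the limiting distribution reached from a flat start, computed by
repeated squaring of $P(t) = e^{Qt}$ with row renormalisation at each step
(squaring alone accumulates rounding drift that explodes after ~80
doublings when rates span many orders of magnitude).

Likelihoods use Felsenstein pruning with per-node rescaling of partial
likelihoods, so trees with many hundreds of tips stay in range. Missing and
inapplicable observations both enter as all-ones partial likelihood vectors,
which gives exactly the likelihood of the tree with those tips pruned while
keeping one tree per analysis; the two codes stay distinct in storage so
data audits can tell them apart. Transition probabilities use a closed form
for binary chains and scaling-and-squaring Padé otherwise. Polytomies are
treated as hard and handled natively by the product over children.

## Maximum likelihood and model choice

Rates are optimised on the log scale (bounds $10^{-9}$–$10^2$ per rate)
with L-BFGS-B from a parsimony-informed start (observed changes divided by
total tree time) plus a fixed set of pseudo-random multistarts, so fits are
deterministic. Candidate sets follow character type: binary characters get
{ER, ARD, ARDeq, UNI01, UNI10}; unordered multistate characters get
{ER, SYM, SYMeq, ARD, ARDeq}; ordered characters add the ORD family.
Ranking uses AICc, $-2\ln L + 2K + 2K(K+1)/(n-K-1)$, with $n$ the number of
tips observed for the character — the effective sample size of a
discrete-character analysis is not well defined, so $n$ is documented as a
knob rather than a constant. Akaike weights are
$w_m \propto \exp(-\Delta_m/2)$.

Marginal ancestral probabilities combine each node's downward partial
likelihood with the likelihood flowing from the rest of the tree via a
root-to-tip message pass. This is valid for non-reversible models (no
re-rooting argument is needed) and matches brute-force enumeration on small
trees to $10^{-10}$. Ties in the modal state (gap below $10^{-9}$) are
reported as ties, never broken silently.

## Parsimony

Sankoff dynamic programming with unit costs by default; an ordered
$|i - j|$ cost matrix is available but off by default, since ordered
parsimony is a modelling decision the user should make explicitly. The
up-pass computes, for every node and state, the minimal total cost of the
whole tree given that assignment, so the reported MPR set is exactly the
set of states attained in at least one minimum-length labeling — nodes with
more than one state are "equivocal". A wholly missing tip contributes zero
cost in every state; its own reported set is the set of states compatible
with an optimal labeling (the brute-force definition), not the full
alphabet.

## The reversible-jump sampler

The Bayesian analysis samples jointly over

* **model** — a partition of the free transition parameters into unlabeled
  positive-rate classes plus a distinguished, possibly empty *zero class*
  (rate exactly 0). The all-zero model is excluded. With an optional zero
  class over $n$ parameters there are $\mathrm{Bell}(n+1) - 1$ models:
  4 for a binary trait ($n = 2$), 51 for the independent two-trait model
  ($n = 4$), and 21,146 for the combined two-binary-trait chain with dual
  transitions excluded ($n = 8$). These counts are reproduced by explicit
  enumeration in the test suite; the model prior is uniform over the space.
* **rates** — one value per class, i.i.d. exponential with mean $m$;
* **hyperprior mean** — $m \sim \mathrm{U}(0,1)$, a weak prior that lets
  the data set the rate scale;
* **tree** — an index into the supplied posterior tree sample, giving
  marginalisation over topology and branch-time uncertainty.

Proposals, with default mix 40/35/10/10/5:

1. *rate update* — multiplicative log-normal on one class rate;
2. *local model move* — move one parameter to another class (an existing
   class, a fresh singleton, or the zero class), with any newborn class
   rate drawn from its conditional prior. The acceptance ratio is
   $\min\{1, (L'/L)\, T(M)/T(M')\}$ where $T(\cdot)$ counts valid moves;
   birth/death prior terms cancel exactly against the proposal densities.
   This one move family subsumes the reassign/split/merge moves often
   listed separately, with a Hastings ratio simple enough to verify: a
   prior-only chain provably targets the uniform model prior, and the test
   suite confirms uniformity by chi-square at $\alpha = 0.01$;
3. *global jump* — an independence proposal drawing a model uniformly from
   the space and all rates from the prior (acceptance $L'/L$), which
   guarantees irreducibility across the 21,146-model space. Spaces of up
   to 10 parameters are enumerated once and cached; larger spaces (e.g.
   the 12 parameters of a 4-state character, Bell(13) ≈ 27.6M models) are
   sampled without enumeration by Stam's urn method, which draws a uniform
   set partition of the parameters plus the zero marker — the proposal is
   uniform either way, so the acceptance ratio is unchanged;
4. *tree switch* — uniform draw from the tree sample, Metropolis on the
   likelihood ratio;
5. *hyperprior update* — independence $\mathrm{U}(0,1)$ draw for $m$.

Defaults mirror large empirical practice — $10^7$ generations, sampling
every 100, $10^6$ burn-in — but every desk-scale run in the tests passes
smaller values explicitly; the vignette's own demonstrations use a few
thousand generations. Chains are seeded and reproducible bit-for-bit. At
each sampled generation the state of every focal node (the MRCA of a named
taxon set, flagged when non-monophyletic in the current tree) is summarised
by its marginal probability vector rather than a single draw — both are
available, and marginalised vectors converge faster. Summaries report the
posterior mean, the equal-tailed 95% credibility interval across samples,
and the effective sample size computed as $n/(1 + 2\sum_k \rho_k)$ with
Geyer's initial-positive-sequence truncation, flagged below 200. The KS
check of the hyperprior marginal thins to every 200th generation because
the mean only renews every ~30 generations; the test needs approximately
independent draws.

## Correlated evolution of binary pairs

Pairs are analysed on the combined 4-state chain over (00, 01, 10, 11),
trait 1 the high bit, with the four dual transitions (both traits changing
in one instant) structurally zero. The ML route fits seven models — four
correlated (ARDnodual, ARDnodualeq, SYMnodual, SYMnodualeq) and three
uncorrelated (ERnodual, UNCORRnodual, UNCORRnodualeq) — and reports the
cumulative Akaike weight of the correlated models. SYMnodual equates each
forward/backward transition pair among the 8 allowed transitions (4 free
parameters; still a dependent model because each trait's rates differ
across the other trait's states). A tip observed for only one trait keeps
partial signal through a positional ambiguity code rather than being
dropped.

The Bayesian route runs the reversible-jump sampler over all 21,146
rate-class models of the 8 parameters, classifies every sampled model as
independent (each trait's gain and loss rates identical across the other
trait's states, zero class included) or dependent, and reports
$$
\mathrm{BF_{DI}} = \frac{P(M_D \mid D) / P(M_I \mid D)}{(21146 - 51)/51},
$$
the posterior odds of dependent models divided by the prior odds implied
by the uniform model prior. Default significance conventions — cumulative
correlated weight above 0.5 and $\mathrm{BF_{DI}} > 3$ — are configuration
values, not fixed constants.

## Confidence scoring

Each trait × focal-node cell combines the three methods on a 0–3 star
scale: 3 stars when parsimony, ML and the Bayesian modal state name the
same single state and the CI lower bound reaches `t_hi` (default 0.75);
2 stars when they agree but the bound only reaches `t_mid` (default 0.5);
1 star when they agree below `t_mid`, or when every method is *compatible*
with the Bayesian modal state but at least one is equivocal; 0 stars when
any method names a state set excluding it. The thresholds and the rule
itself are reconstructions exposed as configuration — published scoring
rules of this kind typically live in supplementary material and vary by
study. Scores are monotone in the CI lower bound by construction.

## The synthetic-data generator

`simulate_yule_tree()` grows a pure-birth tree conditioned on the tip
count: from two lineages, an $\mathrm{Exp}(k\lambda)$ epoch while $k$
lineages exist, a uniformly chosen lineage splitting at each event, and one
final $\mathrm{Exp}(n\lambda)$ epoch after the $n$-th lineage appears, so
the expected root age is exactly $\sum_{k=2}^{n} 1/(k\lambda)$ — the
property the tests assert. Characters evolve by Gillespie event sampling
along each branch (so complete event logs are available, e.g. to verify
that no dual transition ever occurs in pair simulations); matrix-exponential
endpoint sampling would be faster but would discard the event path.
`inject_missing()` masks cells i.i.d. at a target rate with a configurable
inapplicable share — the default emulation target is the ~27% missingness
typical of large, strictly exemplar-scored morphological matrices.
`perturb_tree_sample()` emulates a Bayesian posterior sample by jittering
node ages multiplicatively (tips stay at age zero, parent–child order is
preserved by rejection) and applying age-respecting NNI moves on internal
edges.

What the generator does **not** emulate: non-uniform missingness (real
inapplicability is phylogenetically clustered — a taxon without a perianth
is inapplicable for every perianth character at once), among-lineage rate
variation, serially correlated characters beyond pairs, and topology
uncertainty concentrated at specific weakly supported nodes. Tests passing
on synthetic data therefore validate the *machinery* — likelihoods,
samplers, counts, intervals — not the biological conclusions one would
draw from any particular empirical matrix.

## Problem sizes and numerical conventions

The test suite works at desk scale by design: exhaustive likelihood and
parsimony oracles on trees of up to 8 tips, rate recovery on 100 trees of
300 tips, prior-recovery chains of $10^5$ generations, and cross-method
agreement on 50 simulations of 200 tips with short (3,000-generation)
chains — sizes at which every check completes in minutes while still
exercising the same code paths as full-scale analyses. Other conventions:
branch lengths are arbitrary time units and never converted; ultrametricity
violations warn (relative tolerance $10^{-6}$) but do not abort, since
posterior samples carry rounding noise; zero-length terminal branches are
allowed; rate bounds are $[10^{-9}, 100]$ per rate; node marginals are
normalised per node, making the pruning rescaling factors cancel.

## Known limitations

Single-tree ML (no averaging over tree samples); no hidden-rate models; no
joint (max-posterior-path) ancestral reconstruction; correlation tests are
pairwise only — no method models the joint evolution of three or more
discrete characters without drastic model-space simplification; the
reversible-jump kernel is a documented reconstruction constrained by the
uniform model prior, not a replica of any particular program's proposal
mix.
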