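# Shared fixtures, built in code.

tree2 <- function() read_trees("(A:1,B:1);")$trees[[1]]
tree4 <- function() read_trees("((A:1,B:1):1,(C:1,D:1):1);")$trees[[1]]

# a battery of small topologies, including a polytomy and unequal depths
small_trees <- function() {
  list(
    read_trees("(A:1,B:1);")$trees[[1]],
    read_trees("((A:1,B:1):0.5,C:1.5);")$trees[[1]],
    read_trees("((A:1,B:1):1,(C:1,D:1):1);")$trees[[1]],
    read_trees("(A:1,B:1,C:1,D:1);")$trees[[1]],                 # polytomy
    read_trees("(((A:1,B:2):0.5,C:0.7):1,(D:1,E:1):2);")$trees[[1]],
    read_trees("(((A:1,B:1):1,(C:1,D:1):1):1,(E:2,F:1):1);")$trees[[1]]
  )
}

# deterministic pseudo-random states over an alphabet, some missing
random_states <- function(tree, alphabet, seed, p_missing = 0.15) {
  set.seed(seed)
  n <- length(tree$tip.label)
  s <- sample(alphabet, n, replace = TRUE)
  s[runif(n) < p_missing] <- NA
  if (all(is.na(s))) s[1] <- alphabet[1]
  setNames(s, tree$tip.label)
}

small_binary_matrix <- function() {
  trait_matrix(tibble::tibble(
    species = c("A", "B", "C", "D"),
    x = c("0", "0", "1", "1"),
    y = c("0", "1", "0", "1"),
    z = c("1", "1", "0", "?")))
}
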