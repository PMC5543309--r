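# Internal tree and character helpers shared across modules.

# Postorder edge matrix and branch lengths for the pruning core.
prep_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  tree <- stats::reorder(tree, "postorder")
  if (is.null(tree$edge.length)) {
    stop("tree has no branch lengths", call. = FALSE)
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch length", call. = FALSE)
  }
  tree
}

# Conditional likelihood rows for every tip, in the tree's tip order.
# Observed states are one-hot; missing and inapplicable carry no signal
# and enter as all-ones rows (identical likelihood to pruning the tip).
tip_partials <- function(tree, states, alphabet) {
  k <- length(alphabet)
  labs <- tree$tip.label
  out <- matrix(1, nrow = length(labs), ncol = k)
  obs <- states[labs]
  for (i in seq_along(labs)) {
    s <- obs[[i]]
    if (is.na(s)) next
    j <- match(as.character(s), alphabet)
    if (is.na(j)) {
      if (grepl("?", s, fixed = TRUE) && nchar(s) == nchar(alphabet[1])) {
        # positional ambiguity code, e.g. "?1" over the combined states
        pat <- paste0("^", gsub("?", ".", s, fixed = TRUE), "$")
        hit <- grepl(pat, alphabet)
        if (!any(hit)) {
          stop("tip state '", s, "' matches no alphabet entry", call. = FALSE)
        }
        out[i, ] <- as.numeric(hit)
        next
      }
      stop("tip state '", s, "' not in alphabet {",
           paste(alphabet, collapse = ","), "}", call. = FALSE)
    }
    row <- numeric(k)
    row[j] <- 1
    out[i, ] <- row
  }
  out
}

# Normalize a state vector: entries equal to a missing/inapplicable code
# become NA; everything else is kept as character.
normalize_states <- function(states, missing_code = "?", inapplicable_code = "-") {
  x <- as.character(states)
  x[x %in% c(missing_code, inapplicable_code) | is.na(x)] <- NA_character_
  names(x) <- names(states)
  x
}

# Observed alphabet of a normalized state vector, sorted.
infer_alphabet <- function(states) {
  a <- sort(unique(states[!is.na(states)]))
  if (length(a) == 0) stop("character has no observed states", call. = FALSE)
  a
}

root_node <- function(tree) length(tree$tip.label) + 1L

# Resolve the root prior for a model spec into a probability vector.
resolve_root_prior <- function(spec, Q, root_prior = NULL) {
  k <- spec$k
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == k, all(root_prior >= 0))
    return(root_prior / sum(root_prior))
  }
  mode <- if (is.null(root_prior)) spec$root_prior else root_prior
  switch(mode,
    flat = rep(1 / k, k),
    equilibrium = stationary_distribution(Q),
    implied = {
      p <- numeric(k)
      p[spec$implied_root] <- 1
      p
    },
    stop("unknown root prior mode: ", mode, call. = FALSE)
  )
}
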