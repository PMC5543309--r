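#' Binarize a multistate character by pooling states
#'
#' Collapses a multistate character to binary by keeping a retained state
#' set (typically the hypothesized ancestral state or states) as state
#' `"0"` and pooling every other state as `"1"`. Missing and inapplicable
#' cells pass through unchanged, so the set of species with observed data
#' never changes.
#'
#' @param states named character vector (or a `trait_matrix` column via
#'   [trait_states()]); missing entries `NA` or matrix codes.
#' @param retained_states states pooled into `"0"`; must be a nonempty
#'   proper subset of the observed alphabet.
#' @param missing_code,inapplicable_code codes passed through untouched.
#' @return named character vector of `"0"`/`"1"` (plus untouched codes),
#'   with the mapping recorded in attribute `recoding`.
#' @examples
#' binarize_multistate(c(a = "1", b = "3", c = "?"), retained_states = c("1", "2"))
#' @export
binarize_multistate <- function(states, retained_states,
                                missing_code = "?", inapplicable_code = "-") {
  x <- as.character(states)
  special <- is.na(x) | x %in% c(missing_code, inapplicable_code)
  alphabet <- sort(unique(x[!special]))
  if (length(retained_states) == 0) stop("retained_states is empty", call. = FALSE)
  retained_states <- as.character(retained_states)
  if (all(alphabet %in% retained_states)) {
    stop("retained_states covers the full alphabet; nothing to pool", call. = FALSE)
  }
  out <- x
  out[!special] <- ifelse(x[!special] %in% retained_states, "0", "1")
  names(out) <- names(states)
  attr(out, "recoding") <- list(kind = "binarize_pool",
                                retained = retained_states,
                                pooled = setdiff(alphabet, retained_states))
  out
}

#' Discretize integer counts into an ordered multistate character
#'
#' Bin membership uses half-open intervals `[lo, hi)` over strictly
#' increasing edges; values below the first edge fall in state 0 and values
#' at or above the last edge in the top state. The output is flagged as
#' ordered, making it eligible for the ordered (ORD-family) models.
#'
#' @param counts named integer vector; `NA` passes through.
#' @param edges strictly increasing interior bin boundaries; `k` edges give
#'   `k + 1` ordered states `0..k`.
#' @return named character vector of ordered states with attribute
#'   `ordered = TRUE` and the edges recorded.
#' @examples
#' discretize_count(c(a = 3, b = 6, c = 11), edges = c(6, 11))
#' @export
discretize_count <- function(counts, edges) {
  if (length(edges) < 1 || is.unsorted(edges, strictly = TRUE)) {
    stop("edges must be strictly increasing", call. = FALSE)
  }
  x <- as.numeric(counts)
  state <- findInterval(x, edges)        # [lo, hi) convention
  out <- as.character(state)
  out[is.na(x)] <- NA_character_
  names(out) <- names(counts)
  obs <- out[!is.na(out)]
  if (length(unique(obs)) == 1) {
    warning("all counts fall in a single bin; character is constant", call. = FALSE)
  }
  attr(out, "ordered") <- TRUE
  attr(out, "recoding") <- list(kind = "ordered_bins", edges = edges)
  out
}

#' Build a reduced set of independent binary characters
#'
#' Applies pooling rules to a trait matrix to produce the binary character
#' set used for pairwise correlation tests: one representative per declared
#' redundancy group (multiple recodings of the same underlying character),
#' everything binarized by pooling non-ancestral states.
#'
#' @param matrix a `trait_matrix`.
#' @param retained named list: for each character to binarize, the state(s)
#'   retained as the ancestral pool (characters already binary and listed
#'   with `NULL` are passed through).
#' @param redundancy_groups optional list of character-name vectors; only
#'   the first member of each group is kept.
#' @return list: `matrix` (binary `trait_matrix`), `n_pairs`
#'   (`n(n-1)/2`), and `provenance` tibble of applied rules.
#' @export
build_binary_set <- function(matrix, retained = list(), redundancy_groups = list()) {
  stopifnot(inherits(matrix, "trait_matrix"))
  chars <- setdiff(names(matrix), "species")
  unknown <- setdiff(names(retained), chars)
  if (length(unknown)) {
    stop("rule references unknown character(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  drop <- unlist(lapply(redundancy_groups, function(g) {
    miss <- setdiff(g, chars)
    if (length(miss)) stop("redundancy group references unknown character(s): ",
                           paste(miss, collapse = ", "), call. = FALSE)
    g[-1]
  }))
  keep <- setdiff(chars, drop)
  mc <- attr(matrix, "missing_code"); ic <- attr(matrix, "inapplicable_code")
  out <- matrix[c("species", keep)]
  prov <- list()
  for (ch in keep) {
    v <- trait_states(matrix, ch)
    alpha <- infer_alphabet(v)
    if (!is.null(retained[[ch]])) {
      b <- binarize_multistate(matrix[[ch]], retained[[ch]], mc, ic)
      out[[ch]] <- as.character(b)
      prov[[ch]] <- tibble::tibble(character = ch, kind = "binarize_pool",
                                   detail = paste0("retained {",
                                     paste(retained[[ch]], collapse = ","), "}"))
    } else if (length(alpha) > 2) {
      stop("character '", ch, "' is multistate; provide a retained state set",
           call. = FALSE)
    } else {
      prov[[ch]] <- tibble::tibble(character = ch, kind = "passthrough",
                                   detail = "already binary")
    }
  }
  n <- length(keep)
  list(matrix = trait_matrix(out, mc, ic),
       n_pairs = n * (n - 1) / 2,
       provenance = dplyr::bind_rows(prov))
}
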