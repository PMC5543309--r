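#' Read chronograms from Newick or NEXUS
#'
#' Reads one or more time-calibrated trees. NEXUS translate tables are
#' honoured; branch lengths are preserved as parsed. Negative branch
#' lengths are an error; ultrametricity is checked downstream with
#' [check_ultrametric()] and never enforced here.
#'
#' @param source a file path, or tree text (Newick string(s) or a NEXUS
#'   document).
#' @param format `"newick"` or `"nexus"`; `"auto"` sniffs for `#NEXUS`.
#' @param label provenance label for the sample (e.g. a tree-series name).
#' @return a `tree_sample`: a list of `phylo` trees with a provenance label.
#' @examples
#' read_trees("(A:1,B:1);")
#' @export
read_trees <- function(source, format = c("auto", "newick", "nexus"), label = NULL) {
  format <- match.arg(format)
  is_file <- length(source) == 1 && !grepl("[(;]", source) && file.exists(source)
  txt <- if (is_file) paste(readLines(source, warn = FALSE), collapse = "\n") else
    paste(source, collapse = "\n")
  if (format == "auto") {
    format <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) "nexus" else "newick"
  }
  trees <- if (format == "nexus") {
    tf <- tempfile(fileext = ".nex"); on.exit(unlink(tf))
    writeLines(txt, tf)
    res <- ape::read.nexus(tf)
    if (inherits(res, "phylo")) list(res) else unclass(ape::.uncompressTipLabel(res))
  } else {
    res <- tryCatch(ape::read.tree(text = txt),
                    error = function(e) stop("tree parse error: ",
                                             conditionMessage(e), call. = FALSE))
    if (is.null(res)) stop("tree parse error: no tree found", call. = FALSE)
    if (inherits(res, "phylo")) list(res) else unclass(res)
  }
  for (tr in trees) {
    if (!is.null(tr$edge.length) && any(tr$edge.length < 0)) {
      stop("negative branch length in input tree", call. = FALSE)
    }
  }
  tree_sample(trees, label = label %||% if (is_file) basename(source) else "trees")
}

#' Construct a tree sample
#'
#' @param trees a `phylo`, `multiPhylo`, or list of `phylo` objects.
#' @param label provenance label.
#' @return a `tree_sample` object.
#' @export
tree_sample <- function(trees, label = "trees") {
  if (inherits(trees, "phylo")) trees <- list(trees)
  trees <- unclass(trees)
  stopifnot(length(trees) >= 1, all(vapply(trees, inherits, logical(1), "phylo")))
  structure(list(trees = trees, label = label, size = length(trees)),
            class = "tree_sample")
}

#' @export
print.tree_sample <- function(x, ...) {
  cat("<tree_sample> '", x$label, "': ", x$size, " tree(s), ",
      length(x$trees[[1]]$tip.label), " tips in first tree\n", sep = "")
  invisible(x)
}

#' @export
length.tree_sample <- function(x) x$size

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check that a tree is ultrametric
#'
#' Computes the relative spread of root-to-tip path lengths:
#' `deviation = (max - min) / max`. This is a diagnostic, not a gate —
#' posterior tree samples often carry rounding noise, so callers should
#' warn rather than fail.
#'
#' @param tree a `phylo`.
#' @param rel_tol relative tolerance (default 1e-6).
#' @return one-row tibble: `max_depth`, `min_depth`, `deviation`, `pass`.
#' @examples
#' check_ultrametric(read_trees("((A:1,B:1):1,(C:1,D:1):1);")$trees[[1]])
#' @export
check_ultrametric <- function(tree, rel_tol = 1e-6) {
  stopifnot(inherits(tree, "phylo"), length(tree$tip.label) >= 2)
  d <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  dev <- if (max(d) > 0) (max(d) - min(d)) / max(d) else 0
  tibble::tibble(max_depth = max(d), min_depth = min(d),
                 deviation = dev, pass = dev <= rel_tol)
}

#' Read a species-by-character matrix of discrete states
#'
#' Delimited text (header row = character names, first column = species) or
#' a NEXUS CHARACTERS/DATA block. Missing and inapplicable entries are kept
#' distinct in storage; both are treated as "no signal" by every downstream
#' likelihood and parsimony computation.
#'
#' @param source file path or literal text.
#' @param format `"auto"`, `"csv"`, `"tsv"` or `"nexus"`.
#' @param missing_code symbol for missing data (default `"?"`).
#' @param inapplicable_code symbol for inapplicable data (default `"-"`).
#' @return a `trait_matrix`: a tibble (first column `species`, one column
#'   per character, all character-typed) with attributes `missing_code`,
#'   `inapplicable_code`.
#' @export
read_matrix <- function(source, format = c("auto", "csv", "tsv", "nexus"),
                        missing_code = "?", inapplicable_code = "-") {
  format <- match.arg(format)
  is_file <- length(source) == 1 && !grepl("\n", source) && file.exists(source)
  txt <- if (is_file) paste(readLines(source, warn = FALSE), collapse = "\n") else
    paste(source, collapse = "\n")
  if (format == "auto") {
    format <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) "nexus"
      else if (grepl("\t", strsplit(txt, "\n")[[1]][1])) "tsv" else "csv"
  }
  if (format == "nexus") {
    tf <- tempfile(fileext = ".nex"); on.exit(unlink(tf))
    writeLines(txt, tf)
    dat <- ape::read.nexus.data(tf)
    df <- tibble::tibble(species = names(dat))
    nchar_mat <- length(dat[[1]])
    for (j in seq_len(nchar_mat)) {
      df[[paste0("char", j)]] <- vapply(dat, `[[`, character(1), j)
    }
  } else {
    sep <- if (format == "tsv") "\t" else ","
    df <- utils::read.table(text = txt, sep = sep, header = TRUE,
                            colClasses = "character", check.names = FALSE,
                            strip.white = TRUE)
    names(df)[1] <- "species"
    df <- tibble::as_tibble(df)
  }
  if (anyDuplicated(df$species)) {
    stop("duplicate species row(s): ",
         paste(unique(df$species[duplicated(df$species)]), collapse = ", "),
         call. = FALSE)
  }
  trait_matrix(df, missing_code = missing_code,
               inapplicable_code = inapplicable_code)
}

#' Construct a trait matrix
#'
#' @param df data frame with a `species` column and character columns.
#' @param missing_code,inapplicable_code the cell codes used for missing and
#'   inapplicable observations (stored distinctly).
#' @param alphabets optional named list restricting each character's state
#'   alphabet; observed values outside it (other than the two codes) error.
#' @return a `trait_matrix` tibble.
#' @export
trait_matrix <- function(df, missing_code = "?", inapplicable_code = "-",
                         alphabets = NULL) {
  df <- tibble::as_tibble(df)
  stopifnot("species" %in% names(df))
  df <- dplyr::mutate(df, dplyr::across(-"species", as.character))
  if (anyDuplicated(df$species)) stop("duplicate species identifiers", call. = FALSE)
  for (ch in setdiff(names(df), "species")) {
    vals <- df[[ch]]
    obs <- vals[!is.na(vals) & !vals %in% c(missing_code, inapplicable_code)]
    if (!is.null(alphabets[[ch]]) && length(setdiff(obs, alphabets[[ch]])) > 0) {
      stop("character '", ch, "': value(s) outside declared alphabet: ",
           paste(setdiff(obs, alphabets[[ch]]), collapse = ","), call. = FALSE)
    }
  }
  structure(df, class = c("trait_matrix", class(df)),
            missing_code = missing_code, inapplicable_code = inapplicable_code)
}

#' Extract one character as a named state vector
#'
#' Missing and inapplicable cells both become `NA` (no signal); the
#' distinction remains available in the stored matrix.
#'
#' @param matrix a `trait_matrix`.
#' @param character character (column) name.
#' @return named character vector of states, `NA` for missing/inapplicable.
#' @export
trait_states <- function(matrix, character) {
  stopifnot(inherits(matrix, "trait_matrix"), character %in% names(matrix))
  normalize_states(setNames(matrix[[character]], matrix$species),
                   attr(matrix, "missing_code"), attr(matrix, "inapplicable_code"))
}

#' Missing-data fractions of a trait matrix
#'
#' @param matrix a `trait_matrix`.
#' @return tibble with per-character missing and inapplicable fractions,
#'   plus a `.total` row for the whole matrix.
#' @export
missing_fraction <- function(matrix) {
  mc <- attr(matrix, "missing_code"); ic <- attr(matrix, "inapplicable_code")
  chars <- setdiff(names(matrix), "species")
  per <- purrr::map_dfr(chars, function(ch) {
    v <- matrix[[ch]]
    tibble::tibble(character = ch,
                   missing = mean(is.na(v) | v == mc, na.rm = FALSE),
                   inapplicable = mean(!is.na(v) & v == ic),
                   no_signal = mean(is.na(v) | v %in% c(mc, ic)))
  })
  all_v <- unlist(matrix[chars], use.names = FALSE)
  dplyr::bind_rows(per, tibble::tibble(
    character = ".total",
    missing = mean(is.na(all_v) | all_v == mc),
    inapplicable = mean(!is.na(all_v) & all_v == ic),
    no_signal = mean(is.na(all_v) | all_v %in% c(mc, ic))))
}

#' Restrict trees and matrix to their shared species
#'
#' Prunes every tree to the species present in the matrix and drops matrix
#' rows absent from the trees (e.g. outgroup taxa never scored for the
#' traits). Branch-time sums along retained paths are preserved by pruning.
#'
#' @param trees a `tree_sample` (or single `phylo`).
#' @param matrix a `trait_matrix`.
#' @return list with elements `trees`, `matrix`, and `removed` (tibble log
#'   of taxa removed from each side).
#' @export
align_taxa <- function(trees, matrix) {
  if (inherits(trees, "phylo")) trees <- tree_sample(trees)
  stopifnot(inherits(trees, "tree_sample"), inherits(matrix, "trait_matrix"))
  tips <- trees$trees[[1]]$tip.label
  shared <- intersect(tips, matrix$species)
  if (length(shared) == 0) {
    stop("no species shared between trees and matrix", call. = FALSE)
  }
  drop_tree <- setdiff(tips, shared)
  drop_mat <- setdiff(matrix$species, shared)
  pruned <- lapply(trees$trees, function(tr) {
    extra <- setdiff(tr$tip.label, shared)
    if (length(extra)) ape::drop.tip(tr, extra) else tr
  })
  mat2 <- matrix[matrix$species %in% shared, ]
  mat2 <- trait_matrix(mat2, attr(matrix, "missing_code"),
                       attr(matrix, "inapplicable_code"))
  removed <- dplyr::bind_rows(
    tibble::tibble(taxon = drop_tree, from = "trees"),
    tibble::tibble(taxon = drop_mat, from = "matrix"))
  list(trees = tree_sample(pruned, trees$label), matrix = mat2, removed = removed)
}
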