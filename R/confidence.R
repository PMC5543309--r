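#' Cross-method confidence score for one trait-node cell
#'
#' Combines parsimony, ML and reversible-jump Bayesian reconstructions of
#' one trait at one focal node into a 0-3 star score:
#' \itemize{
#'   \item 3 stars: all three methods name the same single state and the
#'     lower bound of the rjMCMC 95\% credibility interval is at least
#'     `t_hi`;
#'   \item 2 stars: all methods agree but the CI lower bound only reaches
#'     `t_mid`;
#'   \item 1 star: methods agree but the CI lower bound falls below
#'     `t_mid`, or every method is compatible with the Bayesian modal state
#'     but at least one is equivocal (its state set contains that state
#'     among others);
#'   \item 0 stars: any method names a state set that excludes the
#'     Bayesian modal state.
#' }
#' The thresholds (defaults 0.75 and 0.5) are configuration, not fixed
#' constants.
#'
#' @param mp_states parsimony MPR state set (vector, or `"0|1"` string).
#' @param ml_state ML modal state (single state, or several if tied).
#' @param rj_state rjMCMC modal state.
#' @param ci_lower lower bound of the rjMCMC 95\% CI of the modal-state
#'   probability.
#' @param t_hi,t_mid CI-lower-bound thresholds for 3 and 2 stars.
#' @return integer 0-3, or `NA` with a warning when a method result is
#'   missing (cell flagged incomplete).
#' @examples
#' confidence_score("0", "0", "0", ci_lower = 0.91) # 3
#' confidence_score("0|1", "0", "0", ci_lower = 0.55) # 1
#' @export
confidence_score <- function(mp_states, ml_state, rj_state, ci_lower,
                             t_hi = 0.75, t_mid = 0.5) {
  if (anyNA(c(mp_states[1], ml_state[1], rj_state[1], ci_lower))) {
    warning("incomplete cell: missing method result", call. = FALSE)
    return(NA_integer_)
  }
  mp <- unlist(strsplit(as.character(mp_states), "|", fixed = TRUE))
  ml <- unlist(strsplit(as.character(ml_state), "|", fixed = TRUE))
  rj <- as.character(rj_state)

  mp_single <- length(mp) == 1
  ml_single <- length(ml) == 1
  full_agree <- mp_single && ml_single && mp[1] == rj && ml[1] == rj
  if (full_agree) {
    if (ci_lower >= t_hi) return(3L)
    if (ci_lower >= t_mid) return(2L)
    return(1L)
  }
  # a method is compatible when its state set contains the rjMCMC modal
  # state; a single-state call naming a different state is a hard conflict
  if (!(rj %in% mp) || !(rj %in% ml)) return(0L)
  1L  # compatible but at least one method equivocal
}

#' Confidence grid across traits, focal nodes and tree series
#'
#' @param results tibble with columns `trait`, `node`, `series`,
#'   `mp_states`, `ml_state`, `rj_state`, `ci_lower`.
#' @param t_hi,t_mid thresholds passed to [confidence_score()].
#' @return a `confidence_grid` tibble: the input plus `stars` (NA = cell
#'   flagged incomplete).
#' @export
summarize_confidence <- function(results, t_hi = 0.75, t_mid = 0.5) {
  needed <- c("trait", "node", "mp_states", "ml_state", "rj_state", "ci_lower")
  stopifnot(all(needed %in% names(results)))
  if (!"series" %in% names(results)) results$series <- "default"
  results$stars <- purrr::pmap_int(
    results[, c("mp_states", "ml_state", "rj_state", "ci_lower")],
    function(mp_states, ml_state, rj_state, ci_lower) {
      suppressWarnings(
        confidence_score(mp_states, ml_state, rj_state, ci_lower, t_hi, t_mid))
    })
  structure(tibble::as_tibble(results),
            class = c("confidence_grid", class(tibble::as_tibble(results))))
}

#' @export
autoplot.confidence_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$trait, y = .data$node,
                                       fill = factor(.data$stars))) +
    ggplot2::geom_tile(colour = "grey80") +
    ggplot2::facet_wrap(~series) +
    ggplot2::scale_fill_brewer(palette = "Blues", na.value = "grey95",
                               name = "stars") +
    ggplot2::labs(x = "trait", y = "focal node") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
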