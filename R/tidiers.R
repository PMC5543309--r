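# broom-style tidiers and ggplot2 autoplot methods for result objects.

#' @export
tidy.mk_fit <- function(x, ...) {
  tibble::tibble(model = x$model,
                 class = seq_along(x$rates),
                 rate = x$rates)
}

#' @export
glance.mk_fit <- function(x, ...) {
  tibble::tibble(model = x$model, lnL = x$lnL, K = x$K, n = x$n,
                 AICc = x$AICc, converged = x$convergence)
}

#' @export
tidy.model_selection <- function(x, ...) {
  tibble::as_tibble(x)
}

#' @export
glance.model_selection <- function(x, ...) {
  best <- attr(x, "best")
  tibble::tibble(n_models = nrow(x), best_model = best$model,
                 best_AICc = best$AICc, best_lnL = best$lnL)
}

#' @export
tidy.rjmcmc_fit <- function(x, ...) {
  if (is.null(x$summary)) x$model_freq else x$summary
}

#' @export
glance.rjmcmc_fit <- function(x, ...) {
  ess_lnL <- effective_sample_size(x$trace$lnL)
  tibble::tibble(n_samples = nrow(x$trace),
                 n_models_visited = nrow(x$model_freq),
                 top_model = x$model_freq$signature[1],
                 top_model_freq = x$model_freq$freq[1],
                 ess_lnL = ess_lnL$ess,
                 mean_n_classes = mean(x$trace$n_classes))
}

#' @export
tidy.pair_fit <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.pair_fit <- function(x, ...) {
  tibble::tibble(charA = attr(x, "pair")[1], charB = attr(x, "pair")[2],
                 best_model = attr(x, "best_model"),
                 cum_correlated_weight = attr(x, "cum_correlated_weight"),
                 n = attr(x, "n"))
}

#' @export
tidy.pair_rj <- function(x, ...) x$bf

#' @export
glance.pair_rj <- function(x, ...) {
  tibble::tibble(charA = x$pair[1], charB = x$pair[2],
                 freqD = x$freqD, freqI = x$freqI, bf = x$bf$bf,
                 flag = x$bf$flag)
}

#' @export
tidy.mpr_result <- function(x, ...) tibble::as_tibble(x)

#' @export
glance.mpr_result <- function(x, ...) {
  tibble::tibble(length = attr(x, "length"),
                 n_equivocal = sum(x$equivocal))
}

#' Trace plot of a reversible-jump run
#'
#' Panels for the log-likelihood, number of rate classes, zero-class size
#' and hyperprior mean against generation; the standard visual
#' stationarity check.
#'
#' @param object an `rjmcmc_fit`.
#' @param ... unused.
#' @export
autoplot.rjmcmc_fit <- function(object, ...) {
  long <- object$trace |>
    dplyr::select("generation", "lnL", "n_classes", "zero_size",
                  "hyper_mean") |>
    tidyr::pivot_longer(-"generation", names_to = "quantity")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$generation, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "steelblue") +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::theme_minimal()
}

#' Node-probability plot for a marginal reconstruction
#'
#' @param object a `marginal_recon` tibble from [marginal_ancestral()].
#' @param ... unused.
#' @export
autoplot.marginal_recon <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$node), y = .data$prob,
                                       fill = .data$state)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "internal node", y = "marginal probability") +
    ggplot2::theme_minimal()
}
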