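#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an assay result
#'
#' @param x an `endo_assay` from [clonal_growth_assay()].
#' @param ... unused.
#' @return a one-row tibble with the assay's headline numbers.
#' @export
tidy.endo_assay <- function(x, ...) {
  tibble::tibble(n_influx = x$n_influx, T = x$T, seed = x$seed,
                 N_equilibrium = x$N_equilibrium, extinct = x$extinct,
                 leakage_mode = x$toggles$leakage_mode,
                 targeting_h_to_s = x$toggles$targeting$host_to_symbiont,
                 targeting_s_to_h = x$toggles$targeting$symbiont_to_host)
}

#' @rdname tidy.endo_assay
#' @export
glance.endo_assay <- function(x, ...) tidy.endo_assay(x, ...)

#' Generic tidiers
#'
#' `tidy()` and `glance()` generics (re-exported conventions) for the
#' package's result objects.
#'
#' @param x an object.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname tidy
#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot the density trace of a clonal growth assay
#'
#' @param object an `endo_assay`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.endo_assay <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$step, y = .data$N)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$N_equilibrium, linetype = 2) +
    ggplot2::labs(x = "timestep", y = "occupied fraction N",
                  title = sprintf("Clonal growth at n_influx = %g", object$n_influx)) +
    ggplot2::theme_minimal()
}

#' Plot population summaries over time
#'
#' @param summaries a tibble of [population_summary()] rows (as returned by
#'   [run_simulation()]).
#' @return a ggplot of occupied fraction and mean symbiont count.
#' @export
plot_population <- function(summaries) {
  long <- dplyr::bind_rows(
    tibble::tibble(step = summaries$step, value = summaries$N,
                   metric = "occupied fraction N"),
    tibble::tibble(step = summaries$step, value = summaries$mean_symbionts,
                   metric = "mean symbionts per holobiont"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "timestep", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
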