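#' Exhaustive two-agent configuration study
#'
#' Enumerates every distinct two-agent bipartite configuration over
#' `n_events` events and `n_types` link types (degrees
#' `1 <= N_i, N_j <= n_events`), summarized by its sufficient statistic: the
#' per-type link counts of each agent and the per-type overlaps. All
#' reported quantities (mixture and per-type reference p-values, overlap
#' fraction, link-type concentration) depend on the configuration only
#' through this statistic, which is what makes the full enumeration
#' tractable; the default study size (20 events, 3 types) spans about
#' 10^8 classes and runs in minutes. Classes can optionally be weighted by
#' their multiplicity, i.e. the number of labeled event assignments
#' realizing each class, to reproduce counts over raw configurations.
#'
#' Three summaries are produced:
#' \describe{
#'   \item{cells}{mean mixture p-value and the fraction of classes where the
#'     mixture p-value beats the min-aggregated reference, per cell of
#'     (Herfindahl-Hirschman overlap concentration) x (overlap count).}
#'   \item{validated}{fraction of classes validated (`p < alpha`) per
#'     significance level and method.}
#'   \item{minima}{the smallest p-value each method attains anywhere in the
#'     configuration space.}
#' }
#'
#' @param n_events Number of events per configuration (study size: 20).
#' @param n_types Number of link types (study size: 3).
#' @param alpha_grid Significance levels for the validated-fraction curves.
#' @param hh_breaks Bin edges for the concentration axis, spanning
#'   `[1/n_types, 1]`.
#' @param multiplicity Also compute labeled-realization weights? (Slower;
#'   intended for small studies.)
#' @return A `two_agent_study` object (list of tibbles `cells`, `validated`,
#'   `minima`, plus `n_classes`, `total_weight`, `config`), with an
#'   `autoplot()` method drawing the concentration-overlap heatmaps.
#' @examples
#' study <- enumerate_two_agent_study(n_events = 6)
#' study$minima
#' @export
enumerate_two_agent_study <- function(n_events = 20, n_types = 3,
                                      alpha_grid = 10^seq(-12, -1),
                                      hh_breaks = seq(1 / n_types, 1,
                                                      length.out = 11),
                                      multiplicity = FALSE) {
  stopifnot(n_events >= 1, n_types >= 1)
  alpha_grid <- sort(alpha_grid)
  hh_breaks <- sort(hh_breaks)
  raw <- cpp_enumerate_two_agent(as.integer(n_events), as.integer(n_types),
                                 as.numeric(alpha_grid),
                                 as.numeric(hh_breaks), isTRUE(multiplicity))
  models <- c("mixture", "reference_min", "reference_mean", "reference_max")
  nb <- length(hh_breaks) - 1

  cells <- tidyr::expand_grid(hh_bin = seq_len(nb),
                              same_type = seq_len(n_events))
  flat <- function(m) as.vector(m[cbind(cells$hh_bin, cells$same_type)])
  cells <- cells |>
    dplyr::mutate(
      hh_lo = hh_breaks[.data$hh_bin],
      hh_hi = hh_breaks[.data$hh_bin + 1],
      overlap_frac = .data$same_type / n_events,
      n_classes = flat(raw$cell_count),
      mean_p_mixture = ifelse(.data$n_classes > 0,
                              flat(raw$cell_sum_p) / .data$n_classes, NA_real_),
      frac_mixture_lt_refmin = ifelse(.data$n_classes > 0,
                                      flat(raw$cell_lt) / .data$n_classes,
                                      NA_real_)
    )
  if (multiplicity) {
    cells <- cells |>
      dplyr::mutate(
        weight = flat(raw$cell_wcount),
        mean_p_mixture_weighted = ifelse(.data$weight > 0,
                                         flat(raw$cell_wsum_p) / .data$weight,
                                         NA_real_),
        frac_mixture_lt_refmin_weighted = ifelse(.data$weight > 0,
                                                 flat(raw$cell_wlt) / .data$weight,
                                                 NA_real_)
      )
  }

  validated <- tidyr::expand_grid(alpha = alpha_grid, model = models) |>
    dplyr::mutate(fraction = as.vector(t(raw$validated)) / raw$n_classes)
  if (multiplicity) {
    validated$fraction_weighted <-
      as.vector(t(raw$wvalidated)) / raw$total_weight
  }

  structure(
    list(
      cells = cells,
      validated = validated,
      minima = tibble::tibble(model = models, min_p = as.numeric(raw$minima)),
      n_classes = raw$n_classes,
      total_weight = if (multiplicity) raw$total_weight else NA_real_,
      config = list(n_events = n_events, n_types = n_types,
                    alpha_grid = alpha_grid, hh_breaks = hh_breaks,
                    multiplicity = multiplicity)
    ),
    class = "two_agent_study"
  )
}

#' @export
print.two_agent_study <- function(x, ...) {
  cat(sprintf("<two_agent_study> %d events, %d link types, %s classes\n",
              x$config$n_events, x$config$n_types,
              format(x$n_classes, big.mark = ",")))
  print(as.data.frame(x$minima), row.names = FALSE)
  invisible(x)
}

#' Plot a two-agent configuration study
#'
#' Heatmaps over the (overlap concentration) x (overlap fraction) plane:
#' mean mixture p-value per cell, and the fraction of configurations where
#' the mixture p-value is below the min-aggregated reference p-value.
#'
#' @param object A `two_agent_study`.
#' @param which `"mean_p"` or `"frac_lt"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot two_agent_study
#' @export
autoplot.two_agent_study <- function(object, which = c("mean_p", "frac_lt"),
                                     ...) {
  which <- match.arg(which)
  fill <- if (which == "mean_p") "mean_p_mixture" else "frac_mixture_lt_refmin"
  dat <- dplyr::filter(object$cells, .data$n_classes > 0)
  ggplot2::ggplot(dat, ggplot2::aes((.data$hh_lo + .data$hh_hi) / 2,
                                    .data$overlap_frac,
                                    fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "overlap concentration (Herfindahl-Hirschman)",
                  y = "overlap fraction", fill = fill) +
    ggplot2::theme_minimal()
}
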