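#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trace and posterior-density plot for an occupancy fit
#'
#' @param object an [fit_occupancy()] result.
#' @param parameters chains to show.
#' @param ... unused.
#' @return a ggplot object (facetted traces with marginal densities).
#' @method autoplot occupancy_fit
#' @export
autoplot.occupancy_fit <- function(object,
                                   parameters = c("alpha0", "alpha1",
                                                  "sigma_loc"), ...) {
  d <- object$draws |>
    dplyr::select(dplyr::all_of(c(".iteration", parameters))) |>
    tidyr::pivot_longer(-".iteration", names_to = "parameter")
  ggplot2::ggplot(d, ggplot2::aes(.data$.iteration, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2, colour = "steelblue") +
    ggplot2::facet_wrap(~parameter, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "retained iteration", y = NULL,
                  title = paste("MCMC traces:", object$species)) +
    ggplot2::theme_minimal()
}

#' Occurrence probabilities by habitat (species panel)
#'
#' Dot-and-interval chart of the posterior probability of observing each
#' species on coral reef vs algal meadow transects, with 95% credible
#' intervals.
#'
#' @param occupancy the `occupancy` tibble of a [run_pipeline()] report.
#' @return a ggplot object.
#' @export
plot_occurrence <- function(occupancy) {
  d <- dplyr::bind_rows(
    occupancy |> dplyr::transmute(.data$species, habitat = "coral_reef",
                                  mean = .data$p_coral_mean,
                                  lo = .data$p_coral_lo,
                                  hi = .data$p_coral_hi),
    occupancy |> dplyr::transmute(.data$species, habitat = "algal_meadow",
                                  mean = .data$p_algal_mean,
                                  lo = .data$p_algal_lo,
                                  hi = .data$p_algal_hi))
  ggplot2::ggplot(d, ggplot2::aes(.data$mean, .data$species,
                                  colour = .data$habitat)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.6),
                             fatten = 2) +
    ggplot2::scale_colour_manual(values = c(coral_reef = "coral3",
                                            algal_meadow = "seagreen4")) +
    ggplot2::labs(x = "probability of occurrence (posterior mean, 95% CI)",
                  y = NULL) +
    ggplot2::xlim(0, 1) +
    ggplot2::theme_minimal()
}

#' Live/dead coral use vs availability (species panel)
#'
#' Mean percentage of groups on live and on dead coral per species, with 95%
#' confidence intervals and dashed reference lines at the mean live, dead and
#' combined coral availability.
#'
#' @param preference the `preference` tibble of a [run_pipeline()] report.
#' @return a ggplot object.
#' @export
plot_preference <- function(preference) {
  d <- dplyr::bind_rows(
    preference |> dplyr::transmute(.data$species, substrate = "live",
                                   mean = .data$mean_pct_live,
                                   lo = .data$ci_live_lo,
                                   hi = .data$ci_live_hi),
    preference |> dplyr::transmute(.data$species, substrate = "dead",
                                   mean = .data$mean_pct_dead,
                                   lo = .data$ci_dead_lo,
                                   hi = .data$ci_dead_hi))
  refs <- tibble::tibble(
    substrate = c("live", "dead", "combined"),
    value = c(preference$availability_live[1], preference$availability_dead[1],
              preference$availability_combined[1]))
  ggplot2::ggplot(d, ggplot2::aes(.data$mean, .data$species,
                                  colour = .data$substrate)) +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
                             position = ggplot2::position_dodge(width = 0.6),
                             fatten = 2) +
    ggplot2::geom_vline(data = refs,
                        ggplot2::aes(xintercept = .data$value,
                                     colour = .data$substrate),
                        linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(live = "coral3",
                                            dead = "grey40",
                                            combined = "black")) +
    ggplot2::labs(x = "% of groups on substrate (mean, 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Growth-form use, availability and selectivity (species panel)
#'
#' Side-by-side bars of use vs availability proportions per coral growth form,
#' one facet per species, with preferred forms (bootstrap CI lower bound > 1)
#' marked.
#'
#' @param selectivity the `selectivity` tibble of a [run_pipeline()] report.
#' @return a ggplot object.
#' @export
plot_selectivity <- function(selectivity) {
  d <- selectivity |>
    dplyr::filter(.data$status == "ok" | !("status" %in% names(selectivity))) |>
    tidyr::pivot_longer(c("use_proportion", "availability_proportion"),
                        names_to = "quantity", values_to = "proportion")
  marks <- dplyr::filter(selectivity, .data$preferred)
  ggplot2::ggplot(d, ggplot2::aes(.data$growth_form, .data$proportion,
                                  fill = .data$quantity)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_point(data = marks,
                        ggplot2::aes(.data$growth_form, .data$use_proportion),
                        inherit.aes = FALSE, shape = 3, size = 3) +
    ggplot2::facet_wrap(~species) +
    ggplot2::scale_fill_manual(
      values = c(use_proportion = "coral3",
                 availability_proportion = "grey60"),
      labels = c(use_proportion = "use",
                 availability_proportion = "availability")) +
    ggplot2::labs(x = NULL, y = "proportion of live-coral groups / cover") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
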