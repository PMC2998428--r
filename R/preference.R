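#' Per-transect percentages of groups on live and dead coral
#'
#' For each transect where the species occurred, the percentage of its groups
#' recorded on live coral, on dead coral, and their sum (coral structure).
#' Transects where the species was not seen contribute nothing — this is a
#' use measure conditional on occupancy, not an abundance measure.
#'
#' @param table a [survey_table()].
#' @param species species name; must occur in the table.
#' @return a tibble with columns `transect_id`, `n_groups`, `pct_live`,
#'   `pct_dead`, `pct_combined` (percent, 0-100).
#' @export
transect_use_percentages <- function(table, species) {
  obs <- dplyr::filter(table$observations, .data$species == !!species)
  if (nrow(obs) == 0) {
    stop("species '", species, "' not found in survey", call. = FALSE)
  }
  obs |>
    dplyr::group_by(.data$transect_id) |>
    dplyr::summarise(
      n_groups = dplyr::n(),
      pct_live = 100 * sum(.data$microhabitat == "live_coral") / dplyr::n(),
      pct_dead = 100 * sum(.data$microhabitat == "dead_coral") / dplyr::n(),
      .groups = "drop") |>
    dplyr::mutate(pct_combined = .data$pct_live + .data$pct_dead)
}

#' Mean benthic availability of coral substrate in one habitat
#'
#' Arithmetic mean and standard error, across all transects of the given
#' habitat, of live coral and dead coral percent cover; `combined` is the sum
#' of the two means (the coral-structure threshold).
#'
#' @param table a [survey_table()].
#' @param habitat `"coral_reef"` or `"algal_meadow"`.
#' @return a tibble with one row per substrate (`live`, `dead`, `combined`):
#'   `mean_cover`, `se` (NA-free; 0 with a warning for a single transect) and
#'   `n_transects`.
#' @export
mean_availability <- function(table, habitat = "coral_reef") {
  habitat <- match.arg(habitat, HABITATS)
  tr <- dplyr::filter(table$transects, .data$habitat == !!habitat)
  if (nrow(tr) == 0) {
    stop("no transects of habitat '", habitat, "' in survey", call. = FALSE)
  }
  n <- nrow(tr)
  se_of <- function(v) if (n < 2) 0 else sd(v) / sqrt(n)
  if (n < 2) warning("single transect: standard error reported as 0",
                     call. = FALSE)
  live <- mean(tr$live_coral)
  dead <- mean(tr$dead_coral)
  tibble::tibble(
    substrate = c("live", "dead", "combined"),
    mean_cover = c(live, dead, live + dead),
    se = c(se_of(tr$live_coral), se_of(tr$dead_coral),
           se_of(tr$live_coral + tr$dead_coral)),
    n_transects = n)
}

# t-based equal-tailed CI for a mean, df = n - 1; returns c(lo, hi),
# truncated to the feasible [0, 100] percentage range.
t_ci <- function(v, level = 0.95) {
  n <- length(v)
  m <- mean(v)
  half <- qt(1 - (1 - level) / 2, df = n - 1) * sd(v) / sqrt(n)
  c(max(0, m - half), min(100, m + half))
}

boot_ci <- function(v, level = 0.95, n_boot = 2000, seed = 1) {
  means <- with_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(sample(v, length(v), replace = TRUE)),
           numeric(1))
  })
  unname(quantile(means, c((1 - level) / 2, 1 - (1 - level) / 2)))
}

#' Test a species' preference for live coral, dead coral and coral structure
#'
#' Computes the mean, across occupied transects, of the percentage of the
#' species' groups on live coral, dead coral and both combined, with 95%
#' confidence intervals, and flags a preference when the CI lower bound lies
#' above the corresponding mean availability: live coral cover, dead coral
#' cover, and their sum. Availability enters as a point value (its SE is
#' reported by [mean_availability()] but not used in the rule).
#'
#' @param table a [survey_table()].
#' @param species species name.
#' @param availability named list or vector with elements `live` and `dead`
#'   (percent cover). Default `NULL` computes both from the survey's
#'   coral-reef transects via [mean_availability()].
#' @param level confidence level (default 0.95).
#' @param method `"t"` (default) for a t-interval on the per-transect
#'   percentages (df = transects - 1) or `"bootstrap"` for a percentile
#'   interval resampling transects.
#' @param n_boot,seed bootstrap settings (used when `method = "bootstrap"`).
#' @return a one-row tibble: `species`, `n_transects_used`, then for each of
#'   live/dead/combined the mean, CI bounds and preference flag. A species
#'   seen on a single transect gets `NA` CIs, all flags `FALSE` and a warning.
#' @export
species_preference <- function(table, species, availability = NULL,
                               level = 0.95, method = c("t", "bootstrap"),
                               n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  if (is.null(availability)) {
    av <- mean_availability(table, "coral_reef")
    availability <- list(live = av$mean_cover[av$substrate == "live"],
                         dead = av$mean_cover[av$substrate == "dead"])
  }
  use <- transect_use_percentages(table, species)
  n <- nrow(use)
  ci_of <- function(v) {
    if (n < 2) return(c(NA_real_, NA_real_))
    if (method == "t") t_ci(v, level) else
      boot_ci(v, level, n_boot, derive_seed(seed, species))
  }
  if (n < 2) {
    warning("species '", species,
            "' occurs on a single transect: CI undefined, flags FALSE",
            call. = FALSE)
  }
  ci_l <- ci_of(use$pct_live)
  ci_d <- ci_of(use$pct_dead)
  ci_c <- ci_of(use$pct_combined)
  thr_combined <- availability$live + availability$dead
  tibble::tibble(
    species = species, n_transects_used = n,
    mean_pct_live = mean(use$pct_live),
    ci_live_lo = ci_l[1], ci_live_hi = ci_l[2],
    mean_pct_dead = mean(use$pct_dead),
    ci_dead_lo = ci_d[1], ci_dead_hi = ci_d[2],
    mean_pct_combined = mean(use$pct_combined),
    ci_combined_lo = ci_c[1], ci_combined_hi = ci_c[2],
    availability_live = availability$live,
    availability_dead = availability$dead,
    availability_combined = thr_combined,
    prefers_live = n >= 2 && ci_l[1] > availability$live,
    prefers_dead = n >= 2 && ci_d[1] > availability$dead,
    prefers_structure = n >= 2 && ci_c[1] > thr_combined)
}

#' Run the coral-preference test over many species
#'
#' @param table a [survey_table()].
#' @param species character vector of species names (e.g. those passing
#'   [filter_min_individuals()]).
#' @param ... passed on to [species_preference()].
#' @return a tibble with one row per species (rows bound in the given order).
#' @export
preference_screen <- function(table, species, ...) {
  purrr::map_dfr(species, function(sp) species_preference(table, sp, ...))
}
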