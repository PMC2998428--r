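#' Summarise survey observations by species
#'
#' Computes, for every species in the survey, the total number of individuals
#' (sum of group sizes), the number of groups (one observation = one group;
#' a solitary fish counts as a group of one) and the number of distinct
#' transects on which the species was seen. This is the per-species census
#' summary; inclusion filtering is a separate step
#' ([filter_min_individuals()]).
#'
#' @param table a [survey_table()].
#' @return a tibble with columns `family`, `species`, `n_individuals`,
#'   `n_groups`, `n_transects`, sorted by family then species. `family` is
#'   `NA` when no species metadata is attached.
#' @export
summarize_species <- function(table) {
  obs <- table$observations
  if (nrow(obs) == 0) {
    return(tibble::tibble(family = character(), species = character(),
                          n_individuals = integer(), n_groups = integer(),
                          n_transects = integer()))
  }
  out <- obs |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_individuals = as.integer(sum(.data$group_size)),
                     n_groups = dplyr::n(),
                     n_transects = dplyr::n_distinct(.data$transect_id),
                     .groups = "drop")
  meta <- table$species_metadata
  if (!is.null(meta) && "family" %in% names(meta)) {
    out <- out |>
      dplyr::left_join(dplyr::distinct(meta, .data$species, .data$family),
                       by = "species")
  } else {
    out$family <- NA_character_
  }
  out |>
    dplyr::select("family", "species", "n_individuals", "n_groups",
                  "n_transects") |>
    dplyr::arrange(.data$family, .data$species)
}

#' Filter species summaries by a minimum number of individuals
#'
#' The study's first inclusion rule: habitat-scale and coral-microhabitat
#' analyses only consider species with at least `min_individuals` juveniles
#' observed over the whole survey (default 5, boundary inclusive).
#'
#' @param summaries a tibble from [summarize_species()].
#' @param min_individuals integer threshold, at least 1.
#' @return the retained rows of `summaries`, order preserved.
#' @export
filter_min_individuals <- function(summaries, min_individuals = 5) {
  if (!is.numeric(min_individuals) || length(min_individuals) != 1 ||
      min_individuals < 1) {
    stop("min_individuals must be a single integer >= 1", call. = FALSE)
  }
  dplyr::filter(summaries, .data$n_individuals >= min_individuals)
}

#' Species eligible for growth-form selectivity analysis
#'
#' The study's second inclusion rule: growth-form selectivity is assessed only
#' for species that prefer live coral (lower 95% confidence bound of live
#' coral use above mean live coral availability) and were observed on at least
#' `min_transects` transects (default 12, boundary inclusive).
#'
#' @param summaries a tibble from [summarize_species()].
#' @param live_coral_preferrers character vector of species flagged
#'   `prefers_live` by [species_preference()].
#' @param min_transects integer threshold.
#' @return character vector of eligible species (sorted).
#' @export
eligible_growth_form_species <- function(summaries, live_coral_preferrers,
                                         min_transects = 12) {
  enough <- summaries$species[summaries$n_transects >= min_transects]
  sort(intersect(unique(live_coral_preferrers), enough))
}

#' Published census table of juvenile fish at Ningaloo Reef
#'
#' Loads the packaged per-species census counts from the Ningaloo Reef
#' juvenile fish survey (214 transects, 2009-2010): 56 species in 11 families,
#' 6979 individuals in total. Adult-habitat footnote flags are carried as
#' logical columns.
#'
#' @return a tibble with columns `family`, `species`, `individuals`, `groups`,
#'   `transects`, `coral_associated_adult`, `algal_adult`.
#' @export
table1_counts <- function() {
  path <- system.file("extdata", "table1_ningaloo.csv", package = "reefuse",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    family = readr::col_character(),
                    species = readr::col_character(),
                    individuals = readr::col_integer(),
                    groups = readr::col_integer(),
                    transects = readr::col_integer(),
                    coral_associated_adult = readr::col_logical(),
                    algal_adult = readr::col_logical()))
}
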