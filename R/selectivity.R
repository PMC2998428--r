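#' Growth-form selectivity (electivity) indices for one species
#'
#' For a live-coral-associated species, computes per growth form the selection
#' ratio `w = use / availability`, where use is the proportion of the species'
#' live-coral groups found on that growth form (groups pooled across the
#' transects where the species occurred) and availability is that growth
#' form's mean percent cover — expressed, by default, as a fraction of the
#' total benthos — averaged over only the transects where the species
#' occurred. An index above 1 indicates use in excess of availability; the
#' growth form is flagged `preferred` when the lower bound of the 95%
#' bootstrap confidence interval (resampling occupied transects, percentile
#' method) exceeds 1.
#'
#' A growth form with zero availability but nonzero use yields an infinite
#' index with a warning (never silently dropped).
#'
#' @param table a [survey_table()].
#' @param species species name; must have at least one live-coral group.
#' @param availability `"total"` (default): growth-form cover as a fraction of
#'   all benthos; `"live_conditional"`: as a fraction of live coral cover
#'   only.
#' @param level confidence level (default 0.95).
#' @param n_boot bootstrap resamples (default 2000).
#' @param seed integer seed for the bootstrap.
#' @return a tibble with one row per growth form: `species`, `growth_form`,
#'   `use_proportion`, `availability_proportion`, `index_w`, `ci_lo`, `ci_hi`,
#'   `preferred`, `n_transects` (number of occupied transects used).
#' @export
selectivity_indices <- function(table, species,
                                availability = c("total", "live_conditional"),
                                level = 0.95, n_boot = 2000, seed = 1) {
  availability <- match.arg(availability)
  obs <- dplyr::filter(table$observations, .data$species == !!species)
  if (nrow(obs) == 0) {
    stop("species '", species, "' not found in survey", call. = FALSE)
  }
  if (!any(obs$microhabitat == "live_coral")) {
    stop("species '", species, "' has no live-coral groups", call. = FALSE)
  }
  occupied <- unique(obs$transect_id)
  tr <- table$transects[table$transects$transect_id %in% occupied, ]

  point <- selectivity_point(obs, tr, availability)

  # bootstrap over occupied transects (the independent sampling units)
  obs_by_tr <- split(obs, obs$transect_id)
  boot <- with_seed(derive_seed(seed, "selectivity", species), {
    replicate(n_boot, {
      ids <- sample(occupied, length(occupied), replace = TRUE)
      b_obs <- dplyr::bind_rows(obs_by_tr[ids])
      b_tr <- tr[match(ids, tr$transect_id), ]
      if (!any(b_obs$microhabitat == "live_coral")) {
        rep(NA_real_, length(GROWTH_FORMS))
      } else {
        selectivity_point(b_obs, b_tr, availability)$index_w
      }
    })
  })
  lo_p <- (1 - level) / 2
  ci <- apply(boot, 1, function(v) {
    v <- v[is.finite(v)]
    if (length(v) == 0) return(c(NA_real_, NA_real_))
    unname(quantile(v, c(lo_p, 1 - lo_p)))
  })

  out <- point |>
    dplyr::mutate(species = !!species, ci_lo = ci[1, ], ci_hi = ci[2, ],
                  preferred = is.finite(.data$ci_lo) & .data$ci_lo > 1,
                  n_transects = length(occupied)) |>
    dplyr::select("species", "growth_form", "use_proportion",
                  "availability_proportion", "index_w", "ci_lo", "ci_hi",
                  "preferred", "n_transects")
  if (any(is.infinite(out$index_w))) {
    warning("species '", species, "': growth form(s) ",
            paste(out$growth_form[is.infinite(out$index_w)], collapse = ", "),
            " used but with zero estimated availability (infinite index)",
            call. = FALSE)
  }
  out
}

# Point estimates of use, availability and index per growth form.
# obs: observations of one species; tr: the occupied transects (possibly with
# repeats under bootstrap resampling).
selectivity_point <- function(obs, tr, availability) {
  live <- obs[obs$microhabitat == "live_coral", ]
  use_counts <- table(factor(live$growth_form, levels = GROWTH_FORMS))
  use_prop <- as.numeric(use_counts) / sum(use_counts)
  gf_cover <- colMeans(tr[, paste0("gf_", GROWTH_FORMS), drop = FALSE])
  avail_prop <- if (availability == "total") {
    as.numeric(gf_cover) / 100
  } else {
    lc <- mean(tr$live_coral)
    if (lc <= 0) rep(0, length(GROWTH_FORMS)) else as.numeric(gf_cover) / lc
  }
  idx <- ifelse(avail_prop > 0, use_prop / avail_prop,
                ifelse(use_prop > 0, Inf, NA_real_))
  tibble::tibble(growth_form = GROWTH_FORMS, use_proportion = use_prop,
                 availability_proportion = avail_prop, index_w = idx)
}

#' Selectivity indices for a set of candidate species
#'
#' Runs [selectivity_indices()] for each species in the candidate set (as
#' produced by [eligible_growth_form_species()]), in sorted order. Candidates
#' absent from the table (or without live-coral groups) are reported with
#' status `"not_found"` and `NA` results rather than failing the whole screen.
#'
#' @param table a [survey_table()].
#' @param candidate_species character vector of species names.
#' @param ... passed on to [selectivity_indices()].
#' @return a tibble: per species x growth form rows with a `status` column
#'   (`"ok"` or `"not_found"`). Empty candidate set yields an empty tibble.
#' @export
selectivity_screen <- function(table, candidate_species, ...) {
  if (length(candidate_species) == 0) {
    return(tibble::tibble(species = character(), growth_form = character(),
                          use_proportion = numeric(),
                          availability_proportion = numeric(),
                          index_w = numeric(), ci_lo = numeric(),
                          ci_hi = numeric(), preferred = logical(),
                          n_transects = integer(), status = character()))
  }
  purrr::map_dfr(sort(unique(candidate_species)), function(sp) {
    res <- tryCatch(selectivity_indices(table, sp, ...),
                    error = function(e) NULL)
    if (is.null(res)) {
      tibble::tibble(species = sp, growth_form = GROWTH_FORMS,
                     use_proportion = NA_real_,
                     availability_proportion = NA_real_, index_w = NA_real_,
                     ci_lo = NA_real_, ci_hi = NA_real_, preferred = FALSE,
                     n_transects = NA_integer_, status = "not_found")
    } else {
      dplyr::mutate(res, status = "ok")
    }
  })
}

#' Ivlev difference-form electivity
#'
#' Convenience transform `E = (r - p) / (r + p)` of a use proportion `r` and
#' availability proportion `p`, ranging from -1 (complete avoidance) to +1
#' (exclusive use). The analysis path uses the ratio-form selection index
#' ([selectivity_indices()]); this difference form is provided for comparison
#' only.
#'
#' @param use,availability proportions in \[0, 1\].
#' @return numeric vector of electivities; `NA` where both are zero.
#' @export
ivlev_electivity <- function(use, availability) {
  ifelse(use + availability == 0, NA_real_,
         (use - availability) / (use + availability))
}

#' Manly-style normal-approximation CI for a selection ratio
#'
#' Alternative to the bootstrap interval: treats the per-transect selection
#' ratios as an i.i.d. sample and applies a normal (t) interval to their mean.
#' Provided for robustness comparison with the bootstrap percentile interval.
#'
#' @param table a [survey_table()].
#' @param species species name.
#' @param availability as in [selectivity_indices()].
#' @param level confidence level.
#' @return a tibble like [selectivity_indices()] (per-transect-averaged index,
#'   normal-theory CI), without bootstrap columns.
#' @export
selectivity_indices_normal <- function(table, species,
                                       availability = c("total",
                                                        "live_conditional"),
                                       level = 0.95) {
  availability <- match.arg(availability)
  obs <- dplyr::filter(table$observations, .data$species == !!species)
  if (nrow(obs) == 0 || !any(obs$microhabitat == "live_coral")) {
    stop("species '", species, "' has no live-coral groups", call. = FALSE)
  }
  occupied <- unique(obs$transect_id)
  tr <- table$transects[table$transects$transect_id %in% occupied, ]
  per_tr <- purrr::map(occupied, function(id) {
    selectivity_point(obs[obs$transect_id == id, , drop = FALSE],
                      tr[tr$transect_id == id, , drop = FALSE],
                      availability)$index_w
  })
  m <- do.call(rbind, per_tr)
  z <- qt(1 - (1 - level) / 2, df = max(1, length(occupied) - 1))
  est <- colMeans(m, na.rm = TRUE)
  se <- apply(m, 2, function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 2) NA_real_ else sd(v) / sqrt(length(v))
  })
  tibble::tibble(species = species, growth_form = GROWTH_FORMS,
                 index_w = est, ci_lo = pmax(0, est - z * se),
                 ci_hi = est + z * se,
                 preferred = is.finite(est - z * se) & (est - z * se) > 1,
                 n_transects = length(occupied))
}
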