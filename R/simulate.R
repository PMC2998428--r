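#' Ground-truth parameters for one simulated species
#'
#' Encodes everything the generator needs to simulate one species: the
#' occupancy model coefficients on the logit scale (`alpha0` = coral-reef
#' baseline, `alpha1` = shift in algal meadow, `sigma_loc` = sd of the
#' location random intercept), the group-formation process (number of groups
#' per occupied transect is zero-truncated Poisson with rate `groups_rate`;
#' group sizes are shifted-geometric with mean `mean_group_size`), and the
#' electivity weights that tilt microhabitat and growth-form choice away from
#' availability (a weight of 1 everywhere means use follows availability).
#'
#' @param species species name.
#' @param alpha0 logit-scale intercept: occurrence probability on a coral-reef
#'   transect at an average location is `plogis(alpha0)`.
#' @param alpha1 logit-scale habitat effect; negative values mean rarer in
#'   algal meadows.
#' @param sigma_loc standard deviation (logit scale) of the per-location
#'   random intercept, `>= 0`.
#' @param mean_group_size mean individuals per group, `>= 1`.
#' @param groups_rate rate of the zero-truncated Poisson number of groups on
#'   an occupied transect.
#' @param electivity named non-negative weights over
#'   `r paste(MICROHABITATS, collapse = ", ")`; missing names default to 1.
#' @param gf_electivity named non-negative weights over the seven growth
#'   forms; missing names default to 1.
#' @return a `species_truth` list.
#' @export
species_truth <- function(species, alpha0 = 0, alpha1 = 0, sigma_loc = 0,
                          mean_group_size = 2, groups_rate = 1.5,
                          electivity = NULL, gf_electivity = NULL) {
  w <- setNames(rep(1, length(MICROHABITATS)), MICROHABITATS)
  if (!is.null(electivity)) w[names(electivity)] <- electivity
  gw <- setNames(rep(1, length(GROWTH_FORMS)), GROWTH_FORMS)
  if (!is.null(gf_electivity)) gw[names(gf_electivity)] <- gf_electivity
  stopifnot(all(w >= 0), all(gw >= 0), any(w > 0), any(gw > 0),
            sigma_loc >= 0, mean_group_size >= 1, groups_rate > 0)
  structure(list(species = species, alpha0 = alpha0, alpha1 = alpha1,
                 sigma_loc = sigma_loc, mean_group_size = mean_group_size,
                 groups_rate = groups_rate, electivity = w,
                 gf_electivity = gw),
            class = "species_truth")
}

#' Default survey design matching the Ningaloo study layout
#'
#' 18 coral-reef locations carrying 135 transects and 12 algal-meadow
#' locations carrying 79 transects (214 in total), with 3-9 transects per
#' location, allocated as evenly as those totals allow.
#'
#' @return a tibble with columns `location_id`, `habitat`, `n_transects`.
#' @export
default_survey_design <- function() {
  tibble::tibble(
    location_id = sprintf("L%02d", 1:30),
    habitat = rep(c("coral_reef", "algal_meadow"), c(18, 12)),
    # 135 = 9x8 + 9x7; 79 = 7x7 + 5x6 -- all within the 3-9 per-location range
    n_transects = c(rep(8L, 9), rep(7L, 9), rep(7L, 7), rep(6L, 5)))
}

#' Default benthic cover composition by habitat
#'
#' Mean cover fractions per habitat: coral reefs average 38% live coral and
#' 20% dead coral; algal meadows average 46% fleshy macroalgae with under 5%
#' live plus dead coral combined. The growth-form vector splits the live-coral
#' fraction among the seven morphologies.
#'
#' @return a list with elements `coral_reef`, `algal_meadow` (each a named
#'   fraction vector over microhabitats summing to 1) and `growth_forms`
#'   (fractions over growth forms summing to 1).
#' @export
default_cover_params <- function() {
  list(
    coral_reef = c(live_coral = 0.38, dead_coral = 0.20, macroalgae = 0.10,
                   rubble = 0.17, sand = 0.15),
    algal_meadow = c(live_coral = 0.02, dead_coral = 0.02, macroalgae = 0.46,
                     rubble = 0.20, sand = 0.30),
    growth_forms = c(branching = 0.25, corymbose = 0.20, encrusting = 0.10,
                     foliaceous = 0.05, massive = 0.15, plate = 0.15,
                     submassive = 0.10))
}

#' Configuration for the synthetic survey generator
#'
#' @param species a list of [species_truth()] objects.
#' @param design a survey design tibble as from [default_survey_design()]
#'   (columns `location_id`, `habitat`, `n_transects`).
#' @param cover cover composition as from [default_cover_params()].
#' @param concentration Dirichlet concentration of per-transect cover draws
#'   around the habitat means; lower values mean more between-transect
#'   variability. The default 4 reproduces the wide (roughly 10-80%) spread of
#'   live coral cover seen across real reef transects.
#' @param gf_concentration Dirichlet concentration for the growth-form split
#'   of live coral cover.
#' @param seed master integer seed; all draws are keyed on
#'   (seed, location, transect, species), so results are reproducible and
#'   adding a species leaves existing draws unchanged.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(species, design = default_survey_design(),
                              cover = default_cover_params(),
                              concentration = 4, gf_concentration = 10,
                              seed = 1) {
  stopifnot(is.list(species), length(species) > 0,
            all(vapply(species, inherits, logical(1), "species_truth")),
            all(design$n_transects >= 1),
            concentration > 0, gf_concentration > 0)
  for (h in HABITATS) {
    stopifnot(abs(sum(cover[[h]]) - 1) < 1e-8, all(cover[[h]] >= 0))
  }
  stopifnot(abs(sum(cover$growth_forms) - 1) < 1e-8)
  structure(list(species = species, design = tibble::as_tibble(design),
                 cover = cover, concentration = concentration,
                 gf_concentration = gf_concentration,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) <= 0) g <- alpha # degenerate safeguard, keeps proportions valid
  g / sum(g)
}

rztpois <- function(n, lambda) {
  qpois(runif(n, ppois(0, lambda), 1), lambda)
}

#' Generate a synthetic survey with a ground-truth record
#'
#' Simulates the full survey process: per-transect benthic cover is drawn from
#' a Dirichlet distribution around habitat-specific means; for each species a
#' location random intercept is drawn once per location from
#' `Normal(0, sigma_loc^2)`; presence on each transect is Bernoulli with
#' probability `plogis(alpha0 + alpha1 * x + lambda_l)` where `x` indicates
#' algal meadow; on presence, a zero-truncated Poisson number of groups is
#' placed, each with a shifted-geometric size, and each group's microhabitat
#' is drawn multinomially with probability proportional to (transect cover of
#' the category x the species' electivity weight); growth form is assigned the
#' same way within live coral.
#'
#' @param config a [simulation_config()].
#' @return a list with elements `table` (a [survey_table()]) and `truth` (the
#'   parameters used, realized location effects and the per-species,
#'   per-transect presence table).
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  seed <- config$seed
  design <- config$design
  tr <- design |>
    dplyr::rowwise() |>
    dplyr::reframe(location_id = .data$location_id, habitat = .data$habitat,
                   transect_id = sprintf("%s_T%d", .data$location_id,
                                         seq_len(.data$n_transects)))
  n_tr <- nrow(tr)

  covers <- matrix(0, n_tr, length(MICROHABITATS),
                   dimnames = list(NULL, MICROHABITATS))
  gf_covers <- matrix(0, n_tr, length(GROWTH_FORMS),
                      dimnames = list(NULL, paste0("gf_", GROWTH_FORMS)))
  for (i in seq_len(n_tr)) {
    mu <- config$cover[[tr$habitat[i]]][MICROHABITATS]
    p <- with_seed(derive_seed(seed, "cover", tr$transect_id[i]), {
      pm <- rdirichlet1(config$concentration * mu + 1e-8)
      pg <- rdirichlet1(config$gf_concentration * config$cover$growth_forms +
                          1e-8)
      list(pm, pg)
    })
    covers[i, ] <- 100 * p[[1]]
    gf_covers[i, ] <- covers[i, "live_coral"] * p[[2]]
  }
  transects <- dplyr::bind_cols(tr, tibble::as_tibble(covers),
                                tibble::as_tibble(gf_covers)) |>
    dplyr::select(dplyr::all_of(c("location_id", "transect_id", "habitat",
                                  MICROHABITATS,
                                  paste0("gf_", GROWTH_FORMS))))

  lambda_rows <- list()
  presence_rows <- list()
  obs_rows <- list()
  for (sp in config$species) {
    lam <- vapply(design$location_id, function(l) {
      with_seed(derive_seed(seed, "lambda", sp$species, l),
                rnorm(1, 0, sp$sigma_loc))
    }, numeric(1))
    lambda_rows[[sp$species]] <- tibble::tibble(
      species = sp$species, location_id = design$location_id, lambda = lam)
    x <- as.integer(tr$habitat == "algal_meadow")
    eta <- sp$alpha0 + sp$alpha1 * x + lam[tr$location_id]
    present <- vapply(seq_len(n_tr), function(i) {
      with_seed(derive_seed(seed, "presence", sp$species, tr$transect_id[i]),
                rbinom(1, 1, plogis(eta[i])))
    }, integer(1))
    presence_rows[[sp$species]] <- tibble::tibble(
      species = sp$species, transect_id = tr$transect_id,
      present = present == 1L)
    for (i in which(present == 1L)) {
      rows <- with_seed(
        derive_seed(seed, "groups", sp$species, tr$transect_id[i]), {
          n_groups <- rztpois(1, sp$groups_rate)
          sizes <- 1L + rgeom(n_groups, 1 / sp$mean_group_size)
          pm <- covers[i, ] * sp$electivity[MICROHABITATS]
          if (sum(pm) <= 0) {
            stop("electivity weights exclude every available microhabitat on transect ",
                 tr$transect_id[i], call. = FALSE)
          }
          micro <- sample(MICROHABITATS, n_groups, replace = TRUE,
                          prob = pm / sum(pm))
          gf <- rep("none", n_groups)
          on_live <- micro == "live_coral"
          if (any(on_live)) {
            pg <- gf_covers[i, ] * sp$gf_electivity[GROWTH_FORMS]
            if (sum(pg) <= 0) pg <- gf_covers[i, ]
            gf[on_live] <- sample(GROWTH_FORMS, sum(on_live), replace = TRUE,
                                  prob = pg / sum(pg))
          }
          list(i = i, species = sp$species, group_size = as.integer(sizes),
               microhabitat = micro, growth_form = gf)
        })
      obs_rows[[length(obs_rows) + 1]] <- rows
    }
  }
  obs <- if (length(obs_rows) > 0) {
    reps <- vapply(obs_rows, function(r) length(r$group_size), integer(1))
    idx <- rep(vapply(obs_rows, `[[`, integer(1), "i"), reps)
    tibble::tibble(
      location_id = tr$location_id[idx], transect_id = tr$transect_id[idx],
      habitat = tr$habitat[idx],
      species = rep(vapply(obs_rows, `[[`, character(1), "species"), reps),
      group_size = unlist(lapply(obs_rows, `[[`, "group_size")),
      microhabitat = unlist(lapply(obs_rows, `[[`, "microhabitat")),
      growth_form = unlist(lapply(obs_rows, `[[`, "growth_form")))
  } else {
    tibble::tibble(location_id = character(), transect_id = character(),
                   habitat = character(), species = character(),
                   group_size = integer(), microhabitat = character(),
                   growth_form = character())
  }
  table <- survey_table(obs, transects)
  truth <- list(species_params = config$species,
                lambda = dplyr::bind_rows(lambda_rows),
                presence = dplyr::bind_rows(presence_rows),
                config = config)
  list(table = table, truth = truth)
}

#' Deterministic miniature survey reproducing published census rows
#'
#' Builds a fixed six-transect coral-reef survey whose [summarize_species()]
#' output reproduces the published per-species counts for four species of the
#' Ningaloo census: *Chaetodon auriga* (6 individuals, 6 groups, 5 transects),
#' *Coris aygula* (6, 4, 4), *Dischistodus perspicillatus* (5, 4, 4) and
#' *Scolopsis bilineatus* (7, 7, 6). Identical on every call.
#'
#' @return a [survey_table()].
#' @export
table1_like_fixture <- function() {
  mk_tr <- function(id, loc) {
    tibble::tibble(
      location_id = loc, transect_id = id, habitat = "coral_reef",
      live_coral = 40, dead_coral = 20, macroalgae = 10, rubble = 15,
      sand = 15, gf_branching = 10, gf_corymbose = 10, gf_encrusting = 0,
      gf_foliaceous = 0, gf_massive = 0, gf_plate = 10, gf_submassive = 10)
  }
  transects <- dplyr::bind_rows(
    mk_tr("T1", "L1"), mk_tr("T2", "L1"), mk_tr("T3", "L1"),
    mk_tr("T4", "L2"), mk_tr("T5", "L2"), mk_tr("T6", "L2"))
  obs_spec <- list(
    list("Chaetodon auriga", c("T1", "T1", "T2", "T3", "T4", "T5"),
         c(1, 1, 1, 1, 1, 1), "live_coral", "corymbose"),
    list("Coris aygula", c("T1", "T2", "T3", "T4"),
         c(2, 2, 1, 1), "rubble", "none"),
    list("Dischistodus perspicillatus", c("T1", "T2", "T3", "T4"),
         c(2, 1, 1, 1), "dead_coral", "none"),
    list("Scolopsis bilineatus", c("T1", "T2", "T3", "T4", "T5", "T6", "T6"),
         c(1, 1, 1, 1, 1, 1, 1), "sand", "none"))
  obs <- purrr::map_dfr(obs_spec, function(s) {
    tibble::tibble(
      location_id = ifelse(s[[2]] %in% c("T1", "T2", "T3"), "L1", "L2"),
      transect_id = s[[2]], habitat = "coral_reef", species = s[[1]],
      group_size = as.integer(s[[3]]), microhabitat = s[[4]],
      growth_form = s[[5]])
  })
  meta <- table1_counts() |>
    dplyr::filter(.data$species %in% unique(obs$species)) |>
    dplyr::select("species", "family", "coral_associated_adult",
                  "algal_adult")
  survey_table(obs, transects, species_metadata = meta)
}
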