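# Shared fixtures and independent brute-force oracles. The oracles recount
# quantities with plain loops over raw observation rows, deliberately avoiding
# the package's dplyr code paths.

small_design <- function(n_loc = 6, n_tr = 4, habitat = NULL) {
  tibble::tibble(
    location_id = sprintf("L%02d", seq_len(n_loc)),
    habitat = if (is.null(habitat)) {
      rep(c("coral_reef", "algal_meadow"), length.out = n_loc)
    } else habitat,
    n_transects = as.integer(n_tr))
}

random_survey <- function(seed, n_species = 3, n_loc = 6, n_tr = 4) {
  sp <- withr::with_seed(seed, lapply(seq_len(n_species), function(i) {
    species_truth(sprintf("sp%02d", i),
                  alpha0 = runif(1, -0.5, 1.5), alpha1 = runif(1, -2, 2),
                  sigma_loc = runif(1, 0, 1),
                  mean_group_size = runif(1, 1, 5),
                  groups_rate = runif(1, 0.5, 3))
  }))
  generate_survey(simulation_config(sp, design = small_design(n_loc, n_tr),
                                    seed = seed))$table
}

# one row per species, counted with loops
oracle_summarize <- function(obs) {
  species <- sort(unique(obs$species))
  out <- data.frame(species = species, n_individuals = 0L, n_groups = 0L,
                    n_transects = 0L)
  for (k in seq_along(species)) {
    rows <- obs[obs$species == species[k], ]
    out$n_individuals[k] <- sum(rows$group_size)
    out$n_groups[k] <- nrow(rows)
    out$n_transects[k] <- length(unique(rows$transect_id))
  }
  out
}

oracle_use_pct <- function(obs, sp) {
  rows <- obs[obs$species == sp, ]
  ids <- sort(unique(rows$transect_id))
  out <- data.frame(transect_id = ids, pct_live = NA_real_,
                    pct_dead = NA_real_, pct_combined = NA_real_)
  for (k in seq_along(ids)) {
    r <- rows[rows$transect_id == ids[k], ]
    out$pct_live[k] <- 100 * sum(r$microhabitat == "live_coral") / nrow(r)
    out$pct_dead[k] <- 100 * sum(r$microhabitat == "dead_coral") / nrow(r)
    out$pct_combined[k] <- out$pct_live[k] + out$pct_dead[k]
  }
  out
}

# point selectivity indices (availability over total benthos), loop version
oracle_selectivity <- function(table, sp) {
  obs <- table$observations[table$observations$species == sp, ]
  live <- obs[obs$microhabitat == "live_coral", ]
  occupied <- unique(obs$transect_id)
  tr <- table$transects[table$transects$transect_id %in% occupied, ]
  out <- numeric(length(GROWTH_FORMS))
  names(out) <- GROWTH_FORMS
  for (gf in GROWTH_FORMS) {
    use <- sum(live$growth_form == gf) / nrow(live)
    avail <- mean(tr[[paste0("gf_", gf)]]) / 100
    out[gf] <- if (avail > 0) use / avail else if (use > 0) Inf else NA_real_
  }
  out
}

# a tiny hand-checkable survey: 2 locations x 2 transects, 2 species
toy_survey <- function() {
  transects <- tibble::tibble(
    location_id = c("L1", "L1", "L2", "L2"),
    transect_id = c("T1", "T2", "T3", "T4"),
    habitat = c("coral_reef", "coral_reef", "algal_meadow", "algal_meadow"),
    live_coral = c(40, 30, 5, 0), dead_coral = c(20, 25, 5, 0),
    macroalgae = c(10, 15, 60, 70), rubble = c(15, 15, 15, 15),
    sand = c(15, 15, 15, 15),
    gf_branching = c(10, 10, 5, 0), gf_corymbose = c(20, 10, 0, 0),
    gf_encrusting = c(0, 0, 0, 0), gf_foliaceous = c(0, 0, 0, 0),
    gf_massive = c(5, 5, 0, 0), gf_plate = c(5, 5, 0, 0),
    gf_submassive = c(0, 0, 0, 0))
  observations <- tibble::tibble(
    location_id = c("L1", "L1", "L1", "L2"),
    transect_id = c("T1", "T1", "T2", "T3"),
    habitat = c("coral_reef", "coral_reef", "coral_reef", "algal_meadow"),
    species = c("Chromis viridis", "Chromis viridis", "Scarus frenatus",
                "Scarus frenatus"),
    group_size = c(10L, 3L, 1L, 2L),
    microhabitat = c("live_coral", "dead_coral", "live_coral", "macroalgae"),
    growth_form = c("corymbose", "none", "branching", "none"))
  survey_table(observations, transects)
}

# build a synthetic occupancy_fit directly from chains, for the summary and
# diagnostic operations that act on draws alone
fake_fit <- function(p_coral, p_algal, species = "fake") {
  n <- length(p_coral)
  structure(list(
    draws = tibble::tibble(
      .iteration = seq_len(n), alpha0 = qlogis(p_coral),
      alpha1 = qlogis(p_algal) - qlogis(p_coral),
      sigma_loc = rep(0.5, n), p_coral = p_coral, p_algal = p_algal),
    lambda_draws = matrix(0, n, 1), acceptance = c(alpha0 = .4, alpha1 = .4),
    separability = character(), species = species, n_transects = 10,
    n_locations = 1,
    config = mcmc_config(n_burnin = 0, n_iter = max(1, n))),
    class = "occupancy_fit")
}

# direct construction of model data, bypassing survey assembly
make_occ_data <- function(y, x, loc) {
  locs <- sort(unique(loc))
  structure(list(y = as.integer(y), x = as.integer(x),
                 loc = match(loc, locs), locations = as.character(locs),
                 transect_id = sprintf("T%d", seq_along(y)), species = "sim"),
            class = "occupancy_data")
}
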