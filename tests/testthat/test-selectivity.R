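# a survey where use exactly mirrors availability: live coral is the whole
# benthos and group counts are proportional to growth-form covers
neutral_survey <- function(n_transects = 3) {
  tr <- purrr::map_dfr(seq_len(n_transects), function(i) tibble::tibble(
    location_id = "L1", transect_id = paste0("T", i), habitat = "coral_reef",
    live_coral = 100, dead_coral = 0, macroalgae = 0, rubble = 0, sand = 0,
    gf_branching = 40, gf_corymbose = 30, gf_encrusting = 10,
    gf_foliaceous = 0, gf_massive = 10, gf_plate = 10, gf_submassive = 0))
  obs <- purrr::map_dfr(seq_len(n_transects), function(i) {
    gf <- rep(c("branching", "corymbose", "encrusting", "massive", "plate"),
              times = c(4, 3, 1, 1, 1))
    tibble::tibble(location_id = "L1", transect_id = paste0("T", i),
                   habitat = "coral_reef", species = "sp", group_size = 1L,
                   microhabitat = "live_coral", growth_form = gf)
  })
  survey_table(obs, tr)
}

test_that("use identical to availability gives indices exactly 1, none preferred", {
  res <- selectivity_indices(neutral_survey(), "sp", n_boot = 200, seed = 3)
  used <- res[res$use_proportion > 0, ]
  expect_equal(used$index_w, rep(1, nrow(used)))
  expect_equal(used$ci_lo, rep(1, nrow(used)))
  expect_equal(used$ci_hi, rep(1, nrow(used)))
  expect_false(any(res$preferred))
})

test_that("the index is the use/availability ratio", {
  # one transect: corymbose availability 20% of benthos, use 60% of groups
  tr <- tibble::tibble(
    location_id = "L1", transect_id = "T1", habitat = "coral_reef",
    live_coral = 50, dead_coral = 10, macroalgae = 10, rubble = 15, sand = 15,
    gf_branching = 30, gf_corymbose = 20, gf_encrusting = 0,
    gf_foliaceous = 0, gf_massive = 0, gf_plate = 0, gf_submassive = 0)
  obs <- tibble::tibble(
    location_id = "L1", transect_id = "T1", habitat = "coral_reef",
    species = "sp", group_size = 1L, microhabitat = "live_coral",
    growth_form = rep(c("corymbose", "branching"), times = c(6, 4)))
  res <- selectivity_indices(survey_table(obs, tr), "sp", n_boot = 50)
  expect_equal(res$index_w[res$growth_form == "corymbose"], 0.6 / 0.2)
  expect_equal(res$index_w[res$growth_form == "branching"], 0.4 / 0.3)
})

test_that("selectivity point estimates match a brute-force recount", {
  for (seed in c(31, 32)) {
    tab <- random_survey(seed, n_loc = 10, n_tr = 6)
    sps <- unique(tab$observations$species[
      tab$observations$microhabitat == "live_coral"])
    for (sp in sps) {
      got <- suppressWarnings(selectivity_indices(tab, sp, n_boot = 20))
      want <- oracle_selectivity(tab, sp)
      expect_equal(got$index_w, unname(want[got$growth_form]))
      # proportions of use sum to 1; availability sums to the live fraction
      expect_equal(sum(got$use_proportion), 1)
      occ <- unique(tab$observations$transect_id[
        tab$observations$species == sp])
      live_frac <- mean(tab$transects$live_coral[
        tab$transects$transect_id %in% occ]) / 100
      expect_equal(sum(got$availability_proportion), live_frac)
      expect_lte(sum(got$availability_proportion), 1)
    }
  }
})

test_that("conditional availability satisfies the weighted identity", {
  # with availability conditional on live coral, sum_f avail_f * w_f = 1
  tab <- random_survey(33, n_loc = 10, n_tr = 6)
  sps <- unique(tab$observations$species[
    tab$observations$microhabitat == "live_coral"])
  for (sp in sps) {
    res <- suppressWarnings(
      selectivity_indices(tab, sp, availability = "live_conditional",
                          n_boot = 20))
    ok <- is.finite(res$index_w)
    expect_equal(sum(res$availability_proportion[ok] * res$index_w[ok]), 1)
    expect_equal(sum(res$availability_proportion), 1)
  }
})

test_that("indices are invariant to replicating every group", {
  tab <- random_survey(34, n_loc = 8, n_tr = 5)
  sp <- unique(tab$observations$species[
    tab$observations$microhabitat == "live_coral"])[1]
  r1 <- suppressWarnings(selectivity_indices(tab, sp, n_boot = 30, seed = 1))
  tab3 <- survey_table(
    tab$observations[rep(seq_len(nrow(tab$observations)), each = 3), ],
    tab$transects)
  r3 <- suppressWarnings(selectivity_indices(tab3, sp, n_boot = 30, seed = 1))
  expect_equal(r1$index_w, r3$index_w)
  expect_equal(r1$use_proportion, r3$use_proportion)
})

test_that("bootstrap intervals bracket the point index", {
  for (seed in c(35, 36)) {
    tab <- random_survey(seed, n_loc = 10, n_tr = 6)
    live_sp <- tab$observations$species[
      tab$observations$microhabitat == "live_coral"]
    sp <- names(which.max(table(live_sp)))
    res <- suppressWarnings(selectivity_indices(tab, sp, n_boot = 500,
                                                seed = 2))
    ok <- is.finite(res$index_w) & res$use_proportion > 0
    expect_true(all(res$ci_lo[ok] <= res$index_w[ok] + 1e-8))
    expect_true(all(res$ci_hi[ok] >= res$index_w[ok] - 1e-8))
  }
})

test_that("zero availability with nonzero use is reported as infinite", {
  tr <- tibble::tibble(
    location_id = "L1", transect_id = "T1", habitat = "coral_reef",
    live_coral = 40, dead_coral = 20, macroalgae = 10, rubble = 15, sand = 15,
    gf_branching = 40, gf_corymbose = 0, gf_encrusting = 0, gf_foliaceous = 0,
    gf_massive = 0, gf_plate = 0, gf_submassive = 0)
  obs <- tibble::tibble(
    location_id = "L1", transect_id = "T1", habitat = "coral_reef",
    species = "sp", group_size = 1L, microhabitat = "live_coral",
    growth_form = c("corymbose", "branching"))
  expect_warning(res <- selectivity_indices(survey_table(obs, tr), "sp",
                                            n_boot = 20),
                 "zero estimated availability")
  expect_true(is.infinite(res$index_w[res$growth_form == "corymbose"]))
})

test_that("species without live-coral groups are rejected", {
  tab <- toy_survey()
  obs <- tab$observations
  obs$microhabitat[obs$species == "Chromis viridis"] <- "rubble"
  obs$growth_form[obs$species == "Chromis viridis"] <- "none"
  t2 <- survey_table(obs, tab$transects)
  expect_error(selectivity_indices(t2, "Chromis viridis"), "live-coral")
  expect_error(selectivity_indices(tab, "Zebrasoma"), "not found")
})

test_that("the screen isolates failures and keeps 7 rows per species", {
  tab <- neutral_survey()
  res <- selectivity_screen(tab, c("sp", "ghost"), n_boot = 50)
  expect_equal(nrow(res), 14)
  expect_equal(unname(table(res$species)["ghost"]), 7L)
  expect_true(all(res$status[res$species == "ghost"] == "not_found"))
  expect_true(all(res$status[res$species == "sp"] == "ok"))
  empty <- selectivity_screen(tab, character())
  expect_equal(nrow(empty), 0)
})

test_that("ivlev difference-form electivity behaves at its extremes", {
  expect_equal(ivlev_electivity(1, 0), 1)
  expect_equal(ivlev_electivity(0, 0.5), -1)
  expect_equal(ivlev_electivity(0.3, 0.3), 0)
  expect_true(is.na(ivlev_electivity(0, 0)))
})
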