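test_that("write then read is the identity on valid survey tables", {
  for (seed in c(1, 2, 3)) {
    tab <- random_survey(seed)
    d <- withr::local_tempdir()
    op <- file.path(d, "obs.csv")
    tp <- file.path(d, "tr.csv")
    write_survey(tab, op, tp)
    back <- read_survey(op, tp)
    expect_equal(back$observations, tab$observations)
    expect_equal(back$transects, tab$transects, tolerance = 1e-9)
  }
})

test_that("writing the same table twice is byte-stable", {
  tab <- random_survey(1)
  d <- withr::local_tempdir()
  write_survey(tab, file.path(d, "o1.csv"), file.path(d, "t1.csv"))
  write_survey(tab, file.path(d, "o2.csv"), file.path(d, "t2.csv"))
  expect_identical(readBin(file.path(d, "o1.csv"), "raw", 1e6),
                   readBin(file.path(d, "o2.csv"), "raw", 1e6))
  expect_identical(readBin(file.path(d, "t1.csv"), "raw", 1e6),
                   readBin(file.path(d, "t2.csv"), "raw", 1e6))
})

test_that("an empty observation table still round-trips", {
  tab <- toy_survey()
  tab$observations <- tab$observations[0, ]
  d <- withr::local_tempdir()
  op <- file.path(d, "obs.csv")
  tp <- file.path(d, "tr.csv")
  write_survey(tab, op, tp)
  back <- read_survey(op, tp)
  expect_equal(nrow(back$observations), 0)
  expect_equal(nrow(back$transects), 4)
})

test_that("schema and enum errors are reported with context", {
  tab <- toy_survey()
  d <- withr::local_tempdir()
  op <- file.path(d, "obs.csv")
  tp <- file.path(d, "tr.csv")
  write_survey(tab, op, tp)

  # unknown microhabitat value, row cited
  bad <- readLines(op)
  bad[2] <- sub("live_coral", "coral", bad[2])
  bp <- file.path(d, "bad_obs.csv")
  writeLines(bad, bp)
  expect_error(read_survey(bp, tp), "microhabitat.*'coral'.*row 1")

  # missing column named in the error
  obs2 <- tab$observations
  names(obs2)[names(obs2) == "group_size"] <- "size"
  readr::write_csv(obs2, bp)
  expect_error(read_survey(bp, tp), "group_size")

  # orphan transect reference
  obs3 <- tab$observations
  obs3$transect_id[1] <- "T99"
  readr::write_csv(obs3, bp)
  expect_error(read_survey(bp, tp), "T99")
})

test_that("enums parse case-insensitively to canonical values", {
  tab <- toy_survey()
  d <- withr::local_tempdir()
  op <- file.path(d, "obs.csv")
  tp <- file.path(d, "tr.csv")
  write_survey(tab, op, tp)
  txt <- readLines(op)
  txt[2] <- sub("live_coral", "Live_Coral", sub("coral_reef", "CORAL_REEF",
                                                txt[2]))
  writeLines(txt, op)
  back <- read_survey(op, tp)
  expect_identical(back$observations$habitat[1], "coral_reef")
  expect_identical(back$observations$microhabitat[1], "live_coral")
})

test_that("validation rejects broken invariants", {
  tab <- toy_survey()
  t2 <- tab
  t2$observations$group_size[1] <- 0L
  expect_error(validate_survey(t2), "group_size")
  t3 <- tab
  t3$observations$growth_form[2] <- "plate" # dead coral group with a form
  expect_error(validate_survey(t3), "growth_form")
  t4 <- tab
  t4$transects$live_coral[1] <- 90 # cover sum blown
  expect_error(validate_survey(t4), "cover sums")
  t5 <- tab
  t5$transects$gf_corymbose[1] <- 35 # growth forms exceed live cover
  expect_error(validate_survey(t5), "growth-form covers")
  t6 <- tab
  t6$observations$habitat[4] <- "coral_reef" # disagrees with its transect
  expect_error(validate_survey(t6), "habitat disagrees")
})

test_that("summarize_species matches a brute-force recount", {
  for (seed in c(4, 5, 6)) {
    tab <- random_survey(seed)
    got <- summarize_species(tab)
    want <- oracle_summarize(tab$observations)
    got <- got[order(got$species), ]
    expect_equal(got$species, want$species)
    expect_equal(got$n_individuals, want$n_individuals)
    expect_equal(got$n_groups, want$n_groups)
    expect_equal(got$n_transects, want$n_transects)
    # conservation: individuals never lost or invented
    expect_equal(sum(got$n_individuals), sum(tab$observations$group_size))
  }
  expect_equal(nrow(summarize_species(
    survey_table(toy_survey()$observations[0, ], toy_survey()$transects))), 0)
})

test_that("published census counts are reproduced from the packaged table", {
  t1 <- table1_counts()
  cv <- t1[t1$species == "Chromis viridis", ]
  expect_equal(cv$individuals, 447L)
  expect_equal(cv$groups, 29L)
  expect_equal(cv$transects, 22L)
  expect_true(all(t1$groups <= t1$individuals))
  expect_true(all(t1$transects <= t1$groups))
})

test_that("the minimum-individuals filter is inclusive, monotone and idempotent", {
  t1 <- table1_counts() |>
    dplyr::rename(n_individuals = individuals, n_groups = groups,
                  n_transects = transects)
  expect_equal(nrow(filter_min_individuals(t1, 5)), 56)
  expect_equal(nrow(filter_min_individuals(t1, 1000)), 0)
  # oracle scan at threshold 400
  expect_equal(sort(filter_min_individuals(t1, 400)$species),
               sort(t1$species[t1$n_individuals >= 400]))
  # boundary inclusive
  expect_true("Dischistodus perspicillatus" %in%
                filter_min_individuals(t1, 5)$species) # exactly 5 individuals
  # monotone: higher threshold always yields a subset
  prev <- filter_min_individuals(t1, 1)$species
  for (thr in c(5, 20, 100, 400)) {
    cur <- filter_min_individuals(t1, thr)$species
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  # idempotent
  f5 <- filter_min_individuals(t1, 5)
  expect_equal(filter_min_individuals(f5, 5), f5)
  expect_error(filter_min_individuals(t1, 0), "min_individuals")
})

test_that("growth-form eligibility intersects preference with the transect rule", {
  summaries <- tibble::tibble(
    family = NA_character_,
    species = c("a", "b", "c", "d"),
    n_individuals = c(50L, 50L, 50L, 50L),
    n_groups = c(30L, 30L, 30L, 30L),
    n_transects = c(12L, 5L, 20L, 15L))
  # boundary: exactly 12 transects is eligible
  expect_equal(eligible_growth_form_species(summaries, c("a", "b", "c")),
               c("a", "c"))
  expect_equal(eligible_growth_form_species(summaries, character()),
               character())
  # planted truth: 3 preferrers, one on too few transects
  expect_length(eligible_growth_form_species(summaries, c("a", "b", "d")), 2)
})
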