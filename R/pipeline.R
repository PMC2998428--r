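#' Configuration for the full habitat-association pipeline
#'
#' Exactly one of `survey` (observed data) or `simulation` (a
#' [simulation_config()]) must be supplied.
#'
#' @param survey a [survey_table()], or `NULL`.
#' @param simulation a [simulation_config()], or `NULL`.
#' @param min_individuals inclusion threshold for the habitat and coral
#'   analyses (default 5, inclusive).
#' @param min_transects inclusion threshold for the growth-form analysis
#'   (default 12, inclusive; applied together with a live-coral preference).
#' @param mcmc an [mcmc_config()] for the occupancy stage.
#' @param run_occupancy set `FALSE` to skip the MCMC stage (the species
#'   summary and preference stages still run).
#' @param n_boot bootstrap resamples for selectivity CIs.
#' @param seed master seed; each stage derives its own sub-seed from it, so
#'   changing e.g. only the MCMC behaviour never perturbs the deterministic
#'   summary stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(survey = NULL, simulation = NULL,
                            min_individuals = 5, min_transects = 12,
                            mcmc = mcmc_config(), run_occupancy = TRUE,
                            n_boot = 2000, seed = 1) {
  if (is.null(survey) == is.null(simulation)) {
    stop("supply exactly one of 'survey' or 'simulation'", call. = FALSE)
  }
  stopifnot(min_individuals >= 1, min_transects >= 1, n_boot >= 1)
  structure(list(survey = survey, simulation = simulation,
                 min_individuals = min_individuals,
                 min_transects = min_transects, mcmc = mcmc,
                 run_occupancy = isTRUE(run_occupancy),
                 n_boot = n_boot, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full habitat-association analysis
#'
#' Stages, with the study's gating between them:
#' \enumerate{
#'   \item ingest the survey (or generate one from the simulation config);
#'   \item per-species census summary; species with fewer than
#'     `min_individuals` individuals are dropped from further analysis;
#'   \item occupancy: Bayesian hierarchical logistic fit per retained species,
#'     habitat probabilities and CI-overlap classification;
#'   \item coral preference: live/dead/combined use vs availability;
#'   \item growth-form selectivity, only for species that prefer live coral
#'     and occur on at least `min_transects` transects.
#' }
#' Identical `(config, seed)` yields an identical report.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `pipeline_report`: tibbles `species_summary`,
#'   `occupancy`, `preference`, `selectivity`, plus `survey`, `truth` (if
#'   simulated), fits, per-stage `stage_status` (a failed stage yields a
#'   partial report with its error message recorded) and run metadata.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  if (!is.null(config$simulation)) {
    sim <- generate_survey(config$simulation)
    survey <- sim$table
    truth <- sim$truth
  } else {
    survey <- config$survey
    truth <- NULL
  }
  validate_survey(survey)

  summary_all <- summarize_species(survey)
  retained <- filter_min_individuals(summary_all, config$min_individuals)
  status <- list(summary = "ok", occupancy = "skipped", preference = "skipped",
                 selectivity = "skipped")

  occupancy <- NULL
  fits <- list()
  if (config$run_occupancy && nrow(retained) > 0) {
    mcmc <- config$mcmc
    occupancy <- tryCatch(
      purrr::map_dfr(retained$species, function(sp) {
        cfg <- mcmc
        cfg$seed <- derive_seed(config$seed, "occupancy", sp, mcmc$seed)
        fit <- withCallingHandlers(
          fit_occupancy(occupancy_data(survey, sp), cfg),
          warning = function(w) invokeRestart("muffleWarning"))
        fits[[sp]] <<- fit
        p <- posterior_habitat_probabilities(fit)
        coral <- p[p$habitat == "coral_reef", ]
        algal <- p[p$habitat == "algal_meadow", ]
        tibble::tibble(species = sp,
                       p_coral_mean = coral$mean, p_coral_lo = coral$lower,
                       p_coral_hi = coral$upper,
                       p_algal_mean = algal$mean, p_algal_lo = algal$lower,
                       p_algal_hi = algal$upper,
                       classification = classify_habitat_difference(fit),
                       separable = length(fit$separability) > 0)
      }),
      error = function(e) {
        status$occupancy <<- paste("failed:", conditionMessage(e))
        NULL
      })
    if (!is.null(occupancy)) status$occupancy <- "ok"
  }

  preference <- NULL
  if (nrow(retained) > 0) {
    preference <- tryCatch(
      withCallingHandlers(
        preference_screen(survey, retained$species, n_boot = config$n_boot,
                          seed = derive_seed(config$seed, "preference")),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) {
        status$preference <<- paste("failed:", conditionMessage(e))
        NULL
      })
    if (!is.null(preference)) status$preference <- "ok"
  }

  selectivity <- NULL
  if (!is.null(preference) && nrow(preference) > 0) {
    preferrers <- preference$species[preference$prefers_live]
    eligible <- eligible_growth_form_species(retained, preferrers,
                                             config$min_transects)
    selectivity <- tryCatch(
      withCallingHandlers(
        selectivity_screen(survey, eligible, n_boot = config$n_boot,
                           seed = derive_seed(config$seed, "selectivity")),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) {
        status$selectivity <<- paste("failed:", conditionMessage(e))
        NULL
      })
    if (!is.null(selectivity)) status$selectivity <- "ok"
  }

  structure(list(
    species_summary = summary_all, retained_species = retained$species,
    occupancy = occupancy, preference = preference,
    selectivity = selectivity, survey = survey, truth = truth, fits = fits,
    stage_status = status,
    metadata = list(
      package_version = as.character(utils::packageVersion("reefuse")),
      seed = config$seed, min_individuals = config$min_individuals,
      min_transects = config$min_transects,
      n_burnin = config$mcmc$n_burnin, n_iter = config$mcmc$n_iter,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))),
    class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  cat(sprintf("  %d species summarised, %d retained (>= %d individuals)\n",
              nrow(x$species_summary), length(x$retained_species),
              x$metadata$min_individuals))
  if (!is.null(x$occupancy)) {
    cat(sprintf("  occupancy: %d fits (%d coral_greater, %d algal_greater)\n",
                nrow(x$occupancy),
                sum(x$occupancy$classification == "coral_greater"),
                sum(x$occupancy$classification == "algal_greater")))
  }
  if (!is.null(x$preference)) {
    cat(sprintf("  preference: %d live-coral, %d dead-coral, %d structure preferrers\n",
                sum(x$preference$prefers_live),
                sum(x$preference$prefers_dead),
                sum(x$preference$prefers_structure)))
  }
  if (!is.null(x$selectivity)) {
    cat(sprintf("  selectivity: %d species screened, %d preferred form flags\n",
                dplyr::n_distinct(x$selectivity$species),
                sum(x$selectivity$preferred, na.rm = TRUE)))
  }
  invisible(x)
}

#' Write a pipeline report to disk
#'
#' Emits the four result tables as comma-delimited files with stable names
#' (`species_summary.csv`, `occupancy.csv`, `preference.csv`,
#' `selectivity.csv`; absent stages yield header-only files) plus a plain-text
#' `summary.txt`. Re-rendering the same report produces byte-identical files.
#'
#' @param report a [run_pipeline()] result.
#' @param out_dir output directory (created if missing).
#' @return the paths written, invisibly.
#' @export
render_report <- function(report, out_dir) {
  stopifnot(inherits(report, "pipeline_report"))
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  empty <- list(
    species_summary = summarize_species(
      survey_table(report$survey$observations[0, ], report$survey$transects,
                   validate = FALSE)),
    occupancy = tibble::tibble(
      species = character(), p_coral_mean = numeric(),
      p_coral_lo = numeric(), p_coral_hi = numeric(),
      p_algal_mean = numeric(), p_algal_lo = numeric(),
      p_algal_hi = numeric(), classification = character(),
      separable = logical()),
    preference = species_preference(table1_like_fixture(),
                                    "Chaetodon auriga")[0, ],
    selectivity = selectivity_screen(table1_like_fixture(), character()))
  paths <- character()
  for (nm in names(empty)) {
    tab <- report[[nm]]
    if (is.null(tab)) tab <- empty[[nm]]
    num_fmt <- function(df) {
      dplyr::mutate(df, dplyr::across(
        dplyr::where(is.numeric),
        ~ sub("\\.?0+$", "", sprintf("%.10f", .x))))
    }
    p <- file.path(out_dir, paste0(nm, ".csv"))
    readr::write_csv(num_fmt(tab), p, progress = FALSE, na = "")
    paths <- c(paths, p)
  }
  txt <- c(
    "Habitat-association analysis report",
    sprintf("package reefuse %s, seed %d", report$metadata$package_version,
            report$metadata$seed),
    sprintf("species summarised: %d; retained (>= %d individuals): %d",
            nrow(report$species_summary), report$metadata$min_individuals,
            length(report$retained_species)),
    if (!is.null(report$occupancy)) sprintf(
      "occupancy fits: %d (burn-in %d + %d iterations each)",
      nrow(report$occupancy), report$metadata$n_burnin,
      report$metadata$n_iter),
    if (!is.null(report$preference)) sprintf(
      "live-coral preferrers: %d of %d tested",
      sum(report$preference$prefers_live), nrow(report$preference)),
    if (!is.null(report$selectivity)) sprintf(
      "growth-form screen: %d species, %d preferred-form flags",
      dplyr::n_distinct(report$selectivity$species),
      sum(report$selectivity$preferred, na.rm = TRUE)))
  sp <- file.path(out_dir, "summary.txt")
  writeLines(txt, sp)
  invisible(c(paths, sp))
}
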