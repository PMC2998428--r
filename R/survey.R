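#' Construct a survey table from observation and transect data frames
#'
#' A survey table couples two tibbles: `observations`, one row per group of
#' conspecific juveniles seen on a transect (a solitary fish is a group of
#' one), and `transects`, one row per 30 x 1 m belt transect with its habitat
#' class and percent benthic cover by microhabitat category and coral growth
#' form. Optional per-species metadata (family, adult habitat flags) may be
#' attached.
#'
#' @param observations data frame with columns `location_id`, `transect_id`,
#'   `habitat`, `species`, `group_size`, `microhabitat`, `growth_form`.
#' @param transects data frame with columns `location_id`, `transect_id`,
#'   `habitat`, one column per microhabitat category
#'   (`r paste(MICROHABITATS, collapse = ", ")`) and one `gf_`-prefixed column
#'   per growth form, all percents in \[0, 100\].
#' @param species_metadata optional data frame with columns `species`,
#'   `family` and logical flags `coral_associated_adult`, `algal_adult`.
#' @param validate if `TRUE` (default) check all structural invariants.
#' @return an object of class `survey_table`.
#' @export
survey_table <- function(observations, transects, species_metadata = NULL,
                         validate = TRUE) {
  obs <- tibble::as_tibble(observations)
  tr <- tibble::as_tibble(transects)
  out <- structure(
    list(observations = obs, transects = tr,
         species_metadata = if (!is.null(species_metadata))
           tibble::as_tibble(species_metadata)),
    class = "survey_table")
  if (validate) validate_survey(out)
  out
}

#' Validate the structural invariants of a survey table
#'
#' Checks: group sizes are positive integers; microhabitat and growth-form
#' values are legal and growth form is `"none"` exactly when the group is not
#' on live coral; covers are non-negative, sum to 100 within a 1 percentage
#' point tolerance, and growth-form covers sum to the live-coral cover within
#' the same tolerance; transect ids are unique; every observation references
#' an existing transect and agrees with it on habitat.
#'
#' @param table a [survey_table()].
#' @return `table`, invisibly; stops with an informative error otherwise.
#' @export
validate_survey <- function(table) {
  obs <- table$observations
  tr <- table$transects
  obs_cols <- c("location_id", "transect_id", "habitat", "species",
                "group_size", "microhabitat", "growth_form")
  missing_obs <- setdiff(obs_cols, names(obs))
  if (length(missing_obs) > 0) {
    stop("observations: missing column(s): ",
         paste(missing_obs, collapse = ", "), call. = FALSE)
  }
  tr_cols <- c("location_id", "transect_id", "habitat", MICROHABITATS,
               paste0("gf_", GROWTH_FORMS))
  missing_tr <- setdiff(tr_cols, names(tr))
  if (length(missing_tr) > 0) {
    stop("transects: missing column(s): ",
         paste(missing_tr, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(tr$transect_id) > 0) {
    stop("transects: duplicated transect_id ",
         tr$transect_id[anyDuplicated(tr$transect_id)], call. = FALSE)
  }
  if (nrow(obs) > 0) {
    if (any(obs$group_size < 1 | obs$group_size != floor(obs$group_size))) {
      stop("observations: group_size must be an integer >= 1", call. = FALSE)
    }
    bad_gf <- (obs$microhabitat == "live_coral") != (obs$growth_form != "none")
    if (any(bad_gf)) {
      stop(sprintf(
        "observations: growth_form must be 'none' iff microhabitat is not live_coral (row %d)",
        which(bad_gf)[1]), call. = FALSE)
    }
    orphan <- !obs$transect_id %in% tr$transect_id
    if (any(orphan)) {
      stop(sprintf(
        "observations: transect_id '%s' (row %d) not present in transects table",
        obs$transect_id[which(orphan)[1]], which(orphan)[1]), call. = FALSE)
    }
    hab_tr <- tr$habitat[match(obs$transect_id, tr$transect_id)]
    if (any(obs$habitat != hab_tr)) {
      stop(sprintf(
        "observations: habitat disagrees with transect table (row %d)",
        which(obs$habitat != hab_tr)[1]), call. = FALSE)
    }
  }
  covers <- as.matrix(tr[, MICROHABITATS])
  gf_covers <- as.matrix(tr[, paste0("gf_", GROWTH_FORMS)])
  if (any(covers < 0) || any(gf_covers < 0)) {
    stop("transects: cover percents must be >= 0", call. = FALSE)
  }
  tot <- rowSums(covers)
  if (any(abs(tot - 100) > COVER_TOL)) {
    stop(sprintf("transects: cover sums to %.2f on transect '%s' (must be 100 +/- %.1f)",
                 tot[which(abs(tot - 100) > COVER_TOL)[1]],
                 tr$transect_id[which(abs(tot - 100) > COVER_TOL)[1]],
                 COVER_TOL), call. = FALSE)
  }
  gf_tot <- rowSums(gf_covers)
  off <- abs(gf_tot - tr$live_coral) > COVER_TOL
  if (any(off)) {
    stop(sprintf(
      "transects: growth-form covers sum to %.2f but live_coral is %.2f on transect '%s'",
      gf_tot[which(off)[1]], tr$live_coral[which(off)[1]],
      tr$transect_id[which(off)[1]]), call. = FALSE)
  }
  invisible(table)
}

#' @export
print.survey_table <- function(x, ...) {
  cat("<survey_table>\n")
  cat(sprintf("  %d transects (%d coral_reef, %d algal_meadow) at %d locations\n",
              nrow(x$transects),
              sum(x$transects$habitat == "coral_reef"),
              sum(x$transects$habitat == "algal_meadow"),
              dplyr::n_distinct(x$transects$location_id)))
  cat(sprintf("  %d fish-group observations, %d species, %d individuals\n",
              nrow(x$observations),
              dplyr::n_distinct(x$observations$species),
              sum(x$observations$group_size)))
  invisible(x)
}

#' Read a survey from delimited observation and transect files
#'
#' Files are comma-delimited by default; tab-delimited files are detected from
#' the header line. Enum columns (`habitat`, `microhabitat`, `growth_form`)
#' are parsed case-insensitively to canonical lower-snake values; a blank
#' growth form is read as `"none"`. Row order is preserved.
#'
#' @param observations_path,transects_path paths to the two delimited files.
#' @return a validated [survey_table()].
#' @seealso [write_survey()] for the inverse operation.
#' @export
read_survey <- function(observations_path, transects_path) {
  obs <- read_delimited(observations_path)
  tr <- read_delimited(transects_path)
  obs_cols <- c("location_id", "transect_id", "habitat", "species",
                "group_size", "microhabitat", "growth_form")
  miss <- setdiff(obs_cols, names(obs))
  if (length(miss) > 0) {
    stop("observations file: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  tr_cols <- c("location_id", "transect_id", "habitat", MICROHABITATS,
               paste0("gf_", GROWTH_FORMS))
  miss <- setdiff(tr_cols, names(tr))
  if (length(miss) > 0) {
    stop("transects file: missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  obs <- obs |>
    dplyr::mutate(
      location_id = as.character(.data$location_id),
      transect_id = as.character(.data$transect_id),
      habitat = parse_enum(.data$habitat, HABITATS, "habitat"),
      species = as.character(.data$species),
      group_size = as.integer(.data$group_size),
      microhabitat = parse_enum(.data$microhabitat, MICROHABITATS,
                                "microhabitat"),
      growth_form = parse_enum(.data$growth_form, c(GROWTH_FORMS, "none"),
                               "growth_form", allow_blank = TRUE)) |>
    dplyr::select(dplyr::all_of(obs_cols))
  tr <- tr |>
    dplyr::mutate(
      location_id = as.character(.data$location_id),
      transect_id = as.character(.data$transect_id),
      habitat = parse_enum(.data$habitat, HABITATS, "habitat"),
      dplyr::across(dplyr::all_of(c(MICROHABITATS, paste0("gf_", GROWTH_FORMS))),
                    as.numeric)) |>
    dplyr::select(dplyr::all_of(tr_cols))
  survey_table(obs, tr)
}

read_delimited <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1)
  delim <- if (grepl("\t", header)) "\t" else ","
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE, trim_ws = TRUE,
                    col_types = readr::cols(.default = readr::col_character()))
}

#' Write a survey table to delimited files
#'
#' Output is comma-delimited and re-readable by [read_survey()], giving a
#' round-trip identity; writing the same table twice produces byte-identical
#' files. Cover percents are written with full precision.
#'
#' @param table a valid [survey_table()].
#' @param observations_path,transects_path output file paths.
#' @return `table`, invisibly.
#' @export
write_survey <- function(table, observations_path, transects_path) {
  validate_survey(table)
  for (p in c(observations_path, transects_path)) {
    d <- dirname(p)
    if (!dir.exists(d)) stop("cannot write to missing directory: ", d,
                             call. = FALSE)
  }
  fmt <- function(df) {
    df |> dplyr::mutate(dplyr::across(
      dplyr::where(is.numeric),
      ~ sub("\\.?0+$", "", sprintf("%.10f", .x))))
  }
  readr::write_csv(fmt(table$observations), observations_path, progress = FALSE)
  readr::write_csv(fmt(table$transects), transects_path, progress = FALSE)
  invisible(table)
}
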