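#' Assemble presence/absence data for one species from a survey
#'
#' Builds the model data for the habitat occupancy model: a binary presence
#' indicator per transect (1 if at least one group of the species was recorded
#' there), a habitat dummy (0 = coral reef, 1 = algal meadow) and a location
#' index.
#'
#' @param table a [survey_table()].
#' @param species species name; must have at least one transect in the table
#'   (species entirely absent everywhere are still valid: `y` is all zero).
#' @return a list of class `occupancy_data` with elements `y`, `x`, `loc`
#'   (integer index 1..L), `locations` (level names), `transect_id`, `species`.
#' @export
occupancy_data <- function(table, species) {
  tr <- table$transects
  seen <- unique(table$observations$transect_id[
    table$observations$species == species])
  y <- as.integer(tr$transect_id %in% seen)
  x <- as.integer(tr$habitat == "algal_meadow")
  locs <- sort(unique(tr$location_id))
  structure(list(y = y, x = x, loc = match(tr$location_id, locs),
                 locations = locs, transect_id = tr$transect_id,
                 species = species),
            class = "occupancy_data")
}

#' MCMC settings for the occupancy model
#'
#' @param n_burnin adaptation/burn-in iterations, discarded (default 1000).
#' @param n_iter retained iterations (default 10000).
#' @param prior_sd_alpha prior standard deviation of the `Normal(0, sd^2)`
#'   priors on both regression coefficients. The default `sqrt(1000)` (about
#'   31.6) makes the priors effectively non-informative on the logit scale.
#' @param prior_sd_sigma scale of the half-Normal hyperprior on the location
#'   random-effect standard deviation (default 2).
#' @param sigma_loc_fixed optionally fix the random-effect sd to a constant
#'   (use 0 to drop the random effect entirely); `NULL` (default) estimates it.
#' @param init_scales named initial random-walk proposal sds for blocks
#'   `alpha0`, `alpha1`, `lambda`, `log_sigma`; scales adapt toward a 0.44
#'   acceptance rate during burn-in only and are frozen afterwards.
#' @param seed integer RNG seed for the sampler.
#' @return an `mcmc_config` list.
#' @export
mcmc_config <- function(n_burnin = 1000, n_iter = 10000,
                        prior_sd_alpha = sqrt(1000), prior_sd_sigma = 2,
                        sigma_loc_fixed = NULL,
                        init_scales = c(alpha0 = 0.5, alpha1 = 0.5,
                                        lambda = 0.5, log_sigma = 0.5),
                        seed = 1) {
  stopifnot(n_burnin >= 0, n_iter > 0, prior_sd_alpha > 0, prior_sd_sigma > 0,
            all(init_scales > 0))
  structure(list(n_burnin = as.integer(n_burnin), n_iter = as.integer(n_iter),
                 prior_sd_alpha = prior_sd_alpha,
                 prior_sd_sigma = prior_sd_sigma,
                 sigma_loc_fixed = sigma_loc_fixed,
                 init_scales = init_scales, seed = as.integer(seed)),
            class = "mcmc_config")
}

# Bernoulli log likelihood on the logit scale, overflow-safe.
bernoulli_loglik <- function(y, eta) {
  sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
}

# Per-location Bernoulli log likelihood (vector over locations).
bernoulli_loglik_by <- function(y, eta, loc, L) {
  ll <- y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta))))
  as.vector(rowsum(ll, loc, reorder = TRUE))
}

#' Fit the Bayesian hierarchical logistic occupancy model
#'
#' Models transect-level presence of one species as
#' `y_i ~ Bernoulli(p_i)`, `logit(p_i) = alpha0 + alpha1 * x_i + lambda_{l(i)}`
#' with `x_i` the algal-meadow indicator and `lambda_l ~ Normal(0, sigma_loc^2)`
#' a per-location random intercept. Coefficients get flat-ish
#' `Normal(0, 1000)` priors; `sigma_loc` gets a half-Normal(0, 2) hyperprior
#' unless fixed. Sampling is single-chain random-walk Metropolis-within-Gibbs
#' over blocks (alpha0 | alpha1 | all lambda jointly per location | log
#' sigma_loc), with proposal scales adapted toward 0.44 acceptance during
#' burn-in and frozen for the retained draws, preserving detailed balance.
#'
#' If the species was never (or always) seen in one of the habitats the data
#' are separable for that habitat and the posterior there is dominated by the
#' prior; the fit proceeds and the condition is recorded in
#' `fit$separability` (with a one-time warning).
#'
#' @param data an [occupancy_data()] object.
#' @param config an [mcmc_config()].
#' @return an object of class `occupancy_fit`: retained draws of `alpha0`,
#'   `alpha1`, `sigma_loc`, the derived per-habitat occurrence probabilities
#'   `p_coral = plogis(alpha0)` and `p_algal = plogis(alpha0 + alpha1)`, the
#'   lambda draws, per-block acceptance rates and frozen proposal scales.
#' @examples
#' sim <- generate_survey(simulation_config(
#'   list(species_truth("sp", alpha0 = 0.5, alpha1 = -2)), seed = 42))
#' fit <- fit_occupancy(occupancy_data(sim$table, "sp"),
#'                      mcmc_config(n_burnin = 200, n_iter = 500, seed = 1))
#' tidy(fit)
#' @export
fit_occupancy <- function(data, config = mcmc_config()) {
  stopifnot(inherits(data, "occupancy_data"))
  y <- data$y
  x <- data$x
  loc <- data$loc
  n <- length(y)
  if (n == 0) stop("no transects in data", call. = FALSE)
  L <- length(data$locations)

  separability <- character()
  for (h in c(0, 1)) {
    hname <- if (h == 0) "coral_reef" else "algal_meadow"
    yh <- y[x == h]
    if (length(yh) == 0) {
      separability <- c(separability, paste0(hname, ": no transects"))
    } else if (all(yh == 0)) {
      separability <- c(separability, paste0(hname, ": never present"))
    } else if (all(yh == 1)) {
      separability <- c(separability, paste0(hname, ": always present"))
    }
  }
  if (length(separability) > 0) {
    warning("separable data for '", data$species, "' (",
            paste(separability, collapse = "; "),
            "): posterior partly prior-driven", call. = FALSE)
  }

  fixed_sigma <- config$sigma_loc_fixed
  sample_re <- is.null(fixed_sigma) || fixed_sigma > 0
  sample_sigma <- is.null(fixed_sigma)

  with_seed(config$seed, {
    a0 <- 0; a1 <- 0
    lambda <- rep(0, L)
    sigma <- if (sample_sigma) 0.5 else fixed_sigma
    eta <- a0 + a1 * x + lambda[loc]
    ll <- bernoulli_loglik(y, eta)
    scales <- config$init_scales
    lambda_scales <- rep(scales[["lambda"]], L)

    n_total <- config$n_burnin + config$n_iter
    keep <- matrix(NA_real_, config$n_iter, 3,
                   dimnames = list(NULL, c("alpha0", "alpha1", "sigma_loc")))
    keep_lambda <- matrix(NA_real_, config$n_iter, L,
                          dimnames = list(NULL, data$locations))
    acc <- c(alpha0 = 0, alpha1 = 0, lambda = 0, log_sigma = 0)
    acc_batch <- c(alpha0 = 0, alpha1 = 0, log_sigma = 0)
    acc_batch_lambda <- rep(0, L)
    batch_len <- 50
    psd2 <- config$prior_sd_alpha^2

    for (it in seq_len(n_total)) {
      in_burnin <- it <= config$n_burnin
      retained <- !in_burnin

      # alpha0 block: a shift d moves every eta by d
      d <- rnorm(1, 0, scales[["alpha0"]])
      eta_new <- eta + d
      ll_new <- bernoulli_loglik(y, eta_new)
      lr <- ll_new - ll + ((a0^2 - (a0 + d)^2) / (2 * psd2))
      if (log(runif(1)) < lr) {
        a0 <- a0 + d; eta <- eta_new; ll <- ll_new
        acc_batch[["alpha0"]] <- acc_batch[["alpha0"]] + 1
        if (retained) acc[["alpha0"]] <- acc[["alpha0"]] + 1
      }

      # alpha1 block: moves eta only on algal transects
      d <- rnorm(1, 0, scales[["alpha1"]])
      eta_new <- eta + d * x
      ll_new <- bernoulli_loglik(y, eta_new)
      lr <- ll_new - ll + ((a1^2 - (a1 + d)^2) / (2 * psd2))
      if (log(runif(1)) < lr) {
        a1 <- a1 + d; eta <- eta_new; ll <- ll_new
        acc_batch[["alpha1"]] <- acc_batch[["alpha1"]] + 1
        if (retained) acc[["alpha1"]] <- acc[["alpha1"]] + 1
      }

      # lambda block: likelihood factorises over locations, so all L
      # random-walk updates can be decided independently in one pass
      if (sample_re) {
        d_l <- rnorm(L, 0, lambda_scales)
        eta_new <- eta + d_l[loc]
        ll_by <- bernoulli_loglik_by(y, eta, loc, L)
        ll_by_new <- bernoulli_loglik_by(y, eta_new, loc, L)
        lr_l <- ll_by_new - ll_by +
          (lambda^2 - (lambda + d_l)^2) / (2 * sigma^2)
        acc_l <- log(runif(L)) < lr_l
        if (any(acc_l)) {
          lambda[acc_l] <- lambda[acc_l] + d_l[acc_l]
          eta <- eta + (d_l * acc_l)[loc]
          ll <- bernoulli_loglik(y, eta)
        }
        acc_batch_lambda <- acc_batch_lambda + acc_l
        if (retained) acc[["lambda"]] <- acc[["lambda"]] + mean(acc_l)
      }

      # sigma block: random walk on log(sigma); half-Normal prior + Jacobian
      if (sample_sigma) {
        d <- rnorm(1, 0, scales[["log_sigma"]])
        sigma_new <- exp(log(sigma) + d)
        lr <- sum(dnorm(lambda, 0, sigma_new, log = TRUE)) -
          sum(dnorm(lambda, 0, sigma, log = TRUE)) +
          (sigma^2 - sigma_new^2) / (2 * config$prior_sd_sigma^2) +
          (log(sigma_new) - log(sigma))
        if (log(runif(1)) < lr) {
          sigma <- sigma_new
          acc_batch[["log_sigma"]] <- acc_batch[["log_sigma"]] + 1
          if (retained) acc[["log_sigma"]] <- acc[["log_sigma"]] + 1
        }
      }

      # adapt proposal scales toward 0.44 acceptance during burn-in only
      if (in_burnin && it %% batch_len == 0) {
        step <- min(0.1, 1 / sqrt(it / batch_len))
        for (b in c("alpha0", "alpha1", "log_sigma")) {
          scales[[b]] <- scales[[b]] *
            exp(ifelse(acc_batch[[b]] / batch_len > 0.44, step, -step))
        }
        lambda_scales <- lambda_scales *
          exp(ifelse(acc_batch_lambda / batch_len > 0.44, step, -step))
        acc_batch[] <- 0
        acc_batch_lambda[] <- 0
      }

      if (retained) {
        k <- it - config$n_burnin
        keep[k, ] <- c(a0, a1, sigma)
        keep_lambda[k, ] <- lambda
      }
    }

    draws <- tibble::tibble(
      .iteration = seq_len(config$n_iter),
      alpha0 = keep[, "alpha0"], alpha1 = keep[, "alpha1"],
      sigma_loc = keep[, "sigma_loc"],
      p_coral = plogis(keep[, "alpha0"]),
      p_algal = plogis(keep[, "alpha0"] + keep[, "alpha1"]))
    structure(list(
      draws = draws, lambda_draws = keep_lambda,
      acceptance = c(acc[c("alpha0", "alpha1", "log_sigma")] / config$n_iter,
                     lambda = unname(acc[["lambda"]]) / config$n_iter),
      scales = c(scales, lambda_mean = mean(lambda_scales)),
      separability = separability, species = data$species,
      n_transects = n, n_locations = L, config = config),
      class = "occupancy_fit")
  })
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("<occupancy_fit> species '%s': %d transects, %d locations, %d draws\n",
              x$species, x$n_transects, x$n_locations, nrow(x$draws)))
  print(posterior_habitat_probabilities(x))
  if (length(x$separability) > 0) {
    cat("note: separable data (", paste(x$separability, collapse = "; "),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Posterior occurrence probability per habitat
#'
#' Summarises the derived chains `p_coral = plogis(alpha0)` and
#' `p_algal = plogis(alpha0 + alpha1)` by their posterior mean and equal-tailed
#' 95% credible interval (2.5% and 97.5% quantiles, linear interpolation of
#' order statistics).
#'
#' @param fit an [fit_occupancy()] result.
#' @return a tibble with columns `species`, `habitat`, `mean`, `lower`,
#'   `upper`.
#' @export
posterior_habitat_probabilities <- function(fit) {
  stopifnot(inherits(fit, "occupancy_fit"))
  if (nrow(fit$draws) == 0) stop("fit contains no retained draws",
                                 call. = FALSE)
  summ <- function(p) c(mean(p), unname(quantile(p, c(0.025, 0.975),
                                                 type = 7)))
  pc <- summ(fit$draws$p_coral)
  pa <- summ(fit$draws$p_algal)
  tibble::tibble(species = fit$species,
                 habitat = c("coral_reef", "algal_meadow"),
                 mean = c(pc[1], pa[1]), lower = c(pc[2], pa[2]),
                 upper = c(pc[3], pa[3]))
}

#' Classify the habitat difference by credible-interval overlap
#'
#' The occurrence probability is deemed greater in one habitat when the 95%
#' credible intervals for the two habitats do not overlap: `coral_greater`
#' when the coral-reef lower bound exceeds the algal-meadow upper bound,
#' `algal_greater` for the reverse, `no_distinction` otherwise.
#'
#' @param fit an [fit_occupancy()] result.
#' @return one of `"coral_greater"`, `"algal_greater"`, `"no_distinction"`.
#' @export
classify_habitat_difference <- function(fit) {
  p <- posterior_habitat_probabilities(fit)
  coral <- p[p$habitat == "coral_reef", ]
  algal <- p[p$habitat == "algal_meadow", ]
  if (coral$lower > algal$upper) {
    "coral_greater"
  } else if (algal$lower > coral$upper) {
    "algal_greater"
  } else {
    "no_distinction"
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of an occupancy fit
#'
#' @param x an `occupancy_fit`.
#' @param ... unused.
#' @return a tibble with one row per parameter (`alpha0`, `alpha1`,
#'   `sigma_loc`, `p_coral`, `p_algal`): posterior mean (`estimate`), sd
#'   (`std.error`) and equal-tailed 95% interval (`conf.low`, `conf.high`).
#' @method tidy occupancy_fit
#' @export
tidy.occupancy_fit <- function(x, ...) {
  pars <- c("alpha0", "alpha1", "sigma_loc", "p_coral", "p_algal")
  purrr::map_dfr(pars, function(p) {
    v <- x$draws[[p]]
    tibble::tibble(term = p, estimate = mean(v), std.error = sd(v),
                   conf.low = unname(quantile(v, 0.025)),
                   conf.high = unname(quantile(v, 0.975)))
  })
}

#' One-row summary of an occupancy fit
#'
#' @param x an `occupancy_fit`.
#' @param ... unused.
#' @return a tibble with the species, data dimensions, chain length, the
#'   habitat classification and whether the data were separable.
#' @method glance occupancy_fit
#' @export
glance.occupancy_fit <- function(x, ...) {
  tibble::tibble(species = x$species, n_transects = x$n_transects,
                 n_locations = x$n_locations, n_draws = nrow(x$draws),
                 n_burnin = x$config$n_burnin,
                 classification = classify_habitat_difference(x),
                 separable = length(x$separability) > 0,
                 mean_acceptance = mean(x$acceptance[c("alpha0", "alpha1")]))
}
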