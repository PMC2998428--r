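#' MCMC convergence diagnostics for an occupancy fit
#'
#' Runs the chain checks used to validate the occupancy model fits:
#' \itemize{
#'   \item Geweke z-scores comparing the mean of the first 10% of each chain
#'     with the last 50% (spectral-density variance estimate); `|z| > 2`
#'     fails.
#'   \item Raftery-Lewis minimum chain length required to estimate the 2.5%
#'     quantile to within +/- 0.005 with probability 0.95; a requirement
#'     exceeding the available chain length fails.
#'   \item The cross-correlation matrix of the parameter chains; any
#'     off-diagonal absolute correlation above 0.95 fails.
#' }
#'
#' @param fit an [fit_occupancy()] result, or any named list/matrix of equal
#'   length numeric chains. Constant chains (e.g. a fixed `sigma_loc`) are
#'   dropped before testing.
#' @param z_threshold Geweke flag threshold (default 2).
#' @param crosscorr_threshold cross-correlation flag threshold (default 0.95).
#' @return an object of class `mcmc_diagnostics`: tibbles `geweke` and
#'   `raftery`, matrix `crosscorr`, and logical `pass` (all checks passed).
#' @export
convergence_diagnostics <- function(fit, z_threshold = 2,
                                    crosscorr_threshold = 0.95) {
  chains <- if (inherits(fit, "occupancy_fit")) {
    as.matrix(fit$draws[, c("alpha0", "alpha1", "sigma_loc")])
  } else {
    as.matrix(as.data.frame(fit))
  }
  if (nrow(chains) < 100) {
    stop("chains too short for diagnostics (need >= 100 iterations)",
         call. = FALSE)
  }
  keep <- apply(chains, 2, function(v) sd(v) > 0)
  chains <- chains[, keep, drop = FALSE]
  if (ncol(chains) == 0) stop("all chains are constant", call. = FALSE)
  mc <- coda::mcmc(chains)

  gw <- coda::geweke.diag(mc, frac1 = 0.1, frac2 = 0.5)$z
  geweke <- tibble::tibble(parameter = colnames(chains), z = unname(gw),
                           pass = is.finite(gw) & abs(gw) <= z_threshold)

  n_avail <- nrow(chains)
  rl <- tryCatch(coda::raftery.diag(mc, q = 0.025, r = 0.005, s = 0.95),
                 error = function(e) NULL)
  if (!is.null(rl) && is.matrix(rl$resmatrix)) {
    required <- rl$resmatrix[, "N"]
    burn <- rl$resmatrix[, "M"]
  } else {
    required <- rep(NA_real_, ncol(chains))
    burn <- rep(NA_real_, ncol(chains))
  }
  raftery <- tibble::tibble(parameter = colnames(chains),
                            burnin_required = as.numeric(burn),
                            n_required = as.numeric(required),
                            n_available = n_avail,
                            pass = is.finite(as.numeric(required)) &
                              as.numeric(required) <= n_avail)

  cc <- cor(chains)
  off <- cc
  diag(off) <- 0
  crosscorr_pass <- all(abs(off) <= crosscorr_threshold)

  structure(list(geweke = geweke, raftery = raftery, crosscorr = cc,
                 crosscorr_pass = crosscorr_pass,
                 pass = all(geweke$pass) && all(raftery$pass) &&
                   crosscorr_pass),
            class = "mcmc_diagnostics")
}

#' @export
print.mcmc_diagnostics <- function(x, ...) {
  cat("<mcmc_diagnostics>", if (x$pass) "PASS" else "FAIL", "\n")
  cat("Geweke z (first 10% vs last 50%):\n")
  print(x$geweke)
  cat("Raftery-Lewis (q = 0.025, r = 0.005, s = 0.95):\n")
  print(x$raftery)
  cat("max |cross-correlation| off-diagonal:",
      max(abs(x$crosscorr - diag(diag(x$crosscorr)))), "\n")
  invisible(x)
}
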