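test_that("with no random effect the posterior matches the logistic MLE", {
  # sigma_loc fixed at 0: model reduces to plain logistic regression, so the
  # posterior mode/mean under flat priors must sit on the iteratively
  # reweighted least squares fit of glm()
  set.seed(101)
  n <- 5000
  x <- rbinom(n, 1, 0.4)
  eta <- 0 + 1 * x
  y <- rbinom(n, 1, plogis(eta))
  dat <- make_occ_data(y, x, loc = rep(1:10, length.out = n))
  fit <- fit_occupancy(dat, mcmc_config(n_burnin = 500, n_iter = 4000,
                                        sigma_loc_fixed = 0, seed = 7))
  mle <- coef(glm(y ~ x, family = binomial()))
  post <- colMeans(fit$draws[, c("alpha0", "alpha1")])
  expect_lt(abs(post[["alpha0"]] - mle[[1]]), 0.05)
  expect_lt(abs(post[["alpha1"]] - mle[[2]]), 0.05)
  # and within 3 posterior sds of the generating truth
  sds <- c(sd(fit$draws$alpha0), sd(fit$draws$alpha1))
  expect_lt(abs(post[["alpha0"]] - 0), 3 * sds[1])
  expect_lt(abs(post[["alpha1"]] - 1), 3 * sds[2])
})

test_that("saturated presence drives both habitat probabilities high", {
  dat <- make_occ_data(y = rep(1, 120), x = rep(c(0, 1), 60),
                       loc = rep(1:6, each = 20))
  expect_warning(
    fit <- fit_occupancy(dat, mcmc_config(n_burnin = 500, n_iter = 2000,
                                          seed = 3)),
    "separable")
  p <- posterior_habitat_probabilities(fit)
  expect_true(all(p$mean > 0.95))
  expect_true(all(fit$separability != ""))
})

test_that("a single-transect dataset stays within the prior's central mass", {
  dat <- make_occ_data(y = 1, x = 0, loc = 1)
  expect_warning(
    fit <- fit_occupancy(dat, mcmc_config(n_burnin = 2000, n_iter = 4000,
                                          sigma_loc_fixed = 0, seed = 9)))
  p <- posterior_habitat_probabilities(fit)
  # p_coral prior: plogis(Normal(0, 1000)); p_algal adds an independent
  # Normal(0, 1000), so its prior logit sd is sqrt(2000). A single y = 1
  # observation must leave the interval inside the prior's central 99% mass
  # and only nudge the mean upward from the prior's 0.5.
  lo <- plogis(qnorm(0.005, 0, sqrt(c(1000, 2000))))
  hi <- plogis(qnorm(0.995, 0, sqrt(c(1000, 2000))))
  expect_true(all(p$lower >= lo & p$upper <= hi))
  expect_gt(p$mean[p$habitat == "coral_reef"], 0.5)
})

test_that("posterior summaries follow the chains exactly", {
  # constant chain: degenerate interval at the constant
  f <- fake_fit(rep(0.5, 2000), rep(0.5, 2000))
  p <- posterior_habitat_probabilities(f)
  expect_equal(p$mean, c(0.5, 0.5))
  expect_equal(p$lower, c(0.5, 0.5))
  expect_equal(p$upper, c(0.5, 0.5))

  # iid uniform chain: interpolated quantiles near the closed form
  set.seed(11)
  u <- runif(10000)
  f2 <- fake_fit(u, u)
  p2 <- posterior_habitat_probabilities(f2)
  expect_lt(abs(p2$lower[1] - 0.025), 0.02)
  expect_lt(abs(p2$upper[1] - 0.975), 0.02)

  f3 <- fake_fit(numeric(0), numeric(0))
  expect_error(posterior_habitat_probabilities(f3), "no retained draws")
})

test_that("habitat classification follows credible-interval overlap", {
  set.seed(12)
  # forced separation: [~0.6, 0.8] vs [~0.1, 0.3]
  f <- fake_fit(runif(5000, 0.6, 0.8), runif(5000, 0.1, 0.3))
  expect_equal(classify_habitat_difference(f), "coral_greater")
  f2 <- fake_fit(runif(5000, 0.1, 0.3), runif(5000, 0.6, 0.8))
  expect_equal(classify_habitat_difference(f2), "algal_greater")
  # identical chains: total overlap
  u <- runif(5000, 0.2, 0.6)
  expect_equal(classify_habitat_difference(fake_fit(u, u)), "no_distinction")
})

test_that("posterior sd of the habitat effect shrinks like 1/sqrt(n)", {
  sd_at <- function(n, seed) {
    set.seed(seed)
    x <- rep(c(0, 1), n / 2)
    y <- rbinom(n, 1, plogis(0.3 - 1 * x))
    fit <- fit_occupancy(make_occ_data(y, x, rep(1:10, length.out = n)),
                         mcmc_config(n_burnin = 500, n_iter = 4000,
                                     sigma_loc_fixed = 0, seed = seed))
    sd(fit$draws$alpha1)
  }
  ratio <- sd_at(200, 21) / sd_at(2000, 22)
  expect_gt(ratio, sqrt(10) * 0.7)
  expect_lt(ratio, sqrt(10) * 1.3)
})

test_that("relabelling locations leaves the fixed-effect posterior unchanged", {
  set.seed(31)
  L <- 8
  loc <- rep(1:L, each = 15)
  lam <- rnorm(L, 0, 0.7)
  x <- rbinom(length(loc), 1, 0.5)
  y <- rbinom(length(loc), 1, plogis(0.5 - 1.5 * x + lam[loc]))
  perm <- sample(L)
  f1 <- fit_occupancy(make_occ_data(y, x, loc),
                      mcmc_config(n_burnin = 1000, n_iter = 8000, seed = 5))
  f2 <- fit_occupancy(make_occ_data(y, x, perm[loc]),
                      mcmc_config(n_burnin = 1000, n_iter = 8000, seed = 5))
  expect_lt(abs(mean(f1$draws$alpha1) - mean(f2$draws$alpha1)), 0.15)
  expect_lt(abs(mean(f1$draws$alpha0) - mean(f2$draws$alpha0)), 0.15)
  # the lambda draws are the same set of locations, permuted
  expect_equal(unname(sort(colMeans(f1$lambda_draws))),
               unname(sort(colMeans(f2$lambda_draws))), tolerance = 0.2)
})

test_that("proposal adaptation lands acceptance rates near the 0.44 target", {
  set.seed(41)
  y <- rbinom(300, 1, 0.5)
  x <- rep(c(0, 1), 150)
  fit <- fit_occupancy(make_occ_data(y, x, rep(1:10, each = 30)),
                       mcmc_config(seed = 6))
  expect_true(all(fit$acceptance[c("alpha0", "alpha1")] > 0.2))
  expect_true(all(fit$acceptance[c("alpha0", "alpha1")] < 0.7))
})

test_that("tidy and glance expose the fit in broom shape", {
  set.seed(51)
  y <- rbinom(100, 1, 0.5)
  fit <- fit_occupancy(make_occ_data(y, rep(c(0, 1), 50), rep(1:5, each = 20)),
                       mcmc_config(n_burnin = 200, n_iter = 500, seed = 2))
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_setequal(td$term, c("alpha0", "alpha1", "sigma_loc", "p_coral",
                             "p_algal"))
  expect_true(all(td$conf.low <= td$estimate & td$estimate <= td$conf.high))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$n_draws, 500L)
  expect_true(gl$classification %in%
                c("coral_greater", "algal_greater", "no_distinction"))
})

test_that("geweke flags drift and passes stationary chains", {
  set.seed(61)
  iid <- data.frame(theta = rnorm(10000))
  d <- convergence_diagnostics(iid)
  expect_true(all(abs(d$geweke$z) < 2))
  # deterministic drift: mean moves by +0.001 per iteration
  drift <- data.frame(theta = rnorm(10000) + 0.001 * seq_len(10000))
  d2 <- convergence_diagnostics(drift)
  expect_false(all(d2$geweke$pass))
  expect_false(d2$pass)
})

test_that("raftery-lewis compares required with available chain length", {
  set.seed(71)
  iid <- data.frame(theta = rnorm(10000))
  d <- convergence_diagnostics(iid)
  # iid chain: requirement near the theoretical minimum ~3746, well available
  expect_true(all(d$raftery$pass))
  expect_lt(d$raftery$n_required[1], 10000)
  short <- data.frame(theta = rnorm(500))
  d2 <- convergence_diagnostics(short)
  expect_false(any(d2$raftery$pass))
})

test_that("duplicated parameter chains are flagged by cross-correlation", {
  set.seed(81)
  v <- rnorm(5000)
  d <- convergence_diagnostics(data.frame(a = v, b = v + rnorm(5000, 0, 1e-6)))
  expect_false(d$crosscorr_pass)
  expect_false(d$pass)
  expect_error(convergence_diagnostics(data.frame(a = rnorm(50))),
               "too short")
})
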