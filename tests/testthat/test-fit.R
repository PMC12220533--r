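# observations simulated directly from a model at known fluxes, with
# nominal weights; optionally perturbed by seeded Gaussian noise
make_observations <- function(truth, noise = 0, seed = 1) {
  set.seed(seed)
  model <- build_model(truth$condition, truth$tracer, truth$pools_fmol,
                       truth$free_fluxes, truth$growth_rate)
  sim <- simulate_labeling(model, truth$times_min)
  measured <- c("met", "sam", "sah", "hcys", "cyst")
  lab <- do.call(rbind, lapply(measured, function(m) {
    data.frame(metabolite = m, time_min = truth$times_min,
               x1 = pmin(pmax(sim[[m]] + rnorm(length(truth$times_min),
                                               0, noise * 0.02), 0), 1),
               sd = 0.02)
  }))
  conc <- data.frame(metabolite = measured,
                     fmol_per_cell = truth$pools_fmol[measured] *
                       exp(rnorm(5, 0, noise * 0.05)),
                     sd = 0.05 * truth$pools_fmol[measured])
  fl <- truth$fluxes
  net <- c(met = fl[["MET_release"]] - fl[["MET_uptake"]],
           hcys = fl[["HCYS_release"]] - fl[["HCYS_uptake"]])
  rate_sd <- pmax(0.1 * abs(net), 0.02)
  rates <- data.frame(metabolite = c("met", "hcys"),
                      rate = net + rnorm(2, 0, noise * rate_sd),
                      sd = rate_sd)
  protsyn <- list(rate = fl[["PROTSYN"]] * exp(rnorm(1, 0, noise * 0.05)),
                  sd = 0.1 * fl[["PROTSYN"]])
  observation_set(lab, conc, rates, protsyn)
}

test_that("noiseless observations are a zero-residual fixed point", {
  truth <- syn_truths()$syn_tert_met_plus
  obs <- make_observations(truth, noise = 0)
  fit <- fit_fluxes(truth$condition, truth$tracer, obs, truth$growth_rate,
                    multistart = 4, seed = 3)
  expect_true(fit$converged)
  expect_lt(fit$chi_square, 1e-6)
  est <- stats::setNames(fit$fluxes$estimate, fit$fluxes$reaction)
  idf <- identifiable_fluxes(fit)
  rel <- abs(est[idf] - truth$fluxes[idf]) / truth$fluxes[idf]
  expect_lt(max(rel), 1e-2)
  # the well-determined core is recovered much tighter
  core <- intersect(c("MAT", "MET_uptake", "PROTSYN", "CYSTS"), idf)
  expect_lt(max(abs(est[core] - truth$fluxes[core]) / truth$fluxes[core]),
            1e-3)
})

test_that("observation sets require positive uncertainties", {
  truth <- syn_truths()$syn_tert_met_plus
  obs <- make_observations(truth, noise = 0)
  bad <- obs$labeling
  bad$sd[3] <- 0
  expect_error(observation_set(bad, obs$concentrations, obs$exchange_rates,
                               obs$protsyn), "positive sd")
  filled <- obs$labeling
  filled$sd <- NA_real_
  relaxed <- apply_default_weights(
    structure(list(labeling = filled, concentrations = obs$concentrations,
                   exchange_rates = obs$exchange_rates, protsyn = obs$protsyn),
              class = "observation_set"))
  expect_true(all(relaxed$labeling$sd == 0.02))
})

test_that("chi-square statistic, dof and acceptance region are textbook", {
  g <- chi_square_gof(c(1, 2), n_params = 0)
  expect_equal(g$statistic, 5)
  expect_equal(g$dof, 2)
  # zero residuals fall below any central acceptance region
  g0 <- chi_square_gof(rep(0, 10), n_params = 2)
  expect_equal(g0$statistic, 0)
  expect_false(g0$accepted)
  expect_error(chi_square_gof(c(1, 2), n_params = 2), "invalid-argument")
  # frozen independent quantiles (scipy.stats.chi2.ppf at 0.025/0.975)
  ref <- list(
    `1` = c(0.0009820691, 5.023886187),
    `2` = c(0.0506356160, 7.377758908),
    `5` = c(0.8312116135, 12.832501994),
    `10` = c(3.2469727802, 20.483177351),
    `16` = c(6.9076643535, 28.845350723),
    `20` = c(9.5907773923, 34.169606903),
    `27` = c(14.5733827308, 43.194510966),
    `30` = c(16.7907722656, 46.979242244))
  for (dof in names(ref)) {
    g <- chi_square_gof(rep(1, as.integer(dof)), n_params = 0)
    expect_equal(g$acceptance_region, ref[[dof]], tolerance = 1e-8)
  }
})

test_that("mass-balance MTR inference is exact, linear and floored", {
  # uptake covers the whole demand
  expect_equal(mtr_flux_by_mass_balance(6, 4, 10)$flux, 0)
  expect_equal(mtr_flux_by_mass_balance(6, 4, 4)$flux, 6)
  # no exogenous methionine: MTR carries the full consumption
  expect_equal(mtr_flux_by_mass_balance(6, 4, 0)$flux, 10)
  # flooring flags a negative balance instead of returning it
  res <- mtr_flux_by_mass_balance(1, 1, 10)
  expect_equal(res$flux, 0)
  expect_true(res$floored)
  # exact linearity away from the floor
  set.seed(5)
  for (i in 1:20) {
    a <- runif(3, 0, 5); b <- runif(3, 0, 5)
    va <- a[1] + a[2] - a[3]; vb <- b[1] + b[2] - b[3]
    if (va >= 0 && vb >= 0 && va + vb >= 0) {
      expect_equal(mtr_flux_by_mass_balance(a[1] + b[1], a[2] + b[2],
                                            a[3] + b[3])$flux,
                   mtr_flux_by_mass_balance(a[1], a[2], a[3])$flux +
                     mtr_flux_by_mass_balance(b[1], b[2], b[3])$flux,
                   tolerance = 1e-12)
    }
  }
  expect_error(mtr_flux_by_mass_balance(Inf, 1, 1), "invalid-argument")
})

test_that("linearized CIs match the closed-form regression interval", {
  # straight line through the origin with known noise: the linearized se
  # is 1/sqrt(sum((t/sigma)^2)), the textbook weighted-regression result
  set.seed(9)
  t_i <- 1:20
  sigma <- 0.5
  theta_true <- 2.3
  y <- theta_true * t_i + rnorm(20, 0, sigma)
  rfn <- function(theta) (theta * t_i - y) / sigma
  theta_hat <- sum(t_i * y) / sum(t_i^2)
  lin <- linearized_covariance(rfn, c(theta = theta_hat))
  se_closed <- 1 / sqrt(sum((t_i / sigma)^2))
  expect_equal(unname(lin$se), se_closed, tolerance = 1e-6)
  # doubling all sds doubles the CI half-width
  rfn2 <- function(theta) (theta * t_i - y) / (2 * sigma)
  lin2 <- linearized_covariance(rfn2, c(theta = theta_hat))
  expect_equal(unname(lin2$se), 2 * se_closed, tolerance = 1e-6)
})

test_that("95% CIs cover the truth at nominal rate in repeated fits", {
  # linear-model coverage simulation over 200 seeded replicates
  t_i <- 1:10
  sigma <- 1
  theta_true <- 1.7
  z <- qnorm(0.975)
  se_closed <- 1 / sqrt(sum((t_i / sigma)^2))
  set.seed(42)
  covered <- vapply(1:200, function(i) {
    y <- theta_true * t_i + rnorm(10, 0, sigma)
    theta_hat <- sum(t_i * y) / sum(t_i^2)
    abs(theta_hat - theta_true) <= z * se_closed
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 1.00)
  # and the package's linearized se equals the one used above
  y <- theta_true * t_i + rnorm(10, 0, sigma)
  lin <- linearized_covariance(function(th) (th * t_i - y) / sigma,
                               c(theta = sum(t_i * y) / sum(t_i^2)))
  expect_equal(unname(lin$se), se_closed, tolerance = 1e-6)
})

test_that("unidentifiable directions get infinite CIs, not a crash", {
  # two parameters entering only through their sum: rank-deficient J'J
  y <- c(1, 2, 3)
  rfn <- function(th) (th[1] + th[2]) * c(1, 1, 1) - y
  lin <- linearized_covariance(rfn, c(a = 1, b = 1))
  expect_true(all(lin$unidentifiable))
  expect_true(all(is.infinite(lin$se)))
})

test_that("confidence_intervals scales with level and contains the estimate", {
  truth <- syn_truths()$syn_tert_met_plus
  obs <- make_observations(truth, noise = 1, seed = 11)
  fit <- fit_fluxes(truth$condition, truth$tracer, obs, truth$growth_rate,
                    multistart = 2, seed = 4)
  ci95 <- confidence_intervals(fit, 0.95)
  ci50 <- confidence_intervals(fit, 0.50)
  expect_true(all(ci95$lower <= ci95$estimate & ci95$estimate <= ci95$upper))
  w95 <- ci95$upper - ci95$lower
  w50 <- ci50$upper - ci50$lower
  expect_equal(w95 / w50, rep(qnorm(0.975) / qnorm(0.75), nrow(ci95)),
               tolerance = 1e-9)
  # estimates respect the bounds
  expect_true(all(fit$theta >= 0))
  expect_true(all(fit$fluxes$estimate >= -1e-9))
  # the multistart ledger is recorded with the seed
  expect_equal(fit$seed, 4)
  expect_equal(nrow(fit$multistart), 2)
})
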