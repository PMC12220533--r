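#' Weighted least-squares flux estimation
#'
#' Fluxes and pool sizes are estimated by fitting the compartmental
#' labeling model to heavy-fraction time series, intracellular
#' concentrations, net uptake/release rates for methionine and
#' homocysteine, and the protein synthesis rate, minimizing
#' `sum(((obs - pred) / sd)^2)` with the Levenberg-Marquardt algorithm.
#' Steady-state balance is enforced by parameterizing only the free
#' fluxes of the condition's spanning set and deriving the dependent
#' ones (see [complete_fluxes()]). Goodness of fit is assessed with the
#' chi-square test, and confidence intervals by linear approximation
#' around the optimum.
#'
#' @name flux_fit
NULL

#' Assemble an observation set for flux fitting
#'
#' @param labeling data frame with columns metabolite, time_min, x1, sd.
#' @param concentrations data frame with columns metabolite,
#'   fmol_per_cell, sd.
#' @param exchange_rates data frame with columns metabolite (`met`,
#'   `hcys`), rate (fmol/cell/h, release positive), sd.
#' @param protsyn list or vector with `rate` and `sd` (fmol/cell/h).
#' @return object of class `observation_set`.
#' @export
observation_set <- function(labeling, concentrations, exchange_rates, protsyn) {
  need <- function(df, cols, what) {
    if (!is.data.frame(df) || !all(cols %in% names(df))) {
      stop(sprintf("invalid-argument: %s needs columns %s", what,
                   paste(cols, collapse = ", ")))
    }
  }
  need(labeling, c("metabolite", "time_min", "x1", "sd"), "labeling")
  need(concentrations, c("metabolite", "fmol_per_cell", "sd"), "concentrations")
  need(exchange_rates, c("metabolite", "rate", "sd"), "exchange_rates")
  protsyn <- as.list(protsyn)
  sds <- c(labeling$sd, concentrations$sd, exchange_rates$sd, protsyn$sd)
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop("invalid-argument: every observation needs a strictly positive sd")
  }
  if (nrow(labeling) == 0) stop("invalid-argument: labeling observations are empty")
  structure(list(labeling = labeling, concentrations = concentrations,
                 exchange_rates = exchange_rates, protsyn = protsyn),
            class = "observation_set")
}

#' Apply default observation weights
#'
#' Measurement sds are rarely reported with raw tables; these defaults
#' keep the chi-square statistic on a defensible scale and are
#' overridable per observation: an absolute floor of 0.02 on heavy
#' fractions and 10% relative (with a small absolute floor) on
#' concentrations and rates. Documented prominently because the
#' chi-square scale depends on them.
#'
#' @param obs an [observation_set()] whose `sd` columns may contain `NA`.
#' @param hf_floor heavy-fraction sd floor.
#' @param rel relative sd for concentrations and rates.
#' @return the observation set with all sds filled.
#' @export
apply_default_weights <- function(obs, hf_floor = 0.02, rel = 0.10) {
  obs$labeling$sd <- pmax(ifelse(is.na(obs$labeling$sd), hf_floor,
                                 obs$labeling$sd), hf_floor)
  fill_rel <- function(sd, value) {
    ifelse(is.na(sd), pmax(rel * abs(value), 1e-4), sd)
  }
  obs$concentrations$sd <- fill_rel(obs$concentrations$sd,
                                    obs$concentrations$fmol_per_cell)
  obs$exchange_rates$sd <- fill_rel(obs$exchange_rates$sd,
                                    obs$exchange_rates$rate)
  if (is.na(obs$protsyn$sd)) obs$protsyn$sd <- max(rel * abs(obs$protsyn$rate), 1e-4)
  obs
}

.default_flux_init <- function(condition, obs) {
  conc <- stats::setNames(obs$concentrations$fmol_per_cell,
                          obs$concentrations$metabolite)
  c_sam <- if ("sam" %in% names(conc)) conc[["sam"]] else 0.05
  protsyn0 <- max(obs$protsyn$rate, 0.01)
  r_met <- obs$exchange_rates$rate[obs$exchange_rates$metabolite == "met"]
  r_hcys <- obs$exchange_rates$rate[obs$exchange_rates$metabolite == "hcys"]
  r_met <- if (length(r_met)) r_met[1] else 0
  r_hcys <- if (length(r_hcys)) r_hcys[1] else 0
  if (condition == .MET_PLUS) {
    mat0 <- max(2 * c_sam, 0.02)
    hcys_rel0 <- max(r_hcys, 0.02 * mat0)
    cysts0 <- 0.1 * mat0
    c(MTR = max(mat0 - cysts0 - hcys_rel0, 1e-3),
      CYSTS = cysts0, HCYS_release = hcys_rel0, AHCY_rev = 0.5 * mat0,
      PROTSYN = protsyn0, MET_release = max(-r_met, 0.1) * 5)
  } else {
    u_hcys <- max(-r_hcys, 0.1)
    mat0 <- max(1.4 * c_sam, 0.005)
    c(MAT = mat0, AHCY_rev = 2 * mat0 + 0.1,
      CYSTS = 0.05 * u_hcys + 0.01,
      HCYS_release = 0.1 * u_hcys + 0.01,
      PROTSYN = protsyn0, MET_release = 0.01)
  }
}

#' Fit fluxes and pool sizes to an observation set
#'
#' @param condition culture condition, see [build_model()].
#' @param tracer a [tracer_spec].
#' @param observations an [observation_set()]; sds must be positive
#'   (apply [apply_default_weights()] first if any are missing).
#' @param growth_rate specific growth rate (1/h), treated as known.
#' @param flux_init optional named starting values for the free fluxes.
#' @param pools `"free"` (pool sizes of measured metabolites are fitted,
#'   constrained by the concentration observations) or `"fixed"` (pinned
#'   to the observed concentrations; concentration residuals drop out).
#' @param fixed_pools named sizes (fmol/cell) for interior pools without
#'   concentration observations (alpha-ketobutyrate under the deuterated
#'   tracer); never fitted.
#' @param multistart number of Levenberg-Marquardt starts: the first
#'   from `flux_init`, the rest from seeded lognormal perturbations.
#' @param seed integer seed for the perturbations (recorded in the
#'   result).
#' @param alpha significance level for the chi-square acceptance region.
#' @param maxiter maximum LM iterations per start.
#' @return object of class `flux_fit`; see Details.
#' @details The result contains the estimate, standard error and
#'   normal-approximation confidence interval for every reaction
#'   (dependent fluxes via exact linear error propagation), fitted pool
#'   sizes, the chi-square statistic with degrees of freedom and central
#'   acceptance region, per-observation residuals, the free-flux
#'   spanning set used for dof accounting, convergence and
#'   multimodality flags, and the seed.
#' @export
fit_fluxes <- function(condition, tracer, observations, growth_rate,
                       flux_init = NULL, pools = c("free", "fixed"),
                       fixed_pools = c(akb = 0.005),
                       multistart = 10, seed = 1L, alpha = 0.05,
                       maxiter = 150) {
  pools <- match.arg(pools)
  stopifnot(inherits(observations, "observation_set"))
  condition <- match.arg(condition, c("met_plus", "met_minus_hcys_plus"))
  obs <- observations
  fnames <- free_flux_names(condition)
  if (is.null(flux_init)) flux_init <- .default_flux_init(condition, obs)
  if (!all(fnames %in% names(flux_init))) {
    stop("invalid-argument: flux_init must cover the free flux set")
  }
  flux_init <- pmax(flux_init[fnames], 1e-6)

  interior <- c("met", "sam", "sah", "hcys", "cyst",
                if (tracer$element == "H2") "akb")
  conc <- obs$concentrations
  meas_pools <- intersect(conc$metabolite, interior)
  if (length(meas_pools) == 0) stop("invalid-argument: no measured pool sizes")
  conc_val <- stats::setNames(conc$fmol_per_cell, conc$metabolite)[meas_pools]
  conc_sd <- stats::setNames(conc$sd, conc$metabolite)[meas_pools]
  free_pools <- pools == "free"

  theta0 <- if (free_pools) c(flux_init, stats::setNames(conc_val, paste0("C_", meas_pools)))
            else flux_init
  lower <- rep(1e-8, length(theta0))
  upper <- rep(1e5, length(theta0))

  lab <- obs$labeling
  lab_times <- sort(unique(lab$time_min))
  rates <- obs$exchange_rates

  make_pools <- function(theta) {
    ps <- if (free_pools) {
      stats::setNames(theta[paste0("C_", meas_pools)], meas_pools)
    } else conc_val
    missing <- setdiff(interior, names(ps))
    if (length(missing)) {
      extra <- fixed_pools[missing]
      if (any(is.na(extra))) {
        stop(sprintf("invalid-argument: fixed_pools must provide %s",
                     paste(missing[is.na(extra)], collapse = ", ")))
      }
      ps <- c(ps, stats::setNames(as.numeric(extra), missing))
    }
    ps
  }

  residual_fn <- function(theta) {
    theta <- stats::setNames(theta, names(theta0))
    # finite-difference probes may step marginally outside the box
    theta <- pmax(theta, 1e-10)
    free <- theta[fnames]
    ps <- pmax(make_pools(theta), 1e-10)
    model <- build_model(condition, tracer, ps, free, growth_rate)
    sim <- simulate_labeling(model, lab_times, method = "analytic")
    res <- numeric(0)
    pred_lab <- numeric(nrow(lab))
    for (i in seq_len(nrow(lab))) {
      ti <- match(lab$time_min[i], lab_times)
      pred_lab[i] <- sim[[lab$metabolite[i]]][ti]
    }
    res <- c(res, (pred_lab - lab$x1) / lab$sd)
    if (free_pools) {
      res <- c(res, (theta[paste0("C_", meas_pools)] - conc_val) / conc_sd)
    }
    full <- model$fluxes
    pred_rate <- vapply(rates$metabolite, function(m) {
      switch(m,
             met = full[["MET_release"]] - full[["MET_uptake"]],
             hcys = full[["HCYS_release"]] - full[["HCYS_uptake"]],
             stop("invalid-argument: exchange rates only for met and hcys"))
    }, numeric(1))
    res <- c(res, (pred_rate - rates$rate) / rates$sd)
    res <- c(res, (full[["PROTSYN"]] - obs$protsyn$rate) / obs$protsyn$sd)
    unname(res)
  }

  n_res <- nrow(lab) + (if (free_pools) length(meas_pools) else 0L) +
    nrow(rates) + 1L
  if (n_res <= length(theta0)) {
    stop("invalid-argument: fewer observations than free parameters")
  }

  starts <- list(theta0)
  if (multistart > 1) {
    starts <- c(starts, .with_seed(seed, {
      lapply(seq_len(multistart - 1), function(i) {
        pmin(pmax(theta0 * exp(stats::rnorm(length(theta0), 0, 0.5)),
                  lower), upper)
      })
    }))
  }

  runs <- lapply(starts, function(st) {
    tryCatch({
      fit <- minpack.lm::nls.lm(
        par = st, lower = lower, upper = upper, fn = residual_fn,
        control = minpack.lm::nls.lm.control(maxiter = maxiter,
                                             ftol = 1e-12, ptol = 1e-12))
      list(par = stats::setNames(coef(fit), names(theta0)),
           deviance = fit$deviance, info = fit$info,
           converged = fit$info %in% 1:4, message = fit$message)
    }, error = function(e) list(par = st, deviance = Inf, info = -1L,
                                converged = FALSE, message = conditionMessage(e)))
  })
  devs <- vapply(runs, `[[`, numeric(1), "deviance")
  best <- runs[[which.min(devs)]]
  ok_devs <- devs[vapply(runs, `[[`, logical(1), "converged")]
  multimodal <- length(ok_devs) > 1 &&
    (max(ok_devs) - min(ok_devs)) > 1e-4 * max(1, min(ok_devs))

  theta_hat <- best$par
  r_hat <- residual_fn(theta_hat)
  gof <- chi_square_gof(r_hat, length(theta_hat), alpha = alpha)

  lin <- linearized_covariance(residual_fn, theta_hat)
  cov_theta <- lin$cov
  se <- lin$se
  unident <- lin$unidentifiable
  grad_norm <- sqrt(sum((t(lin$jacobian) %*% r_hat)^2))

  z <- stats::qnorm(0.975)
  # full flux vector is linear in the free fluxes; propagate exactly
  all_rxn <- names(complete_fluxes(stats::setNames(rep(1, 6), fnames), condition))
  L <- vapply(seq_along(fnames), function(k) {
    e <- stats::setNames(numeric(6), fnames); e[k] <- 1
    complete_fluxes(e, condition)
  }, numeric(length(all_rxn)))
  rownames(L) <- all_rxn
  flux_hat <- as.numeric(L %*% theta_hat[fnames])
  cov_f <- cov_theta[fnames, fnames, drop = FALSE]
  flux_se <- sqrt(pmax(rowSums((L %*% cov_f) * L), 0))
  flux_se[apply(L[, unident[seq_along(fnames)], drop = FALSE] != 0, 1, any)] <- Inf
  fluxes_df <- data.frame(
    reaction = all_rxn, estimate = flux_hat, se = flux_se,
    lower = flux_hat - z * flux_se, upper = flux_hat + z * flux_se,
    free = all_rxn %in% fnames,
    identifiable = is.finite(flux_se),
    stringsAsFactors = FALSE)

  pool_names <- paste0("C_", meas_pools)
  if (free_pools) {
    p_hat <- theta_hat[pool_names]; p_se <- se[pool_names]
  } else {
    p_hat <- conc_val; p_se <- conc_sd
  }
  pools_df <- data.frame(
    pool = meas_pools, estimate = as.numeric(p_hat), se = as.numeric(p_se),
    lower = as.numeric(p_hat - z * p_se), upper = as.numeric(p_hat + z * p_se),
    fitted = free_pools, stringsAsFactors = FALSE)

  res_df <- data.frame(
    type = c(rep("labeling", nrow(lab)),
             if (free_pools) rep("concentration", length(meas_pools)),
             rep("exchange_rate", nrow(rates)), "protsyn"),
    metabolite = c(lab$metabolite, if (free_pools) meas_pools,
                   rates$metabolite, "protein"),
    time_min = c(lab$time_min, if (free_pools) rep(NA, length(meas_pools)),
                 rep(NA, nrow(rates)), NA),
    weighted_residual = r_hat, stringsAsFactors = FALSE)

  structure(list(
    condition = condition, tracer = tracer, pools_mode = pools,
    converged = best$converged, info = best$info, message = best$message,
    theta = theta_hat, se = se, cov = cov_theta,
    fluxes = fluxes_df, pool_sizes = pools_df,
    chi_square = gof$statistic, dof = gof$dof,
    acceptance_region = gof$acceptance_region, alpha = alpha,
    residuals = res_df, n_obs = n_res,
    spanning_set = fnames, growth_rate = growth_rate,
    multistart = data.frame(deviance = devs,
                            converged = vapply(runs, `[[`, logical(1), "converged")),
    multimodal = multimodal, seed = seed, gradient_norm = grad_norm
  ), class = "flux_fit")
}

#' @export
print.flux_fit <- function(x, ...) {
  cat(sprintf("<flux_fit> %s (%s tracer), converged: %s%s\n",
              x$condition, x$tracer$element, x$converged,
              if (x$multimodal) " [multimodal]" else ""))
  cat(sprintf("chi-square %.2f on %d dof, acceptance region (%.1f, %.1f) at alpha %.2f: %s\n",
              x$chi_square, x$dof, x$acceptance_region[1], x$acceptance_region[2],
              x$alpha,
              if (x$chi_square >= x$acceptance_region[1] &&
                  x$chi_square <= x$acceptance_region[2]) "accepted" else "rejected"))
  cat(sprintf("free fluxes (spanning set for dof): %s\n",
              paste(x$spanning_set, collapse = ", ")))
  print(transform(x$fluxes, estimate = signif(estimate, 4),
                  se = signif(se, 3), lower = signif(lower, 4),
                  upper = signif(upper, 4)), row.names = FALSE)
  invisible(x)
}

#' Chi-square goodness of fit
#'
#' @param residuals vector of weighted residuals at the optimum.
#' @param n_params number of fitted parameters.
#' @param alpha significance level; the acceptance region is the central
#'   `1 - alpha` interval of the chi-square distribution with
#'   `length(residuals) - n_params` degrees of freedom.
#' @return list with `statistic`, `dof`, `acceptance_region`, `accepted`.
#' @export
chi_square_gof <- function(residuals, n_params, alpha = 0.05) {
  dof <- length(residuals) - n_params
  if (dof <= 0) stop("invalid-argument: degrees of freedom must be >= 1")
  stat <- sum(residuals^2)
  region <- stats::qchisq(c(alpha / 2, 1 - alpha / 2), df = dof)
  list(statistic = stat, dof = dof, acceptance_region = region,
       accepted = stat >= region[1] && stat <= region[2])
}

#' Confidence intervals from a flux fit
#'
#' Normal-approximation intervals `estimate +/- z(level) * se`, with
#' standard errors from the linearized covariance `(J'J)^-1` at the
#' optimum (observation sds treated as known, so the residual scale is
#' fixed at 1). Unidentifiable directions (singular normal matrix) give
#' infinite intervals with `identifiable = FALSE`.
#'
#' @param fit a [fit_fluxes()] result.
#' @param level confidence level (default 0.95).
#' @return data frame with parameter, estimate, se, lower, upper,
#'   identifiable.
#' @export
confidence_intervals <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "flux_fit"))
  if (!fit$converged) stop("invalid-argument: fit did not converge")
  z <- stats::qnorm((1 + level) / 2)
  data.frame(parameter = names(fit$theta),
             estimate = as.numeric(fit$theta), se = as.numeric(fit$se),
             lower = as.numeric(fit$theta - z * fit$se),
             upper = as.numeric(fit$theta + z * fit$se),
             identifiable = is.finite(fit$se), stringsAsFactors = FALSE)
}

#' Methionine synthase flux by mass balance
#'
#' Methionine consumed for methylation and protein synthesis must equal
#' methionine uptake plus synthesis via methionine synthase, so
#' `MTR = methylation_net + protsyn - met_uptake`, floored at zero with
#' a flag when the balance goes negative.
#'
#' @param methylation_net net methylation flux (fmol/cell/h).
#' @param protsyn protein synthesis methionine demand (fmol/cell/h).
#' @param met_uptake net methionine uptake (fmol/cell/h, >= 0).
#' @return list with `flux` and `floored`.
#' @export
mtr_flux_by_mass_balance <- function(methylation_net, protsyn, met_uptake) {
  if (!all(is.finite(c(methylation_net, protsyn, met_uptake)))) {
    stop("invalid-argument: inputs must be finite")
  }
  if (met_uptake < 0) stop("invalid-argument: met_uptake must be >= 0")
  v <- methylation_net + protsyn - met_uptake
  list(flux = max(v, 0), floored = v < 0)
}

#' Linearized parameter covariance of a weighted least-squares problem
#'
#' Covariance of the parameters by linear approximation at the optimum:
#' `(J'J)^-1` with J the Jacobian of the weighted residual vector
#' (observation sds treated as known, so the residual scale is 1). A
#' singular normal matrix is pseudo-inverted and the parameters spanning
#' its null space are flagged unidentifiable (infinite standard error).
#'
#' @param residual_fn function mapping a parameter vector to weighted
#'   residuals.
#' @param theta parameter vector at the optimum.
#' @return list with `cov`, `se`, `unidentifiable` (logical) and
#'   `jacobian`.
#' @export
linearized_covariance <- function(residual_fn, theta) {
  J <- pracma::jacobian(residual_fn, theta)
  JtJ <- crossprod(J)
  p <- length(theta)
  # rank detection on the scaled (correlation-form) normal matrix, so
  # parameters on very different scales do not mask each other
  d <- sqrt(pmax(diag(JtJ), 0))
  unident <- d <= max(d) * 1e-12
  cov_theta <- matrix(NA_real_, p, p, dimnames = list(names(theta), names(theta)))
  act <- which(!unident)
  if (length(act)) {
    S <- JtJ[act, act, drop = FALSE] / tcrossprod(d[act])
    sv <- svd(S)
    rank_def <- sv$d < max(sv$d) * 1e-10
    if (any(rank_def)) {
      null_vecs <- sv$v[, rank_def, drop = FALSE]
      unident[act[rowSums(abs(null_vecs)) > 1e-6]] <- TRUE
      d_inv <- ifelse(rank_def, 0, 1 / sv$d)
      S_inv <- sv$v %*% diag(d_inv, length(sv$d)) %*% t(sv$u)
    } else {
      S_inv <- chol2inv(chol(S))
    }
    cov_theta[act, act] <- S_inv / tcrossprod(d[act])
  }
  cov_theta[is.na(cov_theta)] <- 0
  se <- sqrt(pmax(diag(cov_theta), 0))
  se[unident] <- Inf
  list(cov = cov_theta, se = se, unidentifiable = unident, jacobian = J)
}

#' Well-determined fluxes of a fit
#'
#' Returns the reactions whose linearized relative standard error is
#' below `rel_se_max`: the subset of fluxes the data actually pin down.
#' Structurally zero fluxes (estimate and se both zero, e.g. an uptake
#' absent from the condition) are excluded.
#'
#' @param fit a [fit_fluxes()] result.
#' @param rel_se_max maximum relative standard error (default 0.3).
#' @return character vector of reaction names.
#' @export
identifiable_fluxes <- function(fit, rel_se_max = 0.3) {
  stopifnot(inherits(fit, "flux_fit"))
  f <- fit$fluxes
  keep <- is.finite(f$se) & !(f$estimate == 0 & f$se == 0) &
    f$se <= rel_se_max * abs(f$estimate)
  f$reaction[keep]
}

#' SAM turnover half-life implied by a fit
#'
#' `t_half = ln(2) * C_sam / v_MAT`, reported in minutes.
#'
#' @param fit a [fit_fluxes()] result.
#' @return half-life in minutes.
#' @export
sam_half_life <- function(fit) {
  stopifnot(inherits(fit, "flux_fit"))
  c_sam <- fit$pool_sizes$estimate[fit$pool_sizes$pool == "sam"]
  v_mat <- fit$fluxes$estimate[fit$fluxes$reaction == "MAT"]
  if (!length(c_sam) || !length(v_mat)) stop("key-not-found: sam pool or MAT flux")
  log(2) * c_sam / v_mat * 60
}

# run code with a local, restored RNG state
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
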