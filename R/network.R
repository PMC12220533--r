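#' Compartmental model of methionine-cycle labeling kinetics
#'
#' The methionine network is represented as a single compartmental
#' system: each metabolite pool is a mixture of "light" (unlabeled) and
#' "heavy" (carrying the intact labeled moiety) forms, and the state of
#' pool i is its heavy fraction x_i. With constant fluxes v_j
#' (fmol/cell/h) and pool sizes C_i (fmol/cell), labeling follows
#' \deqn{dx_i/dt = \sum_{j \in in(i)} (v_j / C_i) (x_{src(j)} - x_i)}
#' where boundary pools (medium tracer) have fixed enrichment. Reactions
#' that destroy the labeled moiety (methionine synthase under the
#' uniformly carbon-13-labeled methionine tracer, whose product carries
#' only four of five labeled carbons) inject enrichment 0.
#'
#' @name methionine_network
NULL

.MET_PLUS <- "met_plus"
.MET_MINUS <- "met_minus_hcys_plus"

#' Names of the free fluxes for a culture condition
#'
#' The spanning set is chosen so every dependent flux is a nonnegative
#' linear combination of free fluxes: steady-state balance then holds by
#' construction for any admissible free vector.
#'
#' @param condition `"met_plus"` or `"met_minus_hcys_plus"`.
#' @return character vector of free flux names.
#' @export
free_flux_names <- function(condition = c("met_plus", "met_minus_hcys_plus")) {
  condition <- match.arg(condition)
  if (condition == .MET_PLUS) {
    c("MTR", "CYSTS", "HCYS_release", "AHCY_rev", "PROTSYN", "MET_release")
  } else {
    c("MAT", "AHCY_rev", "CYSTS", "HCYS_release", "PROTSYN", "MET_release")
  }
}

#' Complete a free flux vector to the full balanced flux vector
#'
#' Dependent fluxes are derived from steady-state mass balance of every
#' interior pool. In methionine-containing medium there is no
#' homocysteine influx, and homocysteine produced by methylation leaves
#' via remethylation (MTR), transsulfuration (CYSTS) or release, so
#' `MAT = MTR + CYSTS + HCYS_release`. In methionine-free homocysteine
#' medium methionine uptake is zero, so methionine consumed for
#' methylation and protein synthesis (and release) must equal synthesis
#' via MTR: `MTR = MAT + PROTSYN + MET_release`.
#'
#' @param free named numeric vector over [free_flux_names()].
#' @param condition culture condition.
#' @return named numeric vector over all reactions.
#' @export
complete_fluxes <- function(free, condition = c("met_plus", "met_minus_hcys_plus")) {
  condition <- match.arg(condition)
  need <- free_flux_names(condition)
  if (!all(need %in% names(free))) {
    stop(sprintf("invalid-argument: free fluxes must include %s",
                 paste(setdiff(need, names(free)), collapse = ", ")))
  }
  if (any(!is.finite(free[need])) || any(free[need] < 0)) {
    stop("invalid-argument: free fluxes must be finite and >= 0")
  }
  f <- as.list(free[need])
  if (condition == .MET_PLUS) {
    MAT <- f$MTR + f$CYSTS + f$HCYS_release
    full <- c(
      MET_uptake = f$CYSTS + f$HCYS_release + f$PROTSYN + f$MET_release,
      MET_release = f$MET_release,
      HCYS_uptake = 0,
      HCYS_release = f$HCYS_release,
      MAT = MAT,
      METHYLATION = MAT,
      AHCY_fwd = MAT + f$AHCY_rev,
      AHCY_rev = f$AHCY_rev,
      MTR = f$MTR,
      CYSTS = f$CYSTS,
      PROTSYN = f$PROTSYN,
      CYST_efflux = f$CYSTS
    )
  } else {
    MTR <- f$MAT + f$PROTSYN + f$MET_release
    full <- c(
      MET_uptake = 0,
      MET_release = f$MET_release,
      HCYS_uptake = f$PROTSYN + f$MET_release + f$CYSTS + f$HCYS_release,
      HCYS_release = f$HCYS_release,
      MAT = f$MAT,
      METHYLATION = f$MAT,
      AHCY_fwd = f$MAT + f$AHCY_rev,
      AHCY_rev = f$AHCY_rev,
      MTR = MTR,
      CYSTS = f$CYSTS,
      PROTSYN = f$PROTSYN,
      CYST_efflux = f$CYSTS
    )
  }
  full
}

.reaction_table <- function(tracer_element) {
  # substrate NA = boundary influx source handled via 'from'; product NA = efflux
  rt <- data.frame(
    name = c("MET_uptake", "MET_release", "HCYS_uptake", "HCYS_release",
             "MAT", "METHYLATION", "AHCY_fwd", "AHCY_rev", "MTR", "CYSTS",
             "PROTSYN", "CYST_efflux"),
    from = c("medium_met", "met", "medium_hcys", "hcys",
             "met", "sam", "sah", "hcys", "hcys", "hcys",
             "met", "cyst"),
    to = c("met", "medium_met", "hcys", "medium_hcys",
           "sam", "sah", "hcys", "sah", "met", "cyst",
           "metp", NA),
    transmits = TRUE,
    stringsAsFactors = FALSE
  )
  if (tracer_element == "C13") {
    # MTR product is four-labeled-carbon methionine, not the tracked
    # five-carbon isotopomer: the labeled moiety is destroyed.
    rt$transmits[rt$name == "MTR"] <- FALSE
  } else {
    # deuterated moiety survives transsulfuration into alpha-ketobutyrate
    rt$to[rt$name == "CYST_efflux"] <- "akb"
    rt <- rbind(rt, data.frame(name = "AKB_efflux", from = "akb", to = NA,
                               transmits = TRUE, stringsAsFactors = FALSE))
  }
  rt
}

#' Build the methionine-cycle network model
#'
#' Constructs the full network for a culture condition and tracer:
#' interior pools met, sam, sah, hcys, cyst (plus akb under the
#' deuterated homocysteine tracer), the protein-bound methionine sink
#' metp, and boundary medium pools. The tracer medium pool is held at
#' fixed enrichment equal to the tracer atom purity. Protein-bound
#' methionine accumulates with exponential growth, which reduces to a
#' fixed pool of size `PROTSYN / growth_rate` turning over at rate mu.
#'
#' @param condition `"met_plus"` (100 uM methionine medium) or
#'   `"met_minus_hcys_plus"` (methionine-free, 100 uM homocysteine).
#' @param tracer a [tracer_spec]; carbon-13 methionine for `met_plus`,
#'   deuterated homocysteine for `met_minus_hcys_plus`.
#' @param pools_fmol named vector of interior pool sizes (fmol/cell):
#'   met, sam, sah, hcys, cyst, and akb for the deuterated tracer.
#' @param fluxes either a named free-flux vector over
#'   [free_flux_names()] or a full flux vector (validated for balance).
#' @param growth_rate specific growth rate mu (1/h), used for the
#'   protein-bound methionine sink.
#' @return object of class `network_model`.
#' @export
build_model <- function(condition = c("met_plus", "met_minus_hcys_plus"),
                        tracer, pools_fmol, fluxes, growth_rate) {
  condition <- match.arg(condition)
  stopifnot(inherits(tracer, "tracer_spec"))
  rt <- .reaction_table(tracer$element)
  need_pools <- c("met", "sam", "sah", "hcys", "cyst",
                  if (tracer$element == "H2") "akb")
  if (!all(need_pools %in% names(pools_fmol))) {
    stop(sprintf("invalid-argument: pools_fmol must include %s",
                 paste(setdiff(need_pools, names(pools_fmol)), collapse = ", ")))
  }
  if (any(pools_fmol[need_pools] <= 0) || any(!is.finite(pools_fmol[need_pools]))) {
    stop("invalid-argument: interior pool sizes must be positive")
  }
  if (!is.finite(growth_rate) || growth_rate <= 0) {
    stop("invalid-argument: growth_rate must be > 0")
  }

  if (all(free_flux_names(condition) %in% names(fluxes)) &&
      !all(rt$name %in% names(fluxes))) {
    full <- complete_fluxes(fluxes, condition)
  } else {
    if (!all(setdiff(rt$name, "AKB_efflux") %in% names(fluxes))) {
      stop("invalid-argument: fluxes must be a free or full flux vector")
    }
    full <- fluxes
  }
  if (tracer$element == "H2" && !"AKB_efflux" %in% names(full)) {
    full <- c(full, AKB_efflux = unname(full[["CYSTS"]]))
  }
  full <- full[rt$name]
  if (any(!is.finite(full)) || any(full < -1e-9)) {
    stop("invalid-argument: fluxes must be finite and >= 0")
  }

  # stoichiometric balance of every interior pool
  for (p in need_pools) {
    inflow <- sum(full[rt$name[!is.na(rt$to) & rt$to == p]])
    outflow <- sum(full[rt$name[rt$from == p]])
    scale <- max(inflow, outflow, 1)
    if (abs(inflow - outflow) > 1e-6 * scale) {
      stop(sprintf(
        "stoichiometry error: pool '%s' unbalanced (inflow %.6g, outflow %.6g)",
        p, inflow, outflow))
    }
  }

  purity <- tracer$purity
  boundary <- c(
    medium_met = if (condition == .MET_PLUS) purity else 0,
    medium_hcys = if (condition == .MET_MINUS) purity else 0
  )
  sizes <- c(pools_fmol[need_pools],
             metp = unname(full[["PROTSYN"]]) / growth_rate)

  structure(list(
    condition = condition, tracer = tracer,
    pools = sizes, boundary = boundary,
    reactions = rt, fluxes = full, growth_rate = growth_rate,
    moiety_map = moiety_map(tracer)
  ), class = "network_model")
}

#' @export
print.network_model <- function(x, ...) {
  cat(sprintf("<network_model> %s, %s tracer (purity %.3f)\n",
              x$condition, x$tracer$element, x$tracer$purity))
  cat("pools (fmol/cell):\n")
  print(signif(x$pools, 4))
  cat("fluxes (fmol/cell/h):\n")
  print(signif(x$fluxes, 4))
  invisible(x)
}

# Linear system dx/dt = A x + b over interior pools (per hour).
.rate_system <- function(model) {
  pools <- names(model$pools)
  n <- length(pools)
  A <- matrix(0, n, n, dimnames = list(pools, pools))
  b <- stats::setNames(numeric(n), pools)
  rt <- model$reactions
  for (k in seq_len(nrow(rt))) {
    v <- model$fluxes[[rt$name[k]]]
    if (v <= 0) next
    to <- rt$to[k]
    if (is.na(to) || !to %in% pools) next
    Ci <- model$pools[[to]]
    from <- rt$from[k]
    A[to, to] <- A[to, to] - v / Ci
    if (!rt$transmits[k]) next  # inflow at enrichment 0
    if (from %in% pools) {
      A[to, from] <- A[to, from] + v / Ci
    } else {
      b[to] <- b[to] + v / Ci * model$boundary[[from]]
    }
  }
  list(A = A, b = b)
}

#' Simulate labeling dynamics
#'
#' Integrates the heavy-fraction ODE system from initial enrichments
#' (default 0: cells precultured in unlabeled medium, tracer switched on
#' at t = 0). Method `"lsoda"` uses a stiff-capable solver
#' (absolute tolerance 1e-9, relative 1e-6 by default); method
#' `"analytic"` uses the eigendecomposition of the constant-coefficient
#' linear system and is used internally during fitting for speed. The
#' two agree to solver tolerance.
#'
#' @param model a [build_model()] result.
#' @param times_min sorted nonnegative sampling times, minutes.
#' @param x_init named initial heavy fractions per interior pool
#'   (default all 0).
#' @param method `"lsoda"` or `"analytic"`.
#' @param atol,rtol solver tolerances for `"lsoda"`.
#' @return data frame: column `time_min` plus one column per interior
#'   pool with x_i(t) in `[0, 1]`.
#' @export
simulate_labeling <- function(model, times_min, x_init = NULL,
                              method = c("lsoda", "analytic"),
                              atol = 1e-9, rtol = 1e-6) {
  method <- match.arg(method)
  stopifnot(inherits(model, "network_model"))
  times_min <- as.numeric(times_min)
  if (is.unsorted(times_min) || any(times_min < 0)) {
    stop("invalid-argument: times must be sorted and nonnegative")
  }
  pools <- names(model$pools)
  x0 <- stats::setNames(numeric(length(pools)), pools)
  if (!is.null(x_init)) {
    if (any(!names(x_init) %in% pools)) {
      stop("invalid-argument: x_init names must be interior pools")
    }
    if (any(x_init < 0 | x_init > 1)) {
      stop("invalid-argument: x_init must be in [0, 1]")
    }
    x0[names(x_init)] <- x_init
  }
  sys <- .rate_system(model)
  A <- sys$A / 60  # per minute
  b <- sys$b / 60

  run_lsoda <- function() {
    deriv <- function(t, x, parms) list(A %*% x + b)
    tt <- times_min
    prepend <- tt[1] > 0
    if (prepend) tt <- c(0, tt)
    sol <- deSolve::lsoda(y = x0, times = tt, func = deriv, parms = NULL,
                          atol = atol, rtol = rtol)
    m <- as.matrix(sol[, -1, drop = FALSE])
    if (prepend) m <- m[-1, , drop = FALSE]
    m
  }
  out <- if (method == "analytic") {
    # defective or near-singular systems fall back to the stiff solver
    tryCatch(.simulate_analytic(A, b, x0, times_min),
             error = function(e) run_lsoda())
  } else {
    run_lsoda()
  }
  if (any(!is.finite(out))) {
    stop(sprintf("integration-failure: non-finite state (method %s, condition %s)",
                 method, model$condition))
  }
  slack <- 1e-6
  if (any(out < -slack) || any(out > 1 + slack)) {
    stop("integration-failure: heavy fractions left [0, 1] beyond tolerance")
  }
  out <- pmin(pmax(out, 0), 1)
  res <- data.frame(time_min = times_min)
  for (j in seq_along(pools)) res[[pools[j]]] <- out[, j]
  res
}

.simulate_analytic <- function(A, b, x0, times) {
  n <- length(x0)
  out <- matrix(NA_real_, length(times), n,
                dimnames = list(NULL, names(x0)))
  # frozen pools (zero row) evolve nowhere; solve on the active set
  active <- apply(A, 1, function(r) any(r != 0)) | b != 0
  out[] <- rep(x0, each = length(times))
  if (!any(active)) return(out)
  Aa <- A[active, active, drop = FALSE]
  # inactive pools can still feed active ones as constants
  if (any(!active)) {
    ba <- b[active] + A[active, !active, drop = FALSE] %*% x0[!active]
  } else {
    ba <- b[active]
  }
  ba <- as.numeric(ba)
  eg <- eigen(Aa)
  V <- eg$vectors
  lam <- eg$values
  if (rcond(V) < 1e-12 || min(abs(lam)) < 1e-12) {
    stop("analytic-path-unavailable")  # caller falls back to lsoda
  }
  xp <- solve(Aa, -ba)
  z0 <- solve(V, x0[active] - xp)
  for (i in seq_along(times)) {
    xi <- V %*% (exp(lam * times[i]) * z0) + xp
    out[i, active] <- Re(xi)
  }
  out
}

#' Steady-state enrichment of every interior pool
#'
#' Solves the linear balance `0 = sum_j v_j (x_src(j) - x_i)` for the
#' interior pools; this is the t -> infinity limit of
#' [simulate_labeling()].
#'
#' @param model a [build_model()] result.
#' @return named vector of steady-state heavy fractions.
#' @export
steady_state_enrichment <- function(model) {
  sys <- .rate_system(model)
  active <- apply(sys$A, 1, function(r) any(r != 0)) | sys$b != 0
  if (!all(active)) {
    stop(sprintf("unidentifiable: pool(s) %s have no inflow (isolated)",
                 paste(names(model$pools)[!active], collapse = ", ")))
  }
  if (rcond(sys$A) < 1e-14) {
    stop("unidentifiable: singular steady-state system")
  }
  xs <- solve(sys$A, -sys$b)
  stats::setNames(as.numeric(xs), names(model$pools))
}

#' Protein synthesis demand for methionine
#'
#' Methionine incorporation into protein, from cell growth and size:
#' `flux = mu * (protein_density * cell_volume / mean_residue_mass) *
#' met_residue_fraction`. Defaults are configurable physiological
#' constants (mammalian fibroblast scale), not measured values.
#'
#' @param growth_rate specific growth rate, 1/h.
#' @param cell_volume_fl cell volume, fL.
#' @param protein_density_g_l cellular protein density, g/L.
#' @param met_residue_fraction mole fraction of methionine among protein
#'   residues.
#' @param mean_residue_mass mean amino-acid residue mass, g/mol.
#' @return flux in fmol/cell/h.
#' @export
protein_synthesis_flux <- function(growth_rate, cell_volume_fl,
                                   protein_density_g_l = 200,
                                   met_residue_fraction = 0.022,
                                   mean_residue_mass = 110) {
  args <- c(cell_volume_fl, protein_density_g_l, met_residue_fraction,
            mean_residue_mass)
  if (any(!is.finite(c(growth_rate, args))) || any(args <= 0) || growth_rate < 0) {
    stop("invalid-argument: parameters must be positive (growth_rate >= 0)")
  }
  # g/L * fL = 1e-15 g/cell; / (g/mol) = 1e-15 mol = fmol: factors cancel
  growth_rate * protein_density_g_l * cell_volume_fl / mean_residue_mass *
    met_residue_fraction
}

#' Validity diagnostic for the carbon-13 methionine model
#'
#' The single-isotopomer assumption would break if four-labeled-carbon
#' methionine produced by remethylation of labeled homocysteine were
#' substantial. This reports the predicted production rate of that
#' species (MTR flux times steady-state homocysteine enrichment)
#' relative to the methionine influx.
#'
#' @param model a carbon-13 `met_plus` [build_model()] result.
#' @return list with `rate_m4` (fmol/cell/h), `met_influx` and `ratio`.
#' @export
c13_m4_production_check <- function(model) {
  stopifnot(inherits(model, "network_model"))
  if (model$tracer$element != "C13") {
    stop("invalid-argument: diagnostic applies to the carbon-13 tracer model")
  }
  xs <- steady_state_enrichment(model)
  rate <- model$fluxes[["MTR"]] * xs[["hcys"]]
  influx <- model$fluxes[["MET_uptake"]]
  list(rate_m4 = rate, met_influx = influx,
       ratio = if (influx > 0) rate / influx else Inf)
}
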