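# Independent oracles used across the suite. These deliberately avoid the
# package's own solution paths: the ODE oracle uses Matrix::expm on a rate
# matrix assembled from the edge list here, and the mixture oracle is a
# brute-force grid search.

# Random balanced network: a boundary pool feeding a chain of n interior
# pools with random cross-edges; every imbalance is repaired with an
# explicit influx or efflux so steady-state balance holds by construction.
random_balanced_network <- function(n_pools = 5, seed = 1,
                                    boundary_enrichment = 1) {
  set.seed(seed)
  pools <- paste0("P", seq_len(n_pools))
  sizes <- stats::setNames(stats::runif(n_pools, 0.5, 2), pools)
  edges <- data.frame(
    name = character(0), from = character(0), to = character(0),
    flux = numeric(0), stringsAsFactors = FALSE)
  add <- function(from, to, flux) {
    edges <<- rbind(edges, data.frame(
      name = sprintf("e%d", nrow(edges) + 1L), from = from, to = to,
      flux = flux, stringsAsFactors = FALSE))
  }
  add("B", pools[1], stats::runif(1, 0.5, 2))
  for (i in seq_len(n_pools - 1)) {
    add(pools[i], pools[i + 1], stats::runif(1, 0.2, 1.5))
  }
  if (n_pools >= 3) {
    n_cross <- sample(1:2, 1)
    for (k in seq_len(n_cross)) {
      ij <- sort(sample(n_pools, 2))
      add(pools[ij[1]], pools[ij[2]], stats::runif(1, 0.05, 0.5))
    }
  }
  # repair balance with boundary influx / efflux
  for (p in pools) {
    inflow <- sum(edges$flux[edges$to == p & !is.na(edges$to)])
    outflow <- sum(edges$flux[edges$from == p])
    if (inflow > outflow + 1e-12) {
      add(p, NA, inflow - outflow)
    } else if (outflow > inflow + 1e-12) {
      add("B", p, outflow - inflow)
    }
  }
  edges$transmits <- TRUE
  structure(list(
    condition = "synthetic_test", tracer = NULL,
    pools = sizes, boundary = c(B = boundary_enrichment),
    reactions = edges[, c("name", "from", "to", "transmits")],
    fluxes = stats::setNames(edges$flux, edges$name),
    growth_rate = NA, moiety_map = NULL
  ), class = "network_model")
}

# rate matrix assembled independently from the edge list (per minute)
oracle_rate_matrix <- function(net) {
  pools <- names(net$pools)
  n <- length(pools)
  A <- matrix(0, n, n, dimnames = list(pools, pools))
  b <- stats::setNames(numeric(n), pools)
  ed <- net$reactions
  for (k in seq_len(nrow(ed))) {
    v <- net$fluxes[[ed$name[k]]]
    to <- ed$to[k]
    if (is.na(to) || !(to %in% pools) || v <= 0) next
    Ci <- net$pools[[to]]
    A[to, to] <- A[to, to] - v / Ci
    if (ed$from[k] %in% pools) {
      A[to, ed$from[k]] <- A[to, ed$from[k]] + v / Ci
    } else {
      b[to] <- b[to] + v / Ci * net$boundary[[ed$from[k]]]
    }
  }
  list(A = A / 60, b = b / 60)
}

# matrix-exponential solution of dx/dt = A x + b from x0
oracle_expm_solution <- function(net, times_min, x0 = NULL) {
  sys <- oracle_rate_matrix(net)
  pools <- names(net$pools)
  if (is.null(x0)) x0 <- stats::setNames(numeric(length(pools)), pools)
  xp <- solve(sys$A, -sys$b)
  out <- matrix(NA_real_, length(times_min), length(pools),
                dimnames = list(NULL, pools))
  for (i in seq_along(times_min)) {
    E <- as.matrix(Matrix::expm(sys$A * times_min[i]))
    out[i, ] <- as.numeric(E %*% (x0 - xp) + xp)
  }
  out
}

# brute-force 1-D grid minimizer for the mixture model
oracle_grid_heavy_fraction <- function(measured, y0, y1, step = 1e-4) {
  grid <- seq(0, 1, by = step)
  sse <- vapply(grid, function(x) {
    sum((measured - ((1 - x) * y0 + x * y1))^2)
  }, numeric(1))
  grid[which.min(sse)]
}

# assemble a bare network-model structure for hand-built test systems
make_net <- function(pools, boundary, reactions, fluxes) {
  structure(list(condition = "synthetic_test", tracer = NULL,
                 pools = pools, boundary = boundary,
                 reactions = reactions, fluxes = fluxes,
                 growth_rate = NA, moiety_map = NULL),
            class = "network_model")
}

# shared synthetic fixtures (kept small; regenerated per session)
syn_truths <- function() default_ground_truths()
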