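#' Synthetic tracing experiments with known ground truth
#'
#' Generates complete synthetic isotope-tracing experiments — peak-area
#' MID tables, spiked abundance tables, cell counts — from a ground
#' truth (fluxes, pool sizes, tracer, growth, noise model, seed), so the
#' whole pipeline can be validated without any external data. The
#' generator simulates labeling with the compartmental model, converts
#' heavy fractions to full MIDs by mixing the binomial references,
#' applies the forward isotope-dilution mixing for extract and medium
#' standards, grows cell counts exponentially, and adds seeded Gaussian
#' noise. The same seed yields byte-identical tables.
#'
#' @name synthetic_data
NULL

#' Construct a ground truth for a synthetic experiment
#'
#' @param cell_line label written into the tables.
#' @param condition culture condition, see [build_model()].
#' @param free_fluxes named free-flux vector over [free_flux_names()]
#'   (fmol/cell/h).
#' @param pools_uM named intracellular concentrations (uM) for met, sam,
#'   sah, hcys, cyst (and akb for the deuterated tracer).
#' @param mean_diameter_um mean cell diameter.
#' @param doubling_time_h culture doubling time.
#' @param cell_count_final cell count at the end of the tracing window.
#' @param duration_h tracing window (default 24 h).
#' @param medium_volume_ml culture medium volume.
#' @param baseline_medium_uM named baseline medium concentrations (uM)
#'   for met and hcys.
#' @param noise list: `x1_sd` (heavy-fraction scale sd of labeling
#'   measurements), `xmix_sd_extract` and `xmix_sd_medium` (sd of the
#'   measured mixture heavy fraction in spiked extract/medium samples).
#' @param times_min labeling sampling grid (default 5, 15, 30 min and
#'   1, 5, 24 h).
#' @return object of class `ground_truth`.
#' @export
ground_truth <- function(cell_line, condition, free_fluxes, pools_uM,
                         mean_diameter_um, doubling_time_h,
                         cell_count_final, duration_h = 24,
                         medium_volume_ml = 1,
                         baseline_medium_uM = c(met = 100, hcys = 0),
                         noise = list(x1_sd = 0.02, xmix_sd_extract = 0.01,
                                      xmix_sd_medium = 0.002),
                         times_min = c(5, 15, 30, 60, 300, 1440)) {
  condition <- match.arg(condition, c("met_plus", "met_minus_hcys_plus"))
  tracer <- if (condition == "met_plus") {
    tracer_spec("C13", n_atoms = 5, purity = 0.99)
  } else {
    tracer_spec("H2", n_atoms = 4, purity = 0.996)
  }
  mu <- log(2) / doubling_time_h
  v_fl <- cell_volume_fl(mean_diameter_um)
  pools_fmol <- pools_uM * v_fl / 1e6
  # validates balance and positivity
  model <- build_model(condition, tracer, pools_fmol, free_fluxes, mu)
  structure(list(
    cell_line = cell_line, condition = condition, tracer = tracer,
    free_fluxes = free_fluxes[free_flux_names(condition)],
    fluxes = model$fluxes, pools_uM = pools_uM, pools_fmol = pools_fmol,
    mean_diameter_um = mean_diameter_um, cell_volume_fl = v_fl,
    growth_rate = mu, doubling_time_h = doubling_time_h,
    cell_count_final = cell_count_final,
    cell_count_initial = cell_count_final / 2^(duration_h / doubling_time_h),
    duration_h = duration_h, medium_volume_ml = medium_volume_ml,
    baseline_medium_uM = baseline_medium_uM, noise = noise,
    times_min = times_min
  ), class = "ground_truth")
}

#' Bundled synthetic study conditions
#'
#' Four synthetic cell-line/condition fixtures emulating the qualitative
#' regimes of methionine-dependent and -independent fibroblasts: in
#' methionine medium, fast transport exchange (intracellular methionine
#' labeled within minutes), SAM turnover half-life near 15 min, and a
#' SAM:SAH ratio around 40; in methionine-free homocysteine medium,
#' strongly reduced MAT flux, elevated AHCY reverse (exchange) flux,
#' homocysteine accumulation to medium levels and a SAM:SAH ratio near
#' 2. These are fixture choices on the physiological scale of cultured
#' fibroblasts, not measured values. Names carry a `syn_` prefix to mark
#' them as synthetic.
#'
#' @return named list of [ground_truth()] objects.
#' @export
default_ground_truths <- function() {
  list(
    syn_tert_met_plus = ground_truth(
      cell_line = "syn_tert", condition = "met_plus",
      free_fluxes = c(MTR = 0.26, CYSTS = 0.02, HCYS_release = 0.05,
                      AHCY_rev = 0.05, PROTSYN = 2.30, MET_release = 27),
      pools_uM = c(met = 500, sam = 60, sah = 1.5, hcys = 1, cyst = 5),
      mean_diameter_um = 15.6, doubling_time_h = 24,
      cell_count_final = 3.17e5,
      baseline_medium_uM = c(met = 100, hcys = 0)),
    syn_ras_met_plus = ground_truth(
      cell_line = "syn_ras", condition = "met_plus",
      free_fluxes = c(MTR = 0.43, CYSTS = 0.03, HCYS_release = 0.09,
                      AHCY_rev = 0.08, PROTSYN = 2.50, MET_release = 30),
      pools_uM = c(met = 450, sam = 100, sah = 2.5, hcys = 1, cyst = 5),
      mean_diameter_um = 15.6, doubling_time_h = 22,
      cell_count_final = 2.52e5,
      baseline_medium_uM = c(met = 100, hcys = 0)),
    syn_tert_met_minus = ground_truth(
      cell_line = "syn_tert", condition = "met_minus_hcys_plus",
      free_fluxes = c(MAT = 0.022, AHCY_rev = 1.2, CYSTS = 0.02,
                      HCYS_release = 0.10, PROTSYN = 1.84, MET_release = 0.02),
      pools_uM = c(met = 5, sam = 12, sah = 6, hcys = 100, cyst = 8, akb = 2),
      mean_diameter_um = 15.6, doubling_time_h = 30,
      cell_count_final = 3.80e5,
      baseline_medium_uM = c(met = 0, hcys = 100)),
    syn_ras_met_minus = ground_truth(
      cell_line = "syn_ras", condition = "met_minus_hcys_plus",
      free_fluxes = c(MAT = 0.012, AHCY_rev = 1.5, CYSTS = 0.015,
                      HCYS_release = 0.08, PROTSYN = 0.92, MET_release = 0.01),
      pools_uM = c(met = 4, sam = 8, sah = 5, hcys = 110, cyst = 8, akb = 2),
      mean_diameter_um = 15.6, doubling_time_h = 60,
      cell_count_final = 3.14e5,
      baseline_medium_uM = c(met = 0, hcys = 100))
  )
}

# standard spike amounts: matched to the expected analyte scale so the
# mixture heavy fraction is maximally informative
.spike_amounts <- function(truth) {
  n_cells <- truth$cell_count_final
  extract <- signif(truth$pools_fmol * n_cells, 1)
  medium <- pmax(truth$baseline_medium_uM, 10) * truth$medium_volume_ml * 1e6
  list(extract = extract, medium = medium)
}

#' Generate one complete synthetic tracing experiment
#'
#' @param truth a [ground_truth()].
#' @param seed integer seed; fully determines all outputs.
#' @return list of data frames: `mid_table` (peak areas per mass shift),
#'   `abundance_table` (spiked extract/medium/baseline samples),
#'   `cells_table` (counts, diameter, volumes), plus `truth` and the
#'   noiseless `labeling` simulation.
#' @export
generate_experiment <- function(truth, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  .with_seed(seed, {
    tr <- truth$tracer
    model <- build_model(truth$condition, tr, truth$pools_fmol,
                         truth$free_fluxes, truth$growth_rate)
    sim <- simulate_labeling(model, truth$times_min)
    measured <- c("met", "sam", "sah", "hcys", "cyst")
    map <- moiety_map(tr)

    # --- MID peak-area table ---------------------------------------
    mid_rows <- list()
    for (m in measured) {
      n_at <- map[[m]]
      y0 <- natural_abundance_mid(n_at, tr$natural_abundance)$fractions
      y1 <- tracer_mid(n_at, tr$purity)$fractions
      for (i in seq_along(truth$times_min)) {
        # measurement error acts on the heavy-fraction scale: perturb x1,
        # rebuild the mixture MID, and add small channel-level jitter
        x1 <- min(max(sim[[m]][i] + stats::rnorm(1, 0, truth$noise$x1_sd), 0), 1)
        frac <- (1 - x1) * y0 + x1 * y1
        total <- 1e6 * exp(stats::rnorm(1, 0, 0.1))
        areas <- pmax(frac + stats::rnorm(length(frac), 0,
                                          truth$noise$area_sd %||% 0.002),
                      0) * total
        mid_rows[[length(mid_rows) + 1L]] <- data.frame(
          condition = truth$condition, cell_line = truth$cell_line,
          metabolite = m, time_min = truth$times_min[i],
          mass_shift = 0:n_at, peak_area = areas,
          stringsAsFactors = FALSE)
      }
    }
    mid_table <- do.call(rbind, mid_rows)

    # --- spiked abundance table ------------------------------------
    spikes <- .spike_amounts(truth)
    n_cells <- truth$cell_count_final
    i_final <- length(truth$times_min)
    ab_rows <- list()
    add_row <- function(sample_type, metabolite, n_true, x_sample, n_std, sd) {
      x_mix <- (n_true * x_sample) / (n_true + n_std)
      x_mix <- min(max(x_mix + stats::rnorm(1, 0, sd), 0), 1)
      ab_rows[[length(ab_rows) + 1L]] <<- data.frame(
        condition = truth$condition, cell_line = truth$cell_line,
        sample_type = sample_type, metabolite = metabolite,
        x_mix = x_mix, x_mix_sd = sd, x_sample = x_sample,
        n_std_fmol = n_std, x_std = 0, stringsAsFactors = FALSE)
    }
    for (m in measured) {
      add_row("extract", m, truth$pools_fmol[[m]] * n_cells,
              sim[[m]][i_final], spikes$extract[[m]],
              truth$noise$xmix_sd_extract)
    }
    ch <- cell_hours(truth$cell_count_initial, truth$cell_count_final,
                     truth$duration_h)
    fl <- truth$fluxes
    net_release <- c(met = fl[["MET_release"]] - fl[["MET_uptake"]],
                     hcys = fl[["HCYS_release"]] - fl[["HCYS_uptake"]])
    # medium heavy fraction: the tracer species sits at the boundary
    # enrichment; the released species carries the final intracellular
    # enrichment (a small, late contribution)
    x_medium <- c(met = if (truth$condition == "met_plus") tr$purity
                        else sim$met[i_final],
                  hcys = if (truth$condition == "met_plus") sim$hcys[i_final]
                         else tr$purity)
    for (m in c("met", "hcys")) {
      n_base <- truth$baseline_medium_uM[[m]] * truth$medium_volume_ml * 1e6
      n_spent <- n_base + net_release[[m]] * ch
      if (n_base > 0) {
        add_row("baseline_medium", m, n_base, x_medium[[m]],
                spikes$medium[[m]], truth$noise$xmix_sd_medium)
      }
      if (n_spent > 0) {
        add_row("medium", m, n_spent, x_medium[[m]],
                spikes$medium[[m]], truth$noise$xmix_sd_medium)
      }
    }
    abundance_table <- do.call(rbind, ab_rows)

    cells_table <- data.frame(
      condition = truth$condition, cell_line = truth$cell_line,
      cell_count_t0 = truth$cell_count_initial,
      cell_count_t = truth$cell_count_final,
      duration_h = truth$duration_h,
      mean_diameter_um = truth$mean_diameter_um,
      medium_volume_ml = truth$medium_volume_ml,
      stringsAsFactors = FALSE)

    list(mid_table = mid_table, abundance_table = abundance_table,
         cells_table = cells_table, truth = truth, labeling = sim,
         seed = seed)
  })
}

#' Generate a noisy exponential growth curve
#'
#' @param n0 seeded cell count.
#' @param doubling_time_h doubling time in hours.
#' @param days number of daily counts after seeding.
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   count noise.
#' @param seed integer seed.
#' @return data frame with `time_h` and `count`.
#' @export
generate_growth_curves <- function(n0, doubling_time_h, days, noise_cv = 0,
                                   seed = 1L) {
  if (any(c(n0, doubling_time_h, days) <= 0)) {
    stop("invalid-argument: all parameters must be positive")
  }
  .with_seed(seed, {
    t_h <- 24 * seq_len(days)
    mu <- log(2) / doubling_time_h
    counts <- n0 * exp(mu * t_h)
    if (noise_cv > 0) {
      counts <- counts * exp(stats::rnorm(days, 0, noise_cv))
    }
    data.frame(time_h = c(0, t_h), count = c(n0, counts))
  })
}
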