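test_that("the same seed reproduces a byte-identical experiment", {
  truth <- syn_truths()$syn_tert_met_plus
  e1 <- generate_experiment(truth, seed = 7)
  e2 <- generate_experiment(truth, seed = 7)
  expect_identical(e1$mid_table, e2$mid_table)
  expect_identical(e1$abundance_table, e2$abundance_table)
  expect_identical(e1$cells_table, e2$cells_table)
  e3 <- generate_experiment(truth, seed = 8)
  expect_false(identical(e1$mid_table, e3$mid_table))
})

test_that("generated tables are physically valid", {
  for (truth in syn_truths()) {
    e <- generate_experiment(truth, seed = 3)
    expect_true(all(e$mid_table$peak_area >= 0))
    expect_true(all(e$abundance_table$x_mix >= 0 & e$abundance_table$x_mix <= 1))
    expect_true(all(e$abundance_table$n_std_fmol > 0))
    expect_true(all(e$cells_table$cell_count_t0 > 0))
    # condition contract: no methionine baseline row in met-free medium
    base <- e$abundance_table[e$abundance_table$sample_type == "baseline_medium", ]
    if (truth$condition == "met_minus_hcys_plus") {
      expect_false("met" %in% base$metabolite)
      expect_true("hcys" %in% base$metabolite)
    } else {
      expect_true("met" %in% base$metabolite)
    }
  }
})

test_that("ground truths are balanced and regime-faithful", {
  truths <- syn_truths()
  for (truth in truths) {
    # stoichiometric balance holds by construction (build_model validates)
    m <- build_model(truth$condition, truth$tracer, truth$pools_fmol,
                     truth$free_fluxes, truth$growth_rate)
    expect_s3_class(m, "network_model")
  }
  # methionine medium: SAM:SAH ratio high, SAM turnover half-life ~15 min
  for (nm in c("syn_tert_met_plus", "syn_ras_met_plus")) {
    tr <- truths[[nm]]
    expect_gt(tr$pools_uM[["sam"]] / tr$pools_uM[["sah"]], 30)
    t_half <- log(2) * tr$pools_fmol[["sam"]] / tr$fluxes[["MAT"]] * 60
    expect_equal(t_half, 15, tolerance = 0.05)
  }
  # homocysteine medium: ratio collapses, AHCY exchange elevated
  for (nm in c("syn_tert_met_minus", "syn_ras_met_minus")) {
    tr <- truths[[nm]]
    expect_lt(tr$pools_uM[["sam"]] / tr$pools_uM[["sah"]], 5)
    expect_gt(tr$fluxes[["AHCY_rev"]], 10 * tr$fluxes[["METHYLATION"]])
  }
})

test_that("a noise-free experiment inverts through the full pipeline", {
  truth <- syn_truths()$syn_tert_met_plus
  truth$noise <- list(x1_sd = 0, xmix_sd_extract = 1e-6, xmix_sd_medium = 1e-7,
                      area_sd = 0)
  e <- generate_experiment(truth, seed = 5)
  q <- quantify_abundance(e$abundance_table, e$cells_table)
  # quantification recovers pools and rates essentially exactly
  pools <- stats::setNames(q$concentrations$fmol_per_cell,
                           q$concentrations$metabolite)
  expect_equal(pools[names(truth$pools_fmol)[1:5]], truth$pools_fmol[1:5],
               tolerance = 1e-3)
  fit <- run_fit(e$mid_table, q, truth$condition, truth$cell_line,
                 multistart = 3, seed = 2)
  expect_true(fit$converged)
  expect_lt(fit$chi_square, 0.5)
  est <- stats::setNames(fit$fluxes$estimate, fit$fluxes$reaction)
  idf <- identifiable_fluxes(fit)
  expect_true(all(c("MAT", "MTR", "PROTSYN") %in% idf))
  rel <- abs(est[idf] - truth$fluxes[idf]) / truth$fluxes[idf]
  expect_lt(max(rel), 0.02)
})

test_that("growth curves are exact without noise and unbiased with it", {
  g <- generate_growth_curves(1e4, 24, days = 3, noise_cv = 0, seed = 1)
  expect_equal(g$count, 1e4 * c(1, 2, 4, 8))
  expect_identical(generate_growth_curves(5e3, 30, 4, 0.05, seed = 2),
                   generate_growth_curves(5e3, 30, 4, 0.05, seed = 2))
  # doubling time inferred across 100 seeded replicates is unbiased to 1%
  dts <- vapply(1:100, function(s) {
    g <- generate_growth_curves(1e4, 24, days = 4, noise_cv = 0.05, seed = s)
    fit_growth_rate(g$count, g$time_h)$doubling_time
  }, numeric(1))
  expect_lt(abs(mean(dts) - 24) / 24, 0.01)
})

test_that("fitted MTR separates absent from active methionine synthase", {
  # two scenarios built on the methionine-medium fixture: MTR off versus
  # MTR carrying a methylation demand of comparable size to protein
  # synthesis; the fitted mass-balance MTR must separate them cleanly
  base <- syn_truths()$syn_tert_met_plus
  truth_off <- ground_truth(
    cell_line = "syn_off", condition = "met_plus",
    free_fluxes = c(MTR = 0, CYSTS = 0.02, HCYS_release = 0.05,
                    AHCY_rev = 0.05, PROTSYN = 2.30, MET_release = 27),
    pools_uM = base$pools_uM, mean_diameter_um = 15.6,
    doubling_time_h = 24, cell_count_final = 3.17e5)
  truth_on <- ground_truth(
    cell_line = "syn_on", condition = "met_plus",
    free_fluxes = c(MTR = 2.0, CYSTS = 0.02, HCYS_release = 0.05,
                    AHCY_rev = 0.05, PROTSYN = 2.30, MET_release = 27),
    pools_uM = base$pools_uM, mean_diameter_um = 15.6,
    doubling_time_h = 24, cell_count_final = 3.17e5)
  run_one <- function(truth, seed) {
    e <- generate_experiment(truth, seed = seed)
    q <- quantify_abundance(e$abundance_table, e$cells_table)
    fit <- run_fit(e$mid_table, q, truth$condition, truth$cell_line,
                   multistart = 3, seed = seed)
    fit$fluxes[fit$fluxes$reaction == "MTR", c("estimate", "lower", "upper")]
  }
  n_seeds <- 20
  off <- do.call(rbind, lapply(1:n_seeds, function(s) run_one(truth_off, 200 + s)))
  on <- do.call(rbind, lapply(1:n_seeds, function(s) run_one(truth_on, 300 + s)))
  # CIs from the two scenarios never overlap
  expect_lt(max(off$upper), min(on$lower))
})
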