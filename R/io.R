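#' Table readers, writers, configuration and pipeline drivers
#'
#' All tables are comma-separated UTF-8 text with a mandatory header
#' row; times are minutes, concentrations micromolar, amounts
#' femtomoles, fluxes fmol/cell/h. Readers validate every row and
#' report malformed rows with their line numbers; rows are never
#' silently dropped. Every pipeline run writes a manifest (seed,
#' package version, input checksums) sufficient to reproduce its
#' outputs.
#'
#' @name cli_io
NULL

.read_checked <- function(path, required, numeric_cols, what) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0) stop(sprintf("empty input table: %s", path))
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s %s: missing column(s) %s", what, path,
                 paste(missing, collapse = ", ")))
  }
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (any(is.na(df[[col]])) ) bad <- union(bad, which(is.na(df[[col]])))
    if (length(bad)) {
      # +1 for the header row
      stop(sprintf("%s %s: malformed numeric '%s' at line(s) %s", what, path,
                   col, paste(bad + 1L, collapse = ", ")))
    }
    df[[col]] <- vals
  }
  df
}

#' Read a mass-isotopomer peak-area table
#'
#' Long format: one row per condition, cell line, metabolite, time point
#' and mass shift, with the chromatographic peak area.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_mid_table <- function(path) {
  df <- .read_checked(path,
    required = c("condition", "cell_line", "metabolite", "time_min",
                 "mass_shift", "peak_area"),
    numeric_cols = c("time_min", "mass_shift", "peak_area"),
    what = "MID table")
  bad <- which(df$peak_area < 0 | df$mass_shift < 0 |
                 df$mass_shift != round(df$mass_shift))
  if (length(bad)) {
    stop(sprintf("MID table %s: invalid mass_shift/peak_area at line(s) %s",
                 path, paste(bad + 1L, collapse = ", ")))
  }
  df
}

#' Read a spiked abundance table
#'
#' One row per spiked sample: the measured mixture heavy fraction
#' `x_mix` (with its sd), the analyte heavy fraction `x_sample`, and the
#' internal-standard amount and heavy fraction.
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_abundance_table <- function(path) {
  df <- .read_checked(path,
    required = c("condition", "cell_line", "sample_type", "metabolite",
                 "x_mix", "x_mix_sd", "x_sample", "n_std_fmol", "x_std"),
    numeric_cols = c("x_mix", "x_mix_sd", "x_sample", "n_std_fmol", "x_std"),
    what = "abundance table")
  ok_types <- c("extract", "medium", "baseline_medium")
  bad <- which(!df$sample_type %in% ok_types)
  if (length(bad)) {
    stop(sprintf("abundance table %s: unknown sample_type at line(s) %s",
                 path, paste(bad + 1L, collapse = ", ")))
  }
  df
}

#' Read a cell-count / culture table
#'
#' @param path CSV file path.
#' @return validated data frame.
#' @export
read_cells_table <- function(path) {
  df <- .read_checked(path,
    required = c("condition", "cell_line", "cell_count_t0", "cell_count_t",
                 "duration_h", "mean_diameter_um", "medium_volume_ml"),
    numeric_cols = c("cell_count_t0", "cell_count_t", "duration_h",
                     "mean_diameter_um", "medium_volume_ml"),
    what = "cells table")
  bad <- which(df$cell_count_t0 <= 0 | df$cell_count_t <= 0 |
                 df$duration_h <= 0 | df$mean_diameter_um <= 0)
  if (length(bad)) {
    stop(sprintf("cells table %s: nonpositive counts/duration/diameter at line(s) %s",
                 path, paste(bad + 1L, collapse = ", ")))
  }
  df
}

#' Quantify a spiked abundance table
#'
#' Inverts the isotope-dilution mass balance for every sample, converts
#' extract amounts to per-cell amounts and intracellular concentrations
#' and medium amounts to concentrations, and computes net uptake/release
#' rates from spent minus baseline medium. Inversions that hit an error
#' branch are logged and flagged: a mixture within three sds of the
#' standard's heavy fraction is reported as below detection (amount 0),
#' anything else as missing.
#'
#' @param abundance data frame from [read_abundance_table()].
#' @param cells data frame from [read_cells_table()].
#' @param variant dilution-equation variant, see
#'   [isotope_dilution_amount()].
#' @param cytosol_fraction see [cell_volume_fl()].
#' @param protsyn_args list of constants for [protein_synthesis_flux()].
#' @param quiet suppress log messages.
#' @return list with data frames `concentrations` (extract samples:
#'   fmol/cell and uM with sds), `medium` (concentrations in uM),
#'   `rates` (net fmol/cell/h, release positive), `growth` (growth rate,
#'   doubling time, cell-hours, protein synthesis rate), and `log`.
#' @export
quantify_abundance <- function(abundance, cells,
                               variant = c("mass_balance", "as_printed"),
                               cytosol_fraction = 1,
                               protsyn_args = list(), quiet = TRUE) {
  variant <- match.arg(variant)
  log_lines <- character(0)
  note <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    if (!quiet) message(line)
  }

  amounts <- vector("list", nrow(abundance))
  for (i in seq_len(nrow(abundance))) {
    row <- abundance[i, ]
    spike <- standard_spike(row$metabolite, row$n_std_fmol, row$x_std)
    res <- tryCatch({
      n <- isotope_dilution_amount(row$x_mix, row$x_sample, spike,
                                   variant = variant, x_mix_sd = row$x_mix_sd)
      list(n = as.numeric(n), sd = attr(n, "sd"), status = "ok")
    }, error = function(e) {
      if (abs(row$x_mix - row$x_std) <= 3 * row$x_mix_sd) {
        note("row %d (%s %s %s): %s -> below detection, amount set to 0",
             i, row$sample_type, row$cell_line, row$metabolite,
             conditionMessage(e))
        list(n = 0, sd = 3 * row$x_mix_sd * row$n_std_fmol,
             status = "below_detection")
      } else {
        note("row %d (%s %s %s): %s -> missing", i, row$sample_type,
             row$cell_line, row$metabolite, conditionMessage(e))
        list(n = NA_real_, sd = NA_real_, status = "failed")
      }
    })
    amounts[[i]] <- res
  }
  abundance$n_fmol <- vapply(amounts, function(a) a$n, numeric(1))
  abundance$n_sd <- vapply(amounts, function(a) a$sd, numeric(1))
  abundance$status <- vapply(amounts, function(a) a$status, character(1))

  key <- function(df) paste(df$condition, df$cell_line)
  growth_rows <- list(); conc_rows <- list(); med_rows <- list(); rate_rows <- list()
  for (k in unique(key(cells))) {
    cl <- cells[key(cells) == k, ][1, ]
    ab <- abundance[key(abundance) == k, ]
    gr <- doubling_time(cl$cell_count_t0, cl$cell_count_t, cl$duration_h)
    ch <- cell_hours(cl$cell_count_t0, cl$cell_count_t, cl$duration_h)
    v_fl <- cell_volume_fl(cl$mean_diameter_um, cytosol_fraction)
    protsyn <- do.call(protein_synthesis_flux,
                       c(list(growth_rate = gr$growth_rate,
                              cell_volume_fl = v_fl), protsyn_args))
    growth_rows[[k]] <- data.frame(
      condition = cl$condition, cell_line = cl$cell_line,
      growth_rate = gr$growth_rate, doubling_time_h = gr$doubling_time,
      cell_hours = ch, cell_volume_fl = v_fl, protsyn_rate = protsyn,
      protsyn_sd = 0.10 * protsyn, stringsAsFactors = FALSE)

    ex <- ab[ab$sample_type == "extract", ]
    if (nrow(ex)) {
      conc_rows[[k]] <- data.frame(
        condition = ex$condition, cell_line = ex$cell_line,
        metabolite = ex$metabolite,
        fmol_per_cell = ex$n_fmol / cl$cell_count_t,
        sd = ex$n_sd / cl$cell_count_t,
        conc_uM = ex$n_fmol / cl$cell_count_t / v_fl * 1e6,
        status = ex$status, stringsAsFactors = FALSE)
    }

    for (m in unique(ab$metabolite[ab$sample_type %in%
                                   c("medium", "baseline_medium")])) {
      sp <- ab[ab$sample_type == "medium" & ab$metabolite == m, ]
      bl <- ab[ab$sample_type == "baseline_medium" & ab$metabolite == m, ]
      to_uM <- 1 / (cl$medium_volume_ml * 1e6)
      spent <- if (nrow(sp)) sp$n_fmol[1] * to_uM else NA_real_
      spent_sd <- if (nrow(sp)) sp$n_sd[1] * to_uM else NA_real_
      base <- if (nrow(bl)) bl$n_fmol[1] * to_uM else 0
      base_sd <- if (nrow(bl)) bl$n_sd[1] * to_uM else 0
      med_rows[[paste(k, m)]] <- data.frame(
        condition = cl$condition, cell_line = cl$cell_line, metabolite = m,
        baseline_uM = base, baseline_sd = base_sd,
        spent_uM = spent, spent_sd = spent_sd, stringsAsFactors = FALSE)
      if (is.finite(spent)) {
        r <- uptake_release_rate(base, spent, cl$medium_volume_ml, ch,
                                 conc_sd_uM = c(base_sd, spent_sd))
        rate_rows[[paste(k, m)]] <- data.frame(
          condition = cl$condition, cell_line = cl$cell_line, metabolite = m,
          rate = as.numeric(r), sd = attr(r, "sd"), stringsAsFactors = FALSE)
      }
    }
  }
  bind <- function(lst) {
    if (!length(lst)) return(data.frame())
    out <- do.call(rbind, lst); rownames(out) <- NULL; out
  }
  list(concentrations = bind(conc_rows), medium = bind(med_rows),
       rates = bind(rate_rows), growth = bind(growth_rows),
       samples = abundance, log = log_lines)
}

#' Read the bundled (or a user) network/run configuration
#'
#' YAML file with one block per synthetic study condition (cell line,
#' condition, free fluxes, pool concentrations, growth, noise) plus fit
#' options. The bundled default encodes the methionine-cycle topology
#' fixtures for both tracer experiments.
#'
#' @param path YAML path; default the bundled configuration.
#' @return list with `truths` (list of [ground_truth()]) and
#'   `fit_options`.
#' @export
read_run_config <- function(path = system.file("extdata",
                                               "methionine_network.yaml",
                                               package = "methflux")) {
  cfg <- yaml::read_yaml(path)
  truths <- lapply(cfg$experiments, function(e) {
    ground_truth(
      cell_line = e$cell_line, condition = e$condition,
      free_fluxes = unlist(e$free_fluxes), pools_uM = unlist(e$pools_uM),
      mean_diameter_um = e$mean_diameter_um,
      doubling_time_h = e$doubling_time_h,
      cell_count_final = e$cell_count_final,
      medium_volume_ml = e$medium_volume_ml %||% 1,
      baseline_medium_uM = unlist(e$baseline_medium_uM),
      noise = e$noise %||% list(x1_sd = 0.02, xmix_sd_extract = 0.01,
                                xmix_sd_medium = 0.002))
  })
  names(truths) <- vapply(cfg$experiments, function(e)
    paste(e$cell_line, e$condition, sep = "_"), character(1))
  list(truths = truths, fit_options = cfg$fit_options)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate and write a full synthetic experiment bundle
#'
#' Runs [generate_experiment()] for each ground truth and writes the
#' combined MID, abundance and cell tables, the ground-truth JSON and a
#' manifest to `outdir`.
#'
#' @param truths list of [ground_truth()] (default
#'   [default_ground_truths()]).
#' @param outdir output directory (created if needed).
#' @param seed integer seed; per-experiment seeds are derived from it.
#' @return invisibly, the list of generated bundles.
#' @export
run_simulate <- function(truths = default_ground_truths(), outdir,
                         seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  bundles <- lapply(seq_along(truths), function(i) {
    generate_experiment(truths[[i]], seed = seed + i)
  })
  names(bundles) <- names(truths)
  comb <- function(field) {
    out <- do.call(rbind, lapply(bundles, `[[`, field))
    rownames(out) <- NULL
    out
  }
  utils::write.csv(comb("mid_table"), file.path(outdir, "mid_table.csv"),
                   row.names = FALSE)
  utils::write.csv(comb("abundance_table"),
                   file.path(outdir, "abundance_table.csv"), row.names = FALSE)
  utils::write.csv(comb("cells_table"), file.path(outdir, "cells_table.csv"),
                   row.names = FALSE)
  truth_json <- lapply(truths, function(tr) {
    list(cell_line = tr$cell_line, condition = tr$condition,
         fluxes = as.list(tr$fluxes), pools_fmol = as.list(tr$pools_fmol),
         pools_uM = as.list(tr$pools_uM), growth_rate = tr$growth_rate,
         cell_volume_fl = tr$cell_volume_fl, noise = tr$noise)
  })
  jsonlite::write_json(truth_json, file.path(outdir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, seed = seed,
                 files = c("mid_table.csv", "abundance_table.csv",
                           "cells_table.csv", "ground_truth.json"))
  invisible(bundles)
}

#' Quantification driver
#'
#' Reads abundance and cell tables, quantifies them and writes
#' concentration, medium, rate and growth tables plus a manifest.
#'
#' @param abundance_path,cells_path input CSV paths.
#' @param outdir output directory.
#' @param ... passed to [quantify_abundance()].
#' @return invisibly, the [quantify_abundance()] result.
#' @export
run_quantify <- function(abundance_path, cells_path, outdir, ...) {
  ab <- read_abundance_table(abundance_path)
  cl <- read_cells_table(cells_path)
  q <- quantify_abundance(ab, cl, ...)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("concentrations", "medium", "rates", "growth")) {
    utils::write.csv(q[[nm]], file.path(outdir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  writeLines(q$log, file.path(outdir, "quantify.log"))
  write_manifest(outdir, seed = NA,
                 files = c("concentrations.csv", "medium.csv", "rates.csv",
                           "growth.csv"),
                 inputs = c(abundance_path, cells_path))
  invisible(q)
}

#' Assemble a flux-fit observation set from pipeline outputs
#'
#' @param mid_table MID peak-area table (one condition and cell line).
#' @param quant result of [quantify_abundance()] for the same dataset.
#' @param condition,cell_line dataset selectors.
#' @param tracer a [tracer_spec].
#' @param hf_floor heavy-fraction sd floor used for fit weights.
#' @return list with the [observation_set()] and the growth row.
#' @export
assemble_observations <- function(mid_table, quant, condition, cell_line,
                                  tracer, hf_floor = 0.02) {
  sel <- function(df) df[df$condition == condition & df$cell_line == cell_line, ]
  hf <- estimate_heavy_fractions(sel(mid_table), tracer, sd_floor = hf_floor)
  hf <- hf[!hf$missing, c("metabolite", "time_min", "x1", "sd")]
  conc <- sel(quant$concentrations)
  conc <- conc[conc$status == "ok", c("metabolite", "fmol_per_cell", "sd")]
  rates <- sel(quant$rates)[, c("metabolite", "rate", "sd")]
  growth <- sel(quant$growth)
  if (nrow(growth) != 1) stop("key-not-found: dataset not present in growth table")
  obs <- observation_set(hf, conc, rates,
                         list(rate = growth$protsyn_rate, sd = growth$protsyn_sd))
  list(observations = obs, growth = growth)
}

#' Flux-fit driver for one dataset
#'
#' Estimates heavy fractions from the MID table, assembles observations
#' with the quantification outputs, fits the compartmental model, and
#' writes a JSON report plus human-readable summary.
#'
#' @param mid_table data frame (all datasets fine; selected internally).
#' @param quant [quantify_abundance()] result.
#' @param condition,cell_line dataset selectors.
#' @param outdir optional output directory for the report files.
#' @param reference_region optional length-2 numeric printed alongside
#'   the recomputed chi-square acceptance region.
#' @param ... passed to [fit_fluxes()].
#' @return the [fit_fluxes()] result (with `sam_half_life_min` attached).
#' @export
run_fit <- function(mid_table, quant, condition, cell_line, outdir = NULL,
                    reference_region = NULL, ...) {
  tracer <- if (condition == "met_plus") {
    tracer_spec("C13", n_atoms = 5, purity = 0.99)
  } else {
    tracer_spec("H2", n_atoms = 4, purity = 0.996)
  }
  asm <- assemble_observations(mid_table, quant, condition, cell_line, tracer)
  fit <- fit_fluxes(condition, tracer, asm$observations,
                    growth_rate = asm$growth$growth_rate, ...)
  fit$cell_line <- cell_line
  fit$sam_half_life_min <- sam_half_life(fit)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    stem <- file.path(outdir, paste(cell_line, condition, sep = "_"))
    report <- list(
      cell_line = cell_line, condition = condition,
      tracer = unclass(fit$tracer), converged = fit$converged,
      multimodal = fit$multimodal, seed = fit$seed,
      chi_square = fit$chi_square, dof = fit$dof,
      acceptance_region = fit$acceptance_region,
      reference_region = reference_region,
      spanning_set = fit$spanning_set,
      sam_half_life_min = fit$sam_half_life_min,
      fluxes = fit$fluxes, pool_sizes = fit$pool_sizes,
      residuals = fit$residuals)
    jsonlite::write_json(report, paste0(stem, "_fit.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    txt <- c(utils::capture.output(print(fit)),
             sprintf("SAM half-life: %.1f min", fit$sam_half_life_min),
             if (!is.null(reference_region))
               sprintf("reference acceptance region: (%.1f, %.1f)",
                       reference_region[1], reference_region[2]))
    writeLines(txt, paste0(stem, "_fit.txt"))
  }
  fit
}

#' Write a reproducibility manifest
#'
#' @param outdir directory whose outputs the manifest describes.
#' @param seed seed used (NA for deterministic steps).
#' @param files output file names within `outdir` to checksum.
#' @param inputs optional input paths to checksum.
#' @export
write_manifest <- function(outdir, seed, files, inputs = character(0)) {
  paths <- file.path(outdir, files)
  manifest <- list(
    package = "methflux",
    version = as.character(utils::packageVersion("methflux")),
    seed = seed,
    created = "see file mtime",
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(paths)), files)),
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(inputs)), basename(inputs))))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
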