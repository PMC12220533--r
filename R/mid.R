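#' Mass isotopomer distributions and heavy-fraction estimation
#'
#' A mass isotopomer distribution (MID) is the vector of fractional
#' abundances of a metabolite's mass shifts (M+0, M+1, ..., M+n) arising
#' from isotope incorporation. Only the tracer element's atoms in the
#' labeled moiety are modeled; natural abundance of other elements is
#' not corrected for (the unlabeled and fully-labeled reference MIDs are
#' both plain binomials).
#'
#' @name mid
NULL

#' Construct a mass isotopomer distribution
#'
#' @param metabolite metabolite name.
#' @param n_atoms number of tracer-element atoms in the labeled moiety.
#' @param fractions numeric vector of length `n_atoms + 1`; index k + 1 is
#'   the fraction at mass shift k. Must be nonnegative; normalized to sum
#'   to one.
#' @param normalize if `TRUE`, rescale `fractions` to sum to one (used
#'   when converting raw peak areas).
#' @return an object of class `mid`.
#' @export
mid <- function(metabolite, n_atoms, fractions, normalize = FALSE) {
  if (length(n_atoms) != 1L || is.na(n_atoms) || n_atoms < 0 ||
      n_atoms != round(n_atoms)) {
    stop("invalid-argument: n_atoms must be a single nonnegative integer")
  }
  fractions <- as.numeric(fractions)
  if (length(fractions) != n_atoms + 1L) {
    stop("invalid-argument: fractions must have length n_atoms + 1")
  }
  if (any(!is.finite(fractions)) || any(fractions < -1e-12)) {
    stop("invalid-argument: fractions must be finite and nonnegative")
  }
  fractions[fractions < 0] <- 0
  total <- sum(fractions)
  if (normalize) {
    if (total <= 0) stop("missing-data: total peak area is zero, cannot normalize")
    fractions <- fractions / total
  } else if (abs(total - 1) > 1e-6) {
    stop("invalid-argument: fractions must sum to 1 (use normalize = TRUE for raw areas)")
  } else {
    fractions <- fractions / total
  }
  structure(
    list(metabolite = as.character(metabolite), n_atoms = as.integer(n_atoms),
         fractions = fractions),
    class = "mid"
  )
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> %s, %d atoms: [%s]\n", x$metabolite, x$n_atoms,
              paste(signif(x$fractions, 4), collapse = ", ")))
  invisible(x)
}

#' Natural-abundance MID
#'
#' Binomial distribution of heavy isotopes over `n_atoms` positions at the
#' element's natural heavy-isotope abundance. This is the unlabeled
#' reference distribution y0 of the mixture model.
#'
#' @param n_atoms tracer-element atoms in the labeled moiety (>= 0).
#' @param abundance heavy-isotope atom fraction, in `[0, 1)`.
#' @param metabolite optional name attached to the result.
#' @return a [mid] of length `n_atoms + 1`.
#' @export
natural_abundance_mid <- function(n_atoms, abundance, metabolite = "") {
  if (length(abundance) != 1L || !is.finite(abundance) ||
      abundance < 0 || abundance >= 1) {
    stop("invalid-argument: abundance must be in [0, 1)")
  }
  if (n_atoms < 0) stop("invalid-argument: n_atoms must be >= 0")
  mid(metabolite, n_atoms, stats::dbinom(0:n_atoms, n_atoms, abundance))
}

#' Fully-labeled tracer MID at a given atom purity
#'
#' Binomial distribution with success probability equal to the tracer's
#' atom purity: the expected MID of a molecule whose labeled moiety came
#' entirely from the tracer. This is the labeled reference distribution y1
#' of the mixture model; its top fraction is `purity^n_atoms`.
#'
#' @param n_atoms tracer-element atoms in the labeled moiety.
#' @param purity tracer atom purity, in `(0, 1]`.
#' @param metabolite optional name attached to the result.
#' @return a [mid] of length `n_atoms + 1`.
#' @export
tracer_mid <- function(n_atoms, purity, metabolite = "") {
  if (length(purity) != 1L || !is.finite(purity) || purity <= 0 || purity > 1) {
    stop("invalid-argument: purity must be in (0, 1]")
  }
  if (n_atoms < 0) stop("invalid-argument: n_atoms must be >= 0")
  mid(metabolite, n_atoms, stats::dbinom(0:n_atoms, n_atoms, purity))
}

#' Tracer specification
#'
#' @param element tracer element, `"C13"` or `"H2"`.
#' @param n_atoms number of labeled atoms in the tracer molecule.
#' @param purity atom purity (fraction of tracer-element atoms that are
#'   heavy), must be in (0.9, 1] and exceed natural abundance.
#' @param natural_abundance natural heavy-isotope atom fraction of the
#'   element; defaults 0.0107 for carbon-13 and 0.000115 for deuterium.
#' @return an object of class `tracer_spec`.
#' @export
tracer_spec <- function(element = c("C13", "H2"), n_atoms,
                        purity,
                        natural_abundance = NULL) {
  element <- match.arg(element)
  if (is.null(natural_abundance)) {
    natural_abundance <- switch(element, C13 = 0.0107, H2 = 0.000115)
  }
  if (!is.finite(purity) || purity <= 0.9 || purity > 1) {
    stop("invalid-argument: purity must be in (0.9, 1]")
  }
  if (purity <= natural_abundance) {
    stop("invalid-argument: purity must exceed natural abundance")
  }
  if (n_atoms < 1 || n_atoms != round(n_atoms)) {
    stop("invalid-argument: n_atoms must be a positive integer")
  }
  structure(list(element = element, n_atoms = as.integer(n_atoms),
                 purity = purity, natural_abundance = natural_abundance),
            class = "tracer_spec")
}

#' Labeled-moiety atom counts for the methionine network
#'
#' Every metabolite in the network carries at most one labeled isotopomer,
#' whose mass shift depends on the tracer. Under uniformly
#' carbon-13-labeled methionine, SAM retains all five methionine carbons
#' while SAH, homocysteine and cystathionine carry the four-carbon
#' backbone (the methyl carbon is lost at methylation). Under the
#' 3,3,4,4-deuterated homocysteine tracer, the four-deuterium moiety is
#' untouched by every reaction in the model, so all pools carry mass
#' shift 4.
#'
#' @param tracer a [tracer_spec].
#' @return named integer vector mapping metabolite to labeled-moiety atom
#'   count.
#' @export
moiety_map <- function(tracer) {
  stopifnot(inherits(tracer, "tracer_spec"))
  if (tracer$element == "C13") {
    c(met = 5L, sam = 5L, sah = 4L, hcys = 4L, cyst = 4L, metp = 5L)
  } else {
    c(met = 4L, sam = 4L, sah = 4L, hcys = 4L, cyst = 4L, akb = 4L, metp = 4L)
  }
}

#' Mass shift of the single labeled isotopomer of a metabolite
#'
#' @param metabolite metabolite name (one of the network pools).
#' @param tracer a [tracer_spec].
#' @param map optional moiety map (defaults to [moiety_map] of the tracer).
#' @return integer mass shift.
#' @export
labeled_moiety_atoms <- function(metabolite, tracer, map = moiety_map(tracer)) {
  if (!metabolite %in% names(map)) {
    stop(sprintf("key-not-found: metabolite '%s' not in moiety map (%s)",
                 metabolite, paste(names(map), collapse = ", ")))
  }
  unname(map[[metabolite]])
}

#' Estimate the heavy fraction from a measured MID
#'
#' Fits the linear mixture model `y = (1 - x1) * y0 + x1 * y1`, where y0
#' is the natural-abundance MID and y1 the fully-labeled MID at tracer
#' purity, by least squares. The 1-D problem has the closed-form solution
#' `x1 = d' (y - y0) / (d' d)` with `d = y1 - y0`, which is clipped to
#' `[0, 1]`. The standard deviation of x1 is estimated from the residual
#' variance of the mixture fit, floored at `sd_floor` so downstream
#' weights never blow up.
#'
#' @param measured measured [mid] (normalized fractions).
#' @param y0 unlabeled reference [mid].
#' @param y1 labeled reference [mid].
#' @param sd_floor absolute lower bound for the reported sd (default 0.01).
#' @return object of class `heavy_fraction`: list with `x1`, `sd`, `rss`.
#' @export
fit_heavy_fraction <- function(measured, y0, y1, sd_floor = 0.01) {
  m <- if (inherits(measured, "mid")) measured$fractions else as.numeric(measured)
  a <- if (inherits(y0, "mid")) y0$fractions else as.numeric(y0)
  b <- if (inherits(y1, "mid")) y1$fractions else as.numeric(y1)
  if (length(m) != length(a) || length(m) != length(b)) {
    stop("invalid-argument: measured, y0 and y1 must have equal length")
  }
  d <- b - a
  dd <- sum(d * d)
  if (dd < 1e-16) {
    stop("unidentifiable: y0 and y1 coincide, mixture design is degenerate")
  }
  x1 <- sum(d * (m - a)) / dd
  x1 <- min(max(x1, 0), 1)
  r <- m - ((1 - x1) * a + x1 * b)
  n <- length(m)
  s2 <- sum(r * r) / max(n - 1L, 1L)
  sd <- max(sqrt(s2 / dd), sd_floor)
  structure(list(x1 = x1, sd = sd, rss = sum(r * r)), class = "heavy_fraction")
}

#' @export
print.heavy_fraction <- function(x, ...) {
  cat(sprintf("<heavy_fraction> x1 = %.4f (sd %.4f)\n", x$x1, x$sd))
  invisible(x)
}

#' Estimate heavy-fraction time series from a MID peak-area table
#'
#' Groups a long-format peak-area table by condition, cell line,
#' metabolite and time point, normalizes areas to fractions, and fits the
#' binomial mixture model per group. Groups with zero total area are
#' flagged missing (`x1 = NA`) rather than zero.
#'
#' @param mid_table data frame as returned by [read_mid_table()].
#' @param tracer a [tracer_spec].
#' @param sd_floor absolute sd floor passed to [fit_heavy_fraction()].
#' @return data frame with columns condition, cell_line, metabolite,
#'   time_min, x1, sd, missing.
#' @export
estimate_heavy_fractions <- function(mid_table, tracer, sd_floor = 0.01) {
  map <- moiety_map(tracer)
  key <- interaction(mid_table$condition, mid_table$cell_line,
                     mid_table$metabolite, mid_table$time_min, drop = TRUE)
  groups <- split(mid_table, key)
  rows <- lapply(groups, function(g) {
    met <- g$metabolite[1]
    n_at <- labeled_moiety_atoms(met, tracer, map)
    out <- data.frame(condition = g$condition[1], cell_line = g$cell_line[1],
                      metabolite = met, time_min = g$time_min[1],
                      x1 = NA_real_, sd = NA_real_, missing = TRUE,
                      stringsAsFactors = FALSE)
    areas <- numeric(n_at + 1L)
    idx <- g$mass_shift + 1L
    if (any(idx < 1L | idx > n_at + 1L)) {
      stop(sprintf("invalid-argument: mass_shift out of range for %s (0..%d)",
                   met, n_at))
    }
    areas[idx] <- areas[idx] + g$peak_area
    if (sum(areas) <= 0) return(out)
    y0 <- natural_abundance_mid(n_at, tracer$natural_abundance, met)
    y1 <- tracer_mid(n_at, tracer$purity, met)
    hf <- fit_heavy_fraction(mid(met, n_at, areas, normalize = TRUE), y0, y1,
                             sd_floor = sd_floor)
    out$x1 <- hf$x1
    out$sd <- hf$sd
    out$missing <- FALSE
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$condition, res$cell_line, res$metabolite, res$time_min), ,
      drop = FALSE]
}
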