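---
title: "Methionine-cycle flux analysis from isotope tracing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methionine-cycle flux analysis from isotope tracing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methflux)
```

# The problem

Cultured cells fed a stable-isotope tracer — uniformly carbon-13-labeled
methionine in methionine-containing medium (met+), or 3,3,4,4-deuterated
homocysteine in methionine-free, homocysteine-containing medium
(met−hcys+) — incorporate the label into the methionine cycle:
methionine (met) is adenosylated by MAT to S-adenosylmethionine (SAM),
methyl transfer leaves S-adenosylhomocysteine (SAH), the reversible AHCY
reaction interconverts SAH and homocysteine (hcys), and homocysteine is
either remethylated to methionine by methionine synthase (MTR), committed
to transsulfuration via cystathionine synthase (CYSTS), or exchanged with
the medium. Methionine is additionally consumed by protein synthesis
(PROTSYN) into a protein-bound pool (metp). `methflux` estimates these
fluxes, with confidence intervals and a goodness-of-fit test, from three
kinds of measurements: mass-isotopomer peak areas over a labeling time
course, metabolite abundances quantified by isotope dilution against
unlabeled internal standards, and cell counts/diameters.

# Heavy-fraction representation of labeling

Both tracers move through the network as one intact labeled moiety: the
deuterated four-carbon backbone of homocysteine is untouched by every
reaction in the model, and under the carbon-13 methionine tracer each
metabolite likewise carries a single labeled isotopomer (five carbons in
met and SAM, four in SAH, hcys and cystathionine) provided MTR's
production of four-carbon-labeled methionine is negligible. The package
checks that proviso explicitly: `c13_m4_production_check()` reports the
predicted production rate of the four-labeled-carbon species (MTR flux ×
homocysteine enrichment) relative to methionine influx (about 1% under
the bundled study conditions).

Each measured mass-isotopomer distribution (MID) is therefore modeled as
a two-component mixture
$$y = (1 - x_1)\,y^0 + x_1\,y^1,$$
where $y^0$ is the natural-abundance MID and $y^1$ the fully labeled MID
at the tracer's atom purity — both plain binomial distributions over the
tracer-element atoms of the labeled moiety. The heavy fraction $x_1$ has
the closed-form least-squares solution
$x_1 = d^\top (y - y^0) / d^\top d$ with $d = y^1 - y^0$, clipped to
$[0,1]$; because the 1-D objective is convex, clipping the unconstrained
optimum equals constrained optimization on the box. Its standard
deviation is estimated from the mixture-fit residuals and floored (0.01
by default) so that downstream weights never diverge. Zero total peak
area is reported as missing, never as $x_1 = 0$. Non-tracer-element
isotopes (e.g. heavy sulfur or nitrogen) are not corrected for; the two
binomial references are the entire spectral model.

# Compartmental labeling kinetics

At metabolic steady state the fluxes $v_j$ (fmol/cell/h) and pool sizes
$C_i$ (fmol/cell) are constant, and the heavy fraction of pool $i$ obeys
$$\frac{dx_i}{dt} = \sum_{j \in \mathrm{in}(i)} \frac{v_j}{C_i}
\left(x_{\mathrm{src}(j)} - x_i\right),$$
a linear constant-coefficient system. Medium tracer pools are boundary
states held at the tracer atom purity (0.99 for the carbon tracer, 0.996
for the deuterated one) — the intracellular pools exchange with a medium
reservoir that is much larger than the amounts cycled, so its enrichment
is treated as fixed; finite-medium depletion is not simulated. The
preculture in unlabeled medium sets $x_i(0) = 0$ at the tracer switch.
Under the carbon-13 tracer, the MTR inflow to methionine enters at
enrichment zero (the five-carbon labeled moiety is destroyed); under the
deuterated tracer it transmits the homocysteine enrichment.

Protein-bound methionine is an accumulating sink with no turnover back
to free methionine. With exponential growth at rate $\mu$ its labeling
reduces exactly to $dx_{metp}/dt = \mu\,(x_{met} - x_{metp})$, i.e. a
fixed pool of size $\mathrm{PROTSYN}/\mu$; this keeps the system
autonomous. Alpha-ketobutyrate is tracked downstream of cystathionine
only in the deuterated model (the carbon label ends at cystathionine);
its pool size affects no measured quantity and is a fixed small constant
(0.005 fmol/cell) during fitting. Cystathionine leaves the system by
efflux only.

Integration uses the stiff-capable `lsoda` solver (absolute tolerance
1e-9, relative 1e-6, both configurable). Because the system is linear,
an eigendecomposition-based analytic path is also available and is used
inside the fit loop for speed; the two agree to 1e-8 and both are tested
against an independent matrix-exponential oracle. `steady_state_enrichment()`
solves the linear balance directly and equals the long-time limit of the
simulation. Times are minutes internally (matching sampling at 5, 15,
30, 60, 300 and 1440 min); fluxes are fmol/cell/h with explicit
conversion.

# Isotope-dilution quantification and rates

Spiking a known amount $n_{std}$ of unlabeled standard into a sample
containing an unknown amount $n$ of a labeled metabolite and measuring
the mixture's heavy fraction $x^{mix}$ gives, by conservation of labeled
material,
$$(n + n_{std})\,x^{mix} = n\,x + n_{std}\,x^{std},$$
solved as $n = n_{std}(x^{std} - x^{mix})/(x^{mix} - x)$. A variant with
a factor $\tfrac12$ on the mixing side (`variant = "as_printed"`) is
provided for comparison with an alternative printed form of the
equation; it is not the default because it does not conserve amounts on
mixing (at $n = n_{std}$ it is inconsistent with the mixture being the
midpoint). Whether such a factor could encode a racemate correction for
DL-homocystine (only the L-enantiomer being metabolized and measured) is
left open; the default treats 200 µM DL-homocystine as 100 µM available
L-homocysteine, with the D-form inert and invisible. Uncertainty in
$x^{mix}$ is propagated to $n$ by the delta method. A mixture within
three standard deviations of the standard's composition is reported as
below detection (amount zero); one outside the interval spanned by
sample and standard is an inconsistent measurement, logged and flagged,
never silently dropped. Because the inferred amount is monotone in
$x^{mix}$, a mixture closer to the standard always means less analyte.

Extract amounts become intracellular concentrations by dividing by the
total cytosol volume, estimated as spheres from the mean cell diameter
(a configurable cytosol fraction, default 1, rescales the whole-cell
volume). Net uptake/release rates subtract baseline-medium from
spent-medium concentrations and normalize by the time-integral of
exponentially growing cell counts, $(N_T - N_0)/\mu$ (endpoint and
arithmetic-mean alternatives are provided). Doubling times assume
exponential growth; equal counts give an infinite doubling time with a
warning, and shrinking cultures a flagged negative one. Protein
synthesis demand for methionine is
$\mu \cdot (\text{protein density} \times \text{cell volume} /
\text{mean residue mass}) \times \text{methionine residue fraction}$,
with configurable constants (defaults 200 g/L, 110 g/mol, 0.022 — the
physiological scale of cultured fibroblasts, not measured values).

# Flux fitting

`fit_fluxes()` minimizes $\sum ((\mathrm{obs} - \mathrm{pred})/\sigma)^2$
over free fluxes and (optionally) pool sizes with the
Levenberg–Marquardt algorithm (`minpack.lm`), against four observation
classes: heavy-fraction time series, intracellular concentrations, net
exchange rates for methionine and homocysteine, and the protein
synthesis rate. Steady-state balance is enforced structurally: only a
spanning set of six free fluxes is parameterized per condition and the
dependent fluxes are derived, so every candidate is balanced and — by
the choice of spanning set — nonnegative. In met+ the frees are
{MTR, CYSTS, HCYS_release, AHCY_rev, PROTSYN, MET_release} with
MAT = MTR + CYSTS + HCYS_release; in met−hcys+ they are
{MAT, AHCY_rev, CYSTS, HCYS_release, PROTSYN, MET_release} with
MTR = MAT + PROTSYN + MET_release and homocysteine uptake covering the
total demand. The spanning set is recorded in the result for
transparent dof accounting. Reversible AHCY is parameterized as
independent forward/reverse one-way rates (the labeling equations use
one-way rates); net and exchange components are derivable for
reporting. In met−hcys+, methionine uptake is structurally zero and MTR
carries the full methylation plus protein-synthesis demand — the
mass-balance identity exposed directly by `mtr_flux_by_mass_balance()`.
MTR is thus inferred from balance, not from labeling.

Measurement uncertainties are rarely reported with raw tables, and the
chi-square scale depends entirely on them: the defaults (overridable per
observation) are an absolute floor of 0.02 on heavy fractions and 10%
relative on concentrations and rates. When the tables carry propagated
sds (as the synthetic tables do), those are used. Pool sizes may be
fitted (`pools = "free"`, the default, with concentration observations
constraining them) or pinned to the measured concentrations
(`pools = "fixed"`), in which case the concentration residuals drop out
of the fit and the dof changes accordingly; both modes are supported
because either could have been intended in this kind of analysis.

Initialization is demand-balanced from the observed protein synthesis
rate, exchange rates and concentrations; ten Levenberg–Marquardt starts
(the first from the nominal initialization, the rest from seeded
lognormal perturbations, sd 0.5 on the log scale) guard against local
minima, and a fit whose converged restarts spread by more than 1e-4 in
deviance is flagged multimodal. Non-convergence is flagged, never
silent. Every stochastic element records its seed in the result.

Goodness of fit is the chi-square test: statistic $\sum r^2$ at the
optimum, dof = observations − parameters, and a central $1-\alpha$
acceptance region (default $\alpha = 0.05$) from the chi-square
distribution. Confidence intervals are normal-approximation intervals
from the linearized covariance $(J^\top J)^{-1}$ at the optimum, with
the residual scale fixed at 1 because the observation sds are treated as
known — the same convention that makes the chi-square statistic
interpretable. Rank detection runs on the correlation-scaled normal
matrix so parameters on very different scales cannot mask each other;
null-space parameters get infinite intervals and an identifiability
flag. Dependent fluxes are exact linear functions of the frees, so
their standard errors come from exact linear error propagation.
`identifiable_fluxes()` selects the fluxes whose linearized relative
standard error is below 0.3 — the subset the data actually pin down —
which is how the recovery study defines "identifiable". In fast-exchange
regimes a pool equilibrates with its precursor within the first sampling
interval and the corresponding exchange flux (e.g. AHCY reverse flux in
met+ medium, where it is small, or both AHCY one-way rates in met−hcys+
medium, where SAH equilibrates with homocysteine in seconds) retains
only a lower bound; such fluxes report wide or infinite intervals rather
than illusory precision.

# The synthetic-data generator

`generate_experiment()` produces a complete experiment from a ground
truth: labeling simulated by the compartmental model and converted to
peak-area MID tables by mixing the binomial references, spiked abundance
tables built by the forward isotope-dilution mixing, and exponentially
grown cell counts — all under a single seed that makes the output tables
byte-identical across runs. Measurement noise is additive Gaussian at
configurable sds, acting on the quantities actually measured: the heavy
fraction of each labeling MID (sd 0.02, realized by perturbing $x_1$ and
rebuilding the mixture, plus small channel-level jitter, sd 0.002 of
total area), and the mixture heavy fraction of each spiked sample
(sd 0.01 for extracts, 0.002 for medium samples, whose strong signal and
clean matrix support higher precision). Standard spike amounts are
matched to the expected analyte scale, as in practice, so the mixture
composition is maximally informative. Noise magnitudes mirror the fit's
weighting defaults so the chi-square statistic is calibrated on
synthetic data.

The bundled study conditions (`default_ground_truths()`, also encoded in
the shipped YAML configuration) emulate the qualitative regimes of
methionine-dependent and -independent fibroblasts: in met+, fast
transport exchange (intracellular methionine labels within 5 min;
intracellular level several-fold above the 100 µM medium), SAM turnover
half-life of 15 min, SAM:SAH around 40, and transsulfuration flux small
relative to methylation; in met−hcys+, intracellular methionine
collapses ~100-fold, homocysteine rises to medium levels, MAT flux
drops strongly, AHCY reverse (exchange) flux is elevated, and SAM:SAH
falls to ~2. Growth (doubling times 22–60 h), cell size (15.6 µm
diameter, ~2000 fL) and 24-h cell counts around 3×10^5 are on the scale
of cultured fibroblast experiments. These are fixture choices defining
reproducible study conditions with known ground truth — not
measurements — and cell-line labels carry a `syn_` prefix to mark them
synthetic.

What passing the pipeline on these fixtures shows: the estimators invert
their own forward models exactly; the fit recovers identifiable fluxes
within ~6% mean relative error with ~95% CI coverage at the stated noise
level; and the chi-square statistic is calibrated when weights match the
noise. What it cannot show: robustness to features real data have and
the generator omits — chromatographic artifacts, missing isotopologue
peaks, batch effects, matrix effects on the standards, non-Gaussian
outliers, or model misspecification (e.g. SAM consumption by polyamine
synthesis, protein turnover returning label to free methionine, or
compartmentation beyond a single well-mixed cytosol).

# Numerical choices and problem sizes

Closed-form solutions are preferred wherever the problem is linear (the
mixture model, steady-state enrichment, dependent-flux propagation).
The ODE tolerances (1e-9/1e-6), the LM convergence tolerances
(1e-12), the multistart spread (0.5 log-sd), the rank-detection
threshold (1e-10 on the scaled normal matrix) and the identifiability
cutoff (relative se 0.3) are stated defaults, all overridable. The test
suite and the acceptance script run the recovery study at 20 seeds and
the full fits with 10 multistarts — sizes chosen to characterize the
estimator distributions while keeping a complete run in minutes on one
CPU; the statistics stabilize well below these sizes.

# Known limitations

Positional isotopomer (EMU/cumomer) resolution, multi-element
natural-abundance correction matrices, spectral deconvolution from raw
instrument files, profile-likelihood or bootstrap intervals, Bayesian
posteriors, and model selection across alternative topologies are out of
scope. The chi-square scale is only as meaningful as the observation
sds supplied; with defaults in place of measured uncertainties it should
be read comparatively, not absolutely. Fast-exchange fluxes are
structurally hard to pin down from six time points starting at 5 min —
a limitation of the sampling design, which the package reports honestly
through wide intervals rather than resolving.
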