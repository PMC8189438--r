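---
title: "Modeling and quantifying tryptophan-derived one-carbon metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling and quantifying tryptophan-derived one-carbon metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kyntrace)
```

## The biological model

IDO1 (indoleamine 2,3-dioxygenase 1) opens the indole ring of tryptophan to
give N-formyl-kynurenine; hydrolysis to kynurenine releases the formyl carbon
as formate. That single carbon can react with tetrahydrofolate (THF) and
enter the one-carbon cycle, where it becomes available to purine synthesis
(ring positions C2 and C8 via 10-formyl-THF), de novo serine synthesis
(condensation of a one-carbon unit with glycine via SHMT), and methionine
re-methylation (via the 5-methyl-THF/methionine synthase route). kyntrace
models how carbon supplied as a ¹³C tracer — ¹³C₁₁-tryptophan,
¹³C₃¹⁵N₁-serine, or ¹³C₁-formate — propagates into the mass isotopomer
distributions (MIDs) of these products, and quantifies the corresponding
extracellular exchange fluxes.

### Steady-state pool mixing

We deliberately avoid kinetics. Labeling is read out at a 24 h end point,
long relative to the turnover of the free one-carbon, glycine and tryptophan
pools, so each pool is summarized by a single labeled fraction:

* `p` — the labeled fraction of the one-carbon pool. It is a purity-weighted
  mixture of source contributions: `p = f_s * purity` where `f_s` is the
  share of the pool fed by the source that carries the tracer's label
  (`f_trp` for the IDO1-released formyl carbon, `f_ser` for serine/SHMT,
  `f_exo_formate` for exogenous formate). Setting `ido1_active = FALSE`
  zeroes the tryptophan term, modeling IFNγ-free or epacadostat-treated
  conditions.
* `q_gly` — the per-position labeled fraction of the glycine pool.
* `trp_intracellular_labeled` — the labeled fraction of the intracellular
  tryptophan pool.

These are free pool-state parameters: a configuration describing a
tryptophan-tracer experiment sets `q_gly = 0`, because no route in the model
carries tryptophan carbon into glycine (serine synthesis is treated strictly
as glycine + one-carbon condensation; a reverse-SHMT contribution to glycine
is a known limitation, see below).

### Atom bookkeeping

Each measured metabolite declares provenance slots — groups of carbon
positions fed by one pool. A metabolite's tracer-derived MID is the
convolution over its slots of binomial labeling distributions,
`Binomial(n_positions, pool fraction)`, with one exception: slots fed by the
intracellular tryptophan pool are labeled all-or-nothing, because the carbon
skeleton transfers intact. Tryptophan m+11 therefore yields kynurenine
exactly at m+10 — ten of the eleven tracer carbons, the eleventh leaving as
formate. Purine nucleotides carry two one-carbon positions (C2, C8) and two
glycine positions; the CO₂-derived C6 and the ribose are unlabeled under all
three tracers. Acetyl-CoA is labeled only through the adenine ring of its
CoA moiety. The methyl (5-CH₃-THF) pool is assigned the same labeled
fraction as the formyl pool — a single well-mixed one-carbon pool, since the
data distinguish no compartments. The ¹⁵N of the serine tracer shifts the
intact tracer's own mass (serine measured at nominal m+4) but is never
transferred with a donated one-carbon unit; only carbon transits the THF
cycle.

```{r forward}
defs <- default_metabolites()
pars <- one_carbon_params(f_trp = 0.6, f_other = 0.4,
                          trp_intracellular_labeled = 0.99)
trp <- tracer_trp()   # 13C11-tryptophan, 0.08 mM, purity 0.99
sims <- simulate_labeling(pars, trp, defs)
round(as.numeric(sims$ATP), 4)        # binomial over 2 one-carbon positions
round(as.numeric(sims$kynurenine), 4) # block transfer to m+10
```

## Natural abundance and the empirical baseline correction

Measured envelopes convolve tracer-derived labeling with natural isotope
abundance (¹³C ≈ 1.07% per carbon, plus ²H/¹⁵N/¹⁷O/¹⁸O and sulfur isotopes).
`natural_abundance_distribution()` computes this by per-element expansion
and cross-element convolution. The experimental correction mirrors the wet
protocol: unlabeled (¹²C) control cultures provide empirical per-isotopologue
baseline fractions, and for each n ≥ 1

```
corrected_n = sample_PA_n / Σ PA  −  control_PA_n / Σ PA
```

with negative values clamped to zero and the summed labeled fraction reported
as Σ corrected_n. Clamping is a package decision — the figures report
nonnegative labeled fractions, and fractions are physical proportions.
Controls are averaged across replicate unlabeled samples of the same group
before subtraction, which reduces baseline noise. Subtraction is an
approximation: for a C₁₀ ion about 10% of the envelope mass sits at natural
m+≥1, and subtracting control fractions rather than deconvolving
underestimates labeling by roughly `(1 − m0_natural) × labeled fraction`.
The package therefore provides two inversion routes for pool-fraction
recovery:

* `estimate_pool_fractions()` — least squares on tracer-derived-basis MIDs
  over (p, q_gly) ∈ [0, 1]², for inputs that are already fully corrected;
* `estimate_pool_fractions_measured()` — fits the forward model convolved
  with the empirical control envelope directly to measured fractions. This
  route is exact for noiseless data and is what the round-trip validation
  uses. Full correction-matrix deconvolution is kept as a test oracle only,
  to stay faithful to the subtraction method the measurements use.

Both optimizers run a fixed 4×4 multi-start L-BFGS-B followed by a polish
with a 10⁻⁷ finite-difference step; the default 10⁻³ step would cap
parameter accuracy near 10⁻⁶. Degenerate all-m+0 inputs short-circuit to
(0, 0) and are flagged uninformative.

## GC-MS formate quantification and exchange rates

Formate is quantified from derivatized GC-MS peak areas at m/z 136 (¹²C
formate), 137 (¹³C formate) and 138 (d₂-formate internal standard, 50 μM in
every sample, standard and blank). The blank's raw area is subtracted per
channel (no ISTD rescaling of blanks), the result is ratioed against the
sample's m/z 138 area, and an OLS calibration line fitted to a standards
ladder maps ratio to concentration, clamped at zero.

Medium exchange rates use the two-time-point design: the exchanged amount is
`|ct − c0| × volume` (mM × mL × 10⁹ = fmol), normalized by the
exponential-growth mean cell number `n_avg = (nt − n0)/ln(nt/n0)` — standard
exometabolomics practice that reduces to `n0` for non-growing cultures — and
the window length, giving fmol/cell/h. Because every IDO1 turnover that
yields one kynurenine also yields one formate, kynurenine efflux bounds
IDO1-derived formate production, and

```{r retention}
retention_fraction(kyn_efflux = 1, formate_efflux = 0.675)
```

is the share of IDO1-generated formate retained for intracellular use.
Group comparisons use classical two-sided Student t tests (pooled variance
unpaired, difference-based paired), with the p = 1 convention for degenerate
all-equal data.

## What the synthetic generator emulates

`generate_lcms_tables()` produces labeled and unlabeled-control peak-area
tables as `total_area_scale × (tracer_derived ⊛ natural abundance) ×
log-normal noise`, with n = 3 biological replicates and a default area CV of
5% — multiplicative noise because LC-MS area variability is approximately
proportional to signal. `generate_gcms_samples()` emulates the internal-
standard design including a constant instrument background exposed by water
blanks, and `generate_medium_timecourse()` integrates the true per-cell rate
over exponential growth so that `exchange_rate()`'s log-mean normalization
round-trips exactly at zero noise. Ground truth is returned alongside the
tables, so tests never re-derive it from noisy data.

The generator does not emulate chromatographic artifacts, co-elution,
in-source fragmentation, detector saturation, or missing peaks. Passing
tests therefore demonstrate correctness of the computational chain under the
stated noise model, not robustness to raw-spectra pathologies — the pipeline
starts at peak-area tables by design.

Default study conditions baked into the generator: three replicates, 5%
area CV, 24 h window, 2 mL medium, 5×10⁵ starting cells with a 24 h doubling
time, tracer concentrations 0.08 mM (Trp) / 0.4 mM (Ser), tracer purity
0.99. The ¹³C₁-formate tracer concentration is not specified by the source
protocols; the default of 0.5 mM is a typical exogenous formate
supplementation level.

## Numerical choices and limitations

* MID validity is enforced at 10⁻⁹ (sum) with tiny negative round-off
  clamped; convolution truncation at a metabolite's carbon count
  renormalizes the retained mass.
* The inversion problem is near-symmetric in (p, q_gly) for purines alone
  (2 + 2 positions); joint fitting with serine (1 + 2) breaks the symmetry.
  The fixed multi-start grid guards against the residual ambiguity.
* Problem sizes in the validation suite: 1,000 random parameter draws for
  normalization properties, enumeration oracles up to C₆ (and C₁₁
  carbon-only for the baseline-bias study), 200 seeded noisy experiments for
  recovery calibration (p̂ within ±0.05 of truth in ≥95% of runs).
* Serine m+1 observed under the tryptophan tracer is attributed entirely to
  de novo synthesis; any reverse-SHMT exchange contribution is not modeled.
* Absolute kynurenine rates from LC-MS peak areas require a user-supplied
  response factor; none is guessed.
* NAD(P)⁺ synthesis and TCA entry via α-ketoadipate are out of scope (the
  upstream measurements show negligible labeling there), as are kinetic/ODE
  flux models.
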