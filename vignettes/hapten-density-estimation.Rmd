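---
title: "Hapten density estimation from MALDI-TOF spectra of peptide-carrier conjugates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hapten density estimation from MALDI-TOF spectra of peptide-carrier conjugates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haptenms)
```

## The problem

Peptide–carrier conjugate vaccines couple many copies of a short epitope
peptide (a hapten) to an immunogenic carrier protein such as CRM197, the
non-toxic diphtheria-toxin mutant (~58 kDa, 39 lysines of which roughly 20
are solvent accessible).  The conjugation reaction is stochastic: the
product is a mixture of species carrying 0, 1, 2, ... peptides.  The
average number of peptides per carrier — the *hapten density* (HD) — and
its spread govern immunogenicity and batch consistency, but gels and size
exclusion chromatography cannot resolve the individual species.

Linear MALDI-TOF mass spectrometry can.  A conjugate mixture appears as a
ladder of peaks: the species with peptide load $n$ (an integer, `PL`) has
neutral mass $M_0 + n\Delta$ and is observed, at charge $z$, at

$$ c_n = \frac{M_0 + n\Delta + z\,m_p}{z}, \qquad m_p = 1.007276\ \mathrm{Da}, $$

so consecutive species are $\Delta/z$ apart.  For ~60 kDa conjugates the
doubly charged series ($z = 2$) is the one fitted: it is intense and, for
peptides above ~1.5 kDa, still baseline-resolved.  `haptenms` implements
the full analysis: preprocessing, constrained Gaussian-series
deconvolution of that ladder, and the summary statistics.

## The statistics

With $VUC_n$ the area under the fitted Gaussian of species $n$,

$$ \mathrm{HD} = \frac{\sum_n VUC_n \cdot PL_n}{\sum_n VUC_n}, \qquad
   \sigma = \sqrt{\frac{\sum_n VUC_n (PL_n - \mathrm{HD})^2}{\sum_n VUC_n}}. $$

HD is the area-weighted mean peptide load; $\sigma$ — the dispersity — is
the area-weighted *population* standard deviation of the load.  No
parametric form is assumed for the load distribution.  The dispersity has
no universally agreed weighting; this package weights by peak area, the
same weight HD uses, and labels it as such in every output.  Areas come
from the Gaussian closed form $A\sigma\sqrt{2\pi}$, not from numerical
integration, for consistency with the fitted model.

Both statistics are scale invariant in the areas, HD is strictly monotone
under moving area to higher loads, and adding a constant to every load
shifts HD by that constant while leaving $\sigma$ unchanged; the test
suite asserts all three properties on random tables.

## The pipeline

1. **Reading and calibration** (`read_spectrum`, `calibrate`).  Spectra
   arrive as mzML or two-column text.  Calibration is a degree-1 or -2
   polynomial on the m/z axis, least-squares fitted against reference
   species (classically BSA and its multiply charged ions, spanning
   ~13–66 kDa); reference m/z are $(M + z\,m_p)/z$.  Calibration is
   defined on the m/z axis rather than on flight time because every
   downstream computation needs only m/z; with perfect calibrants the
   model is the identity to machine precision.  The polynomial degree is
   an open choice on any given instrument, so both are exposed.

2. **Smoothing** (`savitzky_golay`).  Local polynomial least squares;
   defaults `window = 11` points, `polyorder = 3` — wide enough to damp
   detector noise, narrow enough (well under one peak FWHM at the
   simulated resolution) not to distort peak areas.  The filter reproduces
   polynomials up to its order exactly, which the suite checks with
   random coefficients.  Edges use the fit of the first/last full window;
   a warning fires when the m/z grid spacing varies by more than 10%.

3. **Baseline** (`snip_baseline`, `subtract_baseline`).  Classic SNIP:
   for clipping half-window $m = 1..m_{max}$, each point is replaced by
   $\min\{y_i, (y_{i-m}+y_{i+m})/2\}$.  The default runs in linear space,
   where flat and straight-line spectra are exact fixed points; the
   log-log-square-root compressed variant and the decreasing-$m$ schedule
   are options, since the literature uses both.  $m_{max}$ defaults to
   twice the FWHM of the tallest peak in points (`snip_iterations_for_fwhm`),
   clearly wider than a peak half-width so peaks are not eaten, and is
   always user-settable.  The baseline never exceeds the input and is
   monotone decreasing in $m_{max}$ — both asserted property-style.

   For the ladder fit the subtraction is applied *without* clipping
   negatives (`clip_negative = FALSE` in `estimate_hapten_density`):
   keeping the residual noise zero-mean avoids inflating small fitted
   areas.  Clipping remains the default in `subtract_baseline` itself,
   where a physically non-negative trace is wanted.

4. **Deconvolution** (`fit_ladder`).  Bounded Levenberg–Marquardt least
   squares (with an analytic Jacobian) of

   $$ y(x) = \sum_n A_n \exp\!\big(-(x-c_n)^2/2\sigma_n^2\big) + b $$

   under the constraints that make the ladder identifiable:

   * $A_n \ge 0$, capped at 1.5× the data maximum.  The cap prevents the
     runaway amplitudes that otherwise occur for candidate species whose
     centers fall outside the recorded m/z range (their gradient is
     numerically zero).
   * $c_n = \hat c_n + s + j_n$: the predicted center plus one global
     shift $|s| \le 0.2\,\Delta/z$ (absorbing calibration error and
     uncertainty in $M_0$) plus per-peak jitter
     $|j_n| \le 0.05\,\Delta/z$.  $M_0$ itself is never refit — that
     keeps the load assignment unambiguous.
   * width either shared across the series (default: linear-TOF
     resolution varies slowly over one ladder's span) or affine in m/z
     (`width_model = "linear"`), which is exact when peak width scales
     with m/z.
   * $b$ is a single flat background term (default on).  SNIP estimates
     a baseline at the noise troughs, so subtraction leaves a small
     positive offset under noise; one constant absorbs it.  On noise-free
     data it converges to zero and costs nothing.

   Initialization is deterministic: amplitudes from the local maxima
   nearest the predicted centers, width from the FWHM of the tallest
   peak.  Non-convergence triggers up to three restarts from
   perturbations drawn from a private RNG seeded by `fit_control(seed=)`,
   so identical inputs always give identical results.

   After the first pass, species at the range ends are pruned when their
   amplitude falls below 1% of the maximum *or* below three times the
   residual RMS (the usual S/N ≥ 3 limit of detection), and the reduced
   model is refit once.  Pruning works inward from the ends only, so the
   surviving loads stay contiguous.  `select_load_range` automates range
   choice over a candidate superset, by amplitude or by greedy BIC
   descent; BIC candidates are always compared on the same fixed m/z
   window, since fits over different windows have incomparable
   likelihoods.

5. **Reporting** (`hapten_report`, `write_report`).  HD, $\sigma$, the
   cumulative-fit adjusted
   $R^2 = 1 - (1-R^2)\frac{N-1}{N-p-1}$ and the normalized species table,
   serialized as JSON and TSV with an MD5 digest of the run
   configuration.

## The simulator

`simulation_config` + `simulate_conjugate_spectrum` generate spectra with
known ground truth so that every stage, and the pipeline end to end, is
testable without instrument data.  The defaults encode the study system:
a 58,408 Da carrier with 20 activatable lysines, conjugated through a
thioether crosslinker (SBAP) whose bridging remnant C5H6NO2 and
cysteine-capping adduct C8H13N2O4S are computed from element masses; the
single-epitope mouse peptide design (N-acetylated 13-mer epitope + GG
linker + C-terminal cysteine, ~1.72 kDa) gives an observable ladder
spacing of ~1.60 kDa once a capped site is exchanged for a conjugated
one; the doubly charged series near 31–43 kTh; peak FWHM 0.2% of m/z;
an exponentially decaying baseline (20% of the signal maximum at the low
edge, rate 2×10⁻⁴ per Th); and additive Gaussian noise parameterized as
a fraction of the maximum clean signal (so SNR = 1/`noise_sd`).

The species *load distribution* defaults to binomial over the activatable
sites — the parameter-free consequence of independent site occupancy —
with Poisson and explicit tables as alternatives; fractions are computed
analytically from the pmf (truncated at 10⁻⁶ and renormalized), never
sampled.  Per-species peak *areas* are proportional to molar fraction:
since peak width grows with m/z, making heights proportional instead
would distort the encoded abundances by several percent across a ladder.
Simulations are bitwise reproducible under a fixed seed, drawn from a
private RNG stream that never disturbs the caller's.

What the simulator deliberately does not emulate: ionization/desorption
efficiency differences between loads (assumed equal, as argued for
chemically similar conjugate species), detector saturation, matrix
cluster peaks, isotope structure (irrelevant at linear-MALDI resolution
of 60 kDa species), and Poisson counting noise.  Passing tests therefore
demonstrate correct recovery of the model the instrument is assumed to
produce, not robustness to every instrumental artifact.

## Verification scale and results computed by the suite

The test suite runs the full simulate → smooth → baseline → fit → report
chain on 4000-point spectra.  Three conditions emulating low/medium/high
peptide molar excess (binomial p = 0.10, 0.20, 0.35 over 20 sites, SNR
100) reach a cumulative-fit adjusted R² above 0.99 and a strictly
increasing HD sequence.  Fifty seeded replicates with mean load drawn
from [1, 8] at SNR 50 recover HD within ±0.25 and — with the
width-linear-in-m/z model, which matches the simulator's physics — every
species holding at least 5% of the area within 5% relative error.  These
sizes keep the whole suite around a minute while leaving the fits
overdetermined by two orders of magnitude.

## Peptide-design utilities

`peptide_mass` sums residue masses (a vendored elemental-composition
table times IUPAC atomic masses — average by default, since linear MALDI
of 60 kDa species is isotopically unresolved) plus water plus terminal
modifications.  `ladder_spacing` adds the crosslinker remnant.
`predict_species_masses` applies the capping arithmetic: under the
default all-capped policy the load-0 species carries all 20 capping
adducts and each additional peptide *replaces* one capped site, so the
observable spacing is `delta - capping_adduct_mass`; with no capping the
spacing is `delta` exactly.  `percent_identity` computes *strict*
ungapped identity and says so: over the 13 aligned epitope positions the
mouse/bovine pair gives 12/13 = 92.3%, while the human/bovine pair gives
9/13 = 69.2% by strict count — published similarity figures that count
conservative substitutions (e.g. 77% for this pair) use a scheme that is
not reconstructable from the number alone, so none is guessed here.

## Configuration and reproducibility

Run configurations are single YAML files (diff-able provenance; YAML
rather than TOML because R ships a mature YAML parser), with every fit
and simulation parameter surfaced.  Reports embed an MD5 digest of the
exact configuration used plus the seed, so any result is reproducible
from its report alone.  The `inst/cli/haptenms` script exposes
`simulate`, `design` and `fit` subcommands with documented exit codes
(0 success, 2 usage, 1 runtime).

## Known limitations

* One charge series is fitted at a time; overlapping series from other
  charge states contribute unmodeled signal (the simulator can generate
  a low-weight z = 1 satellite to probe this).
* Peaks are Gaussian only; tailing (EMG) line shapes are not modeled.
* The load range must be contiguous; a genuinely bimodal conjugate with
  an interior empty load would keep the empty species in the fit.
* Strict identity is the only sequence-comparison metric.
* HD accuracy inherits the equal-ionization-efficiency assumption; the
  package cannot detect a violation from a single spectrum.
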