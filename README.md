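# haptenms

Hapten density estimation for peptide–carrier conjugate vaccines from
linear MALDI-TOF mass spectra.

## The problem

Conjugating many copies of a short epitope peptide to a carrier protein
(e.g. CRM197, ~58 kDa) produces a heterogeneous mixture of species
bearing 0, 1, 2, ... peptides.  The average number of peptides per
carrier — the **hapten density (HD)** — and its spread drive
immunogenicity and batch consistency, yet SDS-PAGE and SEC cannot
resolve the individual species.  In a linear MALDI-TOF spectrum the
mixture appears as a ladder of peaks: the species with integer peptide
load `PL = n` has neutral mass `M0 + n·Δ` and is observed at charge `z`
(the doubly charged series for ~60 kDa conjugates) at

    center(n) = (M0 + n·Δ + z·1.007276) / z

`haptenms` deconvolutes that ladder as a constrained sum of Gaussians —
after Savitzky–Golay smoothing and SNIP baseline subtraction — and
reports

    HD = Σ(VUC·PL) / ΣVUC        σ = sqrt( Σ VUC·(PL − HD)² / ΣVUC )

where `VUC` is the fitted peak area of each species, together with the
adjusted R² of the cumulative fit.  It also ships peptide-design
utilities (masses from sequence with terminal modifications, crosslinker
arithmetic, strict epitope identity) and a synthetic-spectrum simulator
with exact ground truth, so the whole pipeline is testable without
instrument data.  Intended users: vaccine/bioconjugate analytical
chemists and MS data analysts.

## Worked example

Simulate a conjugate with binomial peptide load over 20 activatable
sites at occupancy 0.2 (true HD = 4), at signal-to-noise 100, then
recover it:

```r
library(haptenms)

cfg <- simulation_config(load_model = list(type = "binomial", size = 20, prob = 0.2),
                         noise_sd = 0.01, seed = 42)
sim <- simulate_conjugate_spectrum(cfg)
rep <- estimate_hapten_density(sim$spectrum, sim$ladder, sample_id = "demo")
print(rep)
```

prints

```
Hapten density report [demo]
  HD = 3.95 peptides/carrier, dispersity sigma = 1.76, adj R2 = 0.9986
   load  area fraction
1     0  4009 0.011869
2     1 20396 0.060388
3     2 47298 0.140035
4     3 70482 0.208679
5     4 73656 0.218076
6     5 58308 0.172635
7     6 36048 0.106730
8     7 17734 0.052505
9     8  6973 0.020645
10    9  2850 0.008438
```

The estimated HD (3.95) recovers the simulated truth (4.00) within the
pipeline's documented ±0.25 tolerance; `fraction` is each species' share
of the total fitted area, and the adjusted R² of the cumulative fit
exceeds 0.99.  A command-line front-end with `simulate`, `design` and
`fit` subcommands lives at `inst/cli/haptenms`; run configurations are
single YAML files.  Design utilities:

```r
percent_identity("VQHTLTPGDLRDL", "VRHTLTPGDLRDL")  # mouse vs bovine epitope: 92.3
peptide_mass(iris_design("mIRIS1"))                 # 1723.9 Da (average)
```

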