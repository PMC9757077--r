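# NAPbind

Quantitative analysis of DNA binding by bacterial nucleoid-associated
proteins (NAPs) of the Rok / H-NS functional family — the xenogeneic
silencers that bridge and compact AT-rich DNA — for researchers working
with single-molecule titrations, bulk binding assays and strain-comparison
transcriptomics.

The package implements four analysis stages, each with a seeded
synthetic-data generator that emulates the corresponding experiment so the
whole pipeline is testable by parameter recovery:

- **Tethered particle motion (TPM)**: per-bead RMS distributions are
  fitted as Gaussian mixtures by deterministic multi-start EM; occupancy is
  the bound-component area fraction,
  θ = A_bound / (A_bound + A_unbound), and occupancy-vs-concentration
  curves are fitted with the Hill model
  θ(c) = 1 / ((K_D/[c])^n + 1) for the apparent affinity K_D and Hill
  coefficient n.
- **DNA bridging assay**: scintillation counts become recovery
  percentages, 100·(signal − background)/(reference − background), with
  replicate means and sample SDs per condition.
- **Microscale thermophoresis (MST)**: Fnorm/ΔFnorm extraction from
  traces and least-squares fitting of the non-cooperative
  McGhee–von Hippel lattice-binding isotherm
  ν/L = (1/K_D)(1 − nν)[(1 − nν)/(1 − (n−1)ν)]^(n−1), θ = nν,
  with binding-site size n = 30 bp fixed.
- **Differential expression**: library-size normalization, signed
  square-root transformed differences against a deletion strain, a
  maximum-likelihood logistic null, two-sided p-values, Storey q-values,
  DEG selection at q < 1e-3, and three-set Venn partitioning — plus
  Rok/sRok length classification (≥190 aa / ≤189 aa) and alignment
  information-content profiles.

See `vignettes/nap-binding-methods.Rmd` for the models, assumptions and
numerical choices.

## Worked example

Simulate a Rok-like TPM titration (bare DNA 159 nm, bound 105 nm, planted
Hill parameters K_D = 6.1 nM, n = 6.5), rebuild the occupancy curve and
refit:

```r
library(NAPbind)

beads <- simulateTPMTitration(c(0, 3:10), nBeads = 400, seed = 5)
curve <- buildOccupancyCurve(beads)
fitHill(curve)
#> HillFit
#>   K_D: 6.124 nM (se 0.0415)
#>   n:   6.764 (se 0.274)
#>   residual SS: 0.00219 over 9 points
```

The fitted affinity (6.12 nM) and cooperativity (6.8) recover the planted
values within the binomial sampling error of 400 beads per concentration.
The same pattern works for MST:

```r
mst <- simulateMSTDataset(kd = 79.4, amplitude = 0.6, noiseSd = 0.004,
                          seed = 2)
fitMvH(mst)
#> MvHFit (McGhee-von Hippel, non-cooperative)
#>   K_D: 79.38 uM (se 3.36), site size 30 bp
#>   amplitude: 0.6008, residual SS: 8.29e-05
```

and for the bridging assay:

```r
br <- simulateBridging(c(`0 uM` = 0, `0.2 uM` = 0.45, `0.6 uM` = 0.8),
                       seed = 3)
summarizeTitration(br)
#>    label mean_recovery sd_recovery n_replicates below_replication_standard
#> 1   0 uM          0.00      0.0000            3                      FALSE
#> 2 0.2 uM         44.35      0.2774            3                      FALSE
#> 3 0.6 uM         80.16      0.1573            3                      FALSE
```

Zero protein recovers no DNA; recovered percentages estimate the planted
bridging efficiencies with triplicate SDs of a Poisson counting process.

For differential expression, `simulateCountMatrix()` builds a
`SummarizedExperiment` with a deletion-strain baseline and planted
logistic-distributed transformed differences, and
`callDEGs(se, "rok", "drok")` runs the normalization → signed-root →
logistic-null → q-value chain, returning a per-gene table and the fitted
null.

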