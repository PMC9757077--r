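---
title: "Models and methods behind NAPbind"
author: "NAPbind authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind NAPbind}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NAPbind)
```

# Scope

NAPbind quantifies the DNA-binding behaviour of bacterial
nucleoid-associated proteins (NAPs) of the Rok / H-NS functional family
across four measurement modalities, and ships a seeded synthetic-data
generator for each so that every stage of the analysis can be validated by
parameter-recovery experiments without access to instrument data:

1. **Tethered particle motion (TPM)** — per-bead RMS excursions, Gaussian
   mixture occupancy, Hill fitting.
2. **DNA bridging pull-down** — scintillation counts to recovery
   percentages with replicate summaries.
3. **Microscale thermophoresis (MST)** — Fnorm extraction and
   McGhee–von Hippel lattice-binding fits.
4. **Bulk RNA-seq differential expression** — an empirical logistic-null
   caller with Storey q-values and three-set Venn partitioning, plus
   Rok/sRok sequence utilities.

# TPM: mixtures, occupancy and the Hill model

A bead tethered by a single DNA molecule explores a volume set by the
DNA's effective length; protein binding that compacts or bridges the DNA
reduces the bead's RMS excursion. A titration therefore produces, at each
protein concentration, a sample of per-bead RMS values drawn from a
mixture of a bare-DNA population (around 159 nm for the 685 bp substrate
used as the default) and a compacted, protein-bound population (around
105 nm).

`fitRMSMixture()` fits a one- or two-component normal mixture by
expectation-maximization on the **unbinned** per-bead values. Histograms
of RMS values are conventionally fitted with Gaussians; EM on raw values
is the maximum-likelihood formulation of the same model and removes the
bin-width choice, which no instrument convention fixes. EM is run from 10
deterministic initializations (the sample split at the 10 quantiles
p = 1/11 … 10/11, component moments seeded from the two sides), the best
log-likelihood wins, and ties go to the lower bound-component mean — the
fit is therefore a deterministic function of the data. Component SDs are
floored at 1e-6 of the sample SD to exclude the degenerate
spike solutions that make mixture likelihoods unbounded. Convergence is
declared when the log-likelihood gain drops below 1e-10 (relative), with
a 500-iteration cap.

Occupancy follows from the fitted component weights (the areas of the
fitted Gaussians):
$$\theta = \frac{A_{bound}}{A_{bound} + A_{unbound}},$$
with the **lower-mean** component taken as bound, since these proteins
compact DNA. `buildOccupancyCurve()` applies a minor-population rule
before this ratio: components with weight < 0.05 are dropped and the
remainder renormalized. This mirrors the treatment of the occasional
minor RMS populations seen in titrations (at ~125 and ~80 nm), which are
not consistently present and are excluded from occupancy calculations.
The threshold of 0.05 is a package choice: large enough to catch
populations too sparse for a stable Gaussian fit, small enough not to
clip a genuine bound population early in a titration.
Bound/unbound roles per concentration are assigned by proximity to
reference means from a pooled two-component fit across the whole
titration, which makes the rule stable at the extremes where only one
population survives (θ = 0 at zero protein, θ = 1 at saturation).

Occupancies versus concentration are fitted with the Hill model
$$\theta(c) = \frac{1}{(K_D/[c])^n + 1},$$
by unweighted least squares (no weighting scheme is standard for these
curves), with both parameters log-transformed for positivity and
Levenberg–Marquardt refinement from K_D initialized at the concentration
nearest θ = 0.5 and n = 4. On noiseless model curves the generating
(K_D, n) are recovered to better than 1e-6 relative error; this
round-trip, run at the published wild-type (6.1 nM, 6.5) and
linker-deletion (8.8 nM, 5.7) values, is part of the test suite and the
acceptance script.

# Bridging assay

Recovery is the reference-normalized signal
$100\,(signal - background)/(reference - background)$, with background
defaulting to 0 (zero-protein controls recover no DNA, so no implicit
background is assumed) and a reference of ~8000 cpm in the synthetic
generator. Raw values below 0 are clipped; values above 100% are kept
but flagged, since an above-reference signal is informative about
pipetting or counting problems rather than physically meaningful
recovery. Summaries use the sample (n−1) SD, the convention matching
error bars over triplicates, and conditions with fewer than 3 replicates
are flagged as below the replication standard. The reference is taken
per row; whether a shared batch reference was used upstream is a
data-layout question the reader of the table has already resolved.

# MST: Fnorm and the McGhee–von Hippel isotherm

`fnorm()` implements the standard normalized-fluorescence readout: mean
fluorescence in a window centered 1.5 s after IR-laser switch-on divided
by the pre-laser mean, for a 5 s off / 30 s on / 5 s off program. The
instrument's exact hot-window width is not published; the half-width is a
parameter with default 0.5 s. `deltaFnorm()` subtracts the DNA-only
Fnorm.

Binding of a protein that occludes $n$ lattice residues (bp) on a long
DNA is described by the non-cooperative McGhee–von Hippel isotherm
$$\frac{\nu}{L} = \frac{1}{K_D}\,(1 - n\nu)
  \left(\frac{1 - n\nu}{1 - (n-1)\nu}\right)^{n-1},$$
with binding density ν and fractional saturation θ = nν. The
non-cooperative (ω = 1) form is used because only the model name and the
site size n = 30 bp are standard for this assay; cooperativity would add
a parameter the 8-point titration cannot constrain. The association
constant is parameterized as $K_D = 1/K$ in concentration units so fitted
values are directly comparable to reported affinities. Free ligand is
approximated by total ligand: at 0.125–16 µM protein against 40 nM of a
78 bp duplex, depletion is below 1% over the titration.

For given (L, K_D, n) the implicit equation has a unique root
ν ∈ [0, 1/n); `mvhTheta()` finds it by bracketed bisection on
[0, 1/n − 1e-12/n], iterated to an interval below 1e-18 — slower than
Newton steps but convergence is guaranteed and the cost is negligible at
titration scale. The tests check the solver against an independent
`uniroot()` oracle on the original equation form to 1e-10 and against
the dilute-limit closed form θ → nL/K_D.

`fitMvH()` fits ΔFnorm(c) = A·θ(c; K_D, n) with n fixed, A free. The
saturation amplitude is fitted rather than taken from the largest
observed ΔFnorm because the titration does not visibly saturate at these
affinities; both raw-ΔFnorm and pre-normalized-occupancy data enter
through the same interface (an occupancy dataset is simply one with
A ≈ 1). Initialization scans 40 log-spaced K_D candidates with A
profiled out linearly, followed by Levenberg–Marquardt on (log K_D, A).
Noiseless round-trips at the published affinities (79.4 µM without
magnesium, 34.6 µM at 10 mM MgCl₂) recover K_D to better than 1e-4
relative error.

# Differential expression against a logistic null

The caller implements an empirical-null procedure for comparing
overexpression strains against a deletion-strain baseline:

1. **Normalization**: each sample is scaled to the mean library size.
   The procedure this implements does not pin down a normalization
   method; library-size scaling is the simplest choice that keeps
   differences in count units, and the factors are recorded in
   `colData()$sizeFactor`.
2. **Differences**: per gene, mean normalized deletion-strain counts are
   subtracted from mean normalized strain counts.
3. **Signed square root**: differences are transformed as
   $t_g = \mathrm{sign}(d_g)\sqrt{|d_g|}$. A plain square root is
   undefined for the (necessarily signed) half of the genes that go
   down; the signed root is this package's convention for square-root
   transforming signed differences, and it keeps induced and repressed
   genes distinguishable.
4. **Null fit**: a logistic distribution (the family that best models
   such transformed differences; reference parameters location 0.0715,
   scale 0.66927) is fitted to the condition's transformed values by
   maximum likelihood (BFGS on (µ, log s) with analytic gradients;
   gradient norm < 1e-8 at the optimum). The null is fitted **per
   condition** by default: each contrast has its own technical depth and
   biological spread, and pooling would let a noisy condition dilate the
   null for a quiet one. A prefitted null can be passed instead, which
   covers the pooled variant.
5. **p- and q-values**: two-sided $p = 2\min(F(t), 1-F(t))$ — both
   induced and repressed genes count as differentially expressed — then
   Storey q-values with π₀ from the smoother method (λ = 0.05…0.95,
   df-3 smoothing spline evaluated at λ = 0.95), falling back to π₀ = 1
   (plain Benjamini–Hochberg) when the estimate leaves (0, 1].
6. **Selection**: genes with q strictly below 1e-3.

`vennPartition()` decomposes three DEG sets into the 7 disjoint regions
with percentages relative to the union, and guarantees the
reconstruction identities (regions sum to the union; each set equals the
sum of its four regions). Published three-set DEG percentages quoted
with inclusive intersections cannot always be reproduced region-by-region
from disjoint counts; this implementation guarantees internal consistency
instead.

## What the count generator emulates — and what it does not

`simulateCountMatrix()` inverts the analysis transform: per gene a
baseline is drawn from a negative binomial (mean 250, dispersion 0.3 —
a typical bulk RNA-seq marginal for a moderately expressed bacterial
transcriptome), each effect strain receives a planted transformed
difference $t_g \sim \mathrm{logistic}(0.0715, 0.66927)$ applied as a
count-mean shift $\mathrm{sign}(t_g)\,t_g^2$, and integer counts are
produced by **unbiased randomized rounding** of depth-scaled means
(depth factors uniform on 0.9–1.1), so all count expectations are exact.
Negative planted means are clipped at zero and flagged in `rowData()`.
A `degFraction` of genes receives an additional ±12 transformed-unit
effect (default effect size chosen so that planted DEGs clear the
q < 1e-3 boundary even though they themselves inflate the fitted null's
scale — the logistic scale MLE does not have bounded influence).

Two features of real data are deliberately absent. First, there is no
replicate-level biological overdispersion: adding NB noise per replicate
at realistic depths would swamp sub-count planted differences (the
logistic scale of 0.66927 corresponds to typical count differences below
one count), making planted-parameter recovery impossible for any
inference method; the generator targets validation of the inference
chain, not realism of replicate scatter. Second — a genuine
identifiability limit, not a generator artifact — library-size
normalization absorbs any global mean shift: the planted logistic
*location* changes every gene in the same direction, which is exactly
what a library-size factor removes, so only a zero-location null
round-trips through the full count pipeline. The tests therefore check
location recovery on a zero-location generator and scale recovery to
10%, while direct draws from the logistic (no count layer) recover both
published parameters to 2% at n = 1e5 — the recovery the procedure
itself relies on. Consequently, passing tests validate the transform,
fitting, and FDR machinery; they do not demonstrate robustness to
biological replicate noise.

# Sequence utilities

`classifyRokLength()` applies the established length rule for the
Rok/sRok split: ≥ 190 aa is Rok, ≤ 189 aa is sRok (sRok lacks the
central linker). `alignmentProfile()` computes per-column residue
frequencies over the 20 standard amino acids with gaps excluded from
normalization — the convention of profile-HMM-based logo tools — and the
information content $IC = \log_2 20 - H$ in bits. Pseudocounts are off
by default (none are standard for these logos) but available for small
alignments. All-gap columns get IC 0 and are flagged rather than
erroring, since trimmed alignments legitimately contain them.

# Synthetic-data defaults and reproducibility

Every generator takes an explicit integer seed and runs under a locally
seeded Mersenne–Twister RNG (inversion for normals), restoring any
pre-existing global RNG state afterwards; a fixed seed gives
bit-identical output across runs and platforms. Defaults mirror the
published study conditions: bare/bound RMS 159/105 nm, 200 beads per
condition, Hill (6.1 nM, 6.5); 8000 cpm reference and triplicates for
bridging; site size 30 bp, 0.125–16 µM doubling series, 40 nM DNA for
MST; logistic (0.0715, 0.66927) for counts. The per-population RMS SDs
(12 nm) are not published quantities; they are configuration chosen to
reproduce the visual separation of the two populations, and tests treat
them as such.

# Problem sizes

The validation experiments are sized for sharp statistical conclusions
at interactive cost: 400–500 beads for mixture recovery (mean standard
errors ≈ 0.5–0.9 nm against ±2/±3 nm tolerances), 1e5 draws for logistic
MLE recovery (location SE ≈ 0.004), 3000–4000 genes for DEG calibration
and power, 2e4–5e4 genes for pipeline-level null recovery. Noiseless
round-trips (Hill, McGhee–von Hippel) are deterministic and independent
of size beyond identifiability.

# Known limitations

- EM on unbinned values is a deliberate substitute for histogram
  fitting; with heavily overlapping populations (separation ≲ 1 SD) the
  two-component fit becomes weakly identified and the minor-population
  rule may merge genuine states.
- The MvH fit holds n fixed; misspecifying the site size biases K_D
  roughly proportionally, and the 8-point titration cannot estimate n.
- The DEG caller's null is fitted in-sample, so heavy contamination by
  true effects inflates the null scale and costs power (see above); at
  a few percent of genes this is modest, and a full-scale analysis
  has the same property.
- The logistic location is unidentifiable through library-size
  normalization (above); location estimates from the full pipeline
  reflect shape asymmetries, not the planted global shift.
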