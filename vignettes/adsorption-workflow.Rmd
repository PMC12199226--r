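---
title: "Quantifying protein adsorption on polymer microarrays from targeted DIA LESA-MS/MS data"
author: "lesaQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein adsorption on polymer microarrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesaQuant)
```

## The problem

Synthetic polymer surfaces condition cell behaviour largely through the
layer of proteins they adsorb from the culture medium. A high-throughput
way to measure that layer is to print a microarray of homopolymer spots,
incubate it in a defined medium — here Essential 8 (E8), whose protein
content is insulin, transferrin, FGF-2 and TGF-β1 — digest the adsorbed
proteins in place with trypsin, and sample each spot by liquid extraction
surface analysis tandem mass spectrometry (LESA-MS/MS). Each spot yields a
targeted data-independent acquisition (DIA): cycles of 10 MS2 scans, each
isolating one previously chosen peptide ion in a 1 Th window, followed by
one MS1 survey scan over m/z 400–900. Relative protein adsorption is then
the log10-transformed summed peptide-ion intensity in the MS1 scans, and
the polymer-to-polymer variation of that quantity can be modelled from
molecular descriptors of the monomers.

`lesaQuant` implements that computational workflow end to end:

1. **In-silico digestion** (`trypticDigest`, `freePeptides`) — fully
   tryptic peptides with configurable missed cleavages, and a
   disulfide-aware filter for the peptides actually released as free
   species.
2. **Run data model and I/O** (`Spectrum`, `MsRun`, `readRun`,
   `writeRun`, `writeMgf`, `cycles`) — centroided DIA runs organised in
   cycles.
3. **Spectral-library identification** (`SpectralLibrary`,
   `matchSpectrum`, `identifyRun`) — cosine similarity against reference
   fragment spectra, accepted at cos θ > 0.95 with ≥ 5 matched fragments.
4. **Label-free quantification** (`extractMs1Intensity`, `quantifyRun`,
   `buildAdsorptionTable`, `snrFilter`) — MS1 extracted intensities at
   10 ppm, imputation at the peak-intensity threshold of 1000, geometric
   means over triplicate spots and a replicate signal-to-noise (SNR)
   filter at 1.5.
5. **Descriptors** (`atomSignature`, `countSignatures`,
   `loadDescriptorTable`) — atom-centred signature fragment counts
   computed on monomers, plus ingestion of external (e.g. Dragon)
   descriptor tables.
6. **Modelling** (`lassoSelect`, `emSparseRegression`,
   `bootstrapEvaluate`, `rankCoefficients`) — LASSO feature selection and
   sparse multiple linear regression fitted by expectation maximization,
   evaluated over repeated 80/20 splits.
7. **Synthetic data** (`simulationConfig`, `simulateStudy`,
   `processStudy`) — a generator that produces ground-truthed DIA runs
   and descriptor matrices so every stage can be verified without
   external data.

## The insulin worked example

Mature insulin has two chains held together by three disulfide bridges
(A6–A11, A7–B7, A20–B19). Complete tryptic digestion cleaves the B chain
after R22 and K29, but every resulting peptide except GFFYTPK (and the
single residue T) still contains a disulfide-bonded cysteine and stays
tethered to the rest of the molecule. The only free peptide of useful
length is therefore GFFYTPK:

```{r insulin}
ins <- e8Proteins()$insulin
digest <- trypticDigest(ins, maxMissed = 0)
freePeptides(ins, digest, minLength = 2)[, c("sequence", "chain", "start", "end")]
```

The package distinguishes the *formation* of peptides (complete
digestion, 0 missed cleavages) from the *identification search space*
(up to 2 missed cleavages): under missed cleavages GFFYTPKT would also be
free, so the worked example only holds for the complete digest.

## Identification and quantification model

MS2 scans are matched only against library entries whose precursor m/z
falls in the scan's isolation window, taken half-open
`[target − w/2, target + w/2)` so boundary behaviour is deterministic.
Peak pairing is greedy by ascending |Δm/z| with one-to-one use and a
0.02 Da admission tolerance. The cosine is computed over the *union*
vector: unmatched peaks on either side contribute to their own norm and
so penalize the score. This is the conservative reading of "cosine
correlation" and is what makes the 0.95 threshold meaningful; a
matched-peaks-only vectorization and sqrt/log intensity weightings exist
as options since the convention is not uniquely determined. Greedy
pairing is provably equal to the exhaustive optimal pairing whenever
peaks are separated by more than twice the tolerance — always the case
for centroided peptide fragment spectra at 0.02 Da — and the test suite
verifies that equality against a brute-force oracle on 1,000 random
sparse instances.

Quantification follows identify-then-quantify: a protein's intensity in
a run sums only target ions whose peptide was accepted in that same run.
Per MS1 scan, peak intensities within 10 ppm of the target are summed;
the run-level value is the *median* over MS1 scans with at least one
in-window peak, which is robust to single-scan electrospray instability.
Missing intensities are imputed at the linear-scale peak-intensity
threshold of 1000 (log10 = 3) *before* per-protein summation and the log
transform — imputation is described at the peptide level and the log
requires positivity; the alternative order is available through the
configuration. Replicates are aggregated by geometric mean because spot
replicate noise is multiplicative, and rows must pass a replicate SNR
(mean over sample standard deviation, n−1 denominator, linear scale)
strictly greater than 1.5. Linear-scale SNR is the conventional reading
of "signal-to-noise"; a log10-scale variant is exposed as a
configuration option.

## The sparse regression

The response for each protein is the log10 geometric-mean intensity over
the SNR-passing polymers; the design matrix holds molecular descriptors.
Two stages:

**LASSO selection.** L1-penalized regression with the penalty chosen by
5-fold cross-validation under the 1-SE rule, which biases towards
sparsity. The empty selection is legitimate (and is the usual outcome on
pure-noise responses).

**EM sparse refit.** On the selected columns a Bayesian linear model
with a Laplace prior is fitted by expectation maximization, using the
Laplace distribution's representation as a scale mixture of normals:
conditional on a per-coefficient variance τ_j, w_j ~ N(0, τ_j) with
exponentially distributed τ_j. The E-step computes the expected inverse
scale u_j = λ/|w_j| at the current estimate; the M-step solves the
weighted ridge system (XᵀX + diag(u)) w = Xᵀy on the standardized
design. Each M-step maximizes a quadratic surrogate that touches and
majorizes the L1 penalty at the current iterate, so the penalized
log-likelihood is non-decreasing at every iteration; the implementation
asserts this and stores the trace. Coefficients whose magnitude falls
below `pruneTol` (10⁻⁸) are frozen at exactly zero — the E-step weight
diverges as w → 0, so this is both the sparsity mechanism and the
numerical guard. λ defaults to 10⁻³ on the standardized scale: LASSO has
already removed irrelevant columns, so the refit applies only mild
shrinkage and reduces to OLS as the signal-to-noise ratio grows.

Evaluation uses repeated random 80/20 splits ("bootstraps" in the loose
sense; 80/20 proportions are incompatible with classical
with-replacement bootstrap sizing, so Monte-Carlo cross-validation is
the default and the with-replacement reading is not implemented).
Standardization parameters come from the training split only. Test R²
uses the total sum of squares about the *test-split* mean; a test split
with zero response variance records NA and is excluded from summaries.
LASSO runs inside each split by default (no selection leakage);
`lassoMode = "single"` reproduces the leakier run-once variant.
Coefficient interpretation aggregates the per-split fits: selection
frequency, mean coefficient over the fits where the feature was
selected, and sign consensus, with "significant" meaning selected in
more than half the splits.

```{r model-demo}
gen <- generatePolymerLibrary(simulationConfig(nPolymers = 70, seed = 11),
                              proteins = "insulin")
X <- descriptorValues(gen$descriptors)
set.seed(12)
y <- gen$truth$logAdsorption[, "insulin"] + rnorm(70, 0, 0.15)
br <- bootstrapEvaluate(X, y, modelConfig(nBoot = 20L, seed = 13L))
br
head(rankCoefficients(br))
rownames(gen$truth$coefficients)[gen$truth$coefficients[, 1] != 0]
```

## Signature descriptors

Fragment descriptors are canonical atom-centred substructure strings:
the root element followed by parenthesized neighbour subtrees, sorted
lexicographically at every level, with bond orders not encoded. At
height 1 the central carbon of tert-butanol gives `C(CCCO)`; at height 2
each neighbour is expanded one level excluding the edge back to the
root, e.g. `C(C(CFF)C(FFF)FF)` for the backbone carbon of a
perfluorinated side chain and `C(C(O)O(C))` for an ethylene-glycol-like
unit. SMILES parsing is delegated to ChemmineR/ChemmineOB (which
kekulizes aromatic rings; an optional lowercase aromatic labelling
exists but defaults to off since the printed descriptor convention shows
none). Dragon descriptors are proprietary and are only ever *ingested*
from CSV; the one structural stand-in provided, `countTertiaryAmines`
(aliphatic N bonded to exactly three carbons by single bonds, amides
excluded), is a documented proxy for the constitutional count nRNR2 and
is used only in synthetic studies.

## What the simulator emulates — and what it does not

`simulateStudy` generates, per polymer spot and replicate, a DIA run
whose MS2 scans are the targets' library spectra under multiplicative
lognormal peak noise plus uniform noise peaks, and whose MS1 scans carry
one peak per targeted ion at its precursor m/z (±3 ppm uniform jitter)
with intensity `amount × response × lognormal noise`. Response factors
sum to 1 per protein, so the summed peptide-ion intensity of a protein
equals its adsorbed amount — with all noise disabled
(`noiselessConfig()`) the full pipeline must recover the true log10
adsorption to floating-point accuracy, and the acceptance suite verifies
that closure. Defaults mirror the study conditions: 208 polymers in
triplicate, 10 DIA cycles per run, isolation width 1 Th, MS1 range
400–900 Th, log10 noise sd 0.15, replicate CV 0.2, dropout probability
0.1, 120 descriptors (80% Poisson(1) counts, 20% standard normal) with
5 true features per protein whose magnitudes (drawn from [0.5, 1]) are
at least three times the log10 noise sd. Insulin enters through GFFYTPK
alone (charges 1–2); the other proteins through up to five free tryptic
peptide ions within the MS1 range, ranked by descending precursor m/z.
The number of DIA cycles per 2-minute acquisition is not documented for
the instrument method, so it is an explicit parameter (default 10).

Deliberate simplifications: single monoisotopic sticks instead of
isotope envelopes (quantification reads a single target m/z, so
envelopes add no testable behaviour), no electrospray or digestion
kinetics, no retention-time structure (LESA is direct infusion), and no
chimeric interference beyond the random noise peaks. Passing tests
therefore demonstrate the correctness of the computational chain under
the stated noise model, not robustness to every artefact of real
spectra. A protein whose peptides all fall outside the MS1 range would
be dropped from the targeted scheme entirely (with the bundled panel
this does not occur; whether TGF-β1 was ever detected in the real study
is unknown, and an all-dropout protein simply quantifies at the
imputation floor).

The bundled protein panel uses the exact mature insulin chains and
disulfide topology, and standard mature sequences for FGF-2 (155
residues) and TGF-β1 (112 residues). The transferrin entry is a
clearly-labelled synthetic surrogate chain — adequate for exercising
digestion, simulation and quantification, but not the human
serotransferrin sequence, which could not be bundled verbatim.

## Numerical choices and degenerate inputs

* Identical replicates give SNR = ∞ and pass any threshold; fewer than
  two replicates give an undefined SNR and never pass.
* The SNR filter is strict (`>`), so a row at exactly 1.5 is removed.
* Acceptance of an identification is strict in the cosine
  (cos = 0.95 exactly fails) and non-strict in the fragment count.
* Empty spectra match with cosine 0 and are never accepted.
* Ties in the per-scan winner break by higher matched-fragment count,
  then lexicographic peptide id.
* The EM's M-step retries once with a 10⁻¹⁰ ridge jitter on a singular
  system before failing; the objective monotonicity assertion allows
  only float-level slack (10⁻⁸ relative), and pruning perturbs the
  objective by at most the prune tolerance.
* Signature subtree sorting uses radix (C-locale) order so descriptor
  strings do not depend on the session locale.
* Per-stage seeds derive deterministically from the global seed, and
  identical configuration plus seed reproduces every result bit for bit.

## Droplet geometry

`dropletCapVolume` implements the spherical-cap model
V = (π a³/3)(1−cos θ)²(2+cos θ)/sin³ θ for a sessile droplet with
contact radius a and contact angle θ. For a 1.4 mm spot (a = 0.7 mm) at
θ = 5.2° it gives ≈ 24.5 nL. The much smaller volume sometimes quoted
for such droplets (sub-nanoliter) is not reproducible from this geometry
with those inputs; the function implements the stated closed form and
this discrepancy is documented rather than fitted.

## Problem sizes used in the checks

The package's own verification uses scaled problem sizes chosen to make
the properties sharp while keeping the suite quick to run: the noiseless
closure on 10–16 polymers (the closure is exact row by row, so size adds
nothing), matcher oracles on 1,000 random instances with up to 8 peaks a
side, the full-noise study at the complete 208-polymer scale in the
acceptance script, and parameter recovery on the 70-polymer / 120-
descriptor / 5-true-feature scenario over 20 seeds with 50 splits each.

## Known limitations

* No FDR control or decoy libraries: identification quality rests on the
  cosine and fragment-count thresholds, as targeted DIA of a four-protein
  medium permits; library construction by database search is out of
  scope.
* No cross-run normalization; intensities are compared as acquired.
* No isotope-envelope or charge-state deconvolution beyond the
  configured target ions.
* Descriptors are computed on monomers, not polymerized repeat units,
  and heights are limited to 1 and 2 (the printed descriptor vocabulary).
* The EM's λ is fixed, not estimated; it is a refit-stage regularizer,
  not the feature selector.
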