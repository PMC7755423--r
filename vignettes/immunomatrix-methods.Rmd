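---
title: "Methods: position-sensitive biophysical repertoire analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: position-sensitive biophysical repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(immunomatrix)
```

## The matrix model

CDR loops vary in length and show little conservation, so a classical
multiple alignment either fragments the data into length subgroups or
forces arbitrary gap placement. `immunomatrix` instead assigns each of
the six loops (CDR1–3 of light and heavy chain) a fixed span of matrix
columns and center-aligns every loop within its span; zeros fill the
padding and the buffer columns between spans. The structural intuition
is that loop centers — the apex residues that dominate antigen contact
— line up across sequences better than loop ends do. The cost is that
properties near loop edges are blurred across columns whenever lengths
vary; this is a deliberate trade, and every inference downstream is on
matrix columns, not residue numbering in any external scheme. Matrix
coordinates are 0-based with half-open spans.

Residues are encoded 1–21. Only three code assignments are treated as
fixed anchors (leucine 3, histidine 16, arginine 17, the values used in
the worked examples the package reproduces); the remaining order groups
residues by biophysical character — hydrophobic, then polar, then
charged — and code 21 is reserved for X/non-standard letters. Since
every analysis either tabulates codes symbolically (entropy, MI,
frequency maps) or immediately replaces them by property values, the
order of the un-anchored codes has no effect on any statistic; it is
still fixed for reproducibility and configurable in the property-table
CSV format.

Tunable encoding parameters:

* `bufferWidth` (columns of zeros between loops, default 3). Purely
  presentational — buffer columns are constant and excluded from
  testing — but kept configurable because exported matrices are meant
  to be eyeballed as heatmaps.
* Span widths: by default the maximum observed loop length per slot,
  computed over *both* classes so the two populations share one
  coordinate system. An explicit `MatrixLayout` can be supplied to
  co-embed datasets.
* Center-alignment tie-break: for odd padding the extra zero goes to
  the right (`floor((width − len)/2)` on the left). Any fixed choice
  would do; this one is frozen so encodings are byte-reproducible.

## The 62 property masks

A *mask* replaces each residue code by a per-residue scalar, turning
the symbol matrix into a real-valued one. The default `PropertySet`
holds 62 masks in three groups:

* **basic (5)** — `charge` is computed, not tabulated: the
  Henderson–Hasselbalch fractional protonation at pH 7 with side-chain
  pKa values D 3.65, E 4.25, H 6.0, C 8.3, Y 10.07, K 10.53, R 12.48.
  This reproduces the printed anchor values 0.00 (L), 0.091 (H), 1.00
  (R) at 3-decimal rounding; both pH and the pKa table are arguments.
  `hydrophobicity1` (Kyte–Doolittle) and `hydrophobicity2` (Eisenberg
  consensus) are rescaled to [−1, 1] so the two scales are comparable;
  `flexibility` (Vihinen B-value) and `bulk` (Zimmerman) are kept on
  their native scales (z-scoring happens at the feature stage anyway).
* **kidera (10)** — the ten published Kidera factors, shipped verbatim;
  they are standardized descriptors by construction, which the test
  suite checks (near-zero mean, unit-scale spread over the 20
  residues).
* **hotspot (47)** — structural-propensity scales (helix, sheet, turn
  preferences) drawn at run time from the AAindex collection bundled
  with `seqinr` and z-scored over the 20 residues. These are a
  reconstruction of a curated "hotspot variable" set whose exact
  membership is not published alongside the method; the one anchored
  choice is `hotspot6`, pinned to Chou–Fasman α-helix propensity
  because that variable's documented role is α-helix propensity. The
  whole table is data, not code — `loadPropertyTable()` swaps in any
  residue-by-property CSV without touching logic.

Code 21 (X) takes the value 0 under every mask: a neutral imputation,
announced via a message when X residues are actually present. Buffer
and padding zeros also map to 0, so masked matrices stay sparse in
exactly the places the encoding is silent.

## Position statistics

`positionMeanProfile()` reports per-column class means with bootstrap
standard errors: the SD of the column mean over resamples drawn with
replacement *within* class (the empirical distribution), 1000
iterations by default.

`studentizedBootstrapTest()` is the two-sample test used per column.
The statistic is the Studentized mean difference

    z = (Ȳ₂ − Ȳ₁) / sqrt(σ₂²/n₂ + σ₁²/n₁)

with n−1 sample variances. The denominator is the *sum* of the
per-group variance terms — the standard form of the Studentized
statistic; a difference under the root would not be a norm and can go
negative. Null replicates pool both groups without labels and draw n₁
and n₂ values with replacement from the pool (`mode = "pool"`, the
default); `mode = "partition"` randomly splits the pool instead, for
users who prefer the permutation-flavoured null. Two-sidedness comes
from squaring: `p = (1 + #(z² ≥ z₀²))/(R + 1)`, so p is never 0 and
its floor is exactly 1/(R+1). Degenerate inputs have fixed
conventions: both groups constant and equal gives z₀ = 0, p = 1; both
constant but unequal is treated as exceeding every finite null
statistic, p = 1/(R+1).

`permutationTest()` implements the count rule
`p = (1 + #(t ≥ t₀))/(R + 1)` for an arbitrary statistic (difference
of means by default, vectorised). The rule is one-sided in the supplied
statistic; the MI-difference analysis passes |ΔI| so its test is
two-sided.

`profileSignificance()` Bonferroni-corrects with `p_adj = min(1, m·p)`
where m defaults to the number of *testable* columns (columns all-zero
in both classes are skipped as "not testable"), flags columns at
`p_adj ≤ alpha`, and reports contiguous flagged runs as half-open
intervals. One arithmetic consequence worth knowing: the adjusted
p-value can never go below m/(R+1), so with ~76 testable columns and
R = 1000 no column can clear α = 0.05 regardless of effect size. The
recovery analyses in the test suite and acceptance script therefore run
the profile at R = 4999; R = 1000 remains the default and is the value
used for single-column testing and calibration.

Both tests are seeded and bit-reproducible. Their type-I error is
checked by simulation (1000 null repeats at n = 50/50) to lie in
[0.03, 0.07] at nominal 0.05.

## Entropy and mutual information

Per-column Shannon entropy and pairwise mutual information use plug-in
(maximum-likelihood) estimators in bits:
`H(X) = −Σ p̂(x) log₂ p̂(x)`, `H(X|Y)` from the joint histogram, and
`I(X;Y) = H(X) − H(X|Y)`, clipped at 0 to absorb −1e−15 float dust.
The estimator choice is deliberate — no bias correction — because the
class *difference* of MI is the quantity of interest and the plug-in
bias largely cancels between classes of similar size; the estimator is
the natural place to add a Miller–Madow correction later. Note the
analytic maximum for 20 equiprobable residues is log₂20 ≈ 4.32 bits,
and that is the value the package computes and tests.

The buffer/gap code 0 is included as an ordinary symbol by default:
loop-edge columns then carry loop-length information, which is real
signal, not an artifact. `gapMode = "exclude"` restricts estimation to
residue-bearing rows for users who want composition only.

`miDifferenceWithSignificance()` computes ΔI = I(class A) − I(class B)
per column pair and attaches a per-pair permutation p under label
shuffles of |ΔI|, sharing one set of R shuffles across all pairs. Cost
grows as R·L², so the function accepts a `columns` restriction; the
package's own analyses restrict to the loop under study when L is
large.

## Discriminant analysis and classification

`selectFeatures(method = "top_diff")` ranks z-scored features by
absolute class-mean difference, then walks the ranking greedily
dropping any feature correlated above 0.75 (|Pearson r|) with an
already-kept one, and truncates to k = 75. Both values are exposed: k
is the overfitting control, and 0.75 removes the mask redundancy that
inevitably arises when several masks of the same column respond to the
same residue swap. `method = "pca"` substitutes the first k principal
components (components are sign-fixed by making each one's
largest-magnitude loading positive, so results are deterministic).

`ldaFitProject()` is Fisher's two-class discriminant on all data
("mode 1"): `w = Sw⁻¹(μ_A − μ_B)`; a ridge of 1e−6 on the diagonal is
added (with a message) only when the scatter solve fails. Separation
accuracy is the fraction of sequences on the correct side of the
midpoint between projected class means — the midpoint is the natural
threshold when no prior is assumed — and the orientation is chosen so
training accuracy is ≥ 0.5 by construction. Feature count must be
below the sequence count; this is the overfit guard that forces a
selection step first.

`svmLoocv()` is the honest-classification mode: a linear-kernel SVM
(unit cost, class-balanced weights — the minimal, undertuned
configuration) evaluated by leave-one-out cross-validation in which the
standardization *and* the feature selection are refit on each fold's
training rows only. The no-leakage property — perturbing a held-out row
cannot change its fold's selected features — is asserted in the test
suite. `scrambledControl()` repeats the whole procedure under random
label permutations; for balanced classes its expected accuracy is 0.5,
and that band is the package's yardstick for "the classifier learned
something real".

## MHC/MHC-like platform domains

Aligned platform-domain sequences (equal-width FASTA per class) are
segmented by user-declared structural feature boundaries — 0-based
half-open intervals naming the β-strands and α-helices — and each
feature is center-aligned into its own span after in-segment gap
stripping (a flag preserves gaps instead, encoding them as X).
Structure prediction is deliberately out of scope: boundaries are
plain configuration (YAML/JSON or data.frame), which keeps the
pipeline deterministic and lets users bring boundaries from any
predictor. Once encoded, the object is an ordinary `EncodedMatrix` and
every module above applies unchanged.

## The synthetic generator

`generateRepertoire()` exists so that every stage can be validated
against known ground truth without any external download. It emulates
the *structure* of a curated polyreactivity dataset: two labeled
classes of six-loop records with configurable sizes (defaults 529/524,
the aggregate-scale composition such studies report), per-loop length
distributions (CDR3H 10–22, the dominant length-varying loop; CDR2H
fixed at 8, realistic for heavy-chain CDR2; the others narrow ranges),
a residue background (uniform by default; a "natural" preset with
CDR-like serine/glycine/tyrosine enrichment; or any named frequency
vector, including restricted alphabets for analytic MI fixtures), and
reactivity counts drawn consistently with the class (4–7 bound ligands
for polyreactive, 0 for non-polyreactive, mirroring the parsed
labeling scheme).

Signals are implanted with known coordinates: `implantPropertyShift()`
replaces residues at chosen within-loop offsets by draws from a chosen
set with probability δ (e.g. {R, K} at δ = 0.5 to shift charge), and
`implantCoupling()` copies the residue at column i to column j with
probability c (creating mutual information; with a uniform 4-letter
background and c = 1 the analytic limit is 2 bits, which the estimator
reaches within 0.1 bit at n = 2000). Label noise, if any, is applied
after implantation. Everything is reproducible from (spec, seed).

What the generator does *not* emulate — and hence what passing tests
do not show about real data: somatic-hypermutation lineage structure
(records are independent draws, not clonally related), V/D/J gene-usage
composition, position-dependent residue preferences beyond the
implanted signals, and correlations between loop length and loop
composition. Calibration results transfer to real data only insofar as
real sequences are exchangeable under the null, which clonal expansion
can violate.

`generatePlatformClasses()` plays the same role for the MHC path: two
180-residue platform-domain classes (four features of 45 columns —
realistic domain size matters here, because PCA class recovery depends
on averaging over enough columns) whose residue draws are biased 0.7
toward a hydrophobic or a polar set, plus held-out test members from
each class.

## Problem sizes and numerical conventions

The shipped tests and the acceptance script run at desk scale, chosen
to make each check statistically decisive while keeping the full suite
in the minutes range: 1000 null simulations at n = 50/50 for test
calibration; n = 200/200 (shift) and 500/500 (coupling) for recovery;
n = 100/100 with k = 75 features for LOOCV; 20 seeds for platform
recovery. Numerical conventions collected in one place: p-values are
floored at 1/(R+1) and never 0; MI is clipped at 0; constant feature
columns z-score to 0; PCA signs are fixed by the largest loading;
degenerate two-sample inputs follow the conventions listed above; all
RNG flows from explicit seeds.

## Known limitations

* The un-anchored part of the 1–21 code order and the exact membership
  of the 47 hotspot masks are reconstructions; both are data-level
  choices a user can replace wholesale.
* Plug-in entropy is biased upward at small n; per-class MI values at
  n below a few hundred should be read comparatively, not absolutely.
* The Bonferroni floor m/(R+1) couples the achievable adjusted p to R;
  raise R when testing many columns.
* LOOCV accuracy on δ = 0.5 fixtures has an intrinsic ceiling well
  below 1 (the classes genuinely overlap); monotonicity in δ, the
  scrambled-label control, and the no-signal control are the robust
  checks, and single-number accuracies should always be read against
  them.
* Linear models on masked features cannot express arbitrary per-residue
  scoring unless enough independent masks are included; the 62-mask set
  spans residue space generously, but feature selection at small k can
  remove that freedom.
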