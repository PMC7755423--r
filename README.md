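# immunomatrix

Position-sensitive biophysical matrix analysis of immune-receptor
repertoires.

## The problem

Antibody binding behaviour — for instance *polyreactivity*, the
low-affinity binding of one antibody to many biochemically diverse
ligands — is written into the six hypervariable CDR loops, but those
loops vary in length and resist conventional alignment. `immunomatrix`
sidesteps alignment by center-aligning every CDR loop into its own span
of a fixed-width matrix: each residue becomes an integer 1–21 (leucine
= 3, histidine = 16, arginine = 17; 21 is reserved for X), and zeros
buffer the loops. Every downstream analysis operates on this one
coordinate system:

* **Property masks** — the integer codes are replaced by per-residue
  biophysical values. The default set has 62 masks: charge (the
  Henderson–Hasselbalch fractional side-chain charge at pH 7, so
  L/H/R → 0.00/0.091/1.00), two hydrophobicity scales, side-chain
  flexibility and bulk, the ten Kidera factors, and 47
  structural-propensity ("hotspot") scales.
* **Position statistics** — per-column class means with bootstrap
  standard errors, a two-sided nonparametric Studentized bootstrap test
  (`z = (Ȳ₂ − Ȳ₁)/√(σ₂²/n₂ + σ₁²/n₁)`, pooled-null resampling,
  `p = (1 + #(z² ≥ z₀²))/(R + 1)`), a label-permutation test, and
  Bonferroni correction with contiguous-run reporting.
* **Information theory** — per-column Shannon entropy
  `H(X) = −Σ p(x) log₂ p(x)` and pairwise mutual information
  `I(X;Y) = H(X) − H(X|Y)` in bits, plus class MI-difference maps with
  permutation significance ("loop crosstalk").
* **Classification** — amino-acid frequency-difference maps, PCA,
  two-mode linear discriminant analysis, top-difference feature
  selection with a correlation filter, and a linear-kernel SVM
  evaluated by leave-one-out cross-validation with scrambled-label
  controls.
* **MHC platform domains** — aligned MHC/MHC-like sequences are
  segmented by user-declared structural features (β-strands,
  α-helices) into the same matrix form, so the whole pipeline applies
  unchanged.
* **Synthetic repertoires** — a deterministic generator with
  implantable property shifts and positional couplings provides ground
  truth for every stage.

## Worked example

Generate a two-class repertoire in which the polyreactive class is
enriched for charged residues (R/K, probability 0.5) across CDR2H, then
locate and classify that signal:

```r
library(immunomatrix)

spec <- fixtureSpec(nPoly = 100, nNon = 100,
  shifts = list(list(loop = "cdr2h", positions = 0:7,
                     residues = c("R", "K"), delta = 0.5,
                     class = "polyreactive")))
gen <- generateRepertoire(spec, seed = 7)
em  <- encodeRepertoire(gen$records)
em
#> EncodedMatrix: 200 sequences x 91 positions
#>   labels: polyreactive=100, non_polyreactive=100, excluded=0, unknown=0
#> MatrixLayout: 6 segments, buffer 3 -> 91 columns
#>   cdr1l    width 17  span [0, 17)
#>   ...
#>   cdr2h    width  8  span [58, 66)
#>   cdr3h    width 22  span [69, 91)

prof <- profileSignificance(applyMask(em, "charge"), R = 4999, seed = 1)
subset(prof, significant, select = c(column, segment, mean_A, mean_B, p_adj))
#>    column segment mean_A  mean_B  p_adj
#> 59     58   cdr2h  0.513 -0.0687 0.0152
#> 60     59   cdr2h  0.512 -0.0219 0.0152
#> ...
#> 66     65   cdr2h  0.423  0.0513 0.0152
attr(prof, "runs")
#>      start end
#> [1,]    58  66

feat   <- buildFeatureMatrix(em, c("charge", "hydrophobicity1"),
                             standardize = FALSE)
report <- svmLoocv(feat, rowLabels(em), k = 75, seed = 7)
report$accuracy
#> [1] 0.925
```

The profile finds exactly the implanted loop: all eight CDR2H columns
(one contiguous run `[58, 66)`) show a Bonferroni-adjusted bootstrap
p of 0.0152, with class mean charge ≈ 0.5 in the polyreactive class
versus ≈ 0 in the non-polyreactive class. The LOOCV classifier
recovers the class label for 92.5% of held-out sequences; on
label-scrambled data the same pipeline stays at chance.

## Command line

A thin wrapper over `runPipeline()` ships in
`inst/scripts/immunomatrix-cli.R`:

```sh
Rscript inst/scripts/immunomatrix-cli.R simulate --seed 5 --out sim
Rscript inst/scripts/immunomatrix-cli.R classify --input sim/repertoire.csv --out cls
```

Subcommands: `encode`, `profile`, `entropy`, `mi`, `classify`, `mhc`,
`simulate`. Every run serializes its full configuration (including the
seed) into the output directory.

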