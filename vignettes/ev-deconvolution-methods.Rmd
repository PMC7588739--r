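---
title: "Methods: signature construction and EV mixture deconvolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signature construction and EV mixture deconvolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

A bulk extracellular-vesicle long-RNA (exLR-seq) profile is modelled as a
linear mixture of subset-specific expression: for a fluid sample with TPM
vector $a$ over the signature genes,

$$ a = B x + e, $$

where $B$ (genes $\times$ subsets) holds the mean TPM of each marker gene
in each candidate tissue or blood-cell type, $x \ge 0$ are the mixing
contributions, and $e$ absorbs measurement noise and content from sources
not represented in $B$. The model assumes (i) expression mixes additively
in TPM space, (ii) marker genes behave in EVs proportionally to their
behaviour in the reference atlas, and (iii) unrepresented content is not
systematically collinear with a signature column. Assumption (ii) is the
weakest in practice — EV packaging is selective — which is why the
signature is additionally filtered against a background cohort of real
fluid profiles (below) and why every deconvolution carries a p-value for
"no signature content at all".

## Building the signature matrix

**Tissue-specificity score (TSS).** For each gene and subset $t$, with
$m_t$ the mean TPM in $t$, $m_{\max}$ the largest mean over all other
subsets, and pseudocount $\varepsilon = 1$ TPM,

$$ \mathrm{TSS} = \#\bigl\{ k \in \{2,4,8,16,32\} :
   (m_t+\varepsilon) \ge k\,(m_{\max}+\varepsilon) \bigr\}. $$

This yields an integer 0–5 scale, is monotone in enrichment, and is safe
for zero denominators. Under this definition a gene can score above 0
only in the unique subset where it is maximally expressed; a score of 5
marks a $\ge$32-fold enrichment. The pseudocount means scores are only
scale-invariant when $\varepsilon$ is scaled with the data (or
expression $\gg \varepsilon$), which the tests assert in exactly that
form. The tiered-fold-change definition is this package's own concrete
choice for the 0–5 scale; other monotone definitions would be admissible.

**Candidate selection.** Genes whose maximal TSS *strictly* exceeds the
threshold (default 2 for tissue panels, 0 for blood-cell panels, where
markers are more abundant but less exclusive) are assigned to their
maximal subset, ties broken lexicographically by subset label. Before
scoring, subsets expected to confound a solid-tissue panel can be removed
with `excludeSubsets()`; `defaultTissueExclusions()` supplies the
conventional lists for a whole-body atlas (immune-dominated,
gender-biased, and hemopoietic-related subsets — 15 labels, leaving 16
solid-tissue subsets out of a 31-tissue atlas). The lists are
configuration, not hard-coded behaviour, because they are atlas-specific.
The gender-biased list deliberately contains all eight such labels even
though they are sometimes counted as seven.

**Frequency filter.** Markers that are essentially never observed in the
fluid of interest cannot help deconvolute it. `expressionFrequency()`
computes, per gene, the fraction of background-cohort samples with TPM
strictly above a detection threshold (default 0), and
`filterByFrequency()` retains candidates with frequency *strictly*
greater than `minFreq` (default 0.1, so a frequency of exactly 0.10 is
removed). Strict comparisons are used consistently at both thresholds.

**Top-n selection and condition-number optimization.** Within each
subset, candidates are ranked by TSS descending, then mean target-subset
TPM descending, then gene identifier — a deterministic key favouring both
specificity and abundance. `buildSignature(n)` takes the top $n$ per
subset and fills $B$ with subset means. `optimizeSignature()` rebuilds
the matrix for every $n$ in a range (default 2–150, bracketing realistic
panel sizes of roughly 6 tissue markers or 100 blood-cell markers per
subset) and keeps the $B$ with minimal 2-norm condition number
$\kappa(B) = \sigma_{\max}/\sigma_{\min}$; a lower $\kappa$ makes the
solution less sensitive to perturbations of the input profile. Ties go to
the smaller $n$ (fewer genes, cheaper solve), rank-deficient matrices get
$\kappa = \infty$, and the full $(n, \kappa)$ trace is stored in the
provenance. Blood and tissue panels built separately can be stacked with
`mergeSignatures()` to split a sample's total signal into blood versus
tissue; genes missing from one panel are filled from that panel's atlas
means when supplied, else 0.

## Solving the mixture

**Normalization.** `matchAndNormalize()` intersects mixture and signature
genes (unmatched signature genes are dropped with a warning and the
matched fraction is reported; no imputation is attempted) and z-scores
the mixture vector. By default every signature column is z-scored as
well: this puts basis and mixture on a common scale, which the ν-SVR's
$\varepsilon$-tube geometry needs, and removes the arbitrary per-column
TPM magnitude. Because standardization rescales the problem, solver
coefficients $\beta$ are mapped back to the original TPM mixing scale as
$x_j = \beta_j \,\mathrm{sd}(a)/\mathrm{sd}(b_j)$; with that back-scaling
an exactly constructed mixture is recovered exactly by the constrained
least-squares solvers. A `"mixture-only"` scheme (z-score only the
mixture) is available for comparison with pipelines that leave the basis
raw.

**Solvers.** Six are provided behind one interface:

| method | implementation | notes |
|--------|----------------|-------|
| `svr`  | ν-SVR, linear kernel (`e1071::svm`) | core method; ν grid 0.05–0.95 step 0.05, chosen by minimal reconstruction RMSE, ties to the smaller ν (fewer support vectors) |
| `nnls` | Lawson–Hanson active set (`pracma::lsqnonneg`) | coefficients ≥ 0 |
| `qp`   | Goldfarb–Idnani dual QP (`quadprog::solve.QP`) | same optimum as NNLS in `nonneg` mode; optional sum-to-one equality constraint |
| `ols`  | QR least squares | unconstrained; minimum-norm fallback when rank-deficient |
| `rlr`  | Huber M-estimation (`MASS::rlm`), k = 1.345, tol 1e-6, ≤ 100 iterations | downweights outlier genes |
| `ridge`| closed form $(B^\top B+\lambda I)^{-1}B^\top a$ | λ by generalized cross-validation over $10^{-6}..10^{4}$ when unset |

The ν grid spans the open interval only — ν-SVR is degenerate at the
endpoints 0 and 1. The QP adds a relative $10^{-10}$ diagonal nudge
because the dual method requires strict positive definiteness; the
sum-to-one mode renormalizes the (already near-feasible) solution so the
constraint holds exactly. NNLS and QP deliberately travel different
algorithmic routes to the same optimum, which the tests exploit as a
cross-check.

**Outputs.** Relative fractions truncate negatives to zero and normalize
to sum to 1; if no coefficient is positive the sample is flagged
degenerate and reported as all-zero rather than renormalized from noise.
Absolute scores are the truncated, back-scaled coefficients without
renormalization — the package's definition of "absolute", chosen because
back-scaling already places coefficients on the TPM mixing scale shared
by all samples processed with the same signature and scheme. Both are
derived from the same raw coefficients, so doubling the raw vector
doubles absolute scores and leaves relative fractions unchanged.
Reconstruction fit (Pearson correlation and RMSE between $B\beta$ and the
standardized mixture) is computed from the solver's own coefficients.

**Empirical p-value.** The null hypothesis is that the sample contains
none of the signature's subsets. Each of `nIter` (default 500) Monte-Carlo
iterations draws, *without replacement*, a random gene subset of the
mixture of the same size as the matched signature gene set, assigns those
values to the signature gene positions, re-solves, and records the
reconstruction Pearson R. The one-sided p-value uses the add-one
correction $p = (1 + \#\{R_i \ge R_{obs}\})/(1 + n_{iter})$, so
$p \in [1/(n_{iter}+1), 1]$ and is never exactly 0. For the SVR solver,
ν is re-selected inside every permutation by default — the honest null,
since ν selection is part of the procedure being tested — with
`reuseNu = TRUE` available as the cheaper variant. Sampling without
replacement was chosen so a null draw is a genuine relabelling of the
observed profile; with-replacement draws would inflate ties. No
multiple-testing correction is applied across samples.

## Benchmarking utilities

`compareModels()` aggregates per-sample PCC/RMSE, per-subset detection
frequency (relative fraction strictly > 0 — the across-sample frequency
is what is thresholded downstream, not the per-sample fraction), and
per-subset estimate variance. `spikeInExperiment()` mixes a known source
profile into a background at grid proportions with per-gene
multiplicative log-normal noise (multiplicative, so TPMs stay
nonnegative; σ default 0.1), deconvolutes, and reports per-point absolute
error with a default 0.05 tolerance. `rocAUC()` is the rank statistic
(ties count one half; orientation is never auto-flipped — higher score
must mean positive class). `groupDifferenceTest()` gates on Shapiro–Wilk
at α = 0.05 per group, then applies a two-sided t-test (both normal) or a
two-sided Wilcoxon rank-sum test with tie correction; constant groups
route to Wilcoxon because Shapiro–Wilk is undefined for them.

## The synthetic-data generator

`generateReference()` emulates a grouped reference atlas: log-normal
baselines (markers around meanlog $\log 50$, sdlog 0.5; background genes
meanlog $\log 20$, sdlog 1), multiplicative replicate noise (sdlog 0.5),
and a 50-fold marker enrichment in the home subset. Presets size the two
realistic regimes: `"blood"` (7 subsets × 100 markers) and `"tissue"`
(16 subsets × 6 markers). `generateCohort()` draws mixing proportions
from a Dirichlet (concentration 1 per subset by default), forms
$B x$, applies per-gene multiplicative log-normal noise (σ default 0.1),
and adds an *unmodeled content* component: a fresh log-normal profile
over the whole gene space — signature genes included, so it genuinely
perturbs the solve — scaled to a configured fraction of total signal.
`generateNullCohort()` produces i.i.d. log-normal profiles independent of
any signature, used to calibrate the p-value.

What the generator does **not** emulate: selective RNA packaging into
EVs, count-level sampling noise, fragment-length or GC bias, platelet
activation during blood draw, or correlated marker co-expression across
subsets. Passing tests therefore demonstrate correctness of the
algorithms under the stated statistical model, not performance on real
exLR-seq data.

## Numerical choices and problem sizes

* Pseudocount 1 TPM in the TSS ratio; detection threshold TPM > 0.
* All tie-breaks deterministic (smaller ν, smaller n, lexicographic
  subset, gene-identifier ordering), so identical inputs yield
  byte-identical output files.
* Degenerate cases are explicit: constant mixtures error at
  normalization; all-nonpositive coefficient vectors are flagged rather
  than normalized; rank-deficient signatures give $\kappa = \infty$ and a
  minimum-norm OLS fallback.
* Every stochastic routine takes a seed; cohort-level runs derive
  per-sample sub-seeds.
* The test and acceptance simulations use desk-scale sizes chosen to make
  the checked properties sharp rather than exhaustive: reference atlases
  of 5–10 subsets with 5 replicates, signatures of 30–100 genes, cohorts
  of 10–20 samples, 200 null samples × 500 permutations for p-value
  calibration, and a 19-point spike-in grid.

## Known limitations

* The in-sample reconstruction PCC is maximized by unconstrained least
  squares by construction, so PCC-based solver rankings on synthetic
  cohorts compress to within ~1e-4 and should not be over-interpreted;
  on real fluid data the solvers separate on robustness, not in-sample
  fit.
* Absolute scores are comparable only across samples run with the same
  signature and normalization scheme.
* The p-value's null preserves the mixture's marginal value distribution
  but destroys gene identity; structured contamination that mimics a
  signature column can still produce small p-values.
* No batch correction, library-size renormalization, or multi-sample
  joint solving is attempted; TPM quantification is upstream of this
  package.
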