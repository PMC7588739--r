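# EVdeconv

Tissue and blood-cell-of-origin deconvolution for extracellular-vesicle
long RNA (exLR-seq) expression profiles.

## The problem

Extracellular vesicles (EVs) circulating in plasma, serum or CSF carry
long RNAs from every cell type that sheds them. A bulk exLR-seq profile is
therefore a mixture: under the standard linear-mixing assumption, the
observed expression vector of a fluid sample is

```
a  =  B x  +  e
```

where `B` is a **signature matrix** (mean TPM of subset-specific marker
genes in each of the candidate tissues or blood-cell types), `x` is the
vector of mixing proportions to be estimated, and `e` collects noise and
content from sources absent from `B`. EVdeconv provides both halves of
this workflow for researchers doing liquid-biopsy work with EV long-RNA
sequencing:

1. **Signature construction** from a grouped reference expression atlas
   (e.g. a GTEx-style multi-tissue panel or isolated blood-cell profiles):
   - an integer 0–5 **tissue-specificity score** (TSS) per gene and
     subset — the number of fold-change tiers `{2,4,8,16,32}` satisfied by
     `(m_t + 1)/(max other m + 1)`;
   - candidate selection by a strict TSS threshold;
   - a **detection-frequency filter** against a background cohort of
     normal fluid profiles (keep genes detected in more than 10% of
     samples, by default);
   - **condition-number optimization**: the top-*n* markers per subset
     are chosen so that the 2-norm condition number κ(B) is minimal,
     making the inversion maximally tolerant to input noise.
2. **Deconvolution** of mixtures against `B`. The core solver is a
   linear-kernel **ν-support-vector regression** whose ν is selected by
   reconstruction RMSE over a grid; five comparators are provided (NNLS,
   nonnegative QP, ordinary least squares, Huber robust regression,
   ridge). Outputs per sample are raw coefficients, **relative fractions**
   (truncated at zero, normalized to sum to 1), **absolute scores**
   (truncated, unnormalized, comparable across samples), reconstruction
   PCC/RMSE, and a **Monte-Carlo empirical p-value** testing whether the
   sample contains any of the signature's subsets at all.

Benchmarking utilities (multi-solver comparison, spike-in detection-limit
curves, rank-statistic ROC AUC, normality-gated two-group tests) and a
synthetic-data generator with known ground truth round out the package.

## Worked example

Build a 16-subset tissue-style signature from a synthetic atlas, simulate
five mixtures with 20% unrelated content and 10% multiplicative noise,
and deconvolute them with the ν-SVR core:

```r
library(EVdeconv)

spec  <- generatorSpec(preset = "tissue", seed = 1)
ref   <- generateReference(spec)
tss   <- computeTSS(ref$atlas, ref$groups)
cands <- selectSpecificGenes(tss, 2)          # keep TSS > 2
sig   <- optimizeSignature(ref$atlas, ref$groups, cands, nRange = 2:6)
sig
#> SignatureMatrix: 96 genes x 16 subsets; condition number 2.1829

coh <- generateCohort(sig, 5, generatorSpec(preset = "tissue",
                                            unmodeledFraction = 0.2,
                                            noiseSd = 0.1, seed = 2))
res <- deconvolve(coh$mixtures, sig, solverOptions("svr"),
                  nPerm = 100, seed = 3)
res
#> DeconvolutionResult (svr): 5 samples x 16 subsets
#>   median reconstruction PCC: 0.9899
```

`as.data.frame(res)` gives one row per sample with `rel_*` (relative
fractions), `abs_*` (absolute scores), `pcc`, `rmse` and `p_value`
columns:

```
   sample method rel_subset_01 rel_subset_02 rel_subset_03    pcc   rmse p_value
1 mix_001    svr        0.0118        0.0057        0.0000 0.9935 0.1137  0.0099
2 mix_002    svr        0.1005        0.0058        0.0146 0.9935 0.1132  0.0099
```

A reconstruction PCC near 0.99 says the signature explains the mixture
well; `p_value = 0.0099` (the smallest value attainable with 100
permutations and the add-one correction) rejects the null that the sample
contains none of the 16 subsets. The estimated fractions track the
generator's ground truth closely — `cor(est, truth)` for the first sample
is 0.9986.

A thin command-line wrapper with `simulate`, `build-signature`,
`deconvolve` and `spikein` subcommands is installed under
`inst/scripts/evdeconv`.

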