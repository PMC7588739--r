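#' @import methods
NULL

#' Genes-by-samples expression matrix of nonnegative TPM values
#'
#' Thin S4 wrapper around a base numeric matrix that enforces the contract
#' shared by every function in the package: unique, non-empty gene and
#' sample identifiers and finite, nonnegative values (TPM scale). Because
#' the class `contains = "matrix"`, all ordinary matrix operations
#' (subsetting, `rownames()`, `%*%`, ...) work directly; subsetting returns
#' a plain matrix.
#'
#' @slot .Data numeric matrix, genes in rows, samples in columns.
#' @seealso [ExpressionMatrix()], [readExpressionMatrix()]
#' @export
setClass("ExpressionMatrix", contains = "matrix", validity = function(object) {
    v <- object@.Data
    if (!is.numeric(v)) return("values must be numeric")
    if (nrow(v) < 1L || ncol(v) < 1L) return("need at least 1 gene and 1 sample")
    if (is.null(rownames(v)) || is.null(colnames(v)))
        return("gene and sample identifiers are required (dimnames)")
    if (anyDuplicated(rownames(v))) return("duplicate gene identifiers")
    if (anyDuplicated(colnames(v))) return("duplicate sample identifiers")
    if (any(!is.finite(v))) return("all values must be finite")
    if (any(v < 0)) return("negative expression values are not allowed")
    TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix with gene identifiers as rownames and sample
#'   identifiers as colnames; all values finite and `>= 0`.
#' @return an [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(c(1, 0, 5, 2, 3, 4), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
#' ExpressionMatrix(m)
#' @export
ExpressionMatrix <- function(values) {
    new("ExpressionMatrix", as.matrix(values))
}

#' Tissue-specific score table
#'
#' Integer specificity scores in 0..5, one per gene and subset, together
#' with the per-subset mean TPM matrix they were derived from (kept so that
#' downstream candidate selection and signature merging can reuse the means
#' without re-touching the atlas).
#'
#' @slot scores integer matrix, genes x subsets, every entry in `{0,...,5}`.
#' @slot subsetMeans numeric matrix, genes x subsets, mean TPM per subset.
#' @seealso [computeTSS()]
#' @export
setClass("TSSTable",
    representation(scores = "matrix", subsetMeans = "matrix"),
    validity = function(object) {
        s <- object@scores
        if (!all(s %in% 0:5)) return("scores must be integers in 0..5")
        if (!identical(dim(s), dim(object@subsetMeans)))
            return("scores and subsetMeans must share dimensions")
        if (!identical(dimnames(s), dimnames(object@subsetMeans)))
            return("scores and subsetMeans must share dimnames")
        TRUE
    })

#' Signature matrix of subset-specific marker genes
#'
#' The deconvolution basis: mean TPM of each selected marker gene in each
#' subset (tissue or blood-cell type), plus the 2-norm condition number and
#' the construction parameters (provenance). Extends
#' [ExpressionMatrix-class], so it can be used wherever a genes-by-columns
#' matrix is expected.
#'
#' @slot conditionNumber ratio of largest to smallest singular value
#'   (`Inf` when rank-deficient).
#' @slot provenance named list of build parameters: TSS threshold,
#'   frequency threshold, chosen n per subset, and the (n, kappa) search
#'   trace when produced by [optimizeSignature()].
#' @seealso [buildSignature()], [conditionNumber()]
#' @export
setClass("SignatureMatrix", contains = "ExpressionMatrix",
    representation(conditionNumber = "numeric", provenance = "list"),
    validity = function(object) {
        if (length(object@conditionNumber) != 1L)
            return("conditionNumber must be a single number")
        if (!is.na(object@conditionNumber) && object@conditionNumber < 1)
            return("conditionNumber must be >= 1")
        if (nrow(object@.Data) < ncol(object@.Data))
            return("signature needs at least as many genes as subsets")
        TRUE
    })

#' Per-sample deconvolution results for one solver
#'
#' Container for the output of [deconvolve()]: raw solver coefficients,
#' relative fractions (nonnegative, summing to 1 unless degenerate),
#' unnormalized absolute scores, reconstruction fit metrics, optional
#' Monte-Carlo empirical p-values, and the chosen hyperparameters.
#' Coefficient matrices are subsets x samples.
#'
#' @slot method solver label, one of svr/nnls/qp/ols/rlr/ridge.
#' @slot coefficients raw (back-scaled) solver coefficients.
#' @slot relative relative fractions per subset, columns sum to 1 (or 0
#'   when the sample is degenerate).
#' @slot absolute nonnegative absolute scores.
#' @slot pcc,rmse per-sample reconstruction Pearson correlation and RMSE.
#' @slot pvalue per-sample empirical p-value (NA when not computed).
#' @slot degenerate logical per sample: TRUE when no coefficient was > 0.
#' @slot matchedFraction fraction of signature genes found in each sample.
#' @slot hyperparameters list per sample (chosen nu, lambda, ...).
#' @slot failures character vector describing per-sample failures.
#' @seealso [deconvolve()], [writeResults()]
#' @export
setClass("DeconvolutionResult",
    representation(method = "character", coefficients = "matrix",
        relative = "matrix", absolute = "matrix", pcc = "numeric",
        rmse = "numeric", pvalue = "numeric", degenerate = "logical",
        matchedFraction = "numeric", hyperparameters = "list",
        failures = "character"),
    validity = function(object) {
        ns <- ncol(object@coefficients)
        if (!identical(dim(object@relative), dim(object@coefficients)) ||
            !identical(dim(object@absolute), dim(object@coefficients)))
            return("coefficient, relative and absolute matrices must agree in shape")
        if (length(object@pcc) != ns || length(object@rmse) != ns ||
            length(object@pvalue) != ns || length(object@degenerate) != ns)
            return("per-sample vectors must match the number of samples")
        if (any(object@absolute < 0, na.rm = TRUE))
            return("absolute scores must be nonnegative")
        if (any(object@rmse < 0, na.rm = TRUE)) return("rmse must be nonnegative")
        ok <- !object@degenerate & !is.na(object@relative[1L, ])
        sums <- colSums(object@relative)[ok]
        if (length(sums) && any(abs(sums - 1) > 1e-8))
            return("non-degenerate relative fractions must sum to 1")
        TRUE
    })

#' Multi-solver benchmark summary
#'
#' Aggregates of [compareModels()]: per-sample reconstruction PCC and RMSE
#' for each solver, per-subset detection frequency (fraction of samples
#' with relative fraction strictly > 0) and per-subset variance of the
#' relative estimates.
#'
#' @slot models solver labels compared.
#' @slot pcc,rmse samples x models matrices.
#' @slot detectionFrequency,estimateVariance subsets x models matrices.
#' @export
setClass("ModelComparison",
    representation(models = "character", pcc = "matrix", rmse = "matrix",
        detectionFrequency = "matrix", estimateVariance = "matrix"),
    validity = function(object) {
        if (!identical(colnames(object@pcc), object@models))
            return("pcc columns must match models")
        if (any(object@detectionFrequency < 0 | object@detectionFrequency > 1,
                na.rm = TRUE))
            return("detection frequencies must lie in [0, 1]")
        TRUE
    })

#' Spike-in detection-limit curve
#'
#' Result of [spikeInExperiment()]: for each true spiked proportion on the
#' grid, the estimated fraction of the spiked subset(s), the absolute
#' error, and the largest grid proportion recovered within tolerance.
#'
#' @slot grid strictly increasing true proportions in `[0, 1]`.
#' @slot estimated estimated spiked-subset fraction per grid point.
#' @slot error absolute error per grid point.
#' @slot tolerance absolute tolerance used for the in-tolerance flag.
#' @slot maxInTolerance largest grid proportion with error <= tolerance
#'   (NA when none).
#' @slot method solver used.
#' @export
setClass("SpikeInCurve",
    representation(grid = "numeric", estimated = "numeric", error = "numeric",
        tolerance = "numeric", maxInTolerance = "numeric", method = "character"),
    validity = function(object) {
        g <- object@grid
        if (is.unsorted(g, strictly = TRUE)) return("grid must be strictly increasing")
        if (any(g < 0 | g > 1)) return("grid proportions must lie in [0, 1]")
        if (length(object@estimated) != length(g) ||
            length(object@error) != length(g))
            return("estimated and error must align with the grid")
        if (any(object@error < 0, na.rm = TRUE)) return("errors must be nonnegative")
        TRUE
    })
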