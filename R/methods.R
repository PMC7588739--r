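#' @rdname ExpressionMatrix-class
#' @param x an `ExpressionMatrix`.
#' @param ... unused.
#' @export
setMethod("as.matrix", "ExpressionMatrix", function(x, ...) {
    m <- x@.Data
    dimnames(m) <- dimnames(x)
    m
})

#' @describeIn conditionNumber 2-norm condition number of any numeric matrix.
setMethod("conditionNumber", "matrix", function(x) {
    d <- svd(x, nu = 0, nv = 0)$d
    tol <- max(dim(x)) * .Machine$double.eps * d[1L]
    if (length(d) == 0L || d[length(d)] <= tol) return(Inf)
    d[1L] / d[length(d)]
})

#' @describeIn conditionNumber stored condition number of a signature.
setMethod("conditionNumber", "SignatureMatrix",
    function(x) x@conditionNumber)

#' @rdname SignatureMatrix-class
setMethod("provenance", "SignatureMatrix", function(object) object@provenance)

setMethod("show", "ExpressionMatrix", function(object) {
    cat(class(object), "with", nrow(object), "genes x", ncol(object),
        "samples\n")
    cat("  genes:  ", paste(utils::head(rownames(object), 3L), collapse = ", "),
        if (nrow(object) > 3L) "..." else "", "\n")
    cat("  samples:", paste(utils::head(colnames(object), 3L), collapse = ", "),
        if (ncol(object) > 3L) "..." else "", "\n")
})

setMethod("show", "SignatureMatrix", function(object) {
    cat("SignatureMatrix:", nrow(object), "genes x", ncol(object),
        "subsets; condition number", format(object@conditionNumber, digits = 5),
        "\n")
    cat("  subsets:", paste(colnames(object), collapse = ", "), "\n")
    p <- object@provenance
    if (length(p))
        cat("  built with:",
            paste(names(p)[!vapply(p, is.data.frame, logical(1))],
                  collapse = ", "), "\n")
})

setMethod("show", "TSSTable", function(object) {
    cat("TSSTable:", nrow(object@scores), "genes x", ncol(object@scores),
        "subsets; score range", min(object@scores), "-", max(object@scores),
        "\n")
})

#' @rdname DeconvolutionResult-class
setMethod("relativeFractions", "DeconvolutionResult",
    function(object) object@relative)

#' @rdname DeconvolutionResult-class
setMethod("absoluteScores", "DeconvolutionResult",
    function(object) object@absolute)

#' @rdname DeconvolutionResult-class
setMethod("rawCoefficients", "DeconvolutionResult",
    function(object) object@coefficients)

#' @rdname DeconvolutionResult-class
setMethod("reconstructionPCC", "DeconvolutionResult",
    function(object) object@pcc)

#' @rdname DeconvolutionResult-class
setMethod("reconstructionRMSE", "DeconvolutionResult",
    function(object) object@rmse)

#' @rdname DeconvolutionResult-class
setMethod("empiricalP", "DeconvolutionResult",
    function(object) object@pvalue)

setMethod("show", "DeconvolutionResult", function(object) {
    cat("DeconvolutionResult (", object@method, "): ",
        ncol(object@coefficients), " samples x ",
        nrow(object@coefficients), " subsets\n", sep = "")
    cat("  median reconstruction PCC:",
        format(stats::median(object@pcc, na.rm = TRUE), digits = 4), "\n")
    if (any(object@degenerate))
        cat("  degenerate samples:", sum(object@degenerate), "\n")
    if (length(object@failures))
        cat("  failed samples:", length(object@failures), "\n")
})

setMethod("show", "ModelComparison", function(object) {
    cat("ModelComparison over", length(object@models), "models,",
        nrow(object@pcc), "samples\n")
    med <- apply(object@pcc, 2L, stats::median, na.rm = TRUE)
    cat("  median PCC:",
        paste(sprintf("%s=%.3f", object@models, med), collapse = "  "), "\n")
})

setMethod("show", "SpikeInCurve", function(object) {
    cat("SpikeInCurve (", object@method, "): ", length(object@grid),
        " grid points; max in-tolerance proportion ",
        format(object@maxInTolerance), " (tol ", object@tolerance, ")\n",
        sep = "")
})

#' @export
as.data.frame.SpikeInCurve <- function(x, ...) {
    data.frame(true = x@grid, estimated = x@estimated, error = x@error,
               within_tolerance = x@error <= x@tolerance)
}

#' Tabulate a DeconvolutionResult
#'
#' One row per sample; relative-fraction and absolute-score columns are
#' prefixed `rel_` and `abs_` respectively.
#'
#' @param x a [DeconvolutionResult-class].
#' @param ... unused.
#' @return a data.frame.
#' @export
as.data.frame.DeconvolutionResult <- function(x, ...) {
    subsets <- rownames(x@relative)
    rel <- t(x@relative)
    abs_ <- t(x@absolute)
    colnames(rel) <- paste0("rel_", subsets)
    colnames(abs_) <- paste0("abs_", subsets)
    data.frame(sample = colnames(x@relative), method = x@method,
               rel, abs_, pcc = x@pcc, rmse = x@rmse, p_value = x@pvalue,
               matched_fraction = x@matchedFraction,
               degenerate = x@degenerate,
               row.names = NULL, check.names = FALSE)
}
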