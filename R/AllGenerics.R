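#' Condition number of a matrix
#'
#' 2-norm condition number: the ratio of the largest to the smallest
#' singular value. A lower condition number means the deconvolution is
#' more tolerant to noise in the input expression profile. Rank-deficient
#' matrices return `Inf`.
#'
#' @param x a numeric matrix or a [SignatureMatrix-class].
#' @return a single number `>= 1`, or `Inf` when rank-deficient.
#' @examples
#' conditionNumber(diag(3))        # 1
#' conditionNumber(diag(c(10, 1))) # 10
#' @export
setGeneric("conditionNumber", function(x) standardGeneric("conditionNumber"))

#' @rdname SignatureMatrix-class
#' @param object,x a `SignatureMatrix`.
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("relativeFractions", function(object) standardGeneric("relativeFractions"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("absoluteScores", function(object) standardGeneric("absoluteScores"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("rawCoefficients", function(object) standardGeneric("rawCoefficients"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("reconstructionPCC", function(object) standardGeneric("reconstructionPCC"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("reconstructionRMSE", function(object) standardGeneric("reconstructionRMSE"))

#' @rdname DeconvolutionResult-class
#' @export
setGeneric("empiricalP", function(object) standardGeneric("empiricalP"))
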