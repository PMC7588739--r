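#' Monte-Carlo permutation configuration
#'
#' @param nIter Monte-Carlo iterations (default 500).
#' @param seed integer seed.
#' @param reuseNu for the SVR solver, reuse the nu chosen on the observed
#'   data inside each permutation instead of re-selecting it (cheaper,
#'   slightly anti-conservative null); default FALSE.
#' @return a `PermutationConfig` list. The test statistic is fixed to the
#'   Pearson product-moment correlation between the mixture and its
#'   reconstruction.
#' @export
permutationConfig <- function(nIter = 500L, seed = 42L, reuseNu = FALSE) {
    if (nIter < 1L) stop("nIter must be >= 1", call. = FALSE)
    structure(list(nIter = as.integer(nIter), seed = as.integer(seed),
                   reuseNu = isTRUE(reuseNu), statistic = "pearson-R"),
              class = "PermutationConfig")
}

#' Monte-Carlo empirical p-value for one deconvolution
#'
#' Tests the null hypothesis that the mixture contains none of the
#' signature's subsets (i.e. is fully made of unrelated content). The
#' observed statistic is the reconstruction Pearson R of the real
#' deconvolution. Each null replicate draws, without replacement, a
#' random gene subset of the mixture of the same size as the matched
#' signature gene set, assigns those values to the signature gene
#' positions, re-solves, and records the reconstruction R. The one-sided
#' p-value uses the add-one correction
#' \deqn{p = (1 + \#\{R_i \ge R_{obs}\}) / (1 + n_{iter})}
#' so it is never exactly 0 and lies in `[1/(nIter+1), 1]`.
#'
#' @param mixture named numeric vector (one mixture profile); must
#'   contain more genes in total than the matched signature gene set.
#' @param sig a [SignatureMatrix-class].
#' @param options a [solverOptions()] list.
#' @param nIter,seed,reuseNu see [permutationConfig()]; alternatively
#'   pass `config`.
#' @param config optional [permutationConfig()] overriding the three
#'   arguments above.
#' @return list with `observedR`, `p`, and the vector of `nullR` values.
#' @export
empiricalPvalue <- function(mixture, sig, options = solverOptions(),
                            nIter = 500L, seed = 42L, reuseNu = FALSE,
                            config = NULL) {
    if (!is.null(config)) {
        nIter <- config$nIter; seed <- config$seed; reuseNu <- config$reuseNu
    }
    if (is.matrix(mixture))
        mixture <- stats::setNames(mixture[, 1L], rownames(mixture))
    pair <- matchAndNormalize(mixture, sig, options)
    if (length(mixture) <= pair$matchedCount)
        stop("mixture must contain more genes (", length(mixture),
             ") than the matched signature gene set (", pair$matchedCount,
             ") to draw null gene sets", call. = FALSE)
    fit <- dispatchSolver(pair, options)
    obsR <- reconstructionFit(pair, fit$beta)["pcc"]
    nullOptions <- options
    if (options$method == "svr" && reuseNu)
        nullOptions$nuGrid <- fit$details$nu
    runOne <- function(yRaw) {
        sdY <- stats::sd(yRaw)
        if (!is.finite(sdY) || sdY == 0) return(NA_real_)
        nullPair <- pair
        nullPair$y <- (yRaw - mean(yRaw)) / sdY
        nullPair$sdY <- sdY
        nb <- tryCatch(dispatchSolver(nullPair, nullOptions)$beta,
                       error = function(e) NULL)
        if (is.null(nb)) return(NA_real_)
        reconstructionFit(nullPair, nb)["pcc"]
    }
    old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    nullR <- vapply(seq_len(nIter), function(i) {
        idx <- sample.int(length(mixture), pair$matchedCount)
        runOne(unname(mixture[idx]))
    }, numeric(1))
    p <- (1 + sum(nullR >= obsR, na.rm = TRUE)) / (1 + nIter)
    list(observedR = unname(obsR), p = p, nullR = unname(nullR))
}
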