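#' Benchmark several deconvolution solvers on the same cohort
#'
#' Runs [deconvolve()] once per solver and aggregates: per-sample
#' reconstruction PCC and RMSE, per-subset detection frequency (the
#' fraction of samples in which the subset's relative fraction is
#' strictly greater than 0), and the per-subset variance of the relative
#' estimates across samples. Solvers that fail on every sample are
#' excluded with a warning.
#'
#' @param mixtures [ExpressionMatrix-class], at least 2 samples.
#' @param sig a [SignatureMatrix-class].
#' @param models at least 2 solver labels from
#'   `c("svr","nnls","qp","ols","rlr","ridge")`.
#' @param options base [solverOptions()]; the method field is overridden
#'   per model.
#' @param seed seed forwarded to [deconvolve()].
#' @return a [ModelComparison-class].
#' @export
compareModels <- function(mixtures, sig,
                          models = c("svr", "nnls", "qp", "ols", "rlr",
                                     "ridge"),
                          options = solverOptions(), seed = 42L) {
    if (length(models) < 2L) stop("need at least 2 models", call. = FALSE)
    if (ncol(as.matrix(mixtures)) < 2L)
        stop("need at least 2 samples", call. = FALSE)
    runs <- lapply(models, function(mth) {
        opt <- options; opt$method <- mth
        res <- suppressWarnings(deconvolve(mixtures, sig, opt, seed = seed))
        if (all(is.na(res@pcc))) NULL else res
    })
    ok <- !vapply(runs, is.null, logical(1))
    if (any(!ok))
        warning("model(s) failed on all samples and were excluded: ",
                paste(models[!ok], collapse = ", "), call. = FALSE)
    models <- models[ok]; runs <- runs[ok]
    pcc <- vapply(runs, function(r) r@pcc, numeric(ncol(as.matrix(mixtures))))
    rmse <- vapply(runs, function(r) r@rmse, numeric(ncol(as.matrix(mixtures))))
    detFreq <- vapply(runs, function(r)
        rowMeans(r@relative > 0, na.rm = TRUE), numeric(ncol(sig)))
    estVar <- vapply(runs, function(r)
        apply(r@relative, 1L, stats::var, na.rm = TRUE), numeric(ncol(sig)))
    dimnames(pcc) <- list(colnames(as.matrix(mixtures)), models)
    dimnames(rmse) <- dimnames(pcc)
    dimnames(detFreq) <- list(colnames(sig), models)
    dimnames(estVar) <- dimnames(detFreq)
    new("ModelComparison", models = models, pcc = pcc, rmse = rmse,
        detectionFrequency = detFreq, estimateVariance = estVar)
}

#' Spike-in detection-limit experiment
#'
#' Emulates mixing a known source into a background fluid at controlled
#' proportions (e.g. cerebrospinal fluid spiked into plasma) to measure
#' how far the estimated fraction of the spiked subset tracks the truth.
#' For each grid proportion `f` the mixture is
#' `(1 - f) * background + f * spike`, perturbed by per-gene
#' multiplicative log-normal noise `exp(N(0, sigma^2))` (multiplicative
#' noise keeps TPMs nonnegative), then deconvoluted.
#'
#' @param background,spike named TPM vectors on a shared gene space.
#' @param sig a [SignatureMatrix-class].
#' @param spikeSubsets subset label(s) attributed to the spike source;
#'   the estimate at each grid point is the summed relative fraction of
#'   these subsets. Must exist in the signature.
#' @param grid strictly increasing true proportions in `[0, 1]`.
#' @param sigma log-normal noise standard deviation (default 0.1).
#' @param tolerance absolute recovery tolerance (default 0.05).
#' @param seed integer seed for the noise draws.
#' @param options [solverOptions()]; SVR by default.
#' @return a [SpikeInCurve-class].
#' @export
spikeInExperiment <- function(background, spike, sig, spikeSubsets,
                              grid = seq(0.05, 0.95, by = 0.05),
                              sigma = 0.1, tolerance = 0.05, seed = 42L,
                              options = solverOptions("svr")) {
    if (!all(spikeSubsets %in% colnames(sig)))
        stop("spike-associated subset(s) absent from signature: ",
             paste(setdiff(spikeSubsets, colnames(sig)), collapse = ", "),
             call. = FALSE)
    genes <- intersect(names(background), names(spike))
    if (!length(genes))
        stop("background and spike share no genes", call. = FALSE)
    bg <- background[genes]; sp <- spike[genes]
    old <- globalenv()$.Random.seed
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    est <- vapply(grid, function(f) {
        mix <- (1 - f) * bg + f * sp
        if (sigma > 0)
            mix <- mix * exp(stats::rnorm(length(mix), 0, sigma))
        pair <- matchAndNormalize(mix, sig, options)
        rel <- toRelative(dispatchSolver(pair, options)$raw)
        sum(rel[match(spikeSubsets, pair$subsets)])
    }, numeric(1))
    err <- abs(est - grid)
    inTol <- grid[err <= tolerance]
    new("SpikeInCurve", grid = grid, estimated = est, error = err,
        tolerance = tolerance,
        maxInTolerance = if (length(inTol)) max(inTol) else NA_real_,
        method = options$method)
}

#' Area under the ROC curve
#'
#' Rank-statistic AUC: the probability that a randomly chosen positive
#' sample outranks a randomly chosen negative one, with ties counting
#' one half (equivalent to the Wilcoxon-Mann-Whitney statistic). Higher
#' scores are taken as evidence for the positive class; the orientation
#' is never flipped automatically.
#'
#' @param scores numeric score per sample (e.g. an absolute liver
#'   fraction).
#' @param labels binary labels (logical, 0/1, or a 2-level factor whose
#'   second level is positive); both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
rocAUC <- function(scores, labels) {
    if (is.factor(labels)) labels <- labels == levels(labels)[2L]
    labels <- as.logical(labels)
    if (length(scores) != length(labels) || anyNA(labels))
        stop("scores and binary labels must align", call. = FALSE)
    n1 <- sum(labels); n0 <- sum(!labels)
    if (n1 == 0L || n0 == 0L)
        stop("both classes must be present", call. = FALSE)
    r <- rank(scores)  # midranks handle ties as 1/2
    (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Two-group difference test with normality gating
#'
#' Applies the Shapiro-Wilk normality test to each group at alpha 0.05;
#' when both groups look normal a two-sided two-sample t-test is used,
#' otherwise a two-sided Wilcoxon rank-sum test (with the usual tie
#' correction). Constant groups cannot be assessed by Shapiro-Wilk and
#' route to the Wilcoxon branch.
#'
#' @param values numeric vector (e.g. estimated liver fractions).
#' @param groups 2-level grouping of the same length; each group needs
#'   at least 3 observations.
#' @return list with `test` (`"t"` or `"wilcoxon"`), `statistic`,
#'   `p.value`, and `shapiro` (the two normality p-values, NA when not
#'   computable).
#' @export
groupDifferenceTest <- function(values, groups) {
    groups <- droplevels(as.factor(groups))
    if (nlevels(groups) != 2L)
        stop("exactly two groups are required", call. = FALSE)
    split_ <- split(values, groups)
    if (any(vapply(split_, length, integer(1)) < 3L))
        stop("each group needs at least 3 observations", call. = FALSE)
    swp <- vapply(split_, function(v)
        tryCatch(stats::shapiro.test(v)$p.value,
                 error = function(e) NA_real_), numeric(1))
    normal <- all(!is.na(swp) & swp > 0.05)
    if (normal) {
        ht <- stats::t.test(split_[[1L]], split_[[2L]],
                            alternative = "two.sided")
        test <- "t"
    } else {
        ht <- suppressWarnings(
            stats::wilcox.test(split_[[1L]], split_[[2L]],
                               alternative = "two.sided", correct = TRUE))
        test <- "wilcoxon"
    }
    list(test = test, statistic = unname(ht$statistic),
         p.value = ht$p.value, shapiro = swp)
}
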