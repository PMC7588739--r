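#' Specification for the synthetic-data generator
#'
#' Parameters of the log-normal marker/background model used to emulate a
#' grouped reference atlas and signature-consistent mixture cohorts with
#' known ground truth. Expression is log-normal throughout (TPMs are
#' nonnegative and heavy-tailed), markers are fold-enriched in their home
#' subset, mixing proportions are Dirichlet, and an optional unmodeled
#' content component emulates EVs from sources absent from the signature.
#'
#' Presets size the problem to the two realized signature regimes: a
#' blood-cell-like panel (7 subsets, ~100 markers each) and a
#' solid-tissue-like panel (16 subsets, ~6 markers each).
#'
#' @param preset `"blood"`, `"tissue"`, or NULL for the explicit
#'   arguments below (defaults are the blood-like regime).
#' @param nSubsets number of subsets (tissues / cell types).
#' @param markersPerSubset marker genes per subset.
#' @param nBackgroundGenes shared non-specific genes.
#' @param samplesPerSubset replicate reference samples per subset.
#' @param foldEnrichment marker fold-enrichment in the home subset
#'   (default 50, > 1).
#' @param markerMeanLog,markerSdLog log-normal baseline of marker genes.
#' @param backgroundMeanLog,backgroundSdLog log-normal baseline of
#'   background genes (mean/log-sd of log-normal TPM).
#' @param replicateSdLog log-sd of the multiplicative replicate noise in
#'   the reference atlas.
#' @param dirichletAlpha Dirichlet concentration per subset (scalar or
#'   one value per subset).
#' @param unmodeledFraction fraction of total mixture signal contributed
#'   by unrelated content, in `[0, 1)`.
#' @param noiseSd log-sd of per-gene multiplicative noise on mixtures.
#' @param seed integer seed; all generator output is deterministic
#'   under it.
#' @return a `GeneratorSpec` list.
#' @export
generatorSpec <- function(preset = NULL, nSubsets = 7L,
                          markersPerSubset = 100L, nBackgroundGenes = 500L,
                          samplesPerSubset = 5L, foldEnrichment = 50,
                          markerMeanLog = log(50), markerSdLog = 0.5,
                          backgroundMeanLog = log(20), backgroundSdLog = 1,
                          replicateSdLog = 0.5, dirichletAlpha = 1,
                          unmodeledFraction = 0, noiseSd = 0.1,
                          seed = 42L) {
    if (!is.null(preset)) {
        preset <- match.arg(preset, c("blood", "tissue"))
        if (preset == "blood") { nSubsets <- 7L; markersPerSubset <- 100L }
        else { nSubsets <- 16L; markersPerSubset <- 6L }
    }
    stopifnot(nSubsets >= 1L, markersPerSubset >= 1L,
              nBackgroundGenes >= 1L, samplesPerSubset >= 1L)
    if (foldEnrichment <= 1) stop("foldEnrichment must be > 1", call. = FALSE)
    if (unmodeledFraction < 0 || unmodeledFraction >= 1)
        stop("unmodeledFraction must lie in [0, 1)", call. = FALSE)
    if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
    structure(list(nSubsets = as.integer(nSubsets),
                   markersPerSubset = as.integer(markersPerSubset),
                   nBackgroundGenes = as.integer(nBackgroundGenes),
                   samplesPerSubset = as.integer(samplesPerSubset),
                   foldEnrichment = foldEnrichment,
                   markerMeanLog = markerMeanLog, markerSdLog = markerSdLog,
                   backgroundMeanLog = backgroundMeanLog,
                   backgroundSdLog = backgroundSdLog,
                   replicateSdLog = replicateSdLog,
                   dirichletAlpha = dirichletAlpha,
                   unmodeledFraction = unmodeledFraction,
                   noiseSd = noiseSd, seed = as.integer(seed)),
              class = "GeneratorSpec")
}

rdirichlet_ <- function(n, alpha) {
    g <- matrix(stats::rgamma(n * length(alpha), shape = alpha), ncol = n)
    sweep(g, 2L, colSums(g), "/")  # subsets x samples
}

#' Generate a grouped synthetic reference atlas
#'
#' Each subset gets `samplesPerSubset` replicate profiles. Marker genes
#' draw a log-normal baseline, multiplied by `foldEnrichment` in their
#' home subset; background genes are shared across subsets. Replicate
#' noise is multiplicative log-normal.
#'
#' @param spec a [generatorSpec()].
#' @return list with `atlas` ([ExpressionMatrix-class]) and `groups`
#'   (named factor, sample -> subset).
#' @export
generateReference <- function(spec = generatorSpec()) {
    set.seed(spec$seed)
    K <- spec$nSubsets
    subsets <- sprintf("subset_%02d", seq_len(K))
    markers <- paste0("MK_", rep(subsets, each = spec$markersPerSubset), "_",
                      sprintf("%03d", seq_len(spec$markersPerSubset)))
    home <- rep(seq_len(K), each = spec$markersPerSubset)
    bgGenes <- sprintf("BG_%04d", seq_len(spec$nBackgroundGenes))
    genes <- c(markers, bgGenes)
    base <- c(stats::rlnorm(length(markers), spec$markerMeanLog,
                            spec$markerSdLog),
              stats::rlnorm(length(bgGenes), spec$backgroundMeanLog,
                            spec$backgroundSdLog))
    samples <- paste0(rep(subsets, each = spec$samplesPerSubset), "_r",
                      seq_len(spec$samplesPerSubset))
    groups <- structure(factor(rep(subsets, each = spec$samplesPerSubset),
                               levels = subsets),
                        names = samples)
    vals <- matrix(0, length(genes), length(samples),
                   dimnames = list(genes, samples))
    for (j in seq_along(samples)) {
        x <- base * exp(stats::rnorm(length(genes), 0, spec$replicateSdLog))
        inHome <- c(home == as.integer(groups[j]),
                    rep(FALSE, length(bgGenes)))
        x[inHome] <- x[inHome] * spec$foldEnrichment
        vals[, j] <- x
    }
    list(atlas = ExpressionMatrix(vals), groups = groups)
}

#' Generate a mixture cohort with known ground-truth proportions
#'
#' Per sample: draw proportions from a Dirichlet distribution, form the
#' mixture `signature x proportions` over the signature genes, apply
#' per-gene multiplicative log-normal noise, and add an unmodeled-content
#' component — a fresh log-normal profile over the whole gene space
#' (signature genes plus `nBackgroundGenes` extra genes), scaled so it
#' contributes `unmodeledFraction` of the sample's total signal.
#'
#' @param sig a [SignatureMatrix-class] (or genes x subsets matrix).
#' @param nSamples cohort size.
#' @param spec a [generatorSpec()] (fields `dirichletAlpha`,
#'   `unmodeledFraction`, `noiseSd`, `nBackgroundGenes`,
#'   `backgroundMeanLog`, `backgroundSdLog`, `seed`).
#' @return list with `mixtures` ([ExpressionMatrix-class]) and
#'   `proportions` (subsets x samples matrix of true fractions, columns
#'   summing to 1).
#' @export
generateCohort <- function(sig, nSamples, spec = generatorSpec()) {
    set.seed(spec$seed)
    V <- as.matrix(sig)
    K <- ncol(V)
    alpha <- rep(spec$dirichletAlpha, length.out = K)
    props <- rdirichlet_(nSamples, alpha)
    dimnames(props) <- list(colnames(V),
                            sprintf("mix_%03d", seq_len(nSamples)))
    extra <- sprintf("UNREL_%04d", seq_len(spec$nBackgroundGenes))
    genes <- c(rownames(V), extra)
    vals <- matrix(0, length(genes), nSamples,
                   dimnames = list(genes, colnames(props)))
    for (j in seq_len(nSamples)) {
        modeled <- as.vector(V %*% props[, j])
        if (spec$noiseSd > 0)
            modeled <- modeled * exp(stats::rnorm(length(modeled), 0,
                                                  spec$noiseSd))
        u <- numeric(length(genes))
        if (spec$unmodeledFraction > 0) {
            u <- stats::rlnorm(length(genes), spec$backgroundMeanLog,
                               spec$backgroundSdLog)
            target <- spec$unmodeledFraction / (1 - spec$unmodeledFraction) *
                sum(modeled)
            u <- u * target / sum(u)
        }
        vals[seq_len(nrow(V)), j] <- modeled
        vals[, j] <- vals[, j] + u
    }
    list(mixtures = ExpressionMatrix(vals), proportions = props)
}

#' Generate a null cohort unrelated to any signature
#'
#' Mixtures statistically independent of any signature structure:
#' i.i.d. log-normal expression per gene and sample (so no gene is
#' constant across samples). Used to calibrate the Monte-Carlo empirical
#' p-value.
#'
#' @param geneIds gene identifier vector spanning the desired gene space
#'   (e.g. `rownames` of a signature plus extra genes).
#' @param nSamples cohort size.
#' @param spec a [generatorSpec()] (fields `backgroundMeanLog`,
#'   `backgroundSdLog`, `seed`).
#' @return an [ExpressionMatrix-class].
#' @export
generateNullCohort <- function(geneIds, nSamples, spec = generatorSpec()) {
    set.seed(spec$seed)
    sdlog <- max(spec$backgroundSdLog, 1e-6)  # never constant
    vals <- matrix(stats::rlnorm(length(geneIds) * nSamples,
                                 spec$backgroundMeanLog, sdlog),
                   length(geneIds), nSamples,
                   dimnames = list(geneIds,
                                   sprintf("null_%03d", seq_len(nSamples))))
    ExpressionMatrix(vals)
}
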