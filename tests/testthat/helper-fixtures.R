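# Fixture builders shared across the suite. Everything is generated in
# code; no data files.

# Wrap a plain genes x subsets matrix as a SignatureMatrix.
makeSig <- function(values) {
    new("SignatureMatrix", values, conditionNumber = conditionNumber(values),
        provenance = list())
}

# Signature with fold-enriched block markers: nPer markers per subset,
# around `high` in the home subset and around `low` elsewhere. Values are
# jittered deterministically per gene so that columns stay linearly
# independent after per-column centering (uniform blocks would not).
blockSignature <- function(nSubsets = 4L, nPer = 5L, high = 100, low = 1) {
    genes <- paste0("g", seq_len(nSubsets * nPer))
    subsets <- paste0("sub", seq_len(nSubsets))
    jitter <- 0.7 + 0.6 * ((seq_along(genes) * 7L) %% 11L) / 10
    v <- matrix(low * jitter, length(genes), nSubsets,
                dimnames = list(genes, subsets))
    for (j in seq_len(nSubsets))
        v[((j - 1L) * nPer + 1L):(j * nPer), j] <-
            high * jitter[((j - 1L) * nPer + 1L):(j * nPer)]
    makeSig(v)
}

# A NormalizedPair built directly (identity scaling) for solver unit
# tests: y = B %*% beta + noise.
makePair <- function(B, y) {
    structure(list(y = as.vector(y), B = B, sdY = 1,
                   sdB = rep(1, ncol(B)),
                   matchedCount = nrow(B), matchedFraction = 1,
                   genes = rownames(B), subsets = colnames(B)),
              class = "NormalizedPair")
}

# Random well-conditioned regression instance in standardized space.
randomPair <- function(nGenes = 20L, nSubsets = 4L, noise = 0, seed = 1L) {
    set.seed(seed)
    B <- matrix(rnorm(nGenes * nSubsets), nGenes, nSubsets,
                dimnames = list(paste0("g", seq_len(nGenes)),
                                paste0("s", seq_len(nSubsets))))
    beta <- runif(nSubsets)
    y <- as.vector(B %*% beta) + rnorm(nGenes, 0, noise)
    list(pair = makePair(B, y), beta = beta)
}

# Tiny atlas with exact per-subset means: one constant sample per subset.
constantAtlas <- function(means) {
    # means: genes x subsets matrix of the desired subset means
    samples <- paste0(colnames(means), "_r1")
    atlas <- ExpressionMatrix(`colnames<-`(means, samples))
    groups <- structure(factor(colnames(means)), names = samples)
    list(atlas = atlas, groups = groups)
}

# Small generated reference + signature used by several files.
smallWorld <- function(seed = 7L, nSubsets = 5L, markersPerSubset = 12L,
                       n = 12L) {
    spec <- generatorSpec(nSubsets = nSubsets,
                          markersPerSubset = markersPerSubset,
                          nBackgroundGenes = 300L, seed = seed)
    ref <- generateReference(spec)
    tss <- computeTSS(ref$atlas, ref$groups)
    cands <- selectSpecificGenes(tss, 2)
    sig <- suppressMessages(buildSignature(ref$atlas, ref$groups, cands, n))
    list(spec = spec, ref = ref, tss = tss, cands = cands, sig = sig)
}
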