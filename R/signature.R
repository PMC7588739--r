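subsetMeanMatrix <- function(atlas, groups) {
    atlas <- as.matrix(atlas)
    groups <- droplevels(as.factor(groups))
    if (is.null(names(groups)))
        stop("subset assignment must be named by sample identifier",
             call. = FALSE)
    missing <- setdiff(names(groups), colnames(atlas))
    if (length(missing))
        stop("assigned samples absent from atlas: ",
             paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
    vapply(levels(groups), function(l) {
        rowMeans(atlas[, names(groups)[groups == l], drop = FALSE])
    }, numeric(nrow(atlas)))
}

#' Compute tissue-specific scores (TSS)
#'
#' Grades how specifically each gene is expressed in each subset of a
#' grouped reference atlas, on an integer 0-5 scale. With `m_t` the mean
#' TPM of the gene in subset `t`, `m_max` the maximum mean over all other
#' subsets and pseudocount `eps`, the score is the number of fold-change
#' tiers satisfied:
#' \deqn{TSS = |\{k \in \{2,4,8,16,32\} : (m_t + \epsilon) \ge
#'   k (m_{max} + \epsilon)\}|}
#' so only the subset where the gene is maximally expressed can score
#' above 0, and a score of 5 marks a >= 32-fold enrichment.
#'
#' @param atlas [ExpressionMatrix-class] of reference profiles (TPM).
#' @param groups named factor assigning atlas samples to subsets; at least
#'   two subsets, each with at least one sample.
#' @param eps pseudocount in TPM (default 1); guards zero denominators.
#' @param tiers fold-change tiers; the default gives the 0-5 range.
#' @return a [TSSTable-class].
#' @export
computeTSS <- function(atlas, groups, eps = 1, tiers = c(2, 4, 8, 16, 32)) {
    M <- subsetMeanMatrix(atlas, groups)
    if (ncol(M) < 2L)
        stop("tissue specificity is undefined for a single subset",
             call. = FALSE)
    scores <- matrix(0L, nrow(M), ncol(M), dimnames = dimnames(M))
    for (t in seq_len(ncol(M))) {
        otherMax <- apply(M[, -t, drop = FALSE], 1L, max)
        ratio <- (M[, t] + eps) / (otherMax + eps)
        scores[, t] <- as.integer(rowSums(outer(ratio, tiers, ">=")))
    }
    new("TSSTable", scores = scores, subsetMeans = M)
}

#' Select subset-specific candidate genes by TSS threshold
#'
#' Keeps genes whose maximal TSS strictly exceeds `threshold` and assigns
#' each to the subset where it attains that maximum (ties broken
#' lexicographically by subset label). Candidates are ordered per subset
#' by the deterministic top-n ranking used downstream: TSS descending,
#' then mean target-subset TPM descending, then gene identifier.
#'
#' @param tss a [TSSTable-class] from [computeTSS()].
#' @param threshold integer in `[0, 5)`; strictly-greater comparison, so
#'   `threshold = 2` keeps genes with TSS 3 or more.
#' @return a candidate-gene data.frame with columns `gene`, `subset`,
#'   `tss`, `mean_tpm`, `frequency` (NA until [filterByFrequency()]);
#'   the threshold is recorded in `attr(, "tssThreshold")`.
#' @export
selectSpecificGenes <- function(tss, threshold) {
    stopifnot(is(tss, "TSSTable"))
    if (threshold < 0 || threshold >= 5)
        stop("threshold must lie in [0, 5)", call. = FALSE)
    s <- tss@scores
    best <- apply(s, 1L, max)
    keep <- which(best > threshold)
    subsets <- colnames(s)[order(colnames(s))]
    # lexicographically first subset attaining the maximum
    assigned <- vapply(keep, function(i) {
        hits <- colnames(s)[s[i, ] == best[i]]
        sort(hits)[1L]
    }, character(1))
    df <- data.frame(gene = rownames(s)[keep], subset = assigned,
                     tss = best[keep],
                     mean_tpm = tss@subsetMeans[cbind(keep,
                         match(assigned, colnames(s)))],
                     frequency = NA_real_, row.names = NULL)
    df <- df[order(df$subset, -df$tss, -df$mean_tpm, df$gene), , drop = FALSE]
    rownames(df) <- NULL
    attr(df, "tssThreshold") <- threshold
    df
}

#' Restrict a subset assignment by exclusion lists
#'
#' Removes samples belonging to excluded subsets (e.g. immune-dominated,
#' gender-biased and hemopoietic tissues when preparing a solid-tissue
#' signature from a whole-body atlas). Unknown labels warn rather than
#' fail; removing every subset is an error.
#'
#' @param groups named factor (sample -> subset).
#' @param exclude character vector of subset labels to drop, e.g.
#'   `unlist(defaultTissueExclusions())`.
#' @return the restricted named factor (levels dropped).
#' @export
excludeSubsets <- function(groups, exclude) {
    groups <- as.factor(groups)
    unknown <- setdiff(exclude, levels(groups))
    if (length(unknown))
        warning("exclusion labels not present in assignment: ",
                paste(unknown, collapse = ", "), call. = FALSE)
    keep <- !(as.character(groups) %in% exclude)
    if (!any(keep))
        stop("all subsets excluded", call. = FALSE)
    droplevels(groups[keep])
}

#' Default exclusion lists for a whole-body tissue atlas
#'
#' Subsets conventionally removed before building a solid-tissue signature
#' from a GTEx-style 31-tissue atlas: tissues dominated by immune cells,
#' gender-biased tissues, and hemopoietic-related components. These are
#' configuration defaults, not hard-coded behaviour — the lists are
#' atlas-specific and any character vector can be passed to
#' [excludeSubsets()].
#'
#' @return named list with elements `immune`, `genderBiased`,
#'   `hemopoietic` (15 labels in total; 31 - 15 leaves the 16 solid-tissue
#'   subsets of the default signature).
#' @export
defaultTissueExclusions <- function() {
    list(immune = c("adrenal gland", "salivary gland", "spleen", "thyroid"),
         genderBiased = c("breast", "cervix uteri", "fallopian tube",
                          "testis", "ovary", "vagina", "prostate", "uterus"),
         hemopoietic = c("blood", "bone marrow", "blood vessel"))
}

#' Detection frequency of genes in a background cohort
#'
#' For each gene, the fraction of cohort samples in which it is detected
#' (TPM strictly above `detectionThreshold`). Used to drop candidate
#' markers that are essentially never observed in the fluid of interest.
#'
#' @param cohort [ExpressionMatrix-class] of background/normal mixture
#'   profiles.
#' @param genes gene identifiers to score; genes absent from the cohort
#'   get frequency 0 with a warning.
#' @param detectionThreshold TPM above which a gene counts as detected
#'   (default 0).
#' @return named numeric vector of frequencies in `[0, 1]`.
#' @export
expressionFrequency <- function(cohort, genes, detectionThreshold = 0) {
    cohort <- as.matrix(cohort)
    if (ncol(cohort) < 1L) stop("empty cohort", call. = FALSE)
    freq <- stats::setNames(numeric(length(genes)), genes)
    present <- genes[genes %in% rownames(cohort)]
    absent <- setdiff(genes, present)
    if (length(absent))
        warning(length(absent), " gene(s) absent from cohort get frequency 0",
                call. = FALSE)
    if (length(present))
        freq[present] <- rowMeans(cohort[present, , drop = FALSE] >
                                  detectionThreshold)
    freq
}

#' Filter candidate genes by background-cohort frequency
#'
#' Retains candidates whose detection frequency is strictly greater than
#' `minFreq` (so frequency exactly 0.10 is removed at the default 0.1
#' cutoff). Subsets that lose all their candidates are named in a warning.
#'
#' @param candidates candidate data.frame from [selectSpecificGenes()].
#' @param frequencies named frequency vector from [expressionFrequency()];
#'   candidates missing from it are treated as frequency 0.
#' @param minFreq retention cutoff in `[0, 1]` (default 0.1).
#' @return the filtered candidate data.frame, frequencies filled in;
#'   `attr(, "minFreq")` records the cutoff.
#' @export
filterByFrequency <- function(candidates, frequencies, minFreq = 0.1) {
    if (minFreq < 0 || minFreq > 1)
        stop("minFreq must lie in [0, 1]", call. = FALSE)
    f <- frequencies[candidates$gene]
    f[is.na(f)] <- 0
    candidates$frequency <- unname(f)
    kept <- candidates[candidates$frequency > minFreq, , drop = FALSE]
    lost <- setdiff(unique(candidates$subset), unique(kept$subset))
    if (length(lost))
        warning("all candidates removed for subset(s): ",
                paste(lost, collapse = ", "), call. = FALSE)
    rownames(kept) <- NULL
    attr(kept, "tssThreshold") <- attr(candidates, "tssThreshold")
    attr(kept, "minFreq") <- minFreq
    kept
}

#' Build a signature matrix from top-n candidates per subset
#'
#' Selects, for each subset, the top `n` candidates under the
#' deterministic ranking (TSS descending, then mean target-subset TPM
#' descending, then gene identifier; subsets with fewer than `n`
#' candidates contribute all of them, with a message), and fills the
#' matrix with the mean TPM of every selected gene in every subset.
#'
#' @param atlas reference [ExpressionMatrix-class].
#' @param groups named factor over atlas samples (already restricted via
#'   [excludeSubsets()] if desired).
#' @param candidates candidate data.frame ([selectSpecificGenes()] /
#'   [filterByFrequency()]).
#' @param n markers per subset, `>= 1`.
#' @return a [SignatureMatrix-class]; errors if the selection yields fewer
#'   genes than subsets.
#' @export
buildSignature <- function(atlas, groups, candidates, n) {
    if (n < 1L) stop("n must be >= 1", call. = FALSE)
    M <- subsetMeanMatrix(atlas, groups)
    subsets <- colnames(M)
    cand <- candidates[candidates$subset %in% subsets, , drop = FALSE]
    cand <- cand[order(cand$subset, -cand$tss, -cand$mean_tpm, cand$gene), ,
                 drop = FALSE]
    sel <- do.call(rbind, lapply(split(cand, cand$subset), function(d) {
        if (nrow(d) < n)
            message("subset '", d$subset[1L], "' has only ", nrow(d),
                    " candidates (n = ", n, "); using all of them")
        utils::head(d, n)
    }))
    genes <- unique(sel$gene)
    if (length(genes) < length(subsets))
        stop("signature would have fewer genes (", length(genes),
             ") than subsets (", length(subsets), ")", call. = FALSE)
    vals <- M[genes, subsets, drop = FALSE]
    tssThr <- attr(candidates, "tssThreshold")
    freqThr <- attr(candidates, "minFreq")
    new("SignatureMatrix", vals,
        conditionNumber = conditionNumber(vals),
        provenance = list(
            n = n,
            tss_threshold = if (is.null(tssThr)) NA_real_ else tssThr,
            frequency_threshold = if (is.null(freqThr)) NA_real_ else freqThr,
            genes_per_subset = paste(vapply(split(sel, sel$subset), nrow,
                                            integer(1)), collapse = ",")))
}

#' Optimize the markers-per-subset count by condition number
#'
#' Rebuilds the signature for every `n` in `nRange` and returns the one
#' with the minimal 2-norm condition number; a lower condition number
#' makes the deconvolution more tolerant to variation in the input
#' profile. Ties break toward smaller `n` (fewer genes). The full
#' `(n, kappa)` trace is stored in the provenance.
#'
#' @param atlas,groups,candidates as in [buildSignature()].
#' @param nRange integer candidates for n (default `2:150`, bracketing
#'   typical realized signature sizes of ~6 tissue markers and ~100
#'   blood-cell markers per subset).
#' @return the optimal [SignatureMatrix-class], with
#'   `provenance(sig)$trace` a data.frame of n and kappa.
#' @export
optimizeSignature <- function(atlas, groups, candidates, nRange = 2:150) {
    if (!length(nRange) || min(nRange) < 1L)
        stop("nRange must be a nonempty set of integers >= 1", call. = FALSE)
    nRange <- sort(unique(as.integer(nRange)))
    sigs <- vector("list", length(nRange))
    kappa <- rep(Inf, length(nRange))
    for (i in seq_along(nRange)) {
        sigs[[i]] <- tryCatch(
            suppressMessages(buildSignature(atlas, groups, candidates,
                                            nRange[i])),
            error = function(e) NULL)
        if (!is.null(sigs[[i]])) kappa[i] <- conditionNumber(sigs[[i]])
    }
    if (!any(is.finite(kappa)))
        stop("every n in the range yields a rank-deficient or invalid ",
             "signature", call. = FALSE)
    bestI <- which.min(kappa)  # first minimum = smallest n on ties
    best <- sigs[[bestI]]
    best@provenance$trace <- data.frame(n = nRange, kappa = kappa)
    best@provenance$n_range <- paste0(min(nRange), ":", max(nRange))
    validObject(best)
    best
}

#' Merge two signature matrices with disjoint subsets
#'
#' Stacks a blood-cell and a tissue signature into one combined basis for
#' splitting a mixture into total blood versus tissue content. The merged
#' gene set is the union; a gene absent from one source matrix is filled
#' with that source's atlas mean TPM when a per-subset mean matrix is
#' supplied (e.g. `computeTSS(...)@subsetMeans` or a [TSSTable-class]),
#' else with 0; the number of filled cells is reported.
#'
#' @param blood,tissue [SignatureMatrix-class] objects with disjoint
#'   subset labels.
#' @param bloodMeans,tissueMeans optional genes x subsets mean-TPM
#'   matrices (or [TSSTable-class]s) used to fill genes missing from the
#'   corresponding signature.
#' @return a combined [SignatureMatrix-class]; blood subsets first.
#' @export
mergeSignatures <- function(blood, tissue, bloodMeans = NULL,
                            tissueMeans = NULL) {
    if (length(intersect(colnames(blood), colnames(tissue))))
        stop("subset labels overlap: ",
             paste(intersect(colnames(blood), colnames(tissue)),
                   collapse = ", "), call. = FALSE)
    asMeans <- function(x) if (is(x, "TSSTable")) x@subsetMeans else x
    bloodMeans <- asMeans(bloodMeans)
    tissueMeans <- asMeans(tissueMeans)
    genes <- union(rownames(blood), rownames(tissue))
    fillBlock <- function(sig, means) {
        block <- matrix(0, length(genes), ncol(sig),
                        dimnames = list(genes, colnames(sig)))
        have <- intersect(genes, rownames(sig))
        block[have, ] <- as.matrix(sig)[have, , drop = FALSE]
        missing <- setdiff(genes, have)
        filled <- 0L
        if (length(missing) && !is.null(means)) {
            src <- intersect(missing, rownames(means))
            cols <- intersect(colnames(sig), colnames(means))
            if (length(src) && length(cols)) {
                block[src, cols] <- means[src, cols, drop = FALSE]
                filled <- length(src)
            }
        }
        list(block = block, missing = length(missing), filled = filled)
    }
    b <- fillBlock(blood, bloodMeans)
    t_ <- fillBlock(tissue, tissueMeans)
    message("merge: ", b$missing, " gene(s) missing from blood (",
            b$filled, " filled from atlas means), ", t_$missing,
            " missing from tissue (", t_$filled, " filled)")
    vals <- cbind(b$block, t_$block)
    new("SignatureMatrix", vals,
        conditionNumber = conditionNumber(vals),
        provenance = list(merged_from = paste(ncol(blood), "blood +",
                                              ncol(tissue), "tissue subsets")))
}
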