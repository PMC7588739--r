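#' Harmonize gene identifiers
#'
#' Deterministic identifier normalization applied before matching mixture
#' genes against a signature. `"strip-version-suffix"` removes a trailing
#' `.NN` version (the Ensembl/GENCODE convention, e.g.
#' `ENSG00000139618.14` -> `ENSG00000139618`); `"uppercase"` upper-cases
#' symbols; `"as-is"` is the identity.
#'
#' @param ids character vector of gene identifiers.
#' @param policy one of `"as-is"`, `"strip-version-suffix"`, `"uppercase"`.
#' @param strict when TRUE, identifiers that collide after harmonization
#'   raise an error naming them; otherwise collisions are reported with a
#'   warning and left for the caller's duplicate policy.
#' @return character vector of the same length.
#' @examples
#' harmonizeGeneIds("ENSG00000139618.14", "strip-version-suffix")
#' harmonizeGeneIds("alb", "uppercase")
#' @export
harmonizeGeneIds <- function(ids,
                             policy = c("as-is", "strip-version-suffix",
                                        "uppercase"),
                             strict = FALSE) {
    policy <- match.arg(policy)
    out <- switch(policy,
        "as-is" = ids,
        "strip-version-suffix" = sub("\\.[0-9]+$", "", ids),
        "uppercase" = toupper(ids))
    dup <- unique(out[duplicated(out)])
    if (length(dup) && !identical(out, ids)) {
        msg <- paste0("gene identifiers collide after harmonization: ",
                      paste(utils::head(dup, 5L), collapse = ", "))
        if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
    out
}

# Write to a temp file in the destination directory, then rename, so a
# failure never leaves a partial file behind.
atomicWrite <- function(path, writer) {
    dir <- dirname(path)
    if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
    tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
    on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
    writer(tmp)
    if (!file.rename(tmp, path))
        stop("could not write to ", path, call. = FALSE)
    invisible(path)
}

#' Read a genes-by-samples expression table
#'
#' Expects TSV (or CSV via `sep`) with gene identifiers in the first
#' column (`gene_id`) and sample identifiers in the header. Values must be
#' nonnegative finite numbers (TPM). Rows whose gene identifier is
#' duplicated (before or after harmonization) are resolved by `duplicates`:
#' `"sum"` (default; TPM of duplicated annotations is additive), `"mean"`,
#' `"first"`, or `"error"`.
#'
#' @param path file path.
#' @param sep field separator, `"\t"` by default.
#' @param duplicates duplicate-gene policy.
#' @param harmonize identifier policy passed to [harmonizeGeneIds()].
#' @return an [ExpressionMatrix-class].
#' @export
readExpressionMatrix <- function(path, sep = "\t",
                                 duplicates = c("sum", "mean", "first", "error"),
                                 harmonize = "as-is") {
    duplicates <- match.arg(duplicates)
    if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
    df <- tryCatch(
        utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE),
        error = function(e) stop("parse error in ", path, ": ",
                                 conditionMessage(e), call. = FALSE))
    if (nrow(df) < 1L || ncol(df) < 2L)
        stop("parse error in ", path,
             ": need a gene_id column plus at least one sample column",
             call. = FALSE)
    ids <- as.character(df[[1L]])
    vals <- df[, -1L, drop = FALSE]
    for (j in seq_along(vals)) {
        col <- vals[[j]]
        if (!is.numeric(col)) {
            bad <- which(is.na(suppressWarnings(as.numeric(col))))[1L]
            stop("parse error in ", path, ": non-numeric value in column '",
                 colnames(vals)[j], "', row ", bad, call. = FALSE)
        }
    }
    m <- as.matrix(vals)
    if (any(!is.finite(m)))
        stop("validation error in ", path, ": non-finite value", call. = FALSE)
    if (any(m < 0)) {
        idx <- which(m < 0, arr.ind = TRUE)[1L, ]
        stop("validation error in ", path, ": negative value at gene '",
             ids[idx[1L]], "', sample '", colnames(m)[idx[2L]], "'",
             call. = FALSE)
    }
    ids <- harmonizeGeneIds(ids, harmonize)
    if (anyDuplicated(ids)) {
        if (duplicates == "error")
            stop("duplicate gene identifiers in ", path, ": ",
                 paste(utils::head(unique(ids[duplicated(ids)]), 5L),
                       collapse = ", "), call. = FALSE)
        warning("resolving ", sum(duplicated(ids)),
                " duplicated gene rows with policy '", duplicates, "'",
                call. = FALSE)
        f <- factor(ids, levels = unique(ids))
        m <- switch(duplicates,
            sum = rowsum(m, f),
            mean = rowsum(m, f) / as.vector(table(f)),
            first = m[!duplicated(ids), , drop = FALSE])
        ids <- unique(as.character(f))
    }
    rownames(m) <- ids
    ExpressionMatrix(m)
}

#' Write a genes-by-samples expression table
#'
#' @param x an [ExpressionMatrix-class] (or any genes-by-samples matrix).
#' @param path destination TSV path (written atomically).
#' @return `path`, invisibly.
#' @export
writeExpressionMatrix <- function(x, path) {
    df <- data.frame(gene_id = rownames(x), as.matrix(x),
                     check.names = FALSE)
    atomicWrite(path, function(tmp)
        utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                           row.names = FALSE))
}

#' Read a sample-to-subset assignment table
#'
#' TSV with columns `sample` and `subset`; returns a named factor
#' (names = sample identifiers) as used by [computeTSS()] and the
#' synthetic-data generator.
#'
#' @param path file path.
#' @return named factor mapping sample -> subset label.
#' @export
readSubsetAssignment <- function(path) {
    df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                            stringsAsFactors = FALSE)
    if (!all(c("sample", "subset") %in% colnames(df)))
        stop("assignment table needs 'sample' and 'subset' columns",
             call. = FALSE)
    if (anyDuplicated(df$sample))
        stop("duplicate sample identifiers in assignment", call. = FALSE)
    structure(factor(df$subset), names = df$sample)
}

#' @rdname readSubsetAssignment
#' @param groups named factor (sample -> subset).
#' @export
writeSubsetAssignment <- function(groups, path) {
    atomicWrite(path, function(tmp)
        utils::write.table(
            data.frame(sample = names(groups), subset = as.character(groups)),
            tmp, sep = "\t", quote = FALSE, row.names = FALSE))
}

#' Write and read a signature matrix with provenance header
#'
#' The TSV carries a `#`-prefixed header block recording the construction
#' parameters (TSS threshold, frequency threshold, chosen n, condition
#' number), then a `gene_id` column and one column per subset.
#'
#' @param sig a [SignatureMatrix-class].
#' @param path file path.
#' @return `writeSignatureMatrix` returns `path` invisibly;
#'   `readSignatureMatrix` returns a [SignatureMatrix-class].
#' @export
writeSignatureMatrix <- function(sig, path) {
    stopifnot(is(sig, "SignatureMatrix"))
    p <- sig@provenance
    scalars <- p[vapply(p, function(v)
        is.atomic(v) && length(v) == 1L, logical(1))]
    hdr <- c(sprintf("# condition_number=%.17g", sig@conditionNumber),
             sprintf("# %s=%s", names(scalars),
                     vapply(scalars, function(v)
                         format(v, digits = 17), character(1))))
    atomicWrite(path, function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        writeLines(hdr, con)
        utils::write.table(
            data.frame(gene_id = rownames(sig), as.matrix(sig),
                       check.names = FALSE),
            con, sep = "\t", quote = FALSE, row.names = FALSE)
    })
}

#' @rdname writeSignatureMatrix
#' @export
readSignatureMatrix <- function(path) {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    prov <- list()
    for (h in hdr) {
        kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1L]]
        if (length(kv) == 2L) {
            num <- suppressWarnings(as.numeric(kv[2L]))
            prov[[kv[1L]]] <- if (is.na(num)) kv[2L] else num
        }
    }
    m <- readExpressionMatrix(path)
    kappa <- prov[["condition_number"]]
    prov[["condition_number"]] <- NULL
    new("SignatureMatrix", as.matrix(m),
        conditionNumber = if (is.null(kappa)) conditionNumber(as.matrix(m))
                          else kappa,
        provenance = prov)
}

#' Write deconvolution results to TSV
#'
#' One row per sample and method; relative-fraction columns are prefixed
#' `rel_`, absolute-score columns `abs_`. A `#` header line documents the
#' column groups. Accepts a single [DeconvolutionResult-class] or a list
#' of them (e.g. one per solver).
#'
#' @param results a `DeconvolutionResult` or nonempty list of them.
#' @param path destination TSV path (written atomically).
#' @return `path`, invisibly.
#' @export
writeResults <- function(results, path) {
    if (is(results, "DeconvolutionResult")) results <- list(results)
    if (!length(results))
        stop("no results to write", call. = FALSE)
    dfs <- lapply(results, as.data.frame)
    df <- do.call(rbind, dfs)
    hdr <- paste0("# columns: sample, method, rel_<subset> (relative ",
                  "fractions), abs_<subset> (absolute scores), pcc, rmse, ",
                  "p_value, matched_fraction, degenerate")
    atomicWrite(path, function(tmp) {
        con <- file(tmp, "w")
        on.exit(close(con))
        writeLines(hdr, con)
        utils::write.table(df, con, sep = "\t", quote = FALSE,
                           row.names = FALSE)
    })
}

#' @rdname writeResults
#' @export
readResults <- function(path) {
    utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                      check.names = FALSE, stringsAsFactors = FALSE)
}
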