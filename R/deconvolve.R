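#' Solver options for mixture deconvolution
#'
#' @param method solver: `"svr"` (nu-support-vector regression, the
#'   default and recommended core), `"nnls"`, `"qp"`, `"ols"`, `"rlr"`
#'   (Huber robust regression) or `"ridge"`.
#' @param nuGrid nu values tried by the SVR, strictly inside (0, 1); the
#'   nu with the lowest reconstruction RMSE is kept (ties -> smaller nu).
#' @param lambda ridge penalty; `NULL` selects it by generalized
#'   cross-validation over a log grid.
#' @param qpMode `"nonneg"` (coefficients >= 0, matching NNLS) or
#'   `"nonneg-sum-to-one"` (additionally constrains the coefficients to
#'   sum to 1).
#' @param standardize `"both"` (default) z-scores the mixture vector and
#'   every signature column over the matched genes; `"mixture-only"`
#'   z-scores only the mixture.
#' @return a `SolverOptions` list.
#' @export
solverOptions <- function(method = c("svr", "nnls", "qp", "ols", "rlr",
                                     "ridge"),
                          nuGrid = seq(0.05, 0.95, by = 0.05),
                          lambda = NULL,
                          qpMode = c("nonneg", "nonneg-sum-to-one"),
                          standardize = c("both", "mixture-only")) {
    method <- match.arg(method)
    if (any(nuGrid <= 0 | nuGrid >= 1))
        stop("nu grid values must lie strictly inside (0, 1)", call. = FALSE)
    if (!is.null(lambda) && lambda < 0)
        stop("lambda must be >= 0", call. = FALSE)
    structure(list(method = method, nuGrid = sort(nuGrid), lambda = lambda,
                   qpMode = match.arg(qpMode),
                   standardize = match.arg(standardize)),
              class = "SolverOptions")
}

#' Match mixture genes to a signature and standardize
#'
#' Restricts a mixture profile and the signature to their shared genes
#' (in signature order) and standardizes per the configured scheme. The
#' mixture vector is always z-scored to mean 0, variance 1 (zero-mean
#' normalization of the input profile); under the default scheme every
#' signature column is z-scored as well, which puts basis and mixture on
#' a common scale. The per-column and mixture standard deviations are
#' retained so that solver coefficients can be mapped back to the
#' original TPM mixing scale.
#'
#' @param mixture named numeric vector of TPM values (a single mixture
#'   profile), or a 1-column matrix with gene rownames.
#' @param sig a [SignatureMatrix-class] (or genes x subsets matrix).
#' @param options a [solverOptions()] list.
#' @return a `NormalizedPair` list: `y` (standardized mixture), `B`
#'   (standardized signature columns), `sdY`, `sdB`, `matchedCount`,
#'   `matchedFraction`, `genes`, `subsets`.
#' @export
matchAndNormalize <- function(mixture, sig, options = solverOptions()) {
    if (is.matrix(mixture)) {
        stopifnot(ncol(mixture) == 1L)
        mixture <- stats::setNames(mixture[, 1L], rownames(mixture))
    }
    if (is.null(names(mixture)))
        stop("mixture profile must be named by gene identifier",
             call. = FALSE)
    sigM <- as.matrix(sig)
    genes <- rownames(sigM)[rownames(sigM) %in% names(mixture)]
    need <- max(10L, ncol(sigM))
    if (length(genes) < need)
        stop("only ", length(genes), " signature genes matched the mixture",
             " (need at least ", need, ")", call. = FALSE)
    dropped <- nrow(sigM) - length(genes)
    if (dropped > 0L)
        warning(dropped, " signature gene(s) absent from the mixture were",
                " dropped", call. = FALSE)
    yRaw <- mixture[genes]
    B <- sigM[genes, , drop = FALSE]
    sdY <- stats::sd(yRaw)
    if (!is.finite(sdY) || sdY == 0)
        stop("mixture has zero variance over the matched genes",
             call. = FALSE)
    y <- (yRaw - mean(yRaw)) / sdY
    if (options$standardize == "both") {
        sdB <- apply(B, 2L, stats::sd)
        if (any(sdB == 0)) {
            warning("signature column(s) constant over matched genes: ",
                    paste(colnames(B)[sdB == 0], collapse = ", "),
                    call. = FALSE)
            sdB[sdB == 0] <- 1
        }
        B <- scale(B, center = TRUE, scale = sdB)
    } else {
        sdB <- rep(1, ncol(B))
    }
    structure(list(y = as.vector(y), B = unclass(B)[, , drop = FALSE],
                   sdY = sdY, sdB = unname(sdB),
                   matchedCount = length(genes),
                   matchedFraction = length(genes) / nrow(sigM),
                   genes = genes, subsets = colnames(sigM)),
              class = "NormalizedPair")
}

# Map coefficients estimated in standardized space back to the original
# TPM mixing scale: if z(m) = sum_j beta_j z(b_j) then the mixing weights
# satisfy x_j = beta_j * sd(m) / sd(b_j).
backscale <- function(beta, pair) {
    stats::setNames(as.vector(beta) * pair$sdY / pair$sdB, pair$subsets)
}

solverResult <- function(pair, beta, details = list()) {
    list(raw = backscale(beta, pair), beta = as.vector(beta),
         details = details)
}

#' Linear-kernel nu-SVR solver with RMSE-based nu selection
#'
#' Fits a nu-support-vector regression of the standardized mixture on the
#' standardized signature columns for every nu in the grid, computes the
#' reconstruction RMSE of each fit, and keeps the nu with the lowest RMSE
#' (ties toward the smaller nu, which uses fewer support vectors). The
#' regression weights are recovered from the dual coefficients and
#' support vectors.
#'
#' @param pair a `NormalizedPair` from [matchAndNormalize()].
#' @param nuGrid nu values strictly inside (0, 1).
#' @return list with `raw` (back-scaled coefficients, one per subset),
#'   `beta` (standardized-space coefficients) and `details` (`nu`,
#'   per-nu `trace` of RMSE).
#' @export
solveNuSVR <- function(pair, nuGrid = seq(0.05, 0.95, by = 0.05)) {
    nuGrid <- sort(nuGrid)
    rmse <- rep(NA_real_, length(nuGrid))
    betas <- vector("list", length(nuGrid))
    errs <- character(0)
    for (i in seq_along(nuGrid)) {
        fit <- tryCatch(
            e1071::svm(x = pair$B, y = pair$y, type = "nu-regression",
                       kernel = "linear", nu = nuGrid[i], scale = FALSE),
            error = function(e) conditionMessage(e))
        if (is.character(fit)) { errs <- c(errs, fit); next }
        beta <- as.vector(crossprod(fit$coefs, fit$SV))
        betas[[i]] <- beta
        rmse[i] <- sqrt(mean((pair$B %*% beta - pair$y)^2))
    }
    if (all(is.na(rmse)))
        stop("nu-SVR failed at every nu: ",
             paste(unique(errs), collapse = "; "), call. = FALSE)
    best <- which.min(rmse)  # first minimum -> smallest nu
    solverResult(pair, betas[[best]],
                 details = list(nu = nuGrid[best],
                                trace = data.frame(nu = nuGrid, rmse = rmse)))
}

#' Non-negative least squares solver
#'
#' Lawson-Hanson active-set NNLS (via [pracma::lsqnonneg()]): least
#' squares with all coefficients constrained to be >= 0.
#'
#' @inheritParams solveNuSVR
#' @return list with `raw`, `beta`, `details`.
#' @export
solveNNLS <- function(pair) {
    fit <- pracma::lsqnonneg(pair$B, pair$y)
    solverResult(pair, fit$x, details = list(resid_norm = fit$resid.norm))
}

#' Quadratic-programming solver
#'
#' Minimizes the squared reconstruction error as a quadratic program
#' (Goldfarb-Idnani dual method via [quadprog::solve.QP()]) subject to
#' nonnegative coefficients and, in `"nonneg-sum-to-one"` mode, the
#' additional equality constraint that the coefficients sum to 1.
#'
#' @inheritParams solveNuSVR
#' @param mode constraint mode, see [solverOptions()].
#' @return list with `raw`, `beta`, `details` (attained objective).
#' @export
solveQP <- function(pair, mode = c("nonneg", "nonneg-sum-to-one")) {
    mode <- match.arg(mode)
    p <- ncol(pair$B)
    D <- crossprod(pair$B)
    # solve.QP needs strict positive definiteness; nudge the diagonal by a
    # relative epsilon without materially moving the optimum
    D <- D + diag(1e-10 * max(diag(D)), p)
    d <- crossprod(pair$B, pair$y)
    if (mode == "nonneg") {
        A <- diag(p); b0 <- rep(0, p); meq <- 0L
    } else {
        A <- cbind(rep(1, p), diag(p)); b0 <- c(1, rep(0, p)); meq <- 1L
    }
    fit <- tryCatch(quadprog::solve.QP(D, d, A, b0, meq = meq),
                    error = function(e)
                        stop("QP solver failed: ", conditionMessage(e),
                             call. = FALSE))
    beta <- fit$solution
    beta[abs(beta) < 1e-12] <- 0
    if (mode == "nonneg-sum-to-one") beta <- beta / sum(beta)
    obj <- sum((pair$B %*% beta - pair$y)^2)
    solverResult(pair, beta, details = list(mode = mode, objective = obj))
}

#' Ordinary least squares solver
#'
#' Unconstrained linear least squares; coefficients may be negative.
#' Rank-deficient signatures fall back to the minimum-norm solution
#' (Moore-Penrose pseudoinverse) with a warning.
#'
#' @inheritParams solveNuSVR
#' @return list with `raw`, `beta`, `details`.
#' @export
solveOLS <- function(pair) {
    qrB <- qr(pair$B)
    if (qrB$rank < ncol(pair$B)) {
        warning("rank-deficient signature: returning the minimum-norm ",
                "least-squares solution", call. = FALSE)
        beta <- MASS::ginv(pair$B) %*% pair$y
    } else {
        beta <- qr.coef(qrB, pair$y)
    }
    solverResult(pair, beta, details = list(rank = qrB$rank))
}

#' Robust (Huber M-estimation) linear solver
#'
#' Iteratively reweighted least squares with the Huber loss (tuning
#' constant 1.345, convergence tolerance 1e-6, at most 100 iterations)
#' via [MASS::rlm()]. Downweights gross outlier genes; non-convergence
#' warns and returns the last iterate.
#'
#' @inheritParams solveNuSVR
#' @return list with `raw`, `beta`, `details` (`converged`).
#' @export
solveRLR <- function(pair) {
    fit <- suppressWarnings(
        MASS::rlm(x = pair$B, y = pair$y, psi = MASS::psi.huber, k = 1.345,
                  maxit = 100, acc = 1e-6))
    if (!fit$converged)
        warning("robust regression did not converge within 100 iterations; ",
                "returning the last iterate", call. = FALSE)
    solverResult(pair, stats::coef(fit),
                 details = list(converged = fit$converged))
}

#' Ridge-regression solver
#'
#' Closed-form penalized least squares
#' \eqn{\hat\beta = (B^\top B + \lambda I)^{-1} B^\top y}. When `lambda`
#' is `NULL` it is chosen by generalized cross-validation over a log grid
#' `10^seq(-6, 4)`.
#'
#' @inheritParams solveNuSVR
#' @param lambda nonnegative penalty, or `NULL` for GCV selection.
#' @return list with `raw`, `beta`, `details` (`lambda`, and the GCV
#'   trace when selected).
#' @export
solveRidge <- function(pair, lambda = NULL) {
    if (!is.null(lambda) && lambda < 0)
        stop("lambda must be >= 0", call. = FALSE)
    B <- pair$B; y <- pair$y
    sv <- svd(B)
    ridgeBeta <- function(l) {
        # beta = V diag(d / (d^2 + l)) U' y
        sv$v %*% ((sv$d / (sv$d^2 + l)) * crossprod(sv$u, y))
    }
    gcvTrace <- NULL
    if (is.null(lambda)) {
        grid <- 10^seq(-6, 4, length.out = 41)
        n <- length(y)
        gcv <- vapply(grid, function(l) {
            beta <- ridgeBeta(l)
            rss <- sum((B %*% beta - y)^2)
            edf <- sum(sv$d^2 / (sv$d^2 + l))
            n * rss / (n - edf)^2
        }, numeric(1))
        lambda <- grid[which.min(gcv)]
        gcvTrace <- data.frame(lambda = grid, gcv = gcv)
    }
    beta <- if (lambda == 0) solveOLS(pair)$beta else ridgeBeta(lambda)
    solverResult(pair, beta,
                 details = list(lambda = lambda, gcv = gcvTrace))
}

dispatchSolver <- function(pair, options) {
    switch(options$method,
        svr = solveNuSVR(pair, options$nuGrid),
        nnls = solveNNLS(pair),
        qp = solveQP(pair, options$qpMode),
        ols = solveOLS(pair),
        rlr = solveRLR(pair),
        ridge = solveRidge(pair, options$lambda))
}

#' Relative fractions from raw coefficients
#'
#' Negative coefficients are truncated to 0, then the vector is divided
#' by its sum. If no coefficient is positive, an all-zero vector is
#' returned with `attr(, "degenerate") = TRUE`.
#'
#' @param raw numeric coefficient vector (one per subset).
#' @return fractions in `[0, 1]` summing to 1 (or all zero when
#'   degenerate), with a `degenerate` attribute.
#' @examples
#' toRelative(c(2, -1, 3))  # 0.4, 0, 0.6
#' @export
toRelative <- function(raw) {
    r <- pmax(raw, 0)
    s <- sum(r)
    if (s <= 0) return(structure(r * 0, degenerate = TRUE))
    structure(r / s, degenerate = FALSE)
}

#' Absolute scores from raw coefficients
#'
#' The truncated raw coefficient, `max(coefficient, 0)`, without
#' rescaling. Because raw coefficients are back-scaled to the original
#' TPM mixing scale, absolute scores are comparable across samples
#' processed with the same signature and normalization scheme.
#'
#' @param raw numeric coefficient vector.
#' @return nonnegative scores, same length.
#' @export
toAbsolute <- function(raw) pmax(raw, 0)

#' Reconstruction fit metrics
#'
#' Reconstructs the mixture as `signature x coefficients` over the
#' matched genes (in standardized space) and reports the Pearson
#' correlation (PCC) and root-mean-square error against the standardized
#' mixture. PCC is `NA` when the reconstruction has zero variance; RMSE
#' is always reported.
#'
#' @param pair a `NormalizedPair`.
#' @param beta coefficients in standardized space (the `beta` element of
#'   a solver result).
#' @return named numeric vector `c(pcc =, rmse =)`.
#' @export
reconstructionFit <- function(pair, beta) {
    recon <- as.vector(pair$B %*% beta)
    rmse <- sqrt(mean((recon - pair$y)^2))
    pcc <- if (stats::sd(recon) == 0) NA_real_ else
        stats::cor(recon, pair$y)
    c(pcc = pcc, rmse = rmse)
}

#' Deconvolute mixture profiles against a signature matrix
#'
#' For each sample: match and standardize against the signature, solve
#' with the configured method, derive relative fractions and absolute
#' scores, and compute reconstruction PCC/RMSE. Optionally attaches a
#' Monte-Carlo empirical p-value per sample ([empiricalPvalue()]).
#' Per-sample failures are recorded and the run continues.
#'
#' @param mixtures [ExpressionMatrix-class] (genes x samples) or a named
#'   vector for a single sample.
#' @param sig a [SignatureMatrix-class].
#' @param options a [solverOptions()] list.
#' @param nPerm Monte-Carlo iterations for the empirical p-value; 0
#'   (default) skips the test.
#' @param seed integer seed controlling the permutation draws (each
#'   sample uses a sub-seed derived from it).
#' @return a [DeconvolutionResult-class].
#' @export
deconvolve <- function(mixtures, sig, options = solverOptions(),
                       nPerm = 0L, seed = 42L) {
    if (!is.matrix(mixtures) && !is(mixtures, "ExpressionMatrix"))
        mixtures <- matrix(mixtures, ncol = 1L,
                           dimnames = list(names(mixtures), "sample1"))
    m <- as.matrix(mixtures)
    subsets <- colnames(sig)
    ns <- ncol(m)
    empty <- matrix(NA_real_, length(subsets), ns,
                    dimnames = list(subsets, colnames(m)))
    out <- list(coefficients = empty, relative = empty, absolute = empty,
                pcc = rep(NA_real_, ns), rmse = rep(NA_real_, ns),
                pvalue = rep(NA_real_, ns), degenerate = rep(FALSE, ns),
                matchedFraction = rep(NA_real_, ns))
    hyper <- rep(list(list()), ns)
    failures <- character(0)
    for (j in seq_len(ns)) {
        res <- tryCatch({
            pair <- matchAndNormalize(m[, j], sig, options)
            fit <- dispatchSolver(pair, options)
            rel <- toRelative(fit$raw)
            metrics <- reconstructionFit(pair, fit$beta)
            p <- NA_real_
            if (nPerm > 0L)
                p <- empiricalPvalue(m[, j], sig, options, nIter = nPerm,
                                     seed = (seed + j) %% .Machine$integer.max
                                     )$p
            list(pair = pair, fit = fit, rel = rel, metrics = metrics, p = p)
        }, error = function(e) conditionMessage(e))
        if (is.character(res)) {
            failures <- c(failures, paste0(colnames(m)[j], ": ", res))
            next
        }
        out$coefficients[, j] <- res$fit$raw
        out$relative[, j] <- res$rel
        out$absolute[, j] <- toAbsolute(res$fit$raw)
        out$pcc[j] <- res$metrics["pcc"]
        out$rmse[j] <- res$metrics["rmse"]
        out$pvalue[j] <- res$p
        out$degenerate[j] <- attr(res$rel, "degenerate")
        out$matchedFraction[j] <- res$pair$matchedFraction
        hyper[[j]] <- res$fit$details[setdiff(names(res$fit$details),
                                              c("trace", "gcv"))]
    }
    if (length(failures))
        warning(length(failures), " sample(s) failed: ",
                paste(utils::head(failures, 3L), collapse = " | "),
                call. = FALSE)
    new("DeconvolutionResult", method = options$method,
        coefficients = out$coefficients, relative = out$relative,
        absolute = out$absolute, pcc = out$pcc, rmse = out$rmse,
        pvalue = out$pvalue, degenerate = out$degenerate,
        matchedFraction = out$matchedFraction, hyperparameters = hyper,
        failures = failures)
}
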