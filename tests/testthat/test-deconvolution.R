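test_that("matchAndNormalize standardizes over the matched gene set", {
    sig <- blockSignature(nSubsets = 3L, nPer = 6L)
    set.seed(1)
    mix <- stats::setNames(rlnorm(nrow(sig), 2, 1), rownames(sig))
    pair <- matchAndNormalize(mix, sig)
    expect_equal(mean(pair$y), 0, tolerance = 1e-9)
    expect_equal(stats::sd(pair$y), 1, tolerance = 1e-9)
    expect_equal(unname(colMeans(pair$B)), rep(0, 3), tolerance = 1e-9)
    expect_identical(pair$genes, rownames(sig))
    expect_equal(pair$matchedFraction, 1)

    # an already mean-0, variance-1 mixture passes through unchanged
    z <- stats::setNames(as.vector(scale(rnorm(nrow(sig)))), rownames(sig))
    expect_equal(matchAndNormalize(z, sig)$y, unname(z), tolerance = 1e-9)

    # partial overlap: matched fraction reported, missing genes dropped
    mix2 <- mix[-(1:2)]
    expect_warning(pair2 <- matchAndNormalize(mix2, sig), "dropped")
    expect_equal(pair2$matchedFraction, (nrow(sig) - 2) / nrow(sig))

    # degenerate inputs
    const <- stats::setNames(rep(5, nrow(sig)), rownames(sig))
    expect_error(matchAndNormalize(const, sig), "zero variance")
    tiny <- mix[1:4]
    expect_error(matchAndNormalize(tiny, sig), "matched")
})

test_that("nu-SVR recovers constructed mixtures and reports its nu choice", {
    sig <- blockSignature(nSubsets = 2L, nPer = 10L, high = 80, low = 2)
    mix <- stats::setNames(
        as.vector(as.matrix(sig) %*% c(0.6, 0.4)), rownames(sig))
    pair <- matchAndNormalize(mix, sig)
    fit <- solveNuSVR(pair)
    rel <- toRelative(fit$raw)
    expect_equal(as.vector(rel), c(0.6, 0.4), tolerance = 0.02)
    tr <- fit$details$trace
    expect_equal(fit$details$nu, tr$nu[which.min(tr$rmse)])

    pure <- stats::setNames(as.matrix(sig)[, 1], rownames(sig))
    # a pure single-subset profile is constant within blocks; perturb
    # minutely so the mixture has the variance the normalization needs
    set.seed(4)
    pure <- pure * exp(rnorm(length(pure), 0, 0.01))
    relPure <- toRelative(solveNuSVR(matchAndNormalize(pure, sig))$raw)
    expect_gte(relPure[1], 0.95)
})

test_that("NNLS matches constraints, grid oracle, and QP", {
    # orthonormal columns, nonnegative weights: exact recovery
    q <- qr.Q(qr(matrix(rnorm(20), 10, 2)))
    dimnames(q) <- list(paste0("g", 1:10), c("a", "b"))
    pair <- makePair(q, as.vector(q %*% c(0.3, 0.7)))
    expect_equal(unname(solveNNLS(pair)$raw), c(0.3, 0.7), tolerance = 1e-9)

    # nonnegativity binds: mixture = -colA gives the all-zero solution
    pairNeg <- makePair(q, -q[, 1])
    expect_equal(unname(solveNNLS(pairNeg)$raw), c(0, 0), tolerance = 1e-9)

    # 2-subset instances against a 0.001-step grid-search oracle
    # (sum of squares expanded so the full grid can be enumerated)
    for (seed in 1:3) {
        r <- randomPair(nGenes = 15L, nSubsets = 2L, noise = 0.1,
                        seed = seed)
        est <- solveNNLS(r$pair)$beta
        grid <- seq(0, 2, by = 0.001)
        S <- crossprod(r$pair$B)
        sy <- crossprod(r$pair$B, r$pair$y)
        sse <- outer(grid^2 * S[1, 1] - 2 * grid * sy[1],
                     grid^2 * S[2, 2] - 2 * grid * sy[2], "+") +
            2 * S[1, 2] * outer(grid, grid)
        best <- arrayInd(which.min(sse), dim(sse))
        expect_equal(est, c(grid[best[1]], grid[best[2]]),
                     tolerance = 1e-3)
    }

    # QP in nonneg mode finds the same optimum by a different algorithm
    for (seed in 4:8) {
        r <- randomPair(nGenes = 25L, nSubsets = 5L, noise = 0.3,
                        seed = seed)
        expect_equal(solveQP(r$pair, "nonneg")$beta, solveNNLS(r$pair)$beta,
                     tolerance = 1e-6)
    }
})

test_that("QP sum-to-one mode enforces its constraint", {
    sig <- blockSignature(nSubsets = 2L, nPer = 8L)
    mix <- stats::setNames(
        as.vector(as.matrix(sig) %*% c(0.5, 0.5)), rownames(sig))
    pair <- matchAndNormalize(mix, sig, solverOptions("qp",
        standardize = "mixture-only"))
    fit <- solveQP(pair, "nonneg-sum-to-one")
    expect_equal(sum(fit$beta), 1, tolerance = 1e-8)
    for (seed in 1:5) {
        r <- randomPair(nSubsets = 4L, noise = 0.5, seed = seed)
        expect_equal(sum(solveQP(r$pair, "nonneg-sum-to-one")$beta), 1,
                     tolerance = 1e-8)
    }
})

test_that("OLS satisfies the normal equations and the pseudoinverse form", {
    for (seed in 1:5) {
        r <- randomPair(nGenes = 20L, nSubsets = 4L, noise = 0.2,
                        seed = seed)
        beta <- solveOLS(r$pair)$beta
        resid <- r$pair$y - r$pair$B %*% beta
        expect_lt(max(abs(crossprod(r$pair$B, resid))), 1e-8)
        expect_equal(beta, as.vector(MASS::ginv(r$pair$B) %*% r$pair$y),
                     tolerance = 1e-8)
    }
    noiseless <- randomPair(noise = 0, seed = 9)
    fit <- solveOLS(noiseless$pair)
    expect_lt(sqrt(mean((noiseless$pair$B %*% fit$beta -
                         noiseless$pair$y)^2)), 1e-8)
    # rank-deficient basis: minimum-norm solution with a warning
    B <- noiseless$pair$B[, c(1, 1, 2)]
    colnames(B) <- c("a", "b", "c")
    degPair <- makePair(B, noiseless$pair$y)
    expect_warning(mn <- solveOLS(degPair), "minimum-norm")
    expect_equal(mn$beta, as.vector(MASS::ginv(B) %*% degPair$y),
                 tolerance = 1e-8)
})

test_that("robust regression downweights outliers and matches OLS when clean", {
    clean <- randomPair(nGenes = 40L, nSubsets = 3L, noise = 0, seed = 2)
    expect_equal(suppressWarnings(solveRLR(clean$pair)$beta),
                 solveOLS(clean$pair)$beta, tolerance = 1e-6)
    # moderate gaussian noise: RLR within 2 OLS standard errors of OLS
    g <- randomPair(nGenes = 60L, nSubsets = 3L, noise = 0.3, seed = 5)
    ols <- solveOLS(g$pair)$beta
    rlr <- solveRLR(g$pair)$beta
    sigma2 <- sum((g$pair$y - g$pair$B %*% ols)^2) / (60 - 3)
    se <- sqrt(diag(solve(crossprod(g$pair$B))) * sigma2)
    expect_true(all(abs(rlr - ols) <= 2 * se))
    # 10% gross outlier genes: RLR closer to the truth than OLS
    set.seed(11)
    out <- randomPair(nGenes = 50L, nSubsets = 3L, noise = 0.1, seed = 11)
    y <- out$pair$y
    y[1:5] <- y[1:5] + 25
    contaminated <- makePair(out$pair$B, y)
    errRLR <- sum((solveRLR(contaminated)$beta - out$beta)^2)
    errOLS <- sum((solveOLS(contaminated)$beta - out$beta)^2)
    expect_lt(errRLR, errOLS)
})

test_that("ridge matches its closed form, OLS limit, and shrinks", {
    r <- randomPair(nGenes = 20L, nSubsets = 4L, noise = 0.2, seed = 3)
    B <- r$pair$B; y <- r$pair$y
    expect_equal(solveRidge(r$pair, 0)$beta, solveOLS(r$pair)$beta,
                 tolerance = 1e-8)
    for (lam in c(0.1, 1, 10)) {
        oracle <- as.vector(solve(crossprod(B) + lam * diag(4),
                                  crossprod(B, y)))
        expect_equal(solveRidge(r$pair, lam)$beta, oracle,
                     tolerance = 1e-8)
    }
    norms <- vapply(c(0, 0.5, 5, 50, 500, 5e4), function(l)
        sqrt(sum(solveRidge(r$pair, l)$beta^2)), numeric(1))
    expect_true(all(diff(norms) < 0))
    expect_lt(norms[length(norms)], 1e-2)
    expect_error(solveRidge(r$pair, -1), "lambda")
    # GCV selection reports its lambda
    auto <- solveRidge(r$pair)
    expect_true(auto$details$lambda > 0)
})

test_that("relative and absolute transforms follow the truncation rules", {
    rel <- toRelative(c(2, -1, 3))
    expect_equal(as.vector(rel), c(0.4, 0, 0.6))
    expect_false(attr(rel, "degenerate"))
    expect_equal(as.vector(toRelative(c(0.25, 0.75))), c(0.25, 0.75))
    degen <- toRelative(c(-1, -2))
    expect_equal(as.vector(degen), c(0, 0))
    expect_true(attr(degen, "degenerate"))
    expect_equal(toAbsolute(c(2, -1, 3)), c(2, 0, 3))
    expect_equal(toAbsolute(c(0, 0)), c(0, 0))
    # doubling raw coefficients doubles absolute, leaves relative fixed
    raw <- c(1.2, -0.3, 2.5)
    expect_equal(toAbsolute(2 * raw), 2 * toAbsolute(raw))
    expect_equal(as.vector(toRelative(2 * raw)), as.vector(toRelative(raw)))
})

test_that("reconstruction metrics behave at the limit cases", {
    y <- as.vector(scale(rnorm(20, 0, 1)))
    # perfect reconstruction
    pair <- makePair(cbind(a = y), y)
    expect_equal(unname(reconstructionFit(pair, 1)),
                 c(1, 0), tolerance = 1e-12)
    # reconstruction offset by a constant keeps PCC 1, RMSE |constant|
    pair2 <- makePair(cbind(a = y + 2), y)
    fit2 <- reconstructionFit(pair2, 1)
    expect_equal(unname(fit2["pcc"]), 1, tolerance = 1e-12)
    expect_equal(unname(fit2["rmse"]), 2, tolerance = 1e-12)
    # anti-correlated reconstruction
    expect_equal(unname(reconstructionFit(pair, -1)["pcc"]), -1,
                 tolerance = 1e-12)
    # zero-variance reconstruction: PCC unset, RMSE still reported
    fit0 <- reconstructionFit(pair, 0)
    expect_true(is.na(fit0["pcc"]))
    expect_equal(unname(fit0["rmse"]), sqrt(mean(y^2)), tolerance = 1e-9)
})

test_that("every solver recovers noiseless nonnegative mixtures", {
    w <- smallWorld(seed = 31L)
    V <- as.matrix(w$sig)
    set.seed(31)
    truth <- toRelative(rgamma(ncol(V), 2))
    mix <- stats::setNames(as.vector(V %*% truth), rownames(V))
    tol <- c(svr = 0.02, nnls = 1e-6, qp = 1e-6, ols = 1e-6)
    for (m in names(tol)) {
        pair <- matchAndNormalize(mix, w$sig, solverOptions(m))
        fit <- switch(m, svr = solveNuSVR(pair), nnls = solveNNLS(pair),
                      qp = solveQP(pair), ols = solveOLS(pair))
        expect_equal(unname(toRelative(fit$raw)), unname(truth),
                     tolerance = tol[[m]], label = m)
    }
})

test_that("deconvolve returns valid per-sample results and is deterministic", {
    w <- smallWorld(seed = 17L)
    coh <- generateCohort(w$sig, 10,
                          generatorSpec(unmodeledFraction = 0.1,
                                        noiseSd = 0.1, seed = 17))
    res <- deconvolve(coh$mixtures, w$sig, solverOptions("svr"))
    expect_s4_class(res, "DeconvolutionResult")
    rel <- relativeFractions(res)
    expect_equal(ncol(rel), 10L)
    expect_true(all(rel >= 0))
    ok <- !res@degenerate
    expect_true(all(abs(colSums(rel[, ok, drop = FALSE]) - 1) < 1e-8))
    expect_true(all(absoluteScores(res) >= 0))
    # chosen nu is recorded per sample
    expect_true(all(vapply(res@hyperparameters, function(h)
        h$nu %in% seq(0.05, 0.95, by = 0.05), logical(1))))

    # identical runs write identical files
    f1 <- tempfile(); f2 <- tempfile()
    writeResults(deconvolve(coh$mixtures, w$sig, solverOptions("svr"),
                            nPerm = 20, seed = 5), f1)
    writeResults(deconvolve(coh$mixtures, w$sig, solverOptions("svr"),
                            nPerm = 20, seed = 5), f2)
    expect_identical(readLines(f1), readLines(f2))
    unlink(c(f1, f2))
})

test_that("per-sample failures are recorded while the run continues", {
    w <- smallWorld(seed = 23L)
    coh <- generateCohort(w$sig, 3, generatorSpec(noiseSd = 0.05, seed = 23))
    vals <- as.matrix(coh$mixtures)
    vals[, 2] <- 1  # constant profile cannot be standardized
    mixed <- ExpressionMatrix(vals)
    expect_warning(res <- deconvolve(mixed, w$sig, solverOptions("nnls")),
                   "failed")
    expect_length(res@failures, 1L)
    expect_true(is.na(res@pcc[2]))
    expect_false(anyNA(res@pcc[c(1, 3)]))
})

test_that("reconstruction PCC is invariant to affine mixture rescaling", {
    w <- smallWorld(seed = 29L)
    coh <- generateCohort(w$sig, 4, generatorSpec(noiseSd = 0.1, seed = 29))
    m <- as.matrix(coh$mixtures)
    res1 <- deconvolve(ExpressionMatrix(m), w$sig, solverOptions("nnls"))
    res2 <- deconvolve(ExpressionMatrix(3 * m + 7), w$sig,
                       solverOptions("nnls"))
    expect_equal(reconstructionPCC(res1), reconstructionPCC(res2),
                 tolerance = 1e-9)
    expect_equal(relativeFractions(res1), relativeFractions(res2),
                 tolerance = 1e-9)
})

test_that("solver options validate their fields", {
    expect_error(solverOptions(nuGrid = c(0, 0.5)), "strictly inside")
    expect_error(solverOptions(nuGrid = c(0.5, 1)), "strictly inside")
    expect_error(solverOptions(lambda = -2), "lambda")
    expect_error(solverOptions("unknown"))
})
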