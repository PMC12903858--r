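# two analytically distinct state curves on a shared grid
twoStateCurves <- function(q = seq(0.01, 0.5, by = 0.01)) {
    list(fc = scatteringCurve(q, 1000 * exp(-q^2 * 7.5^2 / 3)),
         uf = scatteringCurve(q, 1000 * exp(-q^2 * 13^2 / 3)))
}

# oracle: exhaustive chi2 profile over the weight simplex at 0.01 resolution
gridSearchOracle <- function(experimental, curves, resolution = 0.01) {
    q <- qValues(experimental)
    A <- cbind(glycoSAXS:::.interpolateIntensity(curves$fc, q),
               glycoSAXS:::.interpolateIntensity(curves$uf, q))
    y <- intensities(experimental)
    sg <- if (hasSigma(experimental)) sigmas(experimental)
          else rep(1, length(y))
    ws <- seq(0, 1, by = resolution)
    chi <- vapply(ws, function(w) {
        mix <- A %*% c(w, 1 - w)
        s <- sum(mix * y / sg^2) / sum(mix^2 / sg^2)  # profiled scale
        mean(((s * mix - y) / sg)^2)
    }, numeric(1))
    list(w = ws[which.min(chi)], chi2 = chi, ws = ws)
}

test_that("the active-set NNLS solver matches the pracma oracle", {
    skip_if_not_installed("pracma")
    set.seed(19)
    for (rep in 1:20) {
        A <- matrix(stats::rnorm(40 * 4), 40, 4)
        b <- stats::rnorm(40)
        ours <- glycoSAXS:::.nnls(A, b)
        ref <- pracma::lsqnonneg(A, b)$x
        expect_equal(ours, ref, tolerance = 1e-8)
        expect_true(all(ours >= 0))
        # KKT optimality: gradient non-positive on the active set
        grad <- as.numeric(crossprod(A, b - A %*% ours))
        expect_true(all(grad[ours == 0] < 1e-8))
        expect_true(all(abs(grad[ours > 0]) < 1e-8))
    }
})

test_that("an experimental curve equal to one state gets all its weight", {
    curves <- twoStateCurves()
    fit <- fitPopulations(curves$fc, curves)
    expect_equal(unname(fit@weights[["fc"]]), 1, tolerance = 1e-9)
    expect_equal(unname(fit@weights[["uf"]]), 0, tolerance = 1e-9)
    expect_lt(fit@chi2Reduced, 1e-15)
    expect_equal(degreeOfFolding(fit), 1, tolerance = 1e-9)
})

test_that("exact mixtures are recovered to 1e-6 and match the grid oracle", {
    curves <- twoStateCurves()
    q <- qValues(curves$fc)
    mix <- scatteringCurve(q, 0.75 * intensities(curves$fc) +
                               0.25 * intensities(curves$uf))
    fit <- fitPopulations(mix, curves)
    expect_equal(unname(fit@weights[["fc"]]), 0.75, tolerance = 1e-6)
    expect_equal(fit@scale, 1, tolerance = 1e-6)
    oracle <- gridSearchOracle(mix, curves)
    expect_equal(oracle$w, 0.75, tolerance = 0.011)
    # scale separates from the weights
    mix2 <- scatteringCurve(q, 3.7 * (0.4 * intensities(curves$fc) +
                                      0.6 * intensities(curves$uf)))
    fit2 <- fitPopulations(mix2, curves)
    expect_equal(unname(fit2@weights[["fc"]]), 0.4, tolerance = 1e-6)
    expect_equal(fit2@scale, 3.7, tolerance = 1e-6)
})

test_that("identical state curves trigger the ill-conditioned path", {
    q <- seq(0.01, 0.5, by = 0.01)
    a <- scatteringCurve(q, 100 * exp(-q^2 * 16))
    b <- scatteringCurve(q, 200 * exp(-q^2 * 16))  # same shape, scaled
    expect_warning(fit <- fitPopulations(a, list(fc = a, uf = b)),
                   "indistinguishable")
    expect_true(fit@illConditioned)
    expect_equal(unname(fit@weightUncertainties["lower", ]), c(0, 0))
    expect_equal(unname(fit@weightUncertainties["upper", ]), c(1, 1))
})

test_that("input validation: state count, names, coverage", {
    curves <- twoStateCurves()
    expect_error(fitPopulations(curves$fc, curves[1]), "at least 2")
    expect_error(fitPopulations(curves$fc, unname(curves)), "named")
    short <- scatteringCurve(c(0.6, 0.7), c(1, 1))
    expect_error(fitPopulations(short, curves), "interpolation error")
})

test_that("q-range truncation keeps points at or below the cutoff", {
    cv <- scatteringCurve(c(0.1, 0.3, 0.5), c(3, 2, 1))
    expect_equal(qValues(truncateQRange(cv, 0.4)), c(0.1, 0.3))
    expect_equal(qValues(truncateQRange(cv, 0.9)), c(0.1, 0.3, 0.5))
    expect_error(truncateQRange(cv, 0.05), "below the first point")
    # fitting with q_max restricts the recorded range
    curves <- twoStateCurves()
    q <- qValues(curves$fc)
    mix <- scatteringCurve(q, 0.6 * intensities(curves$fc) +
                               0.4 * intensities(curves$uf))
    fit <- fitPopulations(mix, curves, q_max = 0.4)
    expect_lte(fit@qRangeUsed[2], 0.4)
    expect_equal(unname(fit@weights[["fc"]]), 0.6, tolerance = 1e-6)
})

test_that("the fit is invariant to rescaling and (with b) to offsets", {
    curves <- twoStateCurves()
    q <- qValues(curves$fc)
    set.seed(55)
    I0 <- 0.71 * intensities(curves$fc) + 0.29 * intensities(curves$uf)
    sg <- 0.02 * I0
    I <- I0 + stats::rnorm(length(q), 0, sg)
    base <- fitPopulations(scatteringCurve(q, I, sg), curves)
    resc <- fitPopulations(scatteringCurve(q, 5 * I, 5 * sg), curves)
    expect_equal(resc@weights, base@weights, tolerance = 1e-9)
    expect_equal(resc@scale, 5 * base@scale, tolerance = 1e-9)
    offs <- fitPopulations(scatteringCurve(q, I + 50, sg), curves,
                           fit_background = TRUE)
    with_b <- fitPopulations(scatteringCurve(q, I, sg), curves,
                             fit_background = TRUE)
    expect_equal(offs@weights, with_b@weights, tolerance = 1e-6)
    expect_equal(offs@background - with_b@background, 50, tolerance = 1e-4)
})

test_that("noisy mixtures across the population scale are recovered within 0.05", {
    curves <- twoStateCurves()
    for (w_true in c(0.25, 0.40, 0.71, 0.75)) {
        errs <- vapply(1:10, function(rep) {
            pe <- generatePseudoExperiment(
                curves, c(fc = w_true, uf = 1 - w_true), scale = 1.3,
                noise_fraction = 0.02, seed = 1000 * w_true + rep)
            fit <- fitPopulations(pe, curves)
            unname(fit@weights[["fc"]]) - w_true
        }, numeric(1))
        expect_lt(max(abs(errs)), 0.05)
    }
})

test_that("the optimum beats the truth: chi2(w_hat) <= chi2(w_true)", {
    curves <- twoStateCurves()
    pe <- generatePseudoExperiment(curves, c(fc = 0.4, uf = 0.6),
                                   noise_fraction = 0.03, seed = 8)
    fit <- fitPopulations(pe, curves)
    oracle <- gridSearchOracle(pe, curves)
    chi_true <- oracle$chi2[which.min(abs(oracle$ws - 0.4))]
    chi_opt <- oracle$chi2[which.min(abs(oracle$ws -
                                         unname(fit@weights[["fc"]])))]
    expect_lte(chi_opt, chi_true + 1e-12)
    # and the grid minimum agrees with the fit within its resolution
    expect_lt(abs(oracle$w - unname(fit@weights[["fc"]])), 0.011)
})

test_that("bootstrap intervals are tight when noiseless and seeded", {
    curves <- twoStateCurves()
    q <- qValues(curves$fc)
    mix <- scatteringCurve(q, 0.75 * intensities(curves$fc) +
                               0.25 * intensities(curves$uf))
    fit <- fitPopulations(mix, curves)
    ci <- foldFractionUncertainty(fit, mix, curves, n_boot = 50, seed = 3)
    expect_lt(ci["upper", "fc"] - ci["lower", "fc"], 1e-3)
    # determinism
    ci2 <- foldFractionUncertainty(fit, mix, curves, n_boot = 50, seed = 3)
    expect_identical(ci, ci2)
    expect_error(foldFractionUncertainty(fit, mix, curves, n_boot = 5),
                 "at least 10")
})

test_that("bootstrap intervals cover the truth under 2% noise", {
    curves <- twoStateCurves()
    hits <- vapply(1:20, function(rep) {
        pe <- generatePseudoExperiment(curves, c(fc = 0.75, uf = 0.25),
                                       noise_fraction = 0.02,
                                       seed = 400 + rep)
        fit <- fitPopulations(pe, curves)
        ci <- foldFractionUncertainty(fit, pe, curves, n_boot = 100,
                                      seed = 500 + rep)
        ci["lower", "fc"] <= 0.75 && 0.75 <= ci["upper", "fc"]
    }, logical(1))
    expect_gte(mean(hits), 0.9)
})
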