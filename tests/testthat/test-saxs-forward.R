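test_that("form factors reproduce their q = 0 electron counts", {
    tab <- cromerMannTable()
    co <- tab@coefficients
    for (el in co$element) {
        row <- co[co$element == el, ]
        f0 <- row$c + row$a1 + row$a2 + row$a3 + row$a4
        expect_equal(atomicFormFactor(el, 0), f0, tolerance = 1e-12)
        expect_lt(abs(f0 - row$z), 0.2)  # table sanity: f(0) ~ Z
    }
    expect_lt(abs(atomicFormFactor("C", 0) - 6), 0.2)
    expect_error(atomicFormFactor("Xx", 0.1), "unknown element")
})

test_that("form factors decrease monotonically over the SAXS range", {
    q <- seq(0, 1, by = 0.002)
    for (el in c("C", "N", "O"))
        expect_true(all(diff(atomicFormFactor(el, q)) < 0))
})

test_that("excluded-volume correction behaves as a Gaussian dummy atom", {
    q <- seq(0, 0.5, by = 0.05)
    vac <- solventModel("vacuum")
    no_solv <- solventModel("excluded_volume", electron_density = 0)
    # rho_s = 0 -> identical to vacuum
    expect_equal(effectiveFormFactor("C", q, solvent = no_solv),
                 atomicFormFactor("C", q))
    # q = 0: f(0) - rho_s V, strictly below vacuum
    water <- solventModel("excluded_volume")
    V_C <- cromerMannTable()@coefficients$volume_nm3[
        cromerMannTable()@coefficients$element == "C"]
    expect_equal(effectiveFormFactor("C", 0, solvent = water),
                 atomicFormFactor("C", 0) - 334 * V_C, tolerance = 1e-12)
    expect_true(all(effectiveFormFactor("C", q, solvent = water) <
                    atomicFormFactor("C", q)))
    # hydrogen displaces more electrons than it carries -> negative f_eff(0)
    expect_lt(effectiveFormFactor("H", 0, solvent = water), 0)
})

test_that("Debye intensities match closed forms", {
    q <- seq(0.01, 0.5, by = 0.01)
    # single atom -> f(q)^2
    one <- molecularModel("O", matrix(0, 1, 3))
    expect_equal(intensities(debyeIntensity(one, q)),
                 atomicFormFactor("O", q)^2, tolerance = 1e-12)
    # two identical atoms at r: 2 f^2 (1 + sin(q r)/(q r)), r in nm,
    # q converted to nm^-1
    r <- 0.5
    two <- rigidReferenceShapes("two_points", list(d = r))
    f <- atomicFormFactor("C", q)
    closed <- 2 * f^2 * (1 + sin(10 * q * r) / (10 * q * r))
    expect_equal(intensities(debyeIntensity(two, q)), closed,
                 tolerance = 1e-9)
    # q = 0 limit: (sum f_j(0))^2
    m <- tenAtomModel()
    f0 <- sum(vapply(atoms(m)$element, atomicFormFactor, numeric(1), q = 0))
    expect_equal(intensities(debyeIntensity(m, 0)), f0^2,
                 tolerance = 1e-9 * f0^2)
    # positivity in vacuum mode
    expect_true(all(intensities(debyeIntensity(m, q)) > 0))
})

test_that("Monte-Carlo orientational average is unbiased and seeded", {
    q <- seq(0.05, 0.5, by = 0.05)
    # single atom: phase cancels exactly, any directions
    one <- molecularModel("C", matrix(c(1, 2, 3), 1, 3))
    expect_equal(intensities(orientationalAverageIntensity(one, q,
                     n_vectors = 7)),
                 atomicFormFactor("C", q)^2, tolerance = 1e-10)
    # two-atom model vs closed form within 3 empirical standard errors
    two <- rigidReferenceShapes("two_points", list(d = 0.5))
    ref <- intensities(debyeIntensity(two, q))
    mc <- mcIntensityWithSE(two, q, n_total = 10000, seed = 7)
    expect_true(all(abs(mc$mean - ref) <= 3 * mc$se + 1e-9 * ref))
    # same seed twice -> identical curves
    a <- orientationalAverageIntensity(two, q, n_vectors = 100,
                                       sampling = "random", seed = 99)
    b <- orientationalAverageIntensity(two, q, n_vectors = 100,
                                       sampling = "random", seed = 99)
    expect_identical(intensities(a), intensities(b))
})

test_that("Fibonacci sampling converges to the Debye value at 500 vectors", {
    m <- tenAtomModel()
    q <- seq(0.01, 0.5, by = 0.01)
    ref <- intensities(debyeIntensity(m, q))
    mc <- intensities(orientationalAverageIntensity(m, q, n_vectors = 500))
    rms <- sqrt(mean(((mc - ref) / ref)^2))
    expect_lt(rms, 0.05)
})

test_that("ensemble intensity is the unweighted mean of frame curves", {
    q <- seq(0.01, 0.4, by = 0.02)
    xyz1 <- rbind(c(0, 0, 0), c(0.4, 0, 0), c(0.8, 0, 0))
    xyz2 <- rbind(c(0, 0, 0), c(0.3, 0.3, 0), c(0.1, 0.5, 0.2))
    m <- molecularModel(c("C", "O", "C"), xyz1)
    # identical frames -> equals the single-frame curve
    same <- trajectoryFrames(m, list(xyz1, xyz1, xyz1), 0.1)
    expect_equal(intensities(ensembleIntensity(same, q)),
                 intensities(debyeIntensity(m, q)), tolerance = 1e-12)
    # two distinct frames -> arithmetic mean
    mixed <- trajectoryFrames(m, list(xyz1, xyz2), 0.1)
    m2 <- molecularModel(c("C", "O", "C"), xyz2)
    expected <- (intensities(debyeIntensity(m, q)) +
                 intensities(debyeIntensity(m2, q))) / 2
    expect_equal(intensities(ensembleIntensity(mixed, q)), expected,
                 tolerance = 1e-12)
    # striding keeps every stride-th frame starting from the first
    expect_equal(intensities(ensembleIntensity(mixed, q, stride = 2)),
                 intensities(debyeIntensity(m, q)), tolerance = 1e-12)
})

test_that("compact ensembles peak at higher q than extended ones in Kratky form", {
    spec <- twoStateSpec(seed = 21)
    tmpl <- glycoSAXS:::.twoStateTemplates(spec)
    m <- glycoSAXS:::.twoStateModel(spec)
    q <- seq(0.005, 0.6, by = 0.005)
    jitterFrames <- function(base, n) lapply(seq_len(n), function(k)
        base + matrix(stats::rnorm(length(base), 0, spec$jitter_sd),
                      nrow(base), 3))
    set.seed(31)
    compact <- trajectoryFrames(m, jitterFrames(tmpl$folded, 50), 0.1)
    extended <- trajectoryFrames(m, jitterFrames(tmpl$unfolded, 50), 0.1)
    kc <- kratkyTransform(ensembleIntensity(compact, q))
    ke <- kratkyTransform(ensembleIntensity(extended, q))
    # folded signature: the compact ensemble's Kratky maximum lies inside
    # the window and the curve decays beyond it; the extended ensemble
    # rises monotonically to the window edge (disorder signature)
    i_c <- which.max(intensities(kc))
    i_e <- which.max(intensities(ke))
    expect_lt(i_c, length(q))
    expect_equal(i_e, length(q))
    expect_lt(intensities(kc)[length(q)], 0.98 * max(intensities(kc)))
    upper <- qValues(ke) > 0.3
    expect_true(all(diff(intensities(ke)[upper]) > 0))
})
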