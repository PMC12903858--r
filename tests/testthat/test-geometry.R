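test_that("radius of gyration matches direct-summation oracles", {
    # single atom anywhere
    expect_equal(radiusOfGyration(matrix(c(3, -2, 7), 1, 3)), 0)
    # two unit-weight atoms at distance d -> d/2
    expect_equal(radiusOfGyration(rbind(c(0, 0, 0), c(1.2, 0, 0))), 0.6)
    # 9 collinear unit-weight beads, spacing 0.5 nm: direct summation
    xyz <- cbind((0:8) * 0.5, 0, 0)
    ctr <- colMeans(xyz)
    oracle <- sqrt(mean(rowSums(sweep(xyz, 2, ctr)^2)))
    expect_equal(radiusOfGyration(xyz), oracle)
    expect_equal(oracle, 0.5 * sqrt((9^2 - 1) / 12), tolerance = 1e-12)
    # weighted case against the same oracle with weights
    w <- c(1, 2, 1, 3, 1, 2, 1, 4, 1)
    ctr_w <- colSums(xyz * w) / sum(w)
    oracle_w <- sqrt(sum(w * rowSums(sweep(xyz, 2, ctr_w)^2)) / sum(w))
    expect_equal(radiusOfGyration(xyz, w), oracle_w)
    expect_error(radiusOfGyration(xyz, rep(0, 9)), "zero")
})

test_that("Rg is invariant under rigid motions", {
    set.seed(7)
    xyz <- matrix(stats::runif(45), ncol = 3)
    w <- stats::runif(15, 0.5, 2)
    ref <- radiusOfGyration(xyz, w)
    for (rep in 1:10)
        expect_equal(radiusOfGyration(randomRigidMotion(xyz), w), ref,
                     tolerance = 1e-10)
})

test_that("rgSeries preserves frame order and weighting choice matters", {
    xyz <- rbind(c(0, 0, 0), c(0.3, 0, 0), c(0.3, 0.8, 0))
    m <- molecularModel(c("C", "O", "H"), xyz)
    traj <- trajectoryFrames(m, list(xyz, xyz, xyz), 0.1)
    rg <- rgSeries(traj)
    expect_length(rg, 3L)
    expect_equal(as.numeric(rg), rep(rg[1], 3), ignore_attr = TRUE)
    rg_m <- rgSeries(traj, "mass")[1]
    rg_e <- rgSeries(traj, "electron")[1]
    # direct-summation oracles for both weightings of the asymmetric molecule
    expect_equal(unname(rg_m),
                 radiusOfGyration(xyz, atoms(m)$mass))
    expect_equal(unname(rg_e),
                 radiusOfGyration(xyz, c(6, 8, 1)))
    expect_gt(abs(rg_m - rg_e), 1e-4)
})

test_that("torsion angles follow the IUPAC sign convention", {
    # planar cis -> 0, planar trans -> 180
    expect_equal(dihedralAngle(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                               c(2, 1, 0)), 0)
    expect_equal(dihedralAngle(c(1, 1, 0), c(1, 0, 0), c(2, 0, 0),
                               c(2, -1, 0)), 180)
    expect_equal(dihedralAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                               c(0, 1, 1)), -90)
    expect_error(dihedralAngle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                               c(3, 0, 0)), "collinear|undefined")
})

test_that("torsion symmetry: reversal preserves, mirroring flips sign", {
    set.seed(11)
    for (rep in 1:20) {
        p <- lapply(1:4, function(i) stats::runif(3, -2, 2))
        a <- tryCatch(dihedralAngle(p[[1]], p[[2]], p[[3]], p[[4]]),
                      error = function(e) NULL)
        if (is.null(a)) next
        expect_equal(dihedralAngle(p[[4]], p[[3]], p[[2]], p[[1]]), a,
                     tolerance = 1e-10)
        m <- lapply(p, function(v) v * c(1, 1, -1))
        flipped <- dihedralAngle(m[[1]], m[[2]], m[[3]], m[[4]])
        if (abs(abs(a) - 180) > 1e-8)
            expect_equal(flipped, -a, tolerance = 1e-10)
    }
})

test_that("torsions agree with the bio3d oracle", {
    skip_if_not_installed("bio3d")
    set.seed(23)
    for (rep in 1:10) {
        p <- matrix(stats::runif(12, -1, 1), ncol = 3, byrow = TRUE)
        ours <- dihedralAngle(p[1, ], p[2, ], p[3, ], p[4, ])
        ref <- bio3d::torsion.xyz(as.numeric(t(p)))
        ref <- ref[!is.na(ref)][1]
        expect_equal(ours, ref, tolerance = 1e-6)
    }
})

test_that("dihedralSeries evaluates glycosidic-style quadruples per frame", {
    xyz1 <- rbind(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1),
                  c(1, 1, 1))
    xyz2 <- xyz1; xyz2[4, ] <- c(0, 1, -1)
    m <- molecularModel(rep("C", 5), xyz1)
    traj <- trajectoryFrames(m, list(xyz1, xyz2), 0.1)
    ds <- dihedralSeries(traj, phi_atoms = 1:4, psi_atoms = 2:5)
    expect_equal(nrow(ds), 2L)
    expect_equal(ds$phi[1], -90)
    expect_equal(ds$phi[2], 90)
    expect_error(dihedralSeries(traj, c(1, 2, 3, 9), 2:5), "out of range")
})

test_that("hydrogen-bond classification is the strict product set", {
    # collinear C-H...O, |C-O| = 0.35 nm
    g <- hbondGeometry(c(0, 0, 0), c(0.11, 0, 0), c(0.35, 0, 0))
    expect_equal(g$angle, 180)
    expect_equal(g$distance, 0.35)
    expect_true(g$favorable)
    # distance too long despite good angle
    g2 <- hbondGeometry(c(0, 0, 0), c(0.11, 0, 0), c(0.45, 0, 0))
    expect_false(g2$favorable)
    expect_gt(g2$angle, 170)
    # right angle at H
    g3 <- hbondGeometry(c(-0.1, 0, 0), c(0, 0, 0), c(0, 0.25, 0))
    expect_equal(g3$angle, 90)
    expect_false(g3$favorable)
    expect_error(hbondGeometry(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
                 "coincident")
})

test_that("boundary values 0.4 nm / 150 degrees are NOT favorable", {
    # strict '<' on distance: a geometry sitting exactly AT the distance
    # cutoff (cutoff set to its own measured distance) is unfavorable
    C <- c(0, 0, 0); H <- c(0.1, 0, 0)
    g <- hbondGeometry(C, H, placeAcceptor(C, H, 0.35, 170))
    expect_true(g$favorable)
    expect_false(hbondGeometry(C, H, placeAcceptor(C, H, 0.35, 170),
                               distance_cutoff = g$distance)$favorable)
    # strict '>' on angle likewise
    expect_false(hbondGeometry(C, H, placeAcceptor(C, H, 0.35, 170),
                               angle_cutoff = g$angle)$favorable)
    # values just beyond the measured point flip both back to favorable
    expect_true(hbondGeometry(C, H, placeAcceptor(C, H, 0.35, 170),
                              distance_cutoff = g$distance + 1e-9,
                              angle_cutoff = g$angle - 1e-9)$favorable)
})

test_that("occupancy map matches a counting oracle", {
    # frames alternate favorable / unfavorable by construction
    good <- rbind(c(0, 0, 0), c(0.11, 0, 0), c(0.35, 0, 0))
    bad <- rbind(c(0, 0, 0), c(0.11, 0, 0), c(0.55, 0, 0))
    m <- molecularModel(c("C", "H", "O"), good)
    mk <- function(frames) trajectoryFrames(m, frames, 0.1)
    all_good <- hbondOccupancyMap(mk(list(good, good, good)), 1, 2, 3)
    expect_equal(all_good$favorable_fraction, 1.0)
    none <- hbondOccupancyMap(mk(list(bad, bad)), 1, 2, 3)
    expect_equal(none$favorable_fraction, 0.0)
    half <- hbondOccupancyMap(mk(list(good, bad, good, bad)), 1, 2, 3)
    # counting oracle: 2 of 4 frames favorable
    expect_equal(half$favorable_fraction, 2 / 4)
    expect_equal(half$geometry$favorable, c(TRUE, FALSE, TRUE, FALSE))
    # stride keeps every second frame
    strided <- hbondOccupancyMap(mk(list(good, bad, good, bad)), 1, 2, 3,
                                 stride = 2)
    expect_equal(strided$favorable_fraction, 1.0)
})

test_that("minimum inter-residue distance matches brute force", {
    set.seed(5)
    xyz <- matrix(stats::runif(54, 0, 2), ncol = 3)
    a <- 1:9; b <- 10:18
    brute <- min(apply(xyz[a, ], 1, function(p)
        apply(xyz[b, ], 1, function(q) sqrt(sum((p - q)^2)))))
    expect_equal(minInterresidueDistance(xyz, a, b), brute, tolerance = 1e-12)
    # shared coordinate -> 0
    xyz2 <- rbind(c(0, 0, 0), c(1, 1, 1), c(0, 0, 0))
    expect_equal(minInterresidueDistance(xyz2, 1:2, 3), 0)
    # two single atoms at 1.2 nm
    expect_equal(minInterresidueDistance(rbind(c(0, 0, 0), c(0, 1.2, 0)),
                                         1, 2), 1.2)
    expect_error(minInterresidueDistance(xyz, integer(0), b), "empty")
    expect_error(minInterresidueDistance(xyz, 1:3, 3:5), "disjoint")
})
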