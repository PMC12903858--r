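# Fixtures are built in code at test time; nothing binary on disk.

pdbAtomLine <- function(serial, name, res, resid, x, y, z, element = "") {
    # fixed-column PDB ATOM record; x/y/z in Angstrom
    sprintf("ATOM  %5d %-4s %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
            serial, name, res, resid, x, y, z, element)
}

writeThreeAtomPdb <- function(path) {
    writeLines(c(
        pdbAtomLine(1, " C1 ", "GLC", 1, 0, 0, 0, "C"),
        pdbAtomLine(2, " O2 ", "GLC", 1, 1.5, 0, 0, "O"),
        pdbAtomLine(3, " H1 ", "GLC", 1, 0, 1.0, 0, "H"),
        "END"), path)
    path
}

# k frames of a 2-atom model; frame i has the second atom at x = i Angstrom
writeMultiModelFixture <- function(path, k, drop_atom_in = NULL) {
    lines <- character(0)
    for (i in seq_len(k)) {
        lines <- c(lines, sprintf("MODEL     %4d", i),
                   pdbAtomLine(1, " C1 ", "BED", 1, 0, 0, 0, "C"))
        if (!identical(i, drop_atom_in))
            lines <- c(lines, pdbAtomLine(2, " O1 ", "BED", 1, i, 0, 0, "O"))
        lines <- c(lines, "ENDMDL")
    }
    writeLines(c(lines, "END"), path)
    path
}

writeGroFixture <- function(path, n_frames = 1) {
    lines <- character(0)
    for (i in seq_len(n_frames)) {
        lines <- c(lines,
            sprintf("bead chain t=%d", i),
            "    3",
            sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "BED", "C1", 1L,
                    0, 0, 0),
            sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 1L, "BED", "O1", 2L,
                    0.1 * i, 0, 0),
            sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f", 2L, "BED", "C2", 3L,
                    0, 0.2, 0),
            "   2.00000   2.00000   2.00000")
    }
    writeLines(lines, path)
    path
}

# compact globular bead cluster with exactly known geometry, for Guinier
# cross-checks
beadBallModel <- function(radius = 2, spacing = 0.25) {
    g <- seq(-radius, radius, by = spacing)
    pts <- as.matrix(expand.grid(x = g, y = g, z = g))
    pts <- pts[rowSums(pts^2) <= radius^2, , drop = FALSE]
    molecularModel(rep("C", nrow(pts)), pts)
}

# random rigid motion for invariance properties
randomRigidMotion <- function(xyz) {
    th <- stats::runif(3, 0, 2 * pi)
    Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
                c(0, sin(th[1]), cos(th[1])))
    Rz <- rbind(c(cos(th[2]), -sin(th[2]), 0),
                c(sin(th[2]), cos(th[2]), 0), c(0, 0, 1))
    shift <- matrix(stats::runif(3, -5, 5), nrow(xyz), 3, byrow = TRUE)
    xyz %*% (Rx %*% Rz) + shift
}

# ten-atom mixed-element rigid model for forward-model checks
tenAtomModel <- function() {
    set.seed(42)
    xyz <- matrix(stats::runif(30, 0, 1.2), ncol = 3)
    molecularModel(rep(c("C", "O", "N", "H", "C"), 2), xyz)
}

# Monte-Carlo intensity with its per-direction standard error, one seeded
# uniform-random draw
mcIntensityWithSE <- function(model, q, n_total = 10000L, seed = 1L) {
    out <- orientationalAverageIntensity(model, q, n_vectors = n_total,
                                         sampling = "random", seed = seed,
                                         with_se = TRUE)
    list(mean = intensities(out$curve), se = out$se)
}

# place an acceptor O at an exact C-H...O angle (degrees) and C-O distance:
# with u = C - H, r solves |u - r dir|^2 = d^2 along the direction dir that
# makes the requested angle with u at H
placeAcceptor <- function(C, H, d_co, angle_deg) {
    u <- C - H
    th <- pi - angle_deg * pi / 180  # direction angle from -u
    dir <- c(cos(th), sin(th), 0)
    ud <- sum(u * dir)
    r <- ud + sqrt(ud^2 + d_co^2 - sum(u^2))
    H + r * dir
}
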