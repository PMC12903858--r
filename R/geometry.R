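## Per-frame structural descriptors: radius of gyration, torsions,
## CH...O hydrogen-bond geometry, inter-residue distances.

#' Weighted radius of gyration of one coordinate set
#'
#' Rg^2 = sum_i w_i |r_i - r_bar|^2 / sum_i w_i with r_bar the weighted
#' centroid. Mass weights are the MD convention; electron-count weights give
#' the SAXS-comparable Rg.
#'
#' @param coordinates numeric N x 3 matrix, nm.
#' @param weights per-atom weights, all >= 0 with positive sum.
#' @return Rg in nm.
#' @examples
#' radiusOfGyration(rbind(c(0, 0, 0), c(1, 0, 0)), c(1, 1))  # 0.5
#' @export
radiusOfGyration <- function(coordinates,
                             weights = rep(1, nrow(coordinates))) {
    coordinates <- as.matrix(coordinates)
    stopifnot(nrow(coordinates) >= 1L, ncol(coordinates) == 3L,
              length(weights) == nrow(coordinates))
    if (any(weights < 0)) stop("weights must be >= 0")
    W <- sum(weights)
    if (W <= 0) stop("validation error: weights sum to zero")
    ctr <- colSums(coordinates * weights) / W
    d2 <- rowSums(sweep(coordinates, 2, ctr)^2)
    sqrt(sum(weights * d2) / W)
}

.rgWeights <- function(model, weighting) {
    switch(weighting,
           mass = atoms(model)$mass,
           electron = electronCounts(atoms(model)$element),
           stop("weighting must be 'mass' or 'electron'"))
}

#' @rdname rgSeries
#' @export
setMethod("rgSeries", "TrajectoryFrames", function(x,
        weighting = c("mass", "electron")) {
    weighting <- match.arg(weighting)
    w <- .rgWeights(x@model, weighting)
    out <- vapply(x@frames, radiusOfGyration, numeric(1), weights = w)
    attr(out, "weighting") <- weighting
    out
})

#' Signed torsion angle of four points
#'
#' IUPAC convention: atan2((n1 x n2) . b2_hat, n1 . n2) with b1 = p2 - p1,
#' b2 = p3 - p2, b3 = p4 - p3, n1 = b1 x b2, n2 = b2 x b3. Planar cis is 0,
#' planar trans 180; range (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 points.
#' @return signed dihedral in degrees.
#' @examples
#' dihedralAngle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(0, 1, 1))  # -90
#' @export
dihedralAngle <- function(p1, p2, p3, p4) {
    cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                              a[3] * b[1] - a[1] * b[3],
                              a[1] * b[2] - a[2] * b[1])
    b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
    n1 <- cross(b1, b2); n2 <- cross(b2, b3)
    nb2 <- sqrt(sum(b2^2))
    if (nb2 == 0 || sum(n1^2) == 0 || sum(n2^2) == 0)
        stop("undefined torsion: collinear or coincident points")
    ang <- atan2(sum(cross(n1, n2) * b2) / nb2, sum(n1 * n2)) * 180 / pi
    if (ang <= -180) ang <- ang + 360
    ang
}

#' Glycosidic Phi/Psi torsion series along a trajectory
#'
#' Computes two torsions per frame from explicit atom-index quadruples. For
#' a glycosidic linkage the conventional choice is
#' Phi: O5'-C1'-O2-C2 and Psi: C1'-O2-C2-C1, the carbohydrate analogue of a
#' Ramachandran pair; any quadruples may be supplied.
#'
#' @param traj a [TrajectoryFrames-class].
#' @param phi_atoms,psi_atoms integer length-4 atom indices (1-based).
#' @return data.frame with columns `frame`, `phi`, `psi` (degrees).
#' @export
dihedralSeries <- function(traj, phi_atoms, psi_atoms) {
    stopifnot(length(phi_atoms) == 4L, length(psi_atoms) == 4L,
              anyDuplicated(phi_atoms) == 0L, anyDuplicated(psi_atoms) == 0L)
    n <- nAtoms(traj)
    if (any(c(phi_atoms, psi_atoms) < 1L) || any(c(phi_atoms, psi_atoms) > n))
        stop("atom index out of range 1..", n)
    one <- function(xyz, idx)
        dihedralAngle(xyz[idx[1], ], xyz[idx[2], ], xyz[idx[3], ], xyz[idx[4], ])
    data.frame(frame = seq_len(nFrames(traj)),
               phi = vapply(traj@frames, one, numeric(1), idx = phi_atoms),
               psi = vapply(traj@frames, one, numeric(1), idx = psi_atoms))
}

#' CH...O hydrogen-bond geometry of one frame
#'
#' For a carbon donor C-H and oxygen acceptor O: the donor-acceptor distance
#' is |C - O| (nm) and the angle is the C-H...O angle at the hydrogen
#' (degrees). The interaction is favorable when the distance is strictly
#' below 0.4 nm and the angle strictly above 150 degrees; both boundaries
#' are excluded.
#'
#' @param c_pos,h_pos,o_pos numeric length-3 positions (nm) of the donor
#'   carbon, its hydrogen, and the acceptor oxygen.
#' @param distance_cutoff donor-acceptor cutoff, nm (default 0.4).
#' @param angle_cutoff angle cutoff, degrees (default 150).
#' @return list with `distance` (nm), `angle` (degrees), `favorable`
#'   (logical).
#' @export
hbondGeometry <- function(c_pos, h_pos, o_pos,
                          distance_cutoff = 0.4, angle_cutoff = 150) {
    v1 <- c_pos - h_pos; v2 <- o_pos - h_pos
    n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
    if (n1 == 0 || n2 == 0)
        stop("validation error: coincident points in hydrogen-bond geometry")
    cosang <- min(1, max(-1, sum(v1 * v2) / (n1 * n2)))
    ang <- acos(cosang) * 180 / pi
    d <- sqrt(sum((c_pos - o_pos)^2))
    list(distance = d, angle = ang,
         favorable = (d < distance_cutoff) && (ang > angle_cutoff))
}

#' Hydrogen-bond geometry along a trajectory
#'
#' Per-frame donor-acceptor distance and C-H...O angle for one C/H/O atom
#' triple, plus the fraction of frames where the interaction is favorable
#' (distance < 0.4 nm and angle > 150 degrees, strict). The returned table
#' is the machine twin of a distance-vs-angle population plot.
#'
#' @param traj a [TrajectoryFrames-class].
#' @param c_idx,h_idx,o_idx 1-based atom indices of the donor carbon, its
#'   hydrogen and the acceptor oxygen.
#' @param stride use every `stride`-th frame (default 1 = all frames).
#' @param distance_cutoff,angle_cutoff as in [hbondGeometry()].
#' @return list with `geometry` (data.frame: frame, distance, angle,
#'   favorable) and `favorable_fraction`.
#' @export
hbondOccupancyMap <- function(traj, c_idx, h_idx, o_idx, stride = 1L,
                              distance_cutoff = 0.4, angle_cutoff = 150) {
    n <- nAtoms(traj)
    idx <- c(c_idx, h_idx, o_idx)
    if (any(idx < 1L) || any(idx > n))
        stop("atom index out of range 1..", n)
    keep <- seq(1L, nFrames(traj), by = as.integer(stride))
    rows <- lapply(keep, function(k) {
        xyz <- traj@frames[[k]]
        g <- hbondGeometry(xyz[c_idx, ], xyz[h_idx, ], xyz[o_idx, ],
                           distance_cutoff, angle_cutoff)
        data.frame(frame = k, distance = g$distance, angle = g$angle,
                   favorable = g$favorable)
    })
    geom <- do.call(rbind, rows)
    list(geometry = geom, favorable_fraction = mean(geom$favorable))
}

#' Minimum inter-residue distance in one frame
#'
#' Smallest pairwise Euclidean distance between two disjoint atom sets;
#' used to diagnose strand packing (hairpin/sheet contacts).
#'
#' @param coordinates numeric N x 3 matrix, nm.
#' @param set_a,set_b disjoint non-empty 1-based atom index vectors.
#' @return minimum distance, nm.
#' @export
minInterresidueDistance <- function(coordinates, set_a, set_b) {
    if (length(set_a) == 0L || length(set_b) == 0L)
        stop("validation error: empty atom set")
    if (length(intersect(set_a, set_b)))
        stop("validation error: atom sets must be disjoint")
    a <- coordinates[set_a, , drop = FALSE]
    b <- coordinates[set_b, , drop = FALSE]
    d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * a %*% t(b)
    sqrt(max(0, min(d2)))
}
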