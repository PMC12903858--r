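## User-facing constructors. Validity checking happens in new().

# approximate atomic masses (Da) for elements the form-factor table covers
.ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    Na = 22.990, P = 30.974, S = 32.06)

.massForElement <- function(element) {
    m <- .ATOMIC_MASSES[element]
    m[is.na(m)] <- 12.0  # fallback for elements without a tabulated mass
    unname(m)
}

#' Construct a MolecularModel
#'
#' @param elements character vector of element symbols, one per atom.
#' @param coordinates numeric N x 3 matrix, nm.
#' @param names atom names; default the element symbols.
#' @param masses atomic masses in Da; looked up from the element when omitted.
#' @param residue_id,residue_name per-atom residue assignment.
#' @return a [MolecularModel-class]
#' @examples
#' m <- molecularModel(c("C", "O"), rbind(c(0, 0, 0), c(0.5, 0, 0)))
#' nAtoms(m)
#' @export
molecularModel <- function(elements, coordinates, names = elements,
                           masses = .massForElement(elements),
                           residue_id = rep(1L, length(elements)),
                           residue_name = rep("UNK", length(elements))) {
    coordinates <- as.matrix(coordinates)
    storage.mode(coordinates) <- "double"
    dimnames(coordinates) <- NULL
    new("MolecularModel",
        atoms = data.frame(name = as.character(names),
                           element = as.character(elements),
                           mass = as.numeric(masses),
                           residue_id = as.integer(residue_id),
                           residue_name = as.character(residue_name),
                           stringsAsFactors = FALSE),
        coordinates = coordinates)
}

#' Construct a TrajectoryFrames object
#'
#' @param model a [MolecularModel-class] providing the topology.
#' @param frames list of N x 3 coordinate matrices (nm) or a single matrix.
#' @param frame_time_step time between frames, ns.
#' @return a [TrajectoryFrames-class]
#' @export
trajectoryFrames <- function(model, frames, frame_time_step) {
    if (is.matrix(frames)) frames <- list(frames)
    frames <- lapply(frames, function(f) {
        f <- as.matrix(f); storage.mode(f) <- "double"; dimnames(f) <- NULL; f
    })
    new("TrajectoryFrames", model = model, frames = frames,
        frameTimeStep = as.numeric(frame_time_step))
}

#' Construct a ScatteringCurve
#'
#' @param q momentum transfer, Angstrom^-1, strictly increasing.
#' @param intensity intensities, arbitrary units.
#' @param sigma optional uncertainties (> 0), or NULL.
#' @return a [ScatteringCurve-class]
#' @examples
#' scatteringCurve(c(0.01, 0.02), c(100, 98))
#' @export
scatteringCurve <- function(q, intensity, sigma = NULL) {
    new("ScatteringCurve", q = as.numeric(q),
        intensity = as.numeric(intensity),
        sigma = if (is.null(sigma)) numeric(0) else as.numeric(sigma))
}

#' Construct a SolventModel
#'
#' The implicit-solvent settings of the SAXS forward model. In
#' `"excluded_volume"` mode each atom's form factor is reduced by a Gaussian
#' dummy atom of the solvent (Fraser convention) with the displaced volumes
#' stored in the form-factor table; `"vacuum"` ignores the solvent entirely.
#'
#' @param mode `"vacuum"` or `"excluded_volume"`.
#' @param electron_density solvent electron density, e/nm^3; the default 334
#'   is the experimental value for water used throughout.
#' @return a [SolventModel-class]
#' @examples
#' solventModel("excluded_volume")
#' @export
solventModel <- function(mode = c("vacuum", "excluded_volume"),
                         electron_density = 334) {
    mode <- match.arg(mode)
    new("SolventModel", electronDensity = as.numeric(electron_density),
        mode = mode)
}
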