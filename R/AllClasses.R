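#' @import methods
NULL

## Central S4 containers. Internal length unit is nm throughout; momentum
## transfer q is Angstrom^-1 at every user-facing interface (1 A^-1 = 10 nm^-1).

#' MolecularModel: atoms plus one coordinate set
#'
#' Holds an ordered atom table (name, element, mass, residue id/name) and an
#' N x 3 coordinate matrix in nm.
#'
#' @slot atoms data.frame with columns `name`, `element`, `mass`,
#'   `residue_id`, `residue_name`, one row per atom in file order.
#' @slot coordinates numeric N x 3 matrix, nm.
#'
#' @seealso [readStructure()], [rigidReferenceShapes()]
#' @export
setClass("MolecularModel",
    slots = c(atoms = "data.frame", coordinates = "matrix"))

setValidity("MolecularModel", function(object) {
    a <- object@atoms
    x <- object@coordinates
    msg <- character()
    need <- c("name", "element", "mass", "residue_id", "residue_name")
    if (!all(need %in% names(a)))
        msg <- c(msg, paste("atoms must have columns:",
                            paste(need, collapse = ", ")))
    if (nrow(a) == 0L)
        msg <- c(msg, "model must contain at least one atom")
    if (!is.numeric(x) || ncol(x) != 3L)
        msg <- c(msg, "coordinates must be a numeric N x 3 matrix")
    else if (nrow(x) != nrow(a))
        msg <- c(msg, "coordinate row count must equal atom count")
    else if (!all(is.finite(x)))
        msg <- c(msg, "all coordinates must be finite")
    if ("mass" %in% names(a) && nrow(a) > 0L && any(!is.finite(a$mass) | a$mass <= 0))
        msg <- c(msg, "atom masses must be positive")
    if (length(msg)) msg else TRUE
})

#' TrajectoryFrames: a topology plus a series of coordinate sets
#'
#' @slot model [MolecularModel-class] supplying the topology (atom identities).
#' @slot frames list of N x 3 coordinate matrices (nm), one per frame, in
#'   temporal order.
#' @slot frameTimeStep numeric, time between consecutive frames, ns.
#'
#' @seealso [readTrajectory()], [generateTwoStateTrajectory()]
#' @export
setClass("TrajectoryFrames",
    slots = c(model = "MolecularModel", frames = "list",
              frameTimeStep = "numeric"))

setValidity("TrajectoryFrames", function(object) {
    msg <- character()
    n <- nAtoms(object@model)
    if (length(object@frames) == 0L)
        msg <- c(msg, "trajectory must contain at least one frame")
    bad <- which(!vapply(object@frames, function(f)
        is.matrix(f) && ncol(f) == 3L && nrow(f) == n && all(is.finite(f)),
        logical(1)))
    if (length(bad))
        msg <- c(msg, sprintf(
            "frame %d does not match the topology atom count (%d)", bad[1], n))
    if (length(object@frameTimeStep) != 1L ||
        !is.finite(object@frameTimeStep) || object@frameTimeStep <= 0)
        msg <- c(msg, "frameTimeStep must be a single positive number (ns)")
    if (length(msg)) msg else TRUE
})

#' ScatteringCurve: I(q) with optional uncertainties
#'
#' @slot q numeric, momentum transfer, Angstrom^-1, strictly increasing,
#'   all values >= 0.
#' @slot intensity numeric, arbitrary units, same length as `q`.
#' @slot sigma numeric, point-wise uncertainties (same units as intensity) or
#'   `numeric(0)` when absent.
#'
#' @seealso [readScatteringCurve()], [debyeIntensity()]
#' @export
setClass("ScatteringCurve",
    slots = c(q = "numeric", intensity = "numeric", sigma = "numeric"))

setValidity("ScatteringCurve", function(object) {
    msg <- character()
    q <- object@q
    if (length(q) == 0L)
        msg <- c(msg, "curve must contain at least one point")
    if (any(!is.finite(q)) || any(q < 0))
        msg <- c(msg, "q must be finite and >= 0")
    if (length(q) > 1L && any(diff(q) <= 0))
        msg <- c(msg, "q must be strictly increasing (duplicates not allowed)")
    if (length(object@intensity) != length(q))
        msg <- c(msg, "intensity length must match q")
    if (any(!is.finite(object@intensity)))
        msg <- c(msg, "intensities must be finite")
    if (length(object@sigma) &&
        (length(object@sigma) != length(q) ||
         any(!is.finite(object@sigma) | object@sigma <= 0)))
        msg <- c(msg, "sigma, when present, must match q in length and be > 0")
    if (length(msg)) msg else TRUE
})

#' StateAssignment: interval-based folded/unfolded labels along a trajectory
#'
#' @slot intervals data.frame with columns `start_frame`, `end_frame`
#'   (half-open, 1-based `[start, end)` in frame indices) and `mean_rg` (nm).
#' @slot labels character, per-interval state, each `"fc"` or `"uf"`.
#' @slot threshold numeric, the Rg cutoff used, nm.
#' @slot intervalLength numeric, nominal interval length, ns.
#'
#' @seealso [assignStates()], [mdFoldedFraction()]
#' @export
setClass("StateAssignment",
    slots = c(intervals = "data.frame", labels = "character",
              threshold = "numeric", intervalLength = "numeric"))

setValidity("StateAssignment", function(object) {
    iv <- object@intervals
    msg <- character()
    if (!all(c("start_frame", "end_frame", "mean_rg") %in% names(iv)))
        msg <- c(msg, "intervals needs columns start_frame, end_frame, mean_rg")
    else {
        if (nrow(iv) == 0L)
            msg <- c(msg, "assignment must contain at least one interval")
        if (any(iv$end_frame <= iv$start_frame))
            msg <- c(msg, "every interval must satisfy end_frame > start_frame")
        if (nrow(iv) > 1L &&
            any(iv$start_frame[-1] != iv$end_frame[-nrow(iv)]))
            msg <- c(msg, "intervals must tile the trajectory contiguously")
        if (any(iv$mean_rg < 0))
            msg <- c(msg, "mean_rg must be >= 0")
    }
    if (length(object@labels) != nrow(iv))
        msg <- c(msg, "labels length must equal interval count")
    if (!all(object@labels %in% c("fc", "uf")))
        msg <- c(msg, "labels must be 'fc' or 'uf'")
    if (length(msg)) msg else TRUE
})

#' FormFactorTable: Cromer-Mann coefficients per element
#'
#' Four-Gaussian-plus-constant parametrisation of the X-ray atomic form
#' factor, f(q) = c + sum_k a_k exp(-b_k (q / 4 pi)^2), q in Angstrom^-1,
#' b_k in Angstrom^2, plus the displaced solvent volume per element (nm^3)
#' used by the excluded-volume correction.
#'
#' @slot coefficients data.frame with columns `element`, `a1`..`a4`,
#'   `b1`..`b4`, `c`, `z` (atomic number), `volume_nm3` (may be NA).
#'
#' @seealso [cromerMannTable()], [atomicFormFactor()]
#' @export
setClass("FormFactorTable", slots = c(coefficients = "data.frame"))

setValidity("FormFactorTable", function(object) {
    co <- object@coefficients
    need <- c("element", paste0("a", 1:4), paste0("b", 1:4), "c", "z",
              "volume_nm3")
    msg <- character()
    if (!all(need %in% names(co)))
        msg <- c(msg, paste("coefficients must have columns:",
                            paste(need, collapse = ", ")))
    else {
        if (any(duplicated(co$element)))
            msg <- c(msg, "duplicate element entries")
        bmat <- as.matrix(co[paste0("b", 1:4)])
        if (any(bmat < 0))
            msg <- c(msg, "all b_k must be >= 0")
        f0 <- co$c + rowSums(as.matrix(co[paste0("a", 1:4)]))
        off <- abs(f0 - co$z) > 0.2
        if (any(off))
            msg <- c(msg, sprintf(
                "f(0) deviates from atomic number by > 0.2 for: %s",
                paste(co$element[off], collapse = ", ")))
    }
    if (length(msg)) msg else TRUE
})

#' SolventModel: implicit-solvent settings for the forward model
#'
#' @slot electronDensity numeric, solvent electron density, e/nm^3
#'   (334 for water at the experimental condition modelled here).
#' @slot mode character, `"vacuum"` or `"excluded_volume"`.
#'
#' @seealso [solventModel()], [effectiveFormFactor()]
#' @export
setClass("SolventModel",
    slots = c(electronDensity = "numeric", mode = "character"))

setValidity("SolventModel", function(object) {
    msg <- character()
    if (length(object@electronDensity) != 1L ||
        !is.finite(object@electronDensity) || object@electronDensity < 0)
        msg <- c(msg, "electronDensity must be a single number >= 0")
    if (!object@mode %in% c("vacuum", "excluded_volume"))
        msg <- c(msg, "mode must be 'vacuum' or 'excluded_volume'")
    if (length(msg)) msg else TRUE
})

#' GuinierResult: low-q Guinier fit of a scattering curve
#'
#' @slot rg numeric, radius of gyration, Angstrom.
#' @slot i0 numeric, extrapolated forward scattering I(0).
#' @slot qRangeUsed numeric length-2, (q_min, q_max) of the fitted window,
#'   Angstrom^-1.
#' @slot fitPoints integer, number of points in the fitted window.
#' @slot rSquared numeric, coefficient of determination of the ln I vs q^2
#'   fit.
#' @slot qrgLimit numeric, the q.Rg validity cutoff that defined the window.
#'
#' @seealso [guinierFit()]
#' @export
setClass("GuinierResult",
    slots = c(rg = "numeric", i0 = "numeric", qRangeUsed = "numeric",
              fitPoints = "integer", rSquared = "numeric",
              qrgLimit = "numeric"))

setValidity("GuinierResult", function(object) {
    msg <- character()
    if (object@rg <= 0) msg <- c(msg, "rg must be > 0")
    if (object@fitPoints < 3L) msg <- c(msg, "fit needs at least 3 points")
    if (length(msg)) msg else TRUE
})

#' PopulationFitResult: mixture weights of per-state SAXS curves
#'
#' Result of fitting s * sum_s w_s I_s(q) + b to an experimental curve with
#' w_s >= 0, sum w_s = 1. The weight of the folded-state curve is the
#' degree of folding.
#'
#' @slot weights named numeric, per-state weights on the simplex.
#' @slot scale numeric, global multiplicative factor s (> 0).
#' @slot background numeric, additive constant b (0 when not fitted).
#' @slot chi2Reduced numeric, chi^2 / N at the optimum.
#' @slot qRangeUsed numeric length-2, Angstrom^-1.
#' @slot weightUncertainties named numeric matrix (2 x K, rows `lower`,
#'   `upper`) or a 0 x 0 matrix before [foldFractionUncertainty()] runs.
#' @slot illConditioned logical, TRUE when the state curves are numerically
#'   indistinguishable so weights are not identifiable.
#'
#' @seealso [fitPopulations()], [degreeOfFolding()]
#' @export
setClass("PopulationFitResult",
    slots = c(weights = "numeric", scale = "numeric", background = "numeric",
              chi2Reduced = "numeric", qRangeUsed = "numeric",
              weightUncertainties = "matrix", illConditioned = "logical"))

setValidity("PopulationFitResult", function(object) {
    w <- object@weights
    msg <- character()
    if (is.null(names(w)) || any(!nzchar(names(w))))
        msg <- c(msg, "weights must be named by state")
    if (any(w < -1e-12))
        msg <- c(msg, "weights must be >= 0")
    if (abs(sum(w) - 1) > 1e-9)
        msg <- c(msg, "weights must sum to 1 (within 1e-9)")
    if (object@scale <= 0)
        msg <- c(msg, "scale must be > 0")
    if (length(msg)) msg else TRUE
})
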