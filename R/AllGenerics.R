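#' @rdname MolecularModel-class
#' @param x,object a glycoSAXS object
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname MolecularModel-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname MolecularModel-class
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' @rdname TrajectoryFrames-class
#' @param x a glycoSAXS object
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname TrajectoryFrames-class
#' @param i frame index (1-based)
#' @export
setGeneric("frameCoords", function(x, i) standardGeneric("frameCoords"))

#' @rdname TrajectoryFrames-class
#' @export
setGeneric("frameTimeStep", function(x) standardGeneric("frameTimeStep"))

#' @rdname ScatteringCurve-class
#' @param x a glycoSAXS object
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @rdname ScatteringCurve-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname ScatteringCurve-class
#' @export
setGeneric("sigmas", function(x) standardGeneric("sigmas"))

#' @rdname ScatteringCurve-class
#' @export
setGeneric("hasSigma", function(x) standardGeneric("hasSigma"))

#' @rdname StateAssignment-class
#' @param x a glycoSAXS object
#' @export
setGeneric("stateLabels", function(x) standardGeneric("stateLabels"))

#' @rdname StateAssignment-class
#' @export
setGeneric("intervalTable", function(x) standardGeneric("intervalTable"))

#' Per-frame radius of gyration of a trajectory
#'
#' One Rg value (nm) per frame, in frame order.
#'
#' @param x a [TrajectoryFrames-class] object
#' @param weighting `"mass"` (default, the MD convention) or `"electron"`
#'   (atomic-number weights, the SAXS-comparable choice).
#' @return numeric vector of Rg values, nm, with attribute `weighting`.
#' @export
setGeneric("rgSeries", function(x, weighting = c("mass", "electron"))
    standardGeneric("rgSeries"))

#' @rdname PopulationFitResult-class
#' @param x a [PopulationFitResult-class]
#' @export
setGeneric("degreeOfFolding", function(x) standardGeneric("degreeOfFolding"))
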