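## Accessors and show methods. Slot access stays internal to the package.

#' @rdname MolecularModel-class
#' @export
setMethod("atoms", "MolecularModel", function(x) x@atoms)

#' @rdname MolecularModel-class
#' @export
setMethod("coords", "MolecularModel", function(x) x@coordinates)

#' @rdname MolecularModel-class
#' @export
setMethod("nAtoms", "MolecularModel", function(x) nrow(x@atoms))

#' @rdname TrajectoryFrames-class
#' @export
setMethod("atoms", "TrajectoryFrames", function(x) x@model@atoms)

#' @rdname TrajectoryFrames-class
#' @export
setMethod("nAtoms", "TrajectoryFrames", function(x) nAtoms(x@model))

#' @rdname TrajectoryFrames-class
#' @export
setMethod("nFrames", "TrajectoryFrames", function(x) length(x@frames))

#' @rdname TrajectoryFrames-class
#' @export
setMethod("frameCoords", "TrajectoryFrames", function(x, i) {
    if (i < 1L || i > length(x@frames))
        stop("frame index ", i, " out of range 1..", length(x@frames))
    x@frames[[i]]
})

#' @rdname TrajectoryFrames-class
#' @export
setMethod("frameTimeStep", "TrajectoryFrames", function(x) x@frameTimeStep)

#' @rdname ScatteringCurve-class
#' @export
setMethod("qValues", "ScatteringCurve", function(x) x@q)

#' @rdname ScatteringCurve-class
#' @export
setMethod("intensities", "ScatteringCurve", function(x) x@intensity)

#' @rdname ScatteringCurve-class
#' @export
setMethod("sigmas", "ScatteringCurve", function(x)
    if (length(x@sigma)) x@sigma else NULL)

#' @rdname ScatteringCurve-class
#' @export
setMethod("hasSigma", "ScatteringCurve", function(x) length(x@sigma) > 0L)

#' @rdname ScatteringCurve-class
#' @export
setMethod("length", "ScatteringCurve", function(x) length(x@q))

#' @rdname StateAssignment-class
#' @export
setMethod("stateLabels", "StateAssignment", function(x) x@labels)

#' @rdname StateAssignment-class
#' @export
setMethod("intervalTable", "StateAssignment", function(x) {
    df <- x@intervals
    df$label <- x@labels
    df
})

#' @rdname PopulationFitResult-class
#' @export
setMethod("degreeOfFolding", "PopulationFitResult", function(x) {
    if (!"fc" %in% names(x@weights))
        stop("no state named 'fc' in this fit")
    unname(x@weights[["fc"]])
})

setMethod("show", "MolecularModel", function(object) {
    cat("MolecularModel with", nAtoms(object), "atoms\n")
    tab <- table(object@atoms$element)
    cat("  elements:", paste(sprintf("%s=%d", names(tab), tab),
                             collapse = " "), "\n")
})

setMethod("show", "TrajectoryFrames", function(object) {
    cat("TrajectoryFrames:", nFrames(object), "frames x",
        nAtoms(object), "atoms,",
        format(object@frameTimeStep), "ns/frame (",
        format(nFrames(object) * object@frameTimeStep), "ns total )\n")
})

setMethod("show", "ScatteringCurve", function(object) {
    cat("ScatteringCurve with", length(object@q), "points, q in [",
        format(min(object@q)), ",", format(max(object@q)), "] A^-1,",
        if (hasSigma(object)) "with" else "no", "uncertainties\n")
})

setMethod("show", "StateAssignment", function(object) {
    tab <- table(factor(object@labels, levels = c("fc", "uf")))
    cat("StateAssignment:", nrow(object@intervals), "intervals (fc:",
        tab[["fc"]], ", uf:", tab[["uf"]], "), threshold",
        format(object@threshold), "nm\n")
})

setMethod("show", "GuinierResult", function(object) {
    cat(sprintf(
        "Guinier fit: Rg = %.3f A, I(0) = %.4g, %d points, q in [%.4g, %.4g] A^-1 (q.Rg <= %.2f), R^2 = %.5f\n",
        object@rg, object@i0, object@fitPoints, object@qRangeUsed[1],
        object@qRangeUsed[2], object@qrgLimit, object@rSquared))
})

setMethod("show", "PopulationFitResult", function(object) {
    cat("Population fit (chi2/N =", format(object@chi2Reduced, digits = 4),
        "):\n")
    for (s in names(object@weights))
        cat(sprintf("  %-4s %6.1f%%\n", s, 100 * object@weights[[s]]))
    cat(sprintf("  scale = %.4g, background = %.4g, q range [%.4g, %.4g] A^-1\n",
                object@scale, object@background,
                object@qRangeUsed[1], object@qRangeUsed[2]))
    if (object@illConditioned)
        cat("  WARNING: state curves indistinguishable; weights not identifiable\n")
})

setMethod("show", "SolventModel", function(object) {
    cat("SolventModel:", object@mode, "mode, rho_s =",
        object@electronDensity, "e/nm^3\n")
})

setMethod("show", "FormFactorTable", function(object) {
    cat("FormFactorTable with", nrow(object@coefficients), "elements:",
        paste(object@coefficients$element, collapse = " "), "\n")
})
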