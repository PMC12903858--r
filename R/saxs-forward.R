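## SAXS forward model: exact Debye summation and Monte-Carlo orientational
## averaging with Cromer-Mann form factors. q at all interfaces in A^-1;
## coordinates internal in nm (q is converted once, 1 A^-1 = 10 nm^-1).

#' Exact orientationally averaged intensity (Debye equation)
#'
#' I(q) = sum_i sum_j f_i(q) f_j(q) sin(q r_ij) / (q r_ij), with the i = j
#' and q -> 0 limits equal to 1. Exact for a rigid atom set; O(N^2) per q
#' value, intended for models up to a few thousand atoms.
#'
#' @param model a [MolecularModel-class].
#' @param q_grid momentum transfer values, Angstrom^-1.
#' @param table a [FormFactorTable-class].
#' @param solvent a [SolventModel-class]; default vacuum.
#' @return a [ScatteringCurve-class] (no sigma).
#' @examples
#' m <- rigidReferenceShapes("two_points", list(d = 0.5))
#' debyeIntensity(m, c(0.01, 0.1, 0.3))
#' @export
debyeIntensity <- function(model, q_grid, table = cromerMannTable(),
                           solvent = solventModel("vacuum")) {
    q_grid <- as.numeric(q_grid)
    stopifnot(length(q_grid) >= 1L, all(q_grid >= 0), !is.unsorted(q_grid))
    xyz <- coords(model)
    if (!all(is.finite(xyz))) stop("non-finite coordinates")
    fmat <- .formFactorMatrix(atoms(model)$element, q_grid, table, solvent)
    D <- as.matrix(stats::dist(xyz))  # nm
    I <- vapply(seq_along(q_grid), function(k) {
        fv <- fmat[, k]
        S <- .sinc(10 * q_grid[k] * D)
        as.numeric(crossprod(fv, S %*% fv))
    }, numeric(1))
    scatteringCurve(q_grid, I)
}

#' Monte-Carlo orientationally averaged intensity
#'
#' For each |q| the scattering amplitude A(q_vec) = sum_j f_j(q)
#' exp(i q_vec . r_j) is evaluated over `n_vectors` directions on the unit
#' sphere and |A|^2 averaged — an unbiased estimator of the Debye value.
#' The default 500 directions per |q| follow the protocol's convention.
#' Directions come from a deterministic Fibonacci lattice (low variance) or
#' seeded uniform sampling.
#'
#' @inheritParams debyeIntensity
#' @param n_vectors directions per |q| (default 500).
#' @param sampling `"fibonacci"` (deterministic, default) or `"random"`.
#' @param seed integer seed for `"random"` sampling; ignored otherwise.
#' @param with_se also return the per-q Monte-Carlo standard error of the
#'   mean, sd(|A|^2) / sqrt(n_vectors), computed from the per-direction
#'   samples (a true standard error only for `"random"` sampling).
#' @return a [ScatteringCurve-class]; with `with_se = TRUE` a list with
#'   elements `curve` and `se`.
#' @export
orientationalAverageIntensity <- function(model, q_grid,
        table = cromerMannTable(), solvent = solventModel("vacuum"),
        n_vectors = 500L, sampling = c("fibonacci", "random"), seed = NULL,
        with_se = FALSE) {
    sampling <- match.arg(sampling)
    q_grid <- as.numeric(q_grid)
    stopifnot(n_vectors >= 1L, all(q_grid >= 0), !is.unsorted(q_grid))
    xyz <- coords(model)
    fmat <- .formFactorMatrix(atoms(model)$element, q_grid, table, solvent)
    dirs <- if (sampling == "fibonacci") .fibonacciSphere(n_vectors)
            else .withSeed(seed, .randomSphere(n_vectors))
    proj <- dirs %*% t(xyz)  # n_vectors x N, nm
    per_q <- lapply(seq_along(q_grid), function(k) {
        A <- exp(1i * 10 * q_grid[k] * proj) %*% fmat[, k]
        Mod(A)^2
    })
    I <- vapply(per_q, mean, numeric(1))
    curve <- scatteringCurve(q_grid, I)
    if (!with_se) return(curve)
    list(curve = curve,
         se = vapply(per_q, stats::sd, numeric(1)) / sqrt(n_vectors))
}

#' Ensemble-averaged SAXS intensity of a conformational state
#'
#' Unweighted mean of single-frame intensities over the (optionally strided)
#' frames of a state ensemble, e.g. the concatenated folded or unfolded
#' frames from [concatenateStateFrames()].
#'
#' @param frames a [TrajectoryFrames-class] (the state ensemble).
#' @param q_grid momentum transfer values, Angstrom^-1.
#' @param table,solvent as in [debyeIntensity()].
#' @param method `"debye"` (exact, default) or `"mc"` (Monte-Carlo
#'   orientational average).
#' @param stride use every `stride`-th frame (default 1).
#' @param n_vectors,sampling,seed passed to
#'   [orientationalAverageIntensity()] when `method = "mc"`.
#' @return a [ScatteringCurve-class].
#' @export
ensembleIntensity <- function(frames, q_grid, table = cromerMannTable(),
        solvent = solventModel("vacuum"), method = c("debye", "mc"),
        stride = 1L, n_vectors = 500L,
        sampling = c("fibonacci", "random"), seed = NULL) {
    method <- match.arg(method)
    sampling <- match.arg(sampling)
    keep <- seq(1L, nFrames(frames), by = as.integer(stride))
    if (length(keep) == 0L) stop("empty ensemble after striding")
    q_grid <- as.numeric(q_grid)
    acc <- numeric(length(q_grid))
    for (k in keep) {
        m <- new("MolecularModel", atoms = atoms(frames),
                 coordinates = frames@frames[[k]])
        cur <- if (method == "debye")
            debyeIntensity(m, q_grid, table, solvent)
        else
            orientationalAverageIntensity(m, q_grid, table, solvent,
                                          n_vectors, sampling, seed)
        acc <- acc + intensities(cur)
    }
    scatteringCurve(q_grid, acc / length(keep))
}
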