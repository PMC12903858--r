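## Degree-of-folding estimation: constrained linear combination of
## per-state predicted SAXS curves fitted to an experimental curve.

#' Truncate a scattering curve at a maximum q
#'
#' For large molecules the mixture analysis is restricted to the lower q
#' range (e.g. up to 0.4 Angstrom^-1) to focus on the overall molecular
#' conformation.
#'
#' @param curve a [ScatteringCurve-class].
#' @param q_max keep points with q <= `q_max` (Angstrom^-1).
#' @return a [ScatteringCurve-class].
#' @export
truncateQRange <- function(curve, q_max) {
    keep <- qValues(curve) <= q_max
    if (!any(keep))
        stop("validation error: q_max = ", q_max,
             " A^-1 lies below the first point (", min(qValues(curve)), ")")
    s <- sigmas(curve)
    scatteringCurve(qValues(curve)[keep], intensities(curve)[keep],
                    if (is.null(s)) NULL else s[keep])
}

## Lawson-Hanson active-set non-negative least squares: minimise
## ||A x - b||_2 subject to x >= 0. Exact for the small, well-posed systems
## arising here (a handful of state curves plus optional background
## columns), including degenerate cases with an exactly zero residual.
.nnls <- function(A, b) {
    n <- ncol(A)
    x <- numeric(n)
    passive <- rep(FALSE, n)
    w <- as.numeric(crossprod(A, b))
    tol <- 10 * .Machine$double.eps * max(abs(w), 1) * max(dim(A))
    for (outer in seq_len(30L * n)) {
        w <- as.numeric(crossprod(A, b - A %*% x))
        cand <- which(!passive & w > tol)
        if (length(cand) == 0L) break
        passive[cand[which.max(w[cand])]] <- TRUE
        repeat {
            z <- numeric(n)
            z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
            z[passive][is.na(z[passive])] <- 0
            if (all(z[passive] > tol)) { x <- z; break }
            viol <- passive & (z <= tol)
            alpha <- min(x[viol] / (x[viol] - z[viol]))
            x <- x + alpha * (z - x)
            passive <- passive & (x > tol)
            x[!passive] <- 0
        }
    }
    x
}

## Design matrix of state intensities on the experimental grid.
.stateDesign <- function(experimental, state_curves) {
    q <- qValues(experimental)
    A <- vapply(state_curves, .interpolateIntensity, numeric(length(q)),
                q_target = q)
    matrix(A, nrow = length(q), ncol = length(state_curves),
           dimnames = list(NULL, names(state_curves)))
}

## TRUE when two columns are identical up to a scale factor (weights then
## not identifiable).
.isIllConditioned <- function(A) {
    K <- ncol(A)
    for (i in seq_len(K - 1)) for (j in (i + 1):K) {
        ai <- A[, i]; aj <- A[, j]
        alpha <- sum(ai * aj) / sum(ai * ai)
        if (sqrt(mean((alpha * ai - aj)^2)) <
            1e-8 * sqrt(mean(aj^2)) + 1e-300) return(TRUE)
    }
    FALSE
}

#' Fit conformational-state populations to an experimental SAXS curve
#'
#' Minimises sum_k ((s sum_s w_s I_s(q_k) + b - I_exp(q_k)) / sigma_k)^2
#' subject to w_s >= 0 and sum_s w_s = 1, with a free global scale s > 0
#' and an optional constant background b. With c_s = s w_s (and
#' b = b+ - b-, both non-negative) the problem is an ordinary non-negative
#' least-squares system, solved exactly and deterministically; s and the
#' simplex weights are recovered as s = sum c and w = c / s. The weight of
#' the folded-state curve is the degree of folding. Unweighted least
#' squares is used when the experimental curve carries no sigma column.
#'
#' @param experimental the measured [ScatteringCurve-class].
#' @param state_curves named list of predicted per-state
#'   [ScatteringCurve-class] objects (>= 2; conventionally `fc` and `uf`).
#' @param q_max optional upper q cutoff, Angstrom^-1 (see
#'   [truncateQRange()]); NULL fits the full range.
#' @param fit_background fit an additive constant (default FALSE).
#' @return a [PopulationFitResult-class]. When the state curves are
#'   numerically indistinguishable a warning is emitted and the weight
#'   uncertainties span `[0, 1]`.
#' @export
fitPopulations <- function(experimental, state_curves, q_max = NULL,
                           fit_background = FALSE) {
    if (length(state_curves) < 2L)
        stop("validation error: need at least 2 state curves")
    if (is.null(names(state_curves)) || any(!nzchar(names(state_curves))))
        stop("state_curves must be a named list")
    if (!is.null(q_max)) experimental <- truncateQRange(experimental, q_max)
    q <- qValues(experimental)
    y <- intensities(experimental)
    sig <- if (hasSigma(experimental)) sigmas(experimental)
           else rep(1, length(q))
    A <- .stateDesign(experimental, state_curves)
    K <- ncol(A)

    ill <- .isIllConditioned(A)
    if (ill)
        warning("state curves are indistinguishable up to scale; ",
                "weights are not identifiable")

    Aw <- A / sig
    if (fit_background) Aw <- cbind(Aw, 1 / sig, -1 / sig)
    yw <- y / sig
    cvec <- .nnls(Aw, yw)
    s <- sum(cvec[seq_len(K)])
    if (s <= 0)
        stop("fit failed: all state weights vanish (experimental curve ",
             "anti-correlated with every state curve)")
    w <- cvec[seq_len(K)] / s
    names(w) <- colnames(A)
    b <- if (fit_background) cvec[K + 1] - cvec[K + 2] else 0
    resid <- yw - Aw %*% cvec
    unc <- if (ill)
        matrix(rep(c(0, 1), K), nrow = 2, byrow = FALSE,
               dimnames = list(c("lower", "upper"), names(w)))
    else matrix(numeric(0), 0, 0)
    new("PopulationFitResult", weights = w, scale = s, background = b,
        chi2Reduced = mean(resid^2), qRangeUsed = range(q),
        weightUncertainties = unc, illConditioned = ill)
}

#' Bootstrap confidence intervals for fitted state populations
#'
#' Residual-resampling bootstrap: the fitted curve is perturbed by
#' resampled residuals and refitted `n_boot` times; per-state 2.5/97.5
#' percentiles of the weights are reported. Fully seeded.
#'
#' @param result a prior [fitPopulations()] result.
#' @param experimental,state_curves,q_max,fit_background the inputs of that
#'   fit (same values).
#' @param n_boot bootstrap replicates (>= 10, default 200).
#' @param seed integer seed.
#' @return 2 x K numeric matrix (rows `lower`, `upper`, columns the
#'   states), with the bootstrap weight samples as attribute `"samples"`.
#' @export
foldFractionUncertainty <- function(result, experimental, state_curves,
                                    q_max = NULL, fit_background = FALSE,
                                    n_boot = 200L, seed = NULL) {
    if (n_boot < 10L)
        stop("validation error: n_boot must be at least 10")
    if (!is.null(q_max)) experimental <- truncateQRange(experimental, q_max)
    q <- qValues(experimental)
    y <- intensities(experimental)
    sg <- sigmas(experimental)
    A <- .stateDesign(experimental, state_curves)
    yhat <- result@scale * as.numeric(A %*% result@weights) +
        result@background
    resid <- y - yhat
    samples <- .withSeed(seed, {
        t(vapply(seq_len(n_boot), function(b) {
            ystar <- yhat + sample(resid, replace = TRUE)
            cur <- scatteringCurve(q, ystar, sg)
            fit <- suppressWarnings(fitPopulations(
                cur, state_curves, q_max = NULL,
                fit_background = fit_background))
            fit@weights[names(result@weights)]
        }, numeric(length(result@weights))))
    })
    colnames(samples) <- names(result@weights)
    out <- apply(samples, 2, stats::quantile, probs = c(0.025, 0.975),
                 names = FALSE)
    rownames(out) <- c("lower", "upper")
    attr(out, "samples") <- samples
    out
}
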