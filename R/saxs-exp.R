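## Analysis of measured (or pseudo-experimental) curves: Guinier fit,
## Kratky transform, goodness of fit.

#' Guinier fit of the low-q region
#'
#' Fits ln I = ln I0 - (Rg^2 / 3) q^2 by (weighted) least squares over the
#' largest low-q window satisfying q.Rg <= `qrg_limit` at convergence. The
#' window is found iteratively: starting from the first few points, Rg is
#' estimated, the window regrown to all points with q.Rg within the limit,
#' and the fit repeated until the window is stable. Weights are
#' (I / sigma)^2 (the variance of ln I) when uncertainties are present.
#'
#' @param curve a [ScatteringCurve-class] (q in Angstrom^-1).
#' @param qrg_limit Guinier validity cutoff on q.Rg (default 1.3, the
#'   standard choice for globular particles).
#' @param q_min_points minimum number of points in the window (default 3).
#' @return a [GuinierResult-class]; Rg is reported in Angstrom.
#' @export
guinierFit <- function(curve, qrg_limit = 1.3, q_min_points = 3L) {
    q <- qValues(curve); I <- intensities(curve)
    pos <- I > 0
    if (sum(pos[seq_len(min(length(q), q_min_points))]) < q_min_points ||
        sum(pos) < q_min_points)
        stop("validation error: need at least ", q_min_points,
             " low-q points with positive intensity")
    q <- q[pos]; I <- I[pos]
    w <- if (hasSigma(curve)) (I / sigmas(curve)[pos])^2 else rep(1, length(q))

    fitWindow <- function(n) {
        idx <- seq_len(n)
        fit <- stats::lm.wfit(cbind(1, q[idx]^2), log(I[idx]), w[idx])
        slope <- unname(fit$coefficients[2])
        list(slope = slope, i0 = unname(exp(fit$coefficients[1])),
             rg = if (is.finite(slope) && slope < 0) sqrt(-3 * slope) else NA,
             fit = fit, n = n)
    }

    n <- max(q_min_points, min(length(q), 10L))
    last_n <- -1L
    res <- NULL
    for (iter in 1:50) {
        res <- fitWindow(n)
        if (is.na(res$rg))
            stop("no Guinier region: ln I vs q^2 has no negative slope at low q")
        n_new <- max(q_min_points, sum(q * res$rg <= qrg_limit))
        n_new <- min(n_new, length(q))
        if (n_new == n || n_new == last_n) break
        last_n <- n
        n <- n_new
    }
    idx <- seq_len(res$n)
    y <- log(I[idx])
    ss_res <- sum(w[idx] * res$fit$residuals^2)
    ss_tot <- sum(w[idx] * (y - stats::weighted.mean(y, w[idx]))^2)
    new("GuinierResult", rg = res$rg, i0 = res$i0,
        qRangeUsed = c(q[1], q[res$n]), fitPoints = as.integer(res$n),
        rSquared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
        qrgLimit = qrg_limit)
}

#' Kratky transform q^2 I(q)
#'
#' Diagnoses compact (bell-shaped) versus extended/disordered (rising)
#' conformations; uncertainties propagate as q^2 sigma.
#'
#' @param curve a [ScatteringCurve-class].
#' @return a [ScatteringCurve-class] with intensity replaced by q^2 I(q).
#' @export
kratkyTransform <- function(curve) {
    q <- qValues(curve)
    s <- sigmas(curve)
    ## a q = 0 point transforms to exactly 0 with zero uncertainty; drop the
    ## sigma at q = 0 would violate sigma > 0, so sigma is kept only if all
    ## transformed values stay positive
    new_sigma <- if (!is.null(s) && all(q > 0)) q^2 * s else NULL
    scatteringCurve(q, q^2 * intensities(curve), new_sigma)
}

#' Interpolate a predicted curve onto an experimental q grid
#'
#' Linear interpolation in q; an error is raised when the experimental grid
#' extends beyond the predicted one.
#'
#' @param curve the predicted [ScatteringCurve-class].
#' @param q_target numeric target grid, Angstrom^-1.
#' @return numeric intensities on `q_target`.
#' @keywords internal
.interpolateIntensity <- function(curve, q_target) {
    q <- qValues(curve)
    if (min(q_target) < min(q) - 1e-12 || max(q_target) > max(q) + 1e-12)
        stop("interpolation error: experimental q range [",
             format(min(q_target)), ", ", format(max(q_target)),
             "] not covered by predicted range [", format(min(q)), ", ",
             format(max(q)), "]")
    stats::approx(q, intensities(curve), xout = q_target, rule = 1)$y
}

#' Reduced chi-square between a predicted and an experimental curve
#'
#' chi^2 / N = (1/N) sum_k ((s I_pred(q_k) + b - I_exp(q_k)) / sigma_k)^2
#' with the predicted curve linearly interpolated onto the experimental
#' grid; sigma_k = 1 when the experimental curve carries no uncertainties.
#'
#' @param predicted,experimental [ScatteringCurve-class] objects.
#' @param scale multiplicative factor s applied to the prediction.
#' @param background additive constant b.
#' @return chi^2 / N, dimensionless.
#' @export
chiSquare <- function(predicted, experimental, scale = 1, background = 0) {
    q <- qValues(experimental)
    Ip <- .interpolateIntensity(predicted, q)
    Ie <- intensities(experimental)
    s <- if (hasSigma(experimental)) sigmas(experimental) else rep(1, length(q))
    mean(((scale * Ip + background - Ie) / s)^2)
}
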