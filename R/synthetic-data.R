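## Seeded two-state toy trajectories and pseudo-experimental SAXS curves
## with known ground truth, so every pipeline stage is testable end-to-end
## without external data. Bead chains, not chemically realistic glycans:
## the protocol under test is geometry- and element-generic.

#' Specification of a synthetic two-state bead-polymer system
#'
#' The folded template is a two-leg antiparallel hairpin (strand spacing
#' 0.45 nm); the unfolded template a straight chain. The per-frame state
#' follows a two-state Markov chain with the requested stationary occupancy
#' and mean dwell time, so interval averaging over ~1 ns is meaningful.
#'
#' @param n_atoms beads in the chain (alternating C/O, default 18).
#' @param bond_length bead spacing, nm (default 0.5, the glycosidic
#'   virtual-bond scale).
#' @param occupancy_folded stationary folded fraction in `[0, 1]`
#'   (default 0.75).
#' @param mean_dwell mean state dwell time, ns (default 2).
#' @param jitter_sd per-coordinate Gaussian jitter, nm (default 0.03).
#' @param seed integer seed making the trajectory fully reproducible.
#' @return list of class `"TwoStateSpec"`.
#' @export
twoStateSpec <- function(n_atoms = 18L, bond_length = 0.5,
                         occupancy_folded = 0.75, mean_dwell = 2,
                         jitter_sd = 0.03, seed = 1L) {
    stopifnot(n_atoms >= 4L, bond_length > 0,
              occupancy_folded >= 0, occupancy_folded <= 1,
              mean_dwell > 0, jitter_sd >= 0)
    structure(list(n_atoms = as.integer(n_atoms),
                   bond_length = bond_length,
                   occupancy_folded = occupancy_folded,
                   mean_dwell = mean_dwell, jitter_sd = jitter_sd,
                   seed = as.integer(seed)),
              class = "TwoStateSpec")
}

#' Template coordinates of the two conformers
#'
#' @param spec a [twoStateSpec()] list.
#' @return list with `folded` and `unfolded` N x 3 matrices (nm).
#' @keywords internal
.twoStateTemplates <- function(spec) {
    n <- spec$n_atoms; b <- spec$bond_length
    extended <- cbind((seq_len(n) - 1) * b, 0, 0)
    n1 <- ceiling(n / 2); n2 <- n - n1
    leg1 <- cbind((seq_len(n1) - 1) * b, 0, 0)
    leg2 <- cbind((n1 - 1) * b - (seq_len(n2) - 1) * b, 0.45, 0)
    list(folded = rbind(leg1, leg2), unfolded = extended)
}

.twoStateModel <- function(spec) {
    elements <- rep(c("C", "O"), length.out = spec$n_atoms)
    molecularModel(elements, .twoStateTemplates(spec)$folded,
                   names = paste0(elements, seq_len(spec$n_atoms)),
                   residue_id = seq_len(spec$n_atoms),
                   residue_name = rep("BED", spec$n_atoms))
}

#' Generate a seeded two-state trajectory with known labels
#'
#' State switching is a two-state Markov chain: with stationary occupancy p
#' and overall mean dwell tau, the per-state dwell times are
#' tau_f = 2 p tau and tau_u = 2 (1 - p) tau, giving per-frame exit
#' probabilities dt / tau_state. Occupancy 0 or 1 degenerates to a
#' single-state trajectory (allowed, with a warning). Coordinates are the
#' state template plus Gaussian jitter; identical seeds give bit-identical
#' output.
#'
#' @param spec a [twoStateSpec()].
#' @param n_frames number of frames.
#' @param frame_time_step ns between frames.
#' @return list with `trajectory` ([TrajectoryFrames-class]) and `labels`
#'   (character per frame, `"fc"`/`"uf"`).
#' @export
generateTwoStateTrajectory <- function(spec, n_frames, frame_time_step) {
    stopifnot(inherits(spec, "TwoStateSpec"), n_frames >= 1L,
              frame_time_step > 0)
    p <- spec$occupancy_folded
    if (p %in% c(0, 1))
        warning("occupancy_folded = ", p,
                ": degenerate single-state trajectory")
    tmpl <- .twoStateTemplates(spec)
    model <- .twoStateModel(spec)
    tau_f <- 2 * p * spec$mean_dwell
    tau_u <- 2 * (1 - p) * spec$mean_dwell
    # occupancy 0 or 1: the absorbing state is never left
    exit_f <- if (p == 1) 0 else if (tau_f > 0)
        min(1, frame_time_step / tau_f) else 1
    exit_u <- if (p == 0) 0 else if (tau_u > 0)
        min(1, frame_time_step / tau_u) else 1
    out <- .withSeed(spec$seed, {
        state <- character(n_frames)
        state[1] <- if (stats::runif(1) < p) "fc" else "uf"
        if (n_frames > 1) {
            u <- stats::runif(n_frames - 1)
            for (k in 2:n_frames) {
                prev <- state[k - 1]
                flip <- if (prev == "fc") u[k - 1] < exit_f
                        else u[k - 1] < exit_u
                state[k] <- if (flip) setdiff(c("fc", "uf"), prev) else prev
            }
        }
        frames <- lapply(seq_len(n_frames), function(k) {
            base <- if (state[k] == "fc") tmpl$folded else tmpl$unfolded
            base + matrix(stats::rnorm(length(base), 0, spec$jitter_sd),
                          nrow = nrow(base))
        })
        list(frames = frames, labels = state)
    })
    list(trajectory = trajectoryFrames(model, out$frames, frame_time_step),
         labels = out$labels)
}

#' Build a pseudo-experimental SAXS curve with known mixing weights
#'
#' I_exp(q) = scale * sum_s w_s I_s(q) + background + eps(q) with
#' eps ~ Normal(0, noise_fraction * I_true) point-wise; the sigma column is
#' set to noise_fraction * I_true. With `noise_fraction = 0` the curve is
#' exact and carries no sigma column.
#'
#' @param state_curves named list of [ScatteringCurve-class] on a common q
#'   grid.
#' @param weights named weights on the simplex, names matching
#'   `state_curves`.
#' @param scale,background global scale and additive constant.
#' @param noise_fraction relative Gaussian noise level (e.g. 0.02).
#' @param seed integer seed.
#' @return a [ScatteringCurve-class].
#' @export
generatePseudoExperiment <- function(state_curves, weights, scale = 1,
                                     background = 0, noise_fraction = 0,
                                     seed = NULL) {
    if (is.null(names(weights)) ||
        !setequal(names(weights), names(state_curves)))
        stop("weight names must match state curve names")
    if (abs(sum(weights) - 1) > 1e-9 || any(weights < 0))
        stop("weights must be non-negative and sum to 1")
    stopifnot(noise_fraction >= 0, scale > 0)
    q <- qValues(state_curves[[1]])
    for (s in names(state_curves))
        if (!isTRUE(all.equal(qValues(state_curves[[s]]), q)))
            stop("state curves must share one q grid")
    mix <- Reduce(`+`, lapply(names(weights), function(s)
        weights[[s]] * intensities(state_curves[[s]])))
    I_true <- scale * mix + background
    if (noise_fraction == 0) return(scatteringCurve(q, I_true))
    sg <- noise_fraction * abs(I_true)
    I_obs <- .withSeed(seed, I_true + stats::rnorm(length(q), 0, sg))
    scatteringCurve(q, I_obs, sg)
}

#' Rigid reference shapes with closed-form radius of gyration
#'
#' Analytic oracles for Rg and Debye tests: a discrete rod of n beads at
#' spacing l has Rg = l sqrt((n^2 - 1) / 12); two points at distance d have
#' Rg = d / 2; an n-bead ring of radius R has Rg = R exactly.
#'
#' @param kind `"rod"`, `"two_points"` or `"ring"`.
#' @param params list: rod needs `n`, `spacing` (nm); two_points needs `d`
#'   (nm); ring needs `n`, `radius` (nm). Optional `element` (default "C").
#' @return a [MolecularModel-class].
#' @export
rigidReferenceShapes <- function(kind = c("rod", "two_points", "ring"),
                                 params = list()) {
    kind <- match.arg(kind)
    el <- if (is.null(params$element)) "C" else params$element
    xyz <- switch(kind,
        rod = {
            stopifnot(!is.null(params$n), !is.null(params$spacing),
                      params$n >= 2, params$spacing > 0)
            cbind((seq_len(params$n) - 1) * params$spacing, 0, 0)
        },
        two_points = {
            stopifnot(!is.null(params$d), params$d > 0)
            rbind(c(0, 0, 0), c(params$d, 0, 0))
        },
        ring = {
            stopifnot(!is.null(params$n), !is.null(params$radius),
                      params$n >= 3, params$radius > 0)
            th <- 2 * pi * (seq_len(params$n) - 1) / params$n
            cbind(params$radius * cos(th), params$radius * sin(th), 0)
        })
    molecularModel(rep(el, nrow(xyz)), xyz)
}

#' Write a synthetic system as regression fixtures
#'
#' Emits a multi-model PDB of the trajectory, an ASCII truth-label table and
#' a JSON echo of the generating spec.
#'
#' @param spec a [twoStateSpec()].
#' @param n_frames,frame_time_step as in [generateTwoStateTrajectory()].
#' @param dir output directory (created if needed).
#' @return invisibly, the list of written paths.
#' @export
writeSyntheticFixture <- function(spec, n_frames, frame_time_step, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gen <- generateTwoStateTrajectory(spec, n_frames, frame_time_step)
    paths <- list(
        trajectory = file.path(dir, "trajectory.pdb"),
        labels = file.path(dir, "labels.tsv"),
        spec = file.path(dir, "spec.json"))
    writeMultiModelPdb(gen$trajectory, paths$trajectory)
    utils::write.table(
        data.frame(frame = seq_along(gen$labels), label = gen$labels),
        paths$labels, quote = FALSE, row.names = FALSE, sep = "\t")
    jsonlite::write_json(unclass(spec), paths$spec, auto_unbox = TRUE,
                         digits = NA)
    invisible(paths)
}
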