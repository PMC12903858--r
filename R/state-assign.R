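## Interval-based classification of trajectory frames into Rg-defined
## conformational states (folded fc = compact/low Rg, unfolded uf).

#' Partition a trajectory's Rg series into fixed-length time intervals
#'
#' Averaging Rg over intervals (1 ns by default) suppresses short-time-scale
#' fluctuations so each interval represents a conformational state as a
#' dynamic ensemble rather than a single snapshot. Intervals are
#' consecutive, non-overlapping and frame-exhaustive; a trailing partial
#' interval is kept as its own interval (its mean uses only its own frames).
#'
#' @param rg numeric per-frame Rg values, nm (e.g. from [rgSeries()]).
#' @param frame_time_step time between frames, ns.
#' @param interval_length interval length, ns (default 1); must be at least
#'   one frame.
#' @return data.frame with columns `start_frame`, `end_frame` (1-based,
#'   half-open `[start, end)`) and `mean_rg` (nm).
#' @export
partitionIntervals <- function(rg, frame_time_step, interval_length = 1) {
    stopifnot(length(rg) >= 1L, frame_time_step > 0)
    per <- floor(interval_length / frame_time_step)
    if (per < 1)
        stop("validation error: interval_length (", interval_length,
             " ns) is shorter than one frame (", frame_time_step, " ns)")
    n <- length(rg)
    starts <- seq(1L, n, by = per)
    ends <- pmin(starts + per, n + 1L)
    data.frame(start_frame = starts, end_frame = ends,
               mean_rg = vapply(seq_along(starts), function(k)
                   mean(rg[starts[k]:(ends[k] - 1L)]), numeric(1)))
}

#' Label Rg intervals as folded or unfolded
#'
#' Intervals with mean Rg at or below the threshold are the folded
#' conformers (`fc`, compact); above it the unfolded conformers (`uf`). The
#' tie at the threshold goes to `fc`.
#'
#' @param intervals interval table from [partitionIntervals()].
#' @param threshold Rg cutoff, nm (> 0). The authoritative path is a
#'   user-chosen, molecule-specific cutoff; see [autoThreshold()] for a
#'   data-driven suggestion.
#' @param interval_length nominal interval length, ns (recorded for export).
#' @return a [StateAssignment-class]
#' @export
assignStates <- function(intervals, threshold, interval_length = 1) {
    if (nrow(intervals) == 0L)
        stop("validation error: empty interval list")
    stopifnot(threshold > 0)
    labels <- ifelse(intervals$mean_rg <= threshold, "fc", "uf")
    new("StateAssignment", intervals = intervals, labels = labels,
        threshold = as.numeric(threshold),
        intervalLength = as.numeric(interval_length))
}

#' Data-driven Rg threshold between two conformational states
#'
#' Two-cluster 1D k-means on the interval means, deterministically
#' initialised at the minimum and maximum; the threshold is the midpoint of
#' the converged centroids. The bimodality diagnostic is the ratio of
#' between-cluster to mean within-cluster variance — values well above 4
#' indicate a clean two-population Rg plot.
#'
#' @param interval_means numeric interval mean Rg values, nm (>= 4 values).
#' @return list with `threshold` (nm), `centroids` (nm, sorted),
#'   `bimodality` (dimensionless).
#' @export
autoThreshold <- function(interval_means) {
    m <- as.numeric(interval_means)
    if (length(m) < 4L)
        stop("validation error: need at least 4 interval means")
    if (diff(range(m)) == 0)
        stop("degenerate input: all interval means equal (",
             m[1], " nm); supply a manual threshold")
    km <- stats::kmeans(m, centers = matrix(c(min(m), max(m)), ncol = 1))
    ctr <- sort(as.numeric(km$centers))
    within_var <- km$tot.withinss / max(1L, length(m) - 2L)
    between_var <- km$betweenss / 1
    list(threshold = mean(ctr), centroids = ctr,
         bimodality = if (within_var > 0) between_var / within_var else Inf)
}

#' Concatenate all frames of one conformational state
#'
#' Collects the frames of every interval carrying the requested label, in
#' original temporal order, into a new trajectory — the per-state ensemble
#' whose SAXS profile represents that state.
#'
#' @param traj the [TrajectoryFrames-class] the assignment was derived from.
#' @param assignment a [StateAssignment-class].
#' @param state `"fc"` or `"uf"`.
#' @return a [TrajectoryFrames-class] holding only that state's frames.
#' @export
concatenateStateFrames <- function(traj, assignment, state = c("fc", "uf")) {
    state <- match.arg(state)
    iv <- assignment@intervals
    if (max(iv$end_frame) - 1L > nFrames(traj))
        stop("assignment refers to more frames than the trajectory has")
    sel <- which(assignment@labels == state)
    if (length(sel) == 0L)
        stop("empty ensemble: no interval labelled '", state, "'")
    idx <- unlist(lapply(sel, function(k)
        iv$start_frame[k]:(iv$end_frame[k] - 1L)))
    trajectoryFrames(traj@model, traj@frames[idx], traj@frameTimeStep)
}

#' Folded population predicted by the MD trajectory
#'
#' Fraction of frames (not intervals) inside fc-labelled intervals, so a
#' trailing partial interval is weighted by its true length.
#'
#' @param assignment a [StateAssignment-class].
#' @return fraction in `[0, 1]`.
#' @export
mdFoldedFraction <- function(assignment) {
    iv <- assignment@intervals
    len <- iv$end_frame - iv$start_frame
    sum(len[assignment@labels == "fc"]) / sum(len)
}

#' Export a state assignment as an ASCII table
#'
#' Columns: interval index, start time (ns), end time (ns), mean Rg (nm),
#' label.
#'
#' @param assignment a [StateAssignment-class].
#' @param frame_time_step ns per frame, to convert frame indices to times.
#' @param path destination; when NULL the data.frame is returned instead.
#' @return the table, invisibly when written.
#' @export
exportAssignment <- function(assignment, frame_time_step, path = NULL) {
    iv <- assignment@intervals
    df <- data.frame(
        interval = seq_len(nrow(iv)),
        start_ns = (iv$start_frame - 1L) * frame_time_step,
        end_ns = (iv$end_frame - 1L) * frame_time_step,
        mean_rg_nm = signif(iv$mean_rg, 6),
        label = assignment@labels)
    if (is.null(path)) return(df)
    utils::write.table(df, path, quote = FALSE, row.names = FALSE, sep = "\t")
    invisible(df)
}
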