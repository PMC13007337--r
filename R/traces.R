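#' Cells-by-frames trace matrix
#'
#' Traces move through the pipeline as a numeric `cells x frames` matrix
#' (rownames = cell ids) with a `kind` that may only advance
#' `raw -> dff -> dff_filtered`, the frame rate, the trial it came from
#' (an index, or `"mean"` after trial averaging) and optionally the stimulus
#' label.
#'
#' @param mat Numeric matrix, cells in rows, frames in columns.
#' @param kind One of `"raw"`, `"dff"`, `"dff_filtered"`.
#' @param frame_rate_hz Sampling rate of the columns.
#' @param trial Trial index or `"mean"`.
#' @param stimulus Optional stimulus label.
#' @return A matrix of class `trace_matrix`.
#' @export
trace_matrix <- function(mat, kind = c("raw", "dff", "dff_filtered"),
                         frame_rate_hz, trial = "mean", stimulus = NULL) {
  kind <- match.arg(kind)
  if (!is.matrix(mat) || !is.numeric(mat))
    stop("traces must be a numeric cells x frames matrix", call. = FALSE)
  structure(mat, class = c("trace_matrix", class(mat)),
            kind = kind, frame_rate_hz = frame_rate_hz,
            trial = trial, stimulus = stimulus)
}

trace_kind <- function(x) attr(x, "kind")

#' @export
print.trace_matrix <- function(x, ...) {
  cat("Trace matrix [", trace_kind(x), "]: ", nrow(x), " cells x ",
      ncol(x), " frames @ ", attr(x, "frame_rate_hz"), " Hz (trial ",
      attr(x, "trial"), ")\n", sep = "")
  invisible(x)
}

# pixels (0-based x = col, y = row) within `radius` of an ROI center,
# clipped to the frame; pixel centers sit on the integer grid
.roi_mask <- function(cx, cy, radius, width, height) {
  xr <- max(0L, floor(cx - radius)):min(width - 1L, ceiling(cx + radius))
  yr <- max(0L, floor(cy - radius)):min(height - 1L, ceiling(cy + radius))
  if (cx + radius < 0 || cx - radius > width - 1 ||
      cy + radius < 0 || cy - radius > height - 1)
    return(cbind(x = integer(0), y = integer(0)))
  g <- expand.grid(x = xr, y = yr)
  keep <- (g$x - cx)^2 + (g$y - cy)^2 <= radius^2
  cbind(x = g$x[keep], y = g$y[keep])
}

#' Extract per-cell fluorescence traces from a movie
#'
#' For every ROI the trace at frame `t` is the mean intensity over all
#' pixels whose center lies within `radius` of the (drift-offset) ROI
#' center. Pixels falling outside the frame are dropped; an ROI with no
#' in-frame pixels is an error.
#'
#' @param movie A [movie_stack()].
#' @param rois An [roi_set()]; per-trial offsets are applied when `trial`
#'   is given.
#' @param trial Trial index used to look up drift offsets (optional).
#' @param stimulus Optional stimulus label carried on the result.
#' @return A [trace_matrix()] of kind `"raw"`.
#' @export
extract_traces <- function(movie, rois, trial = NULL, stimulus = NULL) {
  stopifnot(inherits(movie, "movie_stack"), inherits(rois, "roi_set"))
  d <- dim(movie$data)
  T_ <- d[1]; H <- d[2]; W <- d[3]
  r <- .roi_centers(rois, trial)
  out <- matrix(NA_real_, nrow(r), T_,
                dimnames = list(r$cell_id, NULL))
  frame_idx <- seq_len(T_)
  for (i in seq_len(nrow(r))) {
    px <- .roi_mask(r$x[i], r$y[i], r$radius[i], W, H)
    if (nrow(px) == 0L)
      stop("ROI '", r$cell_id[i], "' lies fully outside the frame",
           call. = FALSE)
    lin <- outer(frame_idx, T_ * (px[, "y"] + H * px[, "x"]), "+")
    out[i, ] <- rowMeans(matrix(movie$data[lin], nrow = T_))
  }
  trace_matrix(out, "raw", frame_rate_hz = movie$frame_rate_hz,
               trial = if (is.null(trial)) 1L else trial,
               stimulus = stimulus)
}

#' Average traces across trials
#'
#' Elementwise mean of the retained trials; trials flagged in `discard`
#' (e.g. gross movement artifacts identified by the experimenter) are
#' excluded. All trials must share shape and kind.
#'
#' @param traces List of [trace_matrix()] objects, one per trial.
#' @param discard Integer indices into `traces` to drop.
#' @return A [trace_matrix()] with `trial = "mean"`.
#' @export
average_trials <- function(traces, discard = integer(0)) {
  stopifnot(is.list(traces), length(traces) >= 1L)
  keep <- setdiff(seq_along(traces), discard)
  if (length(keep) == 0L)
    stop("all trials discarded; at least one must remain", call. = FALSE)
  kept <- traces[keep]
  ref <- kept[[1]]
  for (tr in kept)
    if (!identical(dim(tr), dim(ref)) ||
        !identical(trace_kind(tr), trace_kind(ref)))
      stop("trials must share dimensions and kind", call. = FALSE)
  m <- Reduce(`+`, lapply(kept, unclass)) / length(kept)
  trace_matrix(m, trace_kind(ref),
               frame_rate_hz = attr(ref, "frame_rate_hz"),
               trial = "mean", stimulus = attr(ref, "stimulus"))
}

#' Convert raw traces to dF/F
#'
#' Each cell's trace is divided by its F0, the mean of the `n_f0` frames
#' immediately before stimulus onset, and shifted by -1 so the baseline
#' sits at 0: `dff = F / F0 - 1`. Every downstream quantity (response
#' magnitude, peak z-score) is a difference or a standard deviation and is
#' therefore invariant to the -1 shift relative to the plain ratio `F / F0`.
#'
#' @param traces A raw [trace_matrix()].
#' @param protocol The [stim_protocol()] defining stimulus onset.
#' @param n_f0 Number of pre-onset frames in the F0 window (default 10).
#' @return A [trace_matrix()] of kind `"dff"`.
#' @export
compute_dff <- function(traces, protocol, n_f0 = 10L) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (trace_kind(traces) != "raw")
    stop("compute_dff() expects raw traces (got '", trace_kind(traces), "')",
         call. = FALSE)
  win <- f0_window(protocol, n_f0)
  if (win[2] > ncol(traces))
    stop("trace shorter than the F0 window", call. = FALSE)
  f0 <- rowMeans(traces[, .win_idx(win), drop = FALSE])
  bad <- !(is.finite(f0) & f0 > 0)
  if (any(bad))
    stop("nonpositive F0 for cell(s): ",
         paste(rownames(traces)[bad], collapse = ", "), call. = FALSE)
  trace_matrix(unclass(traces) / f0 - 1, "dff",
               frame_rate_hz = attr(traces, "frame_rate_hz"),
               trial = attr(traces, "trial"),
               stimulus = attr(traces, "stimulus"))
}

# zero-phase IIR filtering: odd-reflection padding long enough for the
# filter transient to decay below ~1e-12, then forward and reverse passes
.zero_phase <- function(b, a, x) {
  n <- length(x)
  pmax_ <- max(Mod(polyroot(rev(a))))
  np <- if (pmax_ >= 1 || pmax_ <= 0) n - 1L else
    max(30L, ceiling(log(1e-12) / log(pmax_)))
  np <- min(n - 1L, as.integer(np))
  xe <- c(2 * x[1] - x[(np + 1):2], x, 2 * x[n] - x[(n - 1):(n - np)])
  y <- signal::filter(b, a, xe)
  y <- rev(as.numeric(signal::filter(b, a, rev(as.numeric(y)))))
  y[(np + 1):(np + n)]
}

#' Low-pass filter dF/F traces
#'
#' Zero-phase application (forward and reverse pass, so transient peaks are
#' not delayed) of a Butterworth low-pass design; DC gain is exactly 1.
#' Default 5 Hz cutoff, 4th order.
#'
#' @param traces A [trace_matrix()] of kind `"dff"`.
#' @param cutoff_hz Cutoff frequency; must be below the Nyquist frequency.
#' @param order Butterworth order of the one-way design.
#' @return A [trace_matrix()] of kind `"dff_filtered"`.
#' @export
lowpass <- function(traces, cutoff_hz = 5, order = 4L) {
  stopifnot(inherits(traces, "trace_matrix"))
  if (trace_kind(traces) != "dff")
    stop("lowpass() expects dff traces (got '", trace_kind(traces), "')",
         call. = FALSE)
  fs <- attr(traces, "frame_rate_hz")
  nyq <- fs / 2
  if (cutoff_hz >= nyq)
    stop("cutoff (", cutoff_hz, " Hz) must be below Nyquist (", nyq, " Hz)",
         call. = FALSE)
  bf <- signal::butter(order, cutoff_hz / nyq)
  out <- t(apply(unclass(traces), 1, function(x) .zero_phase(bf$b, bf$a, x)))
  dimnames(out) <- dimnames(traces)
  trace_matrix(out, "dff_filtered", frame_rate_hz = fs,
               trial = attr(traces, "trial"),
               stimulus = attr(traces, "stimulus"))
}

#' Run the full trace pipeline for one stimulus
#'
#' Convenience wrapper: extract each trial, discard flagged trials, average,
#' convert to dF/F and low-pass filter.
#'
#' @param movies List of [movie_stack()] objects, one per trial.
#' @param rois An [roi_set()].
#' @param protocol A [stim_protocol()].
#' @param stimulus Stimulus label for the result.
#' @param discard Trial indices to drop before averaging.
#' @param cutoff_hz,n_f0 Passed to [lowpass()] and [compute_dff()].
#' @param filter If `FALSE`, stop after [compute_dff()].
#' @return A [trace_matrix()] of kind `"dff_filtered"` (or `"dff"`).
#' @export
process_trials <- function(movies, rois, protocol, stimulus = NULL,
                           discard = integer(0), cutoff_hz = 5, n_f0 = 10L,
                           filter = TRUE) {
  per_trial <- lapply(seq_along(movies), function(k)
    extract_traces(movies[[k]], rois, trial = k, stimulus = stimulus))
  avg <- average_trials(per_trial, discard = discard)
  dff <- compute_dff(avg, protocol, n_f0 = n_f0)
  if (filter) lowpass(dff, cutoff_hz = cutoff_hz) else dff
}
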