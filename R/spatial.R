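#' Frame-subtraction activity map
#'
#' Spatial map of odor-evoked activity on a trial-averaged movie: the mean
#' of 10 frames during the odor stimulation period minus the mean of the 10
#' frames immediately preceding the odor. The stimulation window defaults
#' to frames `[onset + 25, onset + 35)` — 1 to 1.4 s into the stimulus at
#' 25 Hz, near the peak of a slow indicator transient; `stim_window_offset`
#' moves it within the stimulus period.
#'
#' @param movie A trial-averaged [movie_stack()].
#' @param protocol A [stim_protocol()].
#' @param stim_window_offset Frames between stimulus onset and the start of
#'   the stimulation window (default 25).
#' @param n_avg Frames averaged in each window (default 10).
#' @return `H x W` matrix of class `activity_map` (signed differences),
#'   with the two windows stored as attributes.
#' @export
frame_subtraction <- function(movie, protocol, stim_window_offset = 25L,
                              n_avg = 10L) {
  stopifnot(inherits(movie, "movie_stack"),
            inherits(protocol, "stim_protocol"))
  T_ <- dim(movie$data)[1]
  on <- onset_frame(protocol)
  stim_win <- c(on + stim_window_offset, on + stim_window_offset + n_avg)
  pre_win <- c(on - n_avg, on)
  if (pre_win[1] < 0 || stim_win[2] > T_)
    stop("frame-subtraction windows [", pre_win[1], ",", pre_win[2],
         ") and [", stim_win[1], ",", stim_win[2],
         ") must lie within the ", T_, "-frame trial", call. = FALSE)
  m_stim <- apply(movie$data[.win_idx(stim_win), , , drop = FALSE], c(2, 3), mean)
  m_pre <- apply(movie$data[.win_idx(pre_win), , , drop = FALSE], c(2, 3), mean)
  structure(m_stim - m_pre, class = c("activity_map", "matrix", "array"),
            stim_window = stim_win, pre_window = pre_win,
            scaling = "none")
}

#' Scale activity maps for display
#'
#' `shared_max` divides every map of a subject by the single largest
#' absolute value across all its maps, so intensity ranges are comparable
#' across odors within the subject; `per_stimulus_max` scales each map to
#' its own maximum. Sign and zeros are preserved; an all-zero map is
#' returned unchanged.
#'
#' @param maps List of [frame_subtraction()] maps from one subject.
#' @param mode `"shared_max"` or `"per_stimulus_max"`.
#' @return List of scaled `activity_map`s.
#' @export
scale_maps <- function(maps, mode = c("shared_max", "per_stimulus_max")) {
  mode <- match.arg(mode)
  stopifnot(is.list(maps), length(maps) >= 1)
  scale1 <- function(m, denom) {
    if (denom > 0) m[] <- m / denom
    attr(m, "scaling") <- mode
    m
  }
  if (mode == "shared_max") {
    denom <- max(vapply(maps, function(m) max(abs(m)), numeric(1)))
    lapply(maps, scale1, denom = denom)
  } else {
    lapply(maps, function(m) scale1(m, max(abs(m))))
  }
}

#' @export
print.activity_map <- function(x, ...) {
  sw <- attr(x, "stim_window"); pw <- attr(x, "pre_window")
  cat("Activity map ", nrow(x), "x", ncol(x), " px: frames [", sw[1], ",",
      sw[2], ") - [", pw[1], ",", pw[2], "), scaling ",
      attr(x, "scaling"), "\n", sep = "")
  invisible(x)
}

#' @export
plot.activity_map <- function(x, main = "Frame subtraction", ...) {
  lim <- max(abs(x), 1e-12)
  graphics::image(t(unclass(x))[, rev(seq_len(nrow(x)))], zlim = c(-lim, lim),
                  col = grDevices::hcl.colors(101, "Blue-Red 3"),
                  axes = FALSE, main = main, useRaster = TRUE, ...)
  graphics::box()
  invisible(x)
}

#' Centroid of positive activity
#'
#' Intensity-weighted centroid of the map pixels above `frac` of the map
#' maximum, in 0-based (x, y) pixel coordinates. Used to localize an
#' active soma on a frame-subtraction map.
#'
#' @param map An [frame_subtraction()] map.
#' @param frac Threshold as a fraction of the positive maximum.
#' @return Named numeric `c(x, y)`, or `c(NA, NA)` if no pixel exceeds the
#'   threshold.
#' @export
map_centroid <- function(map, frac = 0.5) {
  m <- unclass(map)
  mx <- max(m)
  if (mx <= 0) return(c(x = NA_real_, y = NA_real_))
  sel <- which(m >= frac * mx, arr.ind = TRUE)
  w <- m[sel]
  c(x = sum((sel[, 2] - 1) * w) / sum(w),
    y = sum((sel[, 1] - 1) * w) / sum(w))
}
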