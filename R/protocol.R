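#' Stimulus protocol
#'
#' Defines the timing grid and stimulus panel of an imaging experiment.
#' Every trial is `baseline_s` seconds of pre-stimulus recording, followed by
#' `stimulus_s` seconds of odor delivery and `post_s` seconds of post-stimulus
#' recording, sampled at `frame_rate_hz` frames per second. The defaults are
#' the acquisition used throughout the package: 25 Hz, 3 s baseline, 5 s
#' stimulus, 16 s post (600-frame trials, stimulus onset at frame 75), a
#' seven-odor panel and 3 trials per stimulus.
#'
#' Frame indices are 0-based and windows are half-open `[start, end)`; the
#' stimulus onset frame is `round(baseline_s * frame_rate_hz)`. All frame
#' arithmetic is exact integer arithmetic.
#'
#' @param frame_rate_hz Acquisition rate in frames per second.
#' @param baseline_s Pre-stimulus baseline duration, seconds.
#' @param stimulus_s Odor stimulation duration, seconds.
#' @param post_s Post-stimulus duration, seconds.
#' @param stimulus_labels Character vector of unique stimulus names, in
#'   presentation order (this order also breaks preference ties downstream).
#' @param n_trials_per_stimulus Number of repeated trials per stimulus.
#' @param trial_duration_s Optional total trial duration; if given it must
#'   equal `baseline_s + stimulus_s + post_s`.
#'
#' @return An object of class `stim_protocol`.
#' @examples
#' p <- stim_protocol()
#' onset_frame(p)   # 75
#' n_frames(p)      # 600
#' @export
stim_protocol <- function(frame_rate_hz = 25,
                          baseline_s = 3,
                          stimulus_s = 5,
                          post_s = 16,
                          stimulus_labels = c("water", "NaCl", "LCA",
                                              "adenosine", "cadaverine",
                                              "alanine", "NH4Cl"),
                          n_trials_per_stimulus = 3,
                          trial_duration_s = NULL) {
  for (nm in c("frame_rate_hz", "baseline_s", "stimulus_s", "post_s")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive number", call. = FALSE)
  }
  total <- baseline_s + stimulus_s + post_s
  if (!is.null(trial_duration_s) &&
      abs(trial_duration_s - total) > 1e-9)
    stop("trial_duration_s (", trial_duration_s,
         ") must equal baseline_s + stimulus_s + post_s (", total, ")",
         call. = FALSE)
  stimulus_labels <- as.character(stimulus_labels)
  if (length(stimulus_labels) < 1L)
    stop("at least one stimulus label is required", call. = FALSE)
  if (anyDuplicated(stimulus_labels))
    stop("stimulus_labels must be unique", call. = FALSE)
  if (!is.numeric(n_trials_per_stimulus) || n_trials_per_stimulus < 1 ||
      n_trials_per_stimulus != round(n_trials_per_stimulus))
    stop("n_trials_per_stimulus must be a positive integer", call. = FALSE)

  structure(
    list(frame_rate_hz = frame_rate_hz,
         trial_duration_s = total,
         baseline_s = baseline_s,
         stimulus_s = stimulus_s,
         post_s = post_s,
         stimulus_labels = stimulus_labels,
         n_trials_per_stimulus = as.integer(n_trials_per_stimulus)),
    class = "stim_protocol")
}

# round-to-nearest frame count; avoids banker's rounding of round()
.frame_round <- function(x) as.integer(floor(x + 0.5))

#' Protocol frame arithmetic
#'
#' Frame indices are 0-based; windows are half-open `[start, end)`.
#' `onset_frame()` is the first stimulus frame, `n_frames()` the trial length
#' in frames, `stimulus_window()` the full stimulation window and
#' `baseline_window()` the full pre-stimulus window `[0, onset)`.
#' `f0_window()` is the `n`-frame window immediately before onset used to
#' normalize fluorescence to dF/F.
#'
#' @param protocol A [stim_protocol()].
#' @param n Number of frames in the F0 window (default 10).
#' @return Integer frame index, count, or length-2 `c(start, end)` window.
#' @export
onset_frame <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  .frame_round(protocol$baseline_s * protocol$frame_rate_hz)
}

#' @rdname onset_frame
#' @export
n_frames <- function(protocol) {
  stopifnot(inherits(protocol, "stim_protocol"))
  .frame_round(protocol$trial_duration_s * protocol$frame_rate_hz)
}

#' @rdname onset_frame
#' @export
stimulus_window <- function(protocol) {
  on <- onset_frame(protocol)
  off <- .frame_round((protocol$baseline_s + protocol$stimulus_s) *
                        protocol$frame_rate_hz)
  c(on, off)
}

#' @rdname onset_frame
#' @export
baseline_window <- function(protocol) c(0L, onset_frame(protocol))

#' @rdname onset_frame
#' @export
f0_window <- function(protocol, n = 10L) {
  on <- onset_frame(protocol)
  n <- as.integer(n)
  if (n < 1L || on - n < 0L)
    stop("F0 window [", on - n, ", ", on, ") does not fit before onset",
         call. = FALSE)
  c(on - n, on)
}

# convert a 0-based half-open [start, end) frame window to R indices
.win_idx <- function(win) (win[1] + 1L):win[2]

#' Read a stimulus protocol from a YAML configuration
#'
#' The canonical config dialect is YAML with keys `frame_rate_hz`,
#' `baseline_s`, `stimulus_s`, `post_s`, `stimuli` (list of labels) and
#' `n_trials`; every key is optional and missing keys take the package
#' defaults (25 Hz, 3/5/16 s, seven-odor panel, 3 trials). An optional
#' `trial_duration_s` is validated against the three window durations.
#' Unknown keys produce a warning and are otherwise ignored.
#'
#' @param config_source Path to a YAML file, or a literal YAML string.
#' @return A [stim_protocol()].
#' @export
load_protocol <- function(config_source) {
  cfg <- tryCatch(
    if (length(config_source) == 1L && file.exists(config_source))
      yaml::read_yaml(config_source)
    else
      yaml::yaml.load(paste(config_source, collapse = "\n")),
    error = function(e)
      stop("malformed protocol config: ", conditionMessage(e), call. = FALSE))
  if (!is.list(cfg))
    stop("malformed protocol config: expected key-value mappings", call. = FALSE)

  known <- c("frame_rate_hz", "baseline_s", "stimulus_s", "post_s",
             "stimuli", "n_trials", "trial_duration_s")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    warning("ignoring unknown protocol key(s): ",
            paste(extra, collapse = ", "), call. = FALSE)

  default <- stim_protocol()
  pick <- function(key, fallback) if (!is.null(cfg[[key]])) cfg[[key]] else fallback
  stim_protocol(
    frame_rate_hz = pick("frame_rate_hz", default$frame_rate_hz),
    baseline_s = pick("baseline_s", default$baseline_s),
    stimulus_s = pick("stimulus_s", default$stimulus_s),
    post_s = pick("post_s", default$post_s),
    stimulus_labels = unlist(pick("stimuli", default$stimulus_labels)),
    n_trials_per_stimulus = pick("n_trials", default$n_trials_per_stimulus),
    trial_duration_s = cfg$trial_duration_s)
}

#' @export
print.stim_protocol <- function(x, ...) {
  sw <- stimulus_window(x)
  cat("Stimulus protocol: ", x$frame_rate_hz, " Hz, ",
      x$baseline_s, "/", x$stimulus_s, "/", x$post_s,
      " s baseline/stimulus/post (", n_frames(x), " frames, onset ",
      onset_frame(x), ", stimulus [", sw[1], ", ", sw[2], "))\n", sep = "")
  cat("  stimuli (", length(x$stimulus_labels), "): ",
      paste(x$stimulus_labels, collapse = ", "), "\n", sep = "")
  cat("  trials per stimulus:", x$n_trials_per_stimulus, "\n")
  invisible(x)
}
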