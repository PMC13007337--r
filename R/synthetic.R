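# run code under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed %% 2147483629L))
  force(code)
}

.default_tuning <- function() list(
  width = 256L, height = 256L,
  radius = 3,
  min_center_dist = NULL,          # default 2 * radius
  f0_range = c(800, 1200),
  preferred_amp_range = c(0.3, 0.8),
  class_probs = c(selective = 0.7, broad = 0.3),
  off_scale = list(selective = c(0, 0.2), broad = c(0.3, 0.7)),
  suppressed_prob = 0.15,
  suppressed_amp_range = c(-0.2, -0.05),
  rise_tau_s = 0.2, decay_tau_s = 2.0,
  noise_sd = 50, background = 0, bleach_tau_s = NA_real_,
  drift_max_px = 0L)

# dart-throwing placement with an occupancy grid; integer pixel centers,
# minimum pairwise center distance `dmin`, all disks fully inside the frame
.place_cells <- function(n, width, height, radius, dmin) {
  margin <- ceiling(radius)
  lo_x <- margin; hi_x <- width - 1L - margin
  lo_y <- margin; hi_y <- height - 1L - margin
  if (hi_x < lo_x || hi_y < lo_y)
    stop("frame too small for the requested ROI radius", call. = FALSE)
  cs <- max(dmin / sqrt(2), 1)
  ngx <- ceiling((hi_x - lo_x + 1) / cs); ngy <- ceiling((hi_y - lo_y + 1) / cs)
  grid <- vector("list", ngx * ngy)
  xs <- integer(n); ys <- integer(n)
  placed <- 0L
  max_attempts <- 500L * n + 2000L
  for (a in seq_len(max_attempts)) {
    x <- sample(lo_x:hi_x, 1L); y <- sample(lo_y:hi_y, 1L)
    gx <- floor((x - lo_x) / cs); gy <- floor((y - lo_y) / cs)
    ok <- TRUE
    for (ix in max(0, gx - 2):min(ngx - 1, gx + 2)) {
      for (iy in max(0, gy - 2):min(ngy - 1, gy + 2)) {
        for (j in grid[[1L + ix + ngx * iy]]) {
          if ((xs[j] - x)^2 + (ys[j] - y)^2 < dmin^2) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) break
    }
    if (ok) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
      k <- 1L + gx + ngx * gy
      grid[[k]] <- c(grid[[k]], placed)
      if (placed == n) break
    }
  }
  if (placed < n)
    stop("cell placement infeasible: placed ", placed, " of ", n,
         " cells at minimum center distance ", dmin, " px", call. = FALSE)
  cbind(x = xs, y = ys)
}

#' Sample a simulated population with known odor tuning
#'
#' Draws the ground truth of a synthetic nuclear-GCaMP experiment: somata
#' placed on the imaging frame (integer pixel centers, minimum pairwise
#' center distance `min_center_dist`, default twice the soma radius),
#' per-cell baseline brightness, indicator kinetics, and a signed peak
#' dF/F amplitude for every stimulus of the protocol. Each cell has one
#' dominant (preferred) stimulus; a tuning class drawn per cell sets how
#' strong the off-stimulus responses are (`selective`: 0-20% of the
#' preferred amplitude; `broad`: 30-70%), and a fraction of cells carry one
#' suppressed (negative-amplitude) off-stimulus response. The preferred
#' stimulus always attains the cell's maximum signed amplitude.
#'
#' All randomness is governed by `seed`: the same arguments and seed yield
#' an identical ground truth and, downstream, bit-identical movies.
#'
#' @param n_cells Number of cells to place (>= 1).
#' @param protocol A [stim_protocol()]; its labels define the tuning axis.
#' @param tuning Named list overriding entries of the default tuning
#'   configuration (frame size, radius, amplitude ranges, class
#'   probabilities, kinetics `rise_tau_s`/`decay_tau_s`, movie-level
#'   `noise_sd`, `background`, `bleach_tau_s`, `drift_max_px`).
#' @param seed Integer seed.
#' @return An object of class `ground_truth`.
#' @export
sample_ground_truth <- function(n_cells, protocol, tuning = list(), seed = 1L) {
  stopifnot(inherits(protocol, "stim_protocol"), n_cells >= 1)
  cfg <- .default_tuning()
  unknown <- setdiff(names(tuning), names(cfg))
  if (length(unknown))
    warning("ignoring unknown tuning key(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[intersect(names(tuning), names(cfg))] <-
    tuning[intersect(names(tuning), names(cfg))]
  if (is.null(cfg$min_center_dist)) cfg$min_center_dist <- 2 * cfg$radius
  if (cfg$decay_tau_s <= cfg$rise_tau_s)
    stop("decay_tau_s must exceed rise_tau_s", call. = FALSE)
  labels <- protocol$stimulus_labels
  m <- length(labels)
  n_trials <- protocol$n_trials_per_stimulus

  .with_seed(seed, {
    pos <- .place_cells(n_cells, cfg$width, cfg$height, cfg$radius,
                        cfg$min_center_dist)
    cls <- sample(names(cfg$class_probs), n_cells, replace = TRUE,
                  prob = cfg$class_probs)
    pref <- sample.int(m, n_cells, replace = TRUE)
    amp_pref <- stats::runif(n_cells, cfg$preferred_amp_range[1],
                             cfg$preferred_amp_range[2])
    amps <- matrix(0, n_cells, m,
                   dimnames = list(sprintf("cell%03d", seq_len(n_cells)),
                                   labels))
    for (i in seq_len(n_cells)) {
      rng <- cfg$off_scale[[cls[i]]]
      off <- stats::runif(m, rng[1], rng[2]) * amp_pref[i]
      off[pref[i]] <- amp_pref[i]
      if (m > 1 && stats::runif(1) < cfg$suppressed_prob) {
        j <- sample(setdiff(seq_len(m), pref[i]), 1L)
        off[j] <- stats::runif(1, cfg$suppressed_amp_range[1],
                               cfg$suppressed_amp_range[2])
      }
      amps[i, ] <- off
    }
    drift <- data.frame(trial = seq_len(n_trials), dx = 0L, dy = 0L)
    if (cfg$drift_max_px > 0) {
      drift$dx <- sample(-cfg$drift_max_px:cfg$drift_max_px, n_trials, TRUE)
      drift$dy <- sample(-cfg$drift_max_px:cfg$drift_max_px, n_trials, TRUE)
    }
    cells <- data.frame(
      cell_id = rownames(amps),
      x = pos[, "x"], y = pos[, "y"], radius = cfg$radius,
      f0 = stats::runif(n_cells, cfg$f0_range[1], cfg$f0_range[2]),
      class = cls,
      preferred = labels[pref],
      rise_tau_s = cfg$rise_tau_s, decay_tau_s = cfg$decay_tau_s,
      stringsAsFactors = FALSE)
    structure(list(cells = cells, amplitudes = amps,
                   stimulus_labels = labels,
                   noise_sd = cfg$noise_sd, background = cfg$background,
                   bleach_tau_s = cfg$bleach_tau_s, drift = drift,
                   width = cfg$width, height = cfg$height,
                   seed = as.integer(seed)),
              class = "ground_truth")
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth: ", nrow(x$cells), " cells on ", x$width, "x", x$height,
      " px, ", length(x$stimulus_labels), " stimuli, noise sd ",
      x$noise_sd, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# integral of the difference-of-exponentials kernel from 0 to u
.kernel_integral <- function(u, tau_d, tau_r) {
  tau_d * (-expm1(-u / tau_d)) - tau_r * (-expm1(-u / tau_r))
}

#' Render noiseless dF/F traces from a ground truth
#'
#' The odor transient is the stimulus-window boxcar convolved with a
#' difference-of-exponentials indicator kernel
#' `exp(-t/decay_tau) - exp(-t/rise_tau)` (evaluated in closed form at the
#' frame times), scaled so the trace maximum equals the cell's stored
#' signed amplitude for that stimulus. Traces are identically zero before
#' stimulus onset and identical across trials (drift and noise act on the
#' rendered movie, not on the ideal trace).
#'
#' @param truth A [ground_truth()].
#' @param protocol A [stim_protocol()].
#' @return Object of class `ideal_traces`: a named list (one
#'   `cells x frames` matrix per stimulus) with the protocol attached.
#' @export
render_ideal_traces <- function(truth, protocol) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(protocol, "stim_protocol"))
  T_ <- n_frames(protocol)
  on <- onset_frame(protocol)
  fr <- protocol$frame_rate_hz
  t_rel <- (seq_len(T_) - 1 - on) / fr          # seconds from onset
  shapes <- new.env()
  shape_for <- function(tau_r, tau_d) {
    key <- paste(tau_r, tau_d)
    if (!is.null(shapes[[key]])) return(shapes[[key]])
    y <- numeric(T_)
    act <- t_rel >= 0
    u <- t_rel[act]
    y[act] <- .kernel_integral(u, tau_d, tau_r) -
      .kernel_integral(pmax(0, u - protocol$stimulus_s), tau_d, tau_r)
    ymax <- max(y)
    shapes[[key]] <- if (ymax > 0) y / ymax else y
    shapes[[key]]
  }
  out <- lapply(truth$stimulus_labels, function(lab) {
    tr <- matrix(0, nrow(truth$cells), T_,
                 dimnames = list(truth$cells$cell_id, NULL))
    for (i in seq_len(nrow(truth$cells))) {
      a <- truth$amplitudes[i, lab]
      if (a != 0)
        tr[i, ] <- a * shape_for(truth$cells$rise_tau_s[i],
                                 truth$cells$decay_tau_s[i])
    }
    tr
  })
  names(out) <- truth$stimulus_labels
  structure(list(traces = out, protocol = protocol), class = "ideal_traces")
}

#' Render one synthetic movie
#'
#' Pixel model: each soma is an isotropic Gaussian profile (sigma =
#' radius/2, truncated at 2 radii) with intensity `F0 * (1 + dF/F(t))`, on
#' a flat background, all multiplied by an optional exponential
#' photobleaching factor, shifted rigidly by the trial's integer (dx, dy)
#' drift, with additive Gaussian noise of standard deviation `noise_sd`.
#' Negative intensities are clipped at 0 in two places: negative *model*
#' (pre-noise) intensities — possible only with suppression amplitudes
#' below -1 or a negative background — are clipped with a warning when
#' they exceed 1% of pixels, and after noise is added the detector floor
#' clips silently (at a zero background offset, empty pixels fall below
#' zero by noise symmetry alone; this carries no signal distortion). The noise substream is derived
#' deterministically from the ground-truth seed and the (stimulus, trial)
#' pair, so the same inputs give a bit-identical movie.
#'
#' @param truth A [ground_truth()].
#' @param ideal The matching [render_ideal_traces()] output.
#' @param protocol A [stim_protocol()].
#' @param stimulus Stimulus label.
#' @param trial Trial index (1-based), used for the drift offset and the
#'   noise substream.
#' @return A [movie_stack()].
#' @export
render_movie <- function(truth, ideal, protocol, stimulus, trial = 1L) {
  stopifnot(inherits(truth, "ground_truth"), inherits(ideal, "ideal_traces"))
  if (!stimulus %in% truth$stimulus_labels)
    stop("unknown stimulus '", stimulus, "'", call. = FALSE)
  T_ <- n_frames(protocol)
  H <- truth$height; W <- truth$width
  dr <- truth$drift[truth$drift$trial == trial, ]
  dx <- if (nrow(dr)) dr$dx else 0L
  dy <- if (nrow(dr)) dr$dy else 0L
  arr <- array(truth$background, dim = c(T_, H, W))
  dff <- ideal$traces[[stimulus]]
  for (i in seq_len(nrow(truth$cells))) {
    cx <- truth$cells$x[i] + dx
    cy <- truth$cells$y[i] + dy
    r <- truth$cells$radius[i]
    sig <- r / 2
    hw <- ceiling(2 * r)
    xs <- max(0L, cx - hw):min(W - 1L, cx + hw)
    ys <- max(0L, cy - hw):min(H - 1L, cy + hw)
    if (!length(xs) || !length(ys)) next
    prof <- outer(exp(-(ys - cy)^2 / (2 * sig^2)),
                  exp(-(xs - cx)^2 / (2 * sig^2)))
    s <- truth$cells$f0[i] * (1 + dff[i, ])
    arr[, ys + 1L, xs + 1L] <- arr[, ys + 1L, xs + 1L] + outer(s, prof)
  }
  if (is.finite(truth$bleach_tau_s) && !is.na(truth$bleach_tau_s)) {
    t_s <- (seq_len(T_) - 1) / protocol$frame_rate_hz
    arr <- arr * exp(-t_s / truth$bleach_tau_s)
  }
  # negative *model* intensity (e.g. suppression overshooting the baseline)
  # is a pathology worth flagging; the default amplitude ranges cannot
  # produce it, so the scan is skipped when that is provable
  if (min(truth$amplitudes) < -1 || truth$background < 0) {
    neg <- arr < 0
    frac <- mean(neg)
    if (frac > 0.01)
      warning(sprintf("%.2f%% of pixels had negative model intensity; clipped at 0",
                      100 * frac), call. = FALSE)
    arr[neg] <- 0
  }
  if (truth$noise_sd > 0) {
    sub_seed <- (truth$seed + 131071 *
                   match(stimulus, truth$stimulus_labels) +
                   257 * trial) %% 2147483629
    arr <- arr + .with_seed(sub_seed,
                            stats::rnorm(length(arr), 0, truth$noise_sd))
    # physical floor of the detector: counts cannot go below zero
    arr[arr < 0] <- 0
  }
  movie_stack(arr, frame_rate_hz = protocol$frame_rate_hz,
              label = sprintf("%s trial %d (sim seed %d)", stimulus, trial,
                              truth$seed))
}

#' Simulate a full experiment
#'
#' Renders every (stimulus, trial) movie of the protocol. With the default
#' 600-frame 256x256 acquisition each movie is ~300 MB in memory, so for
#' large panels prefer rendering per stimulus with [render_movie()] and
#' processing movies one at a time.
#'
#' @inheritParams render_movie
#' @param stimuli Subset of stimulus labels (default: all).
#' @return Nested list `movies[[stimulus]][[trial]]` of [movie_stack()]s.
#' @export
simulate_experiment <- function(truth, protocol,
                                stimuli = truth$stimulus_labels) {
  ideal <- render_ideal_traces(truth, protocol)
  out <- lapply(stimuli, function(s)
    lapply(seq_len(protocol$n_trials_per_stimulus), function(k)
      render_movie(truth, ideal, protocol, s, k)))
  names(out) <- stimuli
  out
}

#' Render and process one stimulus trial-by-trial
#'
#' Memory-friendly equivalent of rendering every trial with
#' [render_movie()] and running [process_trials()]: each trial movie is
#' rendered, its ROI traces extracted, and the movie discarded before the
#' next trial is touched, so only one full stack is ever held in memory.
#'
#' @inheritParams render_movie
#' @param rois An [roi_set()] (default: the true centers via
#'   [rois_from_truth()]).
#' @param discard,cutoff_hz,n_f0,filter Passed to [process_trials()]
#'   stages.
#' @return A trial-averaged [trace_matrix()] (`"dff_filtered"`, or
#'   `"dff"` when `filter = FALSE`).
#' @export
simulate_stimulus_traces <- function(truth, ideal, protocol, stimulus,
                                     rois = rois_from_truth(truth),
                                     discard = integer(0), cutoff_hz = 5,
                                     n_f0 = 10L, filter = TRUE) {
  per_trial <- vector("list", protocol$n_trials_per_stimulus)
  for (k in seq_len(protocol$n_trials_per_stimulus)) {
    mv <- render_movie(truth, ideal, protocol, stimulus, k)
    per_trial[[k]] <- extract_traces(mv, rois, trial = k,
                                     stimulus = stimulus)
    rm(mv)
  }
  avg <- average_trials(per_trial, discard = discard)
  dff <- compute_dff(avg, protocol, n_f0 = n_f0)
  if (filter) lowpass(dff, cutoff_hz = cutoff_hz) else dff
}

#' ROI set at the true simulated cell positions
#'
#' Builds the ROI table a perfect experimenter would draw: true centers and
#' radii, with per-trial offsets equal to the simulated rigid drift.
#'
#' @param truth A [ground_truth()].
#' @return An [roi_set()].
#' @export
rois_from_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  offsets <- NULL
  if (any(truth$drift$dx != 0 | truth$drift$dy != 0)) {
    offsets <- do.call(rbind, lapply(seq_len(nrow(truth$drift)), function(k)
      data.frame(cell_id = truth$cells$cell_id,
                 trial = truth$drift$trial[k],
                 dx = truth$drift$dx[k], dy = truth$drift$dy[k])))
  }
  roi_set(truth$cells[c("cell_id", "x", "y", "radius")], offsets = offsets,
          width = truth$width, height = truth$height)
}
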