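# Small fixtures shared across tests. Everything is generated in code.

# compact 3-odor protocol on a small frame for fast rendering
small_protocol <- function(labels = c("water", "alanine", "NaCl"),
                           n_trials = 3) {
  stim_protocol(stimulus_labels = labels, n_trials_per_stimulus = n_trials)
}

small_tuning <- function(...) {
  utils::modifyList(list(width = 96L, height = 96L), list(...))
}

# render all trials of one stimulus
render_trials <- function(truth, ideal, protocol, stimulus,
                          trials = seq_len(protocol$n_trials_per_stimulus)) {
  lapply(trials, function(k) render_movie(truth, ideal, protocol, stimulus, k))
}

# a deterministic dff-like trace_matrix built from a plain matrix
as_dff <- function(m, protocol, kind = "dff_filtered") {
  if (is.null(rownames(m)))
    rownames(m) <- sprintf("cell%03d", seq_len(nrow(m)))
  trace_matrix(m, kind, frame_rate_hz = protocol$frame_rate_hz,
               trial = "mean")
}

# run the full pipeline for a set of stimuli and return odor_responses
pipeline_responses <- function(truth, protocol, filter = TRUE) {
  ideal <- render_ideal_traces(truth, protocol)
  rois <- rois_from_truth(truth)
  traces <- lapply(protocol$stimulus_labels, function(s) {
    movies <- render_trials(truth, ideal, protocol, s)
    process_trials(movies, rois, protocol, stimulus = s, filter = filter)
  })
  names(traces) <- protocol$stimulus_labels
  odor_responses(traces, protocol)
}
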