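# shared fixture builders; everything is generated in code at test time

default_beat <- function(...) beat_shape_params(...)

clean_trace <- function(n_beats = 10, seed = 1, ...) {
  generate_trace(default_beat(...), n_beats, noise_sd = 0, seed = seed)
}

noisy_trace <- function(n_beats = 12, noise_sd = 0.5, seed = 1, ...) {
  generate_trace(default_beat(...), n_beats, noise_sd = noise_sd, seed = seed)
}

quiet_analyze <- function(trace, ...) {
  suppressWarnings(analyze_trace(trace, ...))
}

# single-beat ground-truth landmark table (indices relative to the trace)
truth_of <- function(sim) sim$truth$beats
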