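# Shared fixture helpers. Everything is generated in code at test time.

rand_signal <- function(n, fs = 1000) signal1d(stats::rnorm(n), fs)

# Small default-world recording reused by several tests (cached per run).
default_recording <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_recording(synth_spec())
    cache
  }
})

# Labelled candidate events of the default recording.
default_candidates <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      rec <- default_recording()
      cand <- match_to_truth(detect_candidates(rec$signal), rec$truth)
      cache <<- cand[cand$label %in% c("spike", "ripple"), , drop = FALSE]
    }
    cache
  }
})
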