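#' Specification of a synthetic iEEG recording
#'
#' Describes the stated world the generator emulates: coloured background
#' noise, stereotyped triangular interictal spikes (sharp rise, slow-wave
#' fall) and Hann-windowed ripple bursts, inserted at non-overlapping
#' seeded positions. The defaults are the conditions the package's own
#' validation runs under; see the methods vignette for the reasoning
#' behind each constant.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate (Hz); 5 kHz matches high-rate clinical iEEG.
#' @param background_sd standard deviation of the background (amplitude
#'   units, nominally microvolts).
#' @param n_spikes,n_ripples number of inserted events.
#' @param spike_duration_ms_range spike length range (ms); a spike is
#'   `spike_rise_ms` of sharp rise followed by a slow-wave fall filling
#'   the remaining duration.
#' @param spike_rise_ms rise time of the spike's sharp flank (ms).
#' @param spike_amplitude_range spike peak amplitudes, as multiples of
#'   `background_sd`, drawn uniformly; must respect
#'   `spike_amplitude_factor_min`.
#' @param spike_amplitude_factor_min hard lower bound on the spike
#'   amplitude factor (spikes are at least twice the background by
#'   definition).
#' @param ripple_band_hz ripple frequency range (Hz).
#' @param ripple_duration_ms_range ripple burst length range (ms).
#' @param ripple_amplitude_factor ripple peak amplitude as a multiple of
#'   `background_sd`.
#' @param min_separation_ms minimum gap between inserted events.
#' @param seed integer seed; all outputs are pure functions of the spec.
#' @return an object of class `synth_spec`.
#' @export
synth_spec <- function(duration_s = 60, fs = 5000, background_sd = 25,
                       n_spikes = 10, n_ripples = 20,
                       spike_duration_ms_range = c(40, 200),
                       spike_rise_ms = 11,
                       spike_amplitude_range = c(16, 18),
                       spike_amplitude_factor_min = 2,
                       ripple_band_hz = c(80, 250),
                       ripple_duration_ms_range = c(30, 100),
                       ripple_amplitude_factor = 0.8,
                       min_separation_ms = 200, seed = 42L) {
  stopifnot(duration_s > 0, fs > 0, background_sd > 0,
            n_spikes >= 0, n_ripples >= 0,
            length(spike_duration_ms_range) == 2L,
            spike_duration_ms_range[1] > 0,
            diff(spike_duration_ms_range) >= 0,
            spike_rise_ms > 0,
            spike_rise_ms < spike_duration_ms_range[1],
            length(spike_amplitude_range) == 2L,
            diff(spike_amplitude_range) >= 0,
            spike_amplitude_range[1] >= spike_amplitude_factor_min,
            length(ripple_band_hz) == 2L, ripple_band_hz[1] > 0,
            diff(ripple_band_hz) >= 0, ripple_band_hz[2] < fs / 2,
            length(ripple_duration_ms_range) == 2L,
            ripple_duration_ms_range[1] > 0,
            diff(ripple_duration_ms_range) >= 0,
            ripple_amplitude_factor > 0, min_separation_ms >= 0)
  structure(as.list(environment()), class = "synth_spec")
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
    suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  force(code)
}

#' Coloured background noise
#'
#' Zero-mean Gaussian noise spectrally shaped to a 1/f^2 power law (flat
#' below 1 Hz), rescaled so the sample standard deviation equals
#' `background_sd` exactly. The steep spectrum mimics the way iEEG power
#' collapses with frequency, leaving the 80-500 Hz band quiet relative to
#' the broadband amplitude.
#'
#' @param spec a [synth_spec()].
#' @return a [signal1d()].
#' @export
generate_background <- function(spec) {
  n <- as.integer(round(spec$duration_s * spec$fs))
  with_seed(spec$seed, {
    white <- stats::rnorm(n)
    shaped <- shape_spectrum(white, spec$fs, exponent = 2, f_floor = 1)
    shaped <- shaped - mean(shaped)
    signal1d(shaped / stats::sd(shaped) * spec$background_sd, spec$fs)
  })
}

# Multiply the FFT of `white` by f^(-exponent/2) (flat below f_floor).
shape_spectrum <- function(white, fs, exponent, f_floor) {
  n <- length(white)
  sp <- stats::fft(white)
  f <- c(0, seq_len(n - 1)) * fs / n
  f <- pmin(f, fs - f)               # two-sided frequency axis
  gain <- pmax(f, f_floor)^(-exponent / 2)
  gain[1] <- 0                       # remove DC
  Re(stats::fft(sp * gain, inverse = TRUE)) / n
}

#' Triangular interictal spike waveform
#'
#' Piecewise-linear pulse: a sharp linear rise of `rise_ms` to the
#' requested peak, then a slow linear fall over the remaining duration
#' (the slow wave folded into the fall). Passed through an 80-500 Hz
#' band-pass, the corners of this waveform ring and mimic a ripple.
#'
#' @param duration_ms total spike length (ms).
#' @param amplitude peak amplitude (same units as the signal).
#' @param fs sampling rate (Hz).
#' @param rise_ms rise time (ms), must be shorter than `duration_ms`.
#' @return numeric waveform vector.
#' @export
make_spike <- function(duration_ms, amplitude, fs, rise_ms = 10) {
  stopifnot(duration_ms > 0, amplitude > 0, fs > 0, rise_ms > 0,
            rise_ms < duration_ms)
  n <- max(3L, as.integer(round(duration_ms * fs / 1000)))
  n_rise <- max(1L, as.integer(round(rise_ms * fs / 1000)))
  n_rise <- min(n_rise, n - 2L)
  up <- seq(0, 1, length.out = n_rise + 1L)[-1L]
  down <- seq(1, 0, length.out = n - n_rise + 1L)[-1L]
  amplitude * c(up, down)
}

#' Hann-windowed ripple burst waveform
#'
#' @param freq_hz oscillation frequency (Hz).
#' @param duration_ms burst length (ms).
#' @param amplitude peak amplitude at the window centre.
#' @param fs sampling rate (Hz).
#' @return numeric waveform vector (zero mean up to windowing leakage).
#' @export
make_ripple <- function(freq_hz, duration_ms, amplitude, fs) {
  stopifnot(freq_hz > 0, duration_ms > 0, amplitude > 0, fs > 0)
  n <- max(3L, as.integer(round(duration_ms * fs / 1000)))
  t <- seq_len(n) / fs
  hann <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = n)))
  amplitude * hann * sin(2 * pi * freq_hz * t)
}

# Draw non-overlapping 0-based start positions for event lengths `lens`
# with at least `sep` samples between events and clear of both edges.
place_events <- function(lens, n_total, sep, margin) {
  starts <- integer(0)
  ends <- integer(0)
  for (len in lens) {
    placed <- FALSE
    for (try in seq_len(2000L)) {
      s <- sample.int(n_total - len - 2L * margin, 1L) + margin
      if (all(s >= ends + sep | s + len <= starts - sep)) {
        starts <- c(starts, s); ends <- c(ends, s + len)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place all events; increase duration_s or reduce event count",
           call. = FALSE)
    }
  }
  starts
}

#' Generate a labelled synthetic recording
#'
#' Background noise plus `n_spikes` spikes and `n_ripples` ripples at
#' seeded, non-overlapping positions separated by at least
#' `min_separation_ms`. The ground-truth table covers exactly the inserted
#' waveform supports.
#'
#' @param spec a [synth_spec()].
#' @return a list with `signal` (a [signal1d()]), `truth` (a labelled
#'   [event_table()]) and `spec`.
#' @export
generate_recording <- function(spec) {
  bg <- generate_background(spec)
  n_total <- length(bg$samples)
  margin <- as.integer(round(0.1 * spec$fs))  # keep events clear of edges
  with_seed(spec$seed + 1L, {
    n_ev <- spec$n_spikes + spec$n_ripples
    if (n_ev == 0L) {
      return(list(signal = bg, truth = event_table(), spec = spec))
    }
    spike_dur <- stats::runif(spec$n_spikes, spec$spike_duration_ms_range[1],
                              spec$spike_duration_ms_range[2])
    spike_amp <- pmax(spec$spike_amplitude_factor_min,
                      stats::runif(spec$n_spikes, spec$spike_amplitude_range[1],
                                   spec$spike_amplitude_range[2])) * spec$background_sd
    rip_freq <- stats::runif(spec$n_ripples, spec$ripple_band_hz[1],
                             spec$ripple_band_hz[2])
    rip_dur <- stats::runif(spec$n_ripples, spec$ripple_duration_ms_range[1],
                            spec$ripple_duration_ms_range[2])
    waves <- c(
      lapply(seq_len(spec$n_spikes), function(i) {
        make_spike(spike_dur[i], spike_amp[i], spec$fs, spec$spike_rise_ms)
      }),
      lapply(seq_len(spec$n_ripples), function(i) {
        make_ripple(rip_freq[i], rip_dur[i],
                    spec$ripple_amplitude_factor * spec$background_sd, spec$fs)
      })
    )
    labels <- c(rep("spike", spec$n_spikes), rep("ripple", spec$n_ripples))
    lens <- vapply(waves, length, integer(1))
    sep <- as.integer(round(spec$min_separation_ms * spec$fs / 1000))
    starts <- place_events(lens, n_total, sep, margin)
    v <- bg$samples
    for (i in seq_along(waves)) {
      idx <- (starts[i] + 1L):(starts[i] + lens[i])
      v[idx] <- v[idx] + waves[[i]]
    }
    ord <- order(starts)
    list(signal = signal1d(v, spec$fs),
         truth = event_table(starts[ord], starts[ord] + lens[ord], labels[ord]),
         spec = spec)
  })
}
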