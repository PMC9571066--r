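---
title: "Morphological spike filtering for ripple detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphological spike filtering for ripple detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

High-frequency oscillations ("ripples", 80--250 Hz bursts in intracranial
EEG) are a candidate biomarker of epileptogenic tissue. The standard way
to find them starts with an 80--500 Hz band-pass filter, and that is also
the standard way to manufacture false ones: an interictal spike -- a
sharp triangular transient of roughly 40--200 ms with amplitude at least
twice the background -- rings when it passes the filter, and the ringing
looks exactly like a ripple to any energy-based detector. `morphripple`
implements (i) a classical RMS-envelope ripple detector, (ii) a
morphological spike-versus-ripple classifier with a *dynamic*,
spike-shape-dependent threshold that screens the detector's candidate
events, and (iii) the evaluation machinery (sensitivity, false detection
rate, ROC operating point, repeated cross-validation) used to select the
classifier's one tunable parameter.

## The detector

The candidate stage band-passes the trace (80--500 Hz), computes the RMS
in a centred 3 ms window, and keeps maximal runs where the RMS strictly
exceeds the baseline mean plus 5 baseline SDs. Runs closer than 10 ms are
clustered, and the 6 ms minimum duration is applied *after* clustering
(the ordering is genuinely ambiguous in the literature; applying it after
lets two nearby 4 ms bursts form one valid event, which matches the
purpose of the clustering rule). A candidate is *confirmed* as an
oscillation when its rectified band-passed segment has at least 6 local
maxima above the baseline mean plus 3 SDs.

Two deliberate choices:

* **Baseline extent.** The baseline for both thresholds defaults to the
  whole analysed segment, because nothing in the source procedure defines
  a separate baseline epoch; `detect_candidates()` and `confirm_hfo()`
  accept an explicit `baseline = c(start, end)` interval for callers with
  event-free epochs. A consequence worth knowing: with a contaminated
  baseline the 5 SD threshold scales with total event energy, so dense
  recordings self-censor weak events.
* **Candidates vs confirmed events.** The classifier screens the
  *candidate* runs (pre-confirmation). A spike's ringing run is typically
  10--15 ms long; at a ringing frequency near the lower band edge such a
  window physically cannot contain 6 rectified peaks, so spikes rarely
  survive confirmation -- yet published candidate sets for this problem
  contain substantial numbers of spikes. Treating the candidate stage as
  the event source reproduces that situation; the confirmation stage
  remains available and separately tested.

## The classifier

For each event, a window of the *raw* trace (event plus 100 ms of context
per side, clamped at the recording edges) is conditioned into a feature
signal: rectified first difference `|diff(x)|` (right-padded with its
last value to preserve length), then a 10 ms centred moving average. On
this feature signal two flat one-dimensional morphological operators act:

* **closing** (dilation then erosion, 1 ms window) envelopes the feature
  signal from above -- `envelope_peak` is its maximum over the core event;
* **opening** (erosion then dilation, `open_ms` window) truncates any
  peak narrower than the window down to the level at which it is at least
  that wide -- `truncated_level` is the opened maximum over the core.

Erosion and dilation under a flat symmetric element are exact sliding
minima/maxima; the package computes them with an O(n) monotonic-wedge
algorithm in C++ whose output is bit-identical to a brute-force oracle
(order statistics, no tolerance), with edge samples replicated, and
window widths converted to the nearest odd sample count (ties upward, so
1 ms at 5 kHz is 5 samples).

The **dynamic threshold** is the maximum `truncated_level` over a
training set of events. A sharp spike loses most of its feature peak to
the opening, a broad oscillatory event loses almost nothing, so the
largest surviving truncated level sits above every ripple's envelope peak
but below the spike peaks; an event is called a spike when its
`envelope_peak` strictly exceeds the threshold. The compared statistic is
the closing-envelope peak: the threshold lives in the units of the
feature signal and the envelope is the only per-event statistic in those
units, but note this is this package's reading -- the original procedure
never names the compared statistic, nor whether "truncated value" means
the opened maximum or the clipped-off height. We use the opened maximum.

The opening window is the method's real parameter. Small windows truncate
nothing (threshold too high, spikes missed); large windows truncate
broad events too (threshold too low, ripples misclassified). The shipped
sweep covers 1--8 ms (`default_sweep_windows()`), each window is scored
by SE = TP/(TP+FN) and FDR = FP/(FP+TP) with *spikes as the positive
class*, and the operating point minimises the Euclidean distance
`sqrt(FDR^2 + (1-SE)^2)` to the ideal point, ties going to the smaller
window. The validated default is 4 ms. `cross_validate()` repeats a
stratified random split (default fraction 0.5 -- the source states a
train/test division but no proportions), selects the window on the
training half, refits the threshold, and scores the held-out half.

Undefined ratios (no spikes in a split, nothing called a spike) raise
errors rather than returning silent zeros; displayed percentages round
half away from zero while raw fractions are retained.

## The synthetic world

Patient recordings are not shipped; every empirical claim the tests make
is about seeded synthetic recordings from `synth_spec()`. The generator's
defaults are a *stated world*, chosen once:

* **Background**: zero-mean Gaussian noise shaped to a 1/f^2 power
  spectrum (flat below 1 Hz), SD 25 (nominal microvolts), 5 kHz. A 1/f^1
  spectrum extending to the 2.5 kHz Nyquist was rejected on analysis: it
  puts ~23% of its power into 80--500 Hz and makes the background's
  per-sample first difference larger than any realistic spike flank
  slope, so neither the detector nor the gradient feature can see events
  at clinically plausible amplitudes. Real iEEG spectra fall at least as
  fast as 1/f^2 above a few Hz.
* **Ripples**: Hann-windowed sinusoid bursts, 80--250 Hz, 30--100 ms,
  peak amplitude 0.8 x background SD (well below the broadband
  background, far above the quiet in-band noise -- the realistic
  situation that makes ripples invisible to the eye and findable by the
  RMS detector).
* **Spikes**: piecewise-linear pulses with an 11 ms rise to the peak and
  a slow-wave fall occupying the rest of a 40--200 ms duration, peak
  amplitude 16--18 x background SD (stereotyped high-amplitude focal
  discharges). Two generator choices deserve emphasis. First, the rise
  is *not* a quarter of the duration: with the fixed 10 ms feature
  smoothing, any rise much longer than the smoothing window yields a
  flat-topped feature plateau that no 1--8 ms opening can truncate, and
  any much shorter rise yields the same plateau from the smoothing
  itself; a rise comparable to the smoothing window is the regime where
  the opening sweep actually grades truncation, which is the regime the
  published sweep behaviour implies. Second, the amplitudes are
  stereotyped (spread ~12%) because the dynamic threshold is a maximum
  over training truncated levels: at the 4 ms window a pointed spike
  keeps ~80-90% of its peak, so spikes whose peaks spread more than the
  truncated fraction would fall below a threshold set by the largest of
  them. This is a genuine, documented limitation of the max-based
  threshold, not of the generator.
* **Placement**: events are inserted at seeded uniform positions,
  non-overlapping, at least 200 ms apart and 100 ms clear of the edges;
  ground truth covers exactly the inserted supports. All outputs are pure
  functions of the spec, including its seed.

What a green synthetic test establishes: that the pipeline's stages
interlock as designed (spikes ring into false candidates, features
separate the classes, the swept threshold lands between them) in a world
whose spectra, amplitudes and event shapes are plausible but idealised.
What it does not establish: clinical performance. Real spikes vary in
shape within and across patients, ripples co-occur with spikes, and
electrode artifacts exist; none of that is emulated, and the published
headline averages (~94% sensitivity, ~14% FDR on patient data) are
deliberately outside this package's claims.

## Numerical and interface choices

* Band-pass: Hamming-windowed sinc FIR (transition ~20 Hz at 5 kHz,
  scaled with fs), applied zero-phase via FFT convolution with the group
  delay removed, so event timing stays aligned with the raw trace. No
  filter family is prescribed by the source; any implementation with the
  stated passband that rings on spikes is conformant. Signals shorter
  than the kernel are rejected.
* All centred windows use odd sample counts (nearest odd, ties up) and
  edge replication, identically in the moving average, RMS, and
  morphology (fast path and oracle).
* Events are half-open, 0-based sample intervals everywhere, including
  the CSV serialisation; seconds columns in files are derived, never
  authoritative.
* Threshold crossings are strict; local maxima are samples strictly above
  both neighbours, with plateaus contributing their centre once.
* EDF output quantises to 16 bits over the per-channel range and pads the
  last record to a whole second; CSV round trips are exact to the printed
  precision.
* The CLI (`hfo_cli()`, also installed as `exec/morphripple`) is a thin
  shell over the library functions -- outputs are identical to direct
  calls -- and every output file carries a provenance comment (tool
  version, parameters, seed).

## Known limitations

* The max-based dynamic threshold has breakdown point zero: one outlier
  training event owns the threshold. Robust variants (quantiles) would
  change the published method and are not implemented.
* The 6-peak confirmation intrinsically rejects short, slow ripples (a
  30 ms burst at 85 Hz cannot produce 6 qualifying rectified peaks);
  recovery figures should be read with that in mind.
* With the whole-segment baseline, detector thresholds rise with event
  density; sparse-event recordings are the intended regime.
* The classifier assumes a single gain for the whole recording; no
  amplitude normalisation across recordings is attempted.
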