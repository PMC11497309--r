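---
title: "Spike detection and conduction-speed estimation in microchannel MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike detection and conduction-speed estimation in microchannel MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The setting

When cortical or thalamic axons grow through a PDMS microchannel laid over a
microelectrode array (MEA), the channel insulates the extracellular space
around the axon bundle and amplifies its action potentials: spikes of
0.4 mV or more appear against a noise floor of roughly 0.2 mV peak-to-peak.
Several electrodes (up to five at the standard 500 µm pitch of a 6×10
array) sit under one channel, so the same action potential is seen at each
electrode with a delay set by its conduction speed. `axonmea` implements
the analysis chain for such recordings — spike detection, per-channel
firing rates, and conduction-speed estimation — together with a seeded
simulator that provides exact ground truth for every stage.

```{r, eval = FALSE}
library(axonmea)
g   <- default_geometry()                       # 5 electrodes, 500 um pitch
cfg <- sim_config(duration_s = 40, conduction_speed_m_s = 0.5, seed = 1)
rec <- simulate_recording(g, cfg)
trains <- detect_recording(rec)
speeds <- estimate_conduction_speed(g, trains)
channel_speed_summary(speeds)
```

# Spike detection

Traces sampled at 25 kHz are high-pass filtered with an order-4 Butterworth
at 200 Hz. The filter is applied forward and backward so it contributes no
net phase: offline analysis permits the acausal pass, and detected peak
times are then not skewed by filter delay. The implementation uses
steady-state initial conditions and odd-extension padding at both trace
ends, so a constant (DC) trace maps to zero without a startup transient.

The noise level is estimated robustly from the median absolute deviation,

$$\sigma = b \cdot \mathrm{MAD}, \qquad b = 1.4826,$$

with MAD taken about the median. $b$ is $1/\Phi^{-1}(3/4)$, which makes
$\sigma$ unbiased for Gaussian noise; unlike the sample standard deviation,
the MAD is nearly unaffected by the spikes riding on the trace, so the
threshold tracks the noise floor. Detection then accepts local minima below
$-5\sigma$ (spikes in these preparations are negative-dominant), scanning
candidates in time order and discarding any candidate within 3 ms of the
last accepted event. The dead-time rule is *greedy* — each accepted spike
opens a fresh 3 ms window — which is one of the two readings of "peaks
within 3 ms after the first detected peak are discarded"; the greedy
variant is idempotent (re-filtering an accepted train changes nothing) and
is what the test suite pins down against a brute-force oracle. Equal-valued
adjacent minima resolve to the earliest sample. $\sigma$ is estimated once
per electrode on the full filtered trace; chunked re-estimation was
considered and not adopted, as the simulated noise is stationary.

Two degenerate inputs are handled explicitly: an empty trace is an error in
the noise estimator, and $\sigma = 0$ on a non-zero trace raises a
degenerate-threshold error rather than letting every local minimum fire.
For deliberately noiseless validation recordings the detector accepts a
fixed `sigma_override`, since a silent trace has no MAD noise floor to
estimate.

# Conduction speed from latency histograms

For an ordered electrode pair along the channel, the spike-triggered time
histogram (STTH) accumulates, for every reference spike, the latencies of
all target-electrode spikes within a 16 ms window into 0.05 ms bins
(320 bins). Binning is half-open $[k\,\Delta, (k+1)\Delta)$; a latency of
exactly zero is excluded (a coincident spike is not propagation) and a
latency exactly at the window edge falls in the last bin. All spikes in the
window are counted, not only the first. The conduction speed of a pair is

$$v = \frac{d_{elec}\ [\mathrm{mm}]}{t_{peak}\ [\mathrm{ms}]}
\quad [\mathrm{m\,s^{-1}}],$$

where $t_{peak}$ is the *lower edge* of the bin holding the histogram
maximum (earliest bin on ties — the conservative, higher-speed choice).
Positions are micrometres internally; the single conversion to mm/ms
happens at this formula, so no hidden unit factors exist elsewhere. The
16 ms window sets a per-pair floor on resolvable speed, $d_{elec}/16\,$ms
(0.15 m/s for a 2.4 mm pair), which the per-pair output reports.

A peak counts as evidence of propagation only when three conditions hold:
the reference train has at least 50 spikes; the peak count exceeds
mean + 3·sd over all bins; and the peak count exceeds a Bonferroni-corrected
Poisson upper quantile at the mean bin count (family-wise rate 0.001 across
the 320 bins). The third condition is this package's addition to the usual
sd criterion: in the sparse regime — a reversed, non-propagating pair
contributes only a handful of chance coincidences spread over 320 bins —
the maximum of 320 roughly-Poisson bins routinely exceeds mean + 3 sd, so
the sd rule alone flags noise. A genuine propagation peak collects a large
share of the reference spikes and clears all three conditions easily. All
constants (`min_ref_spikes`, `z`, `guard_alpha`) are arguments. A peak in
the first bin (lower edge 0 ms) cannot yield a finite speed and is reported
non-significant. The channel summary is the median speed over significant
pairs; the choice of pairs entering a published estimate is generally
unstated in this literature, so all ordered upstream→downstream pairs are
used.

Two quantization effects bound the recoverable accuracy. Arrival times are
rendered at the nearest sample (≤ 0.02 ms at 25 kHz), and the histogram
quantizes latencies to 0.05 ms, so a noise-free estimate lies in the
envelope $d/(t + \Delta) \le \hat v \le d/(t - \Delta)$ with $\Delta$ one
bin. The envelope is widest for the shortest pair: an adjacent 500 µm pair
at 1 m/s (0.5 ms true delay) can be off by 11%, while the 2 mm pair is
within 2.6%; the median over all ten pairs of a five-electrode channel is
well inside 10%. The property suite checks the envelope exactly (to float
round-off) on noise-free runs and the 10% recovery on noisy ones.

# Activity metrics and morphometrics

The mean firing rate (MFR) is reported per channel — the activity of the
axon bundle, not of any single cell. The per-channel value aggregates
electrode rates by their mean (default), making channels with different
electrode counts comparable; `sum` and `max` are available. Group
comparisons use the tie-corrected Kruskal–Wallis H with a $\chi^2_{k-1}$
p-value via `stats::kruskal.test`; the degenerate all-tied case returns
H = 0, p = 1 by convention. No multiple-testing correction is applied by
default, matching the single starred comparison typical of these figures.

Morphometric inputs arrive as tables: axon lengths per condition (channel
width or channel count) are summarised as median and quartiles with the
linear-interpolation convention, and tunnel-penetration counts become
fractions with Wilson 95% intervals — Wilson rather than Wald because the
number of tunnels per width is small. The package bundles *synthetic*
example tables (`inst/extdata/synthetic_*.csv`); they illustrate the table
schemas and exercise the code, and carry no measured data.

# The synthetic generator

The simulator emulates the recording conditions the analysis was designed
for: homogeneous Poisson source trains (default 5 Hz) entering a channel,
propagation at a fixed speed (delay = position/speed, exact before sample
quantization), a fixed biphasic template of ~1 ms width — dominant negative
lobe scaled so the global minimum is exactly the configured amplitude,
default 0.4 mV — and independent white Gaussian noise per electrode. The
default noise σ (≈ 24.6 µV) is derived from the 0.2 mV peak-to-peak level
by inverting the expected range of 25 000 Gaussian samples
(`ptp_to_sigma()`), i.e. the peak-to-peak level an experimenter would read
off a 1 s sweep. One master seed feeds per-unit and per-electrode derived
streams (`derive_seed()`), so a fixed configuration is bit-reproducible and
sub-components are independently reproducible.

What the generator does *not* model — and therefore what passing tests do
not certify about real data: spike-shape variability along an axon,
bursting and network dynamics, electrode-to-electrode noise correlation,
non-Gaussian or non-stationary noise, stimulation artifacts, and multiple
units per channel with overlapping waveforms (a multi-unit mode exists for
stress tests, but superposition effects are not calibrated). Amplitude is
constant along the channel, whereas real bundles show position-dependent
amplitudes.

# Problem sizes and reproducibility

The validation suite runs at sizes chosen to make each check statistically
decisive while keeping a full run short: detection is verified against a
brute-force oracle on 1000 random traces of up to 10 000 samples; the
false-positive bound uses ten 600 s noise recordings at 25 kHz; speed
recovery uses 40 s recordings (≈ 200 reference spikes per electrode, four
times the 50-spike significance minimum) over 50 seeds for each of 0.2,
0.5 and 1.0 m/s at SNR 8; the Kruskal–Wallis null calibration uses 1000
simulations of 12 + 12 observations. `scripts/acceptance.R` recomputes the
headline quantities from scratch under a caller-supplied seed, and
`run_pipeline()` writes a manifest with config snapshot and output
checksums; a fixed seed reproduces every CSV byte-for-byte.

# Known limitations

Speeds are only resolvable between $d/16\,$ms and $d/0.05\,$ms per pair;
delays shorter than one bin alias into the first bins and are rejected by
the zero-edge rule. The greedy dead time merges genuinely distinct events
closer than 3 ms (at 5 Hz Poisson this is rare). The significance guard
assumes approximately independent background bins; strongly bursty trains
would violate that and warrant a shuffled-train surrogate baseline, which
is not implemented. Vendor acquisition formats are not read; recordings
enter through the documented float64 + JSON container.
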