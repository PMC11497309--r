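# axonmea

Analysis of extracellular recordings from axon bundles confined in PDMS
microchannels over microelectrode arrays (MEAs). When axons grow through a
microchannel laid over a row of electrodes, the channel amplifies their
action potentials (spikes ≥ 0.4 mV against ~0.2 mV peak-to-peak noise) and
the same spike is seen at successive electrodes with a delay set by its
conduction speed. `axonmea` is for electrophysiologists working with such
preparations who need a tested, reproducible pipeline from raw traces to
firing rates and conduction speeds — plus a ground-truth simulator to
validate every stage.

## What it computes

**Spike detection** — traces (25 kHz) are high-pass filtered (order-4
zero-phase Butterworth, 200 Hz); the noise level is estimated robustly as

    sigma = b * MAD,  b = 1.4826

with the MAD about the median; local minima below −5·sigma are accepted as
spikes, and further candidates within a 3 ms dead time are discarded as
duplicates.

**Conduction speed** — for each ordered electrode pair along a channel, a
spike-triggered time histogram (STTH) accumulates latencies of downstream
spikes within 16 ms of each upstream spike into 0.05 ms bins. A latency
peak that clears the baseline criteria indicates propagation, and

    v [m/s] = d_elec [mm] / t_peak [ms]

with `t_peak` the lower edge of the peak bin. The channel's speed is the
median over significant pairs.

**Activity & morphometrics** — mean firing rate per channel (bundle-level
activity), Kruskal–Wallis group comparisons, axon-length median/quartile
profiles per condition, and tunnel-penetration fractions with Wilson 95%
intervals.

**Simulator** — seeded, bit-reproducible recordings: Poisson source trains,
fixed-speed propagation down the channel (delay = distance/speed), biphasic
spike templates, calibrated Gaussian noise, with the ground truth attached
to every recording.

## Worked example

```r
library(axonmea)

g   <- default_geometry()            # 5 electrodes, 500 um pitch, one channel
cfg <- sim_config(duration_s = 40, conduction_speed_m_s = 0.5, seed = 1)
rec <- simulate_recording(g, cfg)    # 0.4 mV spikes, ~24.6 uV noise sigma

trains <- detect_recording(rec)      # filter + MAD sigma + 5-sigma detection
speeds <- estimate_conduction_speed(g, trains)
channel_speed_summary(speeds)
#>   channel_id n_pairs n_significant speed_m_s
#> 1        ch1      10            10       0.5
```

The ten upstream→downstream pairs all show significant latency peaks, and
the median recovered speed is 0.5 m/s — the simulated truth. A 500 µm pair
at 0.5 m/s has a 1.0 ms delay, so its peak lands at bin edge 1.00 ms and
`0.5 mm / 1.00 ms = 0.5 m/s` exactly.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → detect → conduction → metrics), writing tables under
`results/`. Their printed summary on the default seed:

```
main:  median speed 0.500 m/s over 10 significant pairs (truth 0.50, error 0.0%)
floor: median speed 0.150 m/s over 1 significant pairs (truth 0.15, error 0.3%)
main:  channel MFR 4.405 Hz over 5 electrodes
null:  channel MFR 0.005 Hz over 5 electrodes
Kruskal-Wallis main vs null: H = 7.759, p = 0.005346
```

The `floor` scenario is a 2.4 mm electrode pair at the slowest speed the
16 ms STTH window can resolve, `2.4 mm / 16 ms ≈ 0.15 m/s`; the `null`
scenario is noise only, and its 0.005 Hz rate shows the 5-sigma false
positive floor. See `vignettes/microchannel-conduction.Rmd` for the methods
in full.

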