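# rampfold

Analysis of optical-trap force-ramp experiments on modular proteins, built
around the mechanics of the inner-ear tip link. Hearing depends on tip
links — filaments of a PCDH15 dimer joined to a CDH23 dimer — conveying
sound-derived tension to the hair cell's transduction channels. Whether the
tip link itself is soft enough to be the "gating spring" of that channel is
a question about the force-extension behaviour of its proteins: how much
entropic slack they have, how stiff they are once taut, how often their
domains unfold under physiological force, and how reliably they refold
between stimuli, all as functions of Ca²⁺ and of deafness-associated
mutations such as PCDH15 V507D.

rampfold is for researchers analysing (or simulating) single-molecule
force-ramp data of this kind: repeated cycles in which force rises at a
constant rate from a ~1 pN rest to a peak and returns, with the end-to-end
extension sampled throughout.

## The model

A trajectory segment is described by a saturation model with a
linear-spring term,

```
x(F) = x_E / (1 + F_half / F) + F / K
```

with `x_E` the maximal entropic extension (nm), `F_half` the force at which
entropic extension is half complete (pN), and `K` the enthalpic stiffness
(pN/nm ≡ mN/m). Discrete unfolding events raise `x_E`; the fitted `x_E` is
the coordinate in which trajectory segments are clustered into
conformational states and tracked across cycles. Springs in series compose
as `1/K_tl = 1/K_pcdh15 + 1/K_cdh23`, and stiffness scales inversely with
contour length, which links the measured PCDH15 stiffness to an estimate
for the whole tip link.

The package covers the full analysis chain:

* `condition_presets()`, `simulate_cycle()`, `simulate_dataset()` — a
  Bell–Evans unfolding simulator with ground-truth event logs for the six
  study conditions (wild-type / V507D × 3 mM / 20 µM / 0 M EDTA Ca²⁺);
* `write_dataset()` / `read_dataset()`, `split_phases()`,
  `build_heatmap()` — a plain-text trajectory format and occupancy
  heatmaps;
* `detect_events()`, `segment_cycle()`, `total_unfolding_per_cycle()`,
  `event_size_distribution()` — change-point detection of unfolding steps
  and event statistics;
* `enthalpic_stiffness()`, `fit_segment()`, `fit_phase()` — the two-stage
  fitting protocol (stiffness from the high-force slope, then per-segment
  fits with `K` fixed);
* `define_states()`, `classify_segment()`, `build_transition_map()`,
  `refolding_summary()`, `entropic_stiffness_by_state()`,
  `tether_statistics()` — six-state clustering, kNN assignment, transition
  maps, refolding and per-state stiffness;
* `run_pipeline()` — end-to-end orchestration with delimited-text tables
  and a JSON run manifest (also scriptable via `inst/cli/rampfold.R`).

## Worked example

```r
library(rampfold)

# tip-link stiffness from the series-spring calculus
k_cdh23 <- scaled_stiffness(6.4, 2.3)      # CDH23 is ~2.3x as long as PCDH15
series_stiffness(6.4, k_cdh23)

# simulate a Ca2+-free V507D dataset and analyse one cycle
cfg <- condition_presets("V507D", "0 M EDTA")
ds  <- simulate_dataset(cfg, 25, seed = 7)
cyc <- ds$cycles[[3]]
ev  <- detect_events(cyc)
ev[, c("phase", "force_pN", "size_nm")]
total_unfolding_per_cycle(ev)

K <- enthalpic_stiffness(ds$cycles)        # per-condition stiffness
segs <- segment_cycle(cyc, ev)
s1 <- segs[segs$phase == "extension" & segs$ordinal == 1, ]
fit_segment(cyc$samples$force_pN[s1$start:s1$end],
            cyc$samples$extension_nm[s1$start:s1$end], k_fixed = K$value)
```

which prints

```
CDH23 stiffness: 2.78 mN/m
tip-link stiffness: 1.94 mN/m
      phase force_pN size_nm
1 extension     25.4    5.66
2 extension     59.4   28.16
total unfolding (extension): 33.8 nm
Stiffness 1.26 pN/nm +/- 0.011 (SEM), n = 50
Force-extension fit: x_E = 70.9 nm, F_half = 3.26 pN, K = 1.26 pN/nm
  residual RMS 0.451 nm over 1223 samples
```

Read: combining the measured PCDH15 dimer stiffness (6.4 mN/m) with a
length-scaled CDH23 gives a tip link of about 1.9 mN/m, inside the measured
gating-spring range. The simulated mutant cycle shows a small linker event
(5.7 nm at 25 pN) and a domain-scale event (28 nm near the peak), and its
first segment fits to `x_E` ≈ 71 nm — the molecule already carried an
unfolded domain from the previous cycle, which is the refolding failure the
pipeline quantifies condition by condition.

The methods vignette (`vignettes/force-ramp-analysis.Rmd`) documents the
model assumptions, the simulator's design constants, the detection and
fitting choices, and known limitations.

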