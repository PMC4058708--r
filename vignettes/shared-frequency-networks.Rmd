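---
title: "Shared-frequency EEG networks: model, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shared-frequency EEG networks: model, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sfnet)
```

## The analysis in one paragraph

Comatose patients after cardiac arrest are monitored with continuous 19-channel
scalp EEG. The premise of this analysis is that groups of neurons that
oscillate at a common frequency are functionally coupled, so two electrodes
that both carry a significant oscillation at the same frequency in the same
second can be treated as connected. Each second therefore yields a binary
19 × 19 adjacency matrix, from which graph-theoretical summaries are derived:
the network size (electrodes with at least one connection), the number of
connections, the clustering coefficient C, the average shortest path length L,
and the small-world index SWI = C/L. C and L are additionally expressed
relative to random graphs of identical size and edge count. Per-second values
are averaged over 5-minute epochs, epochs over clinical windows (0–24, 0–48,
0–72 h after the arrest), and the resulting per-subject summaries are compared
between survivors (CPC 1–4) and non-survivors (CPC 5), correlated with the CPC
score, combined into a sum-of-ranks composite, and assessed with ROC analysis.

## Spectral peak detection

Spectra are computed with 2-s Hann windows starting every second (50%
overlap), giving a 0.5 Hz grid; only 1–25 Hz is analysed. Amplitudes are
moduli of the Fourier coefficients, scaled so that a sinusoid of amplitude
*A* µV at an exact grid frequency reads *A*. A bin is significant when all
three criteria hold:

* **(a)** its amplitude is at least 5% of the maximum of the *same* bin over
  the surrounding 4 s (windows whose starts lie within ±2 s, truncated at
  epoch edges);
* **(b)** it is at least 50% of the largest amplitude in its window over
  1–25 Hz;
* **(c)** it strictly exceeds its four spectral neighbours (±0.5, ±1.0 Hz).
  Ties fail. Spectra carry margin bins at 0–0.5 and 25.5–26 Hz so that 1 and
  25 Hz have four neighbours and are not systematically excluded.

The thresholds are configuration values (`criteria_config()`); their defaults
are the published ones. Criterion (a) at 5% is extremely permissive — it only
removes bins that are nearly silent relative to their own recent history — and
in practice (b) and (c) do almost all the work. We implement it as stated and
keep it configurable.

**The optional amplitude floor.** The three criteria are purely relative: they
are invariant to rescaling a channel. A channel containing only noise
therefore still produces "significant" bins every second, and a montage of
near-silent channels would masquerade as a dense random network — the opposite
of the near-empty networks that severely attenuated (low-voltage or
iso-electric) EEG should produce. `criteria_config()` therefore exposes an
absolute amplitude floor in µV, off by default to match the published
criteria. The pipeline configuration (`default_config()`) enables it at 3 µV:
below the smallest EEG amplitudes of clinical interest (low-voltage EEG is
conventionally < 10 µV) and above the spectral amplitude of instrument-level
noise. With the floor on, iso-electric recordings yield empty networks, as
clinical experience requires.

## Network conventions

Per second, electrodes i ≠ j are connected iff their significant-frequency
sets intersect; the diagonal entry marks electrodes with at least one detected
oscillation. Counting conventions:

* `n_connections` counts nonzero entries of the full 19 × 19 matrix (maximum
  361, diagonal included) — this matches the published counting; the
  undirected edge count m = (count − trace)/2 feeds every graph algorithm.
* network size counts electrodes with at least one *off-diagonal* connection;
  a lone oscillating electrode is not a network.
* C is the Watts–Strogatz clustering coefficient averaged over present nodes;
  nodes of degree < 2 contribute 0.
* L averages shortest-path lengths over all ordered pairs of present nodes,
  excluding unreachable pairs, which keeps L finite for fragmented networks
  without inventing a component-selection rule.
* Degenerate networks (size < 2) take C = 0, L = 1, SWI = 0.

C and L depend strongly on size and density, so they are normalized by the
mean C and L of `n_rand` graphs drawn uniformly from G(n, m) — all graphs with
the same number of present nodes and edges — under identical conventions
(default `n_rand` = 50, seeded, memoised per (n, m) within an epoch).
Uniform G(n, m) sampling, rather than degree-preserving rewiring, is the
reference implied by "same size and number of connections". For degenerate
seconds the reference does not exist; C_rel and L_rel are then flagged
missing and skipped by the epoch and window averages (SWI is still 0 by the
convention above). A consequence worth knowing: a subject whose every second
is degenerate (e.g. fully iso-electric) has no C_rel/L_rel and is excluded
from the sum-of-ranks composite, while their size, connection count and SWI
(all 0) remain in the single-metric comparisons.

Both SWI = C_rel/L_rel (the headline index) and SWI_raw = C_raw/L_raw are
reported; displayed values in the clinical literature are typically truncated,
not rounded, to two decimals.

## Cohort statistics

Subject summaries are means over the epochs available in each window —
subjects whose registration stopped early contribute what they have. Group
comparisons use the classic pooled-variance two-sample t-test. Correlations
with CPC use tie-aware Spearman rank correlation; for n ≤ 8 the two-sided
p-value is exact (full enumeration of the 8! ≤ 40,320 rank permutations),
beyond that the asymptotic tie-corrected approximation is used — full
enumeration at n = 9–10 (0.36–3.6 M permutations) buys no practical accuracy
for its cost.

**Sum of ranks.** Each of network size, connection count, C_rel and L_rel is
ranked across the cohort (mid-ranks for ties) and centered by subtracting the
mean rank, so cohort scores sum to zero and group means can be negative.
Orientation: size, connections and L ascending, C inverted, so that all four
components point "toward survival" — survivors have larger, better-connected,
relatively *longer-path* and *less-clustered* networks. The orientation is a
configuration entry. Scores are compared with the Wilcoxon rank-sum test; its
p-value is computed from the exact permutation distribution of the rank sum
(tie-aware, by dynamic programming over mid-rank subset sums) for cohorts of
up to 40 subjects, and by the normal approximation beyond. The exact
distribution matters: composite scores routinely separate small cohorts
completely, where the normal approximation materially overstates p.

ROC analysis (via pROC) reports the full curve and the operating point used
for prognostication — maximum sensitivity among thresholds with zero false
positives. Subgroup contrasts mirror the clinical comparisons: bilaterally
absent versus present SSEP, and pooled iso-electric + low-voltage versus
diffuse slowing (burst suppression and other categories excluded from that
contrast).

## The synthetic cohort generator

No recordings are distributed with this package; the generator provides
ground-truth-bearing substitutes. An epoch is a set of *shared oscillators* —
sinusoids on the 0.5 Hz grid, each present in a chosen subset of channels —
superposed on independent Gaussian channel noise, with an archetype-specific
temporal envelope (continuous; low-voltage; iso-electric; burst suppression
with a 10-s on/off period at a given duty cycle; periodic discharges as
difference-of-Gaussians transients). The expected adjacency implied by the
oscillator sets is returned alongside the waveform, which is what makes
planted-network recovery testable.

Oscillators are written with alternating +/− polarity across their channel
set. Physical EEG sources project onto an average-referenced montage with
near-zero mean; a single-signed topography would bleed a fraction of every
oscillation into all other channels upon re-referencing and silently corrupt
the planted ground truth.

Cohorts are generated from a per-subject latent severity u ∈ [0, 1]
(1 = intact cortical network): survivors draw u from U(0.45, 1),
non-survivors from U(0, 0.25), iso-electric subjects are pinned to u = 0.
Severity drives every structural knob monotonically, each with its own
multiplicative jitter, drawn once per subject and held across epochs:

* oscillator count 4 + 10u (log-t₃ jitter, scale 0.3) — network size and
  connection count;
* fraction of oscillators shared by 3–4 channels rather than 2,
  0.5 − 0.45u (log-normal jitter 0.4) — severe injury leaves few tight
  clusters (high relative clustering, short paths), intact cortex is
  dominated by cross-cutting pairwise sharings, whose union graph is close
  to a uniform random graph;
* burst-suppression duty cycle 0.25 + 0.6u;
* survivors' activity occupies a random regional pool of 10–19 electrodes.

The heavy-tailed (Student-t in the log) jitter is deliberate: real cohorts
contain extreme individuals, and it is exactly this regime that separates
moment statistics from rank statistics — occasional outliers inflate
group standard deviations and blunt t-tests, while the rank-based composite
is unaffected. Non-survivors draw their archetype at 0.08 / 0.47 / 0.45
(iso-electric / low-voltage / burst-suppression); amplitude regimes follow
clinical convention (continuous background 25–45 µV, low-voltage 6–9.5 µV,
iso-electric noise ≤ 2 µV), with oscillator amplitudes within a factor of
two of each other so that a channel carrying several oscillators keeps all
of them above the 50%-of-maximum criterion. CPC for survivors is a graded
function of u; bilateral SSEP absence concentrates in iso-electric and
low-voltage subjects.

**What the generator does and does not emulate.** It reproduces the
statistical structure the analysis consumes: shared oscillations with known
topology, amplitude regimes, and ICU-EEG temporal envelopes. It does not
attempt physiological realism — no 1/f background, spindles, reactivity, or
volume conduction. Passing tests on synthetic cohorts therefore demonstrate
that the pipeline recovers planted connectivity and group structure, not that
it would show identical effect sizes on clinical recordings.

**Problem sizes.** Simulated cohort epochs default to 60 s at hours 6, 30 and
60; per-second network estimates stabilise well below the 300 s used for
clinical epochs, and three epochs per subject exercise the window-averaging
logic (a subject's 0–24 h window holds one epoch, 0–72 h all three). Real
recordings are scheduled as 300-s epochs, hourly through 48 h and two-hourly
beyond — the published schedule wording is ambiguous at the 24–48 h boundary;
hourly through 48 h matches the 0–48 h aggregation granularity.

## Numerical choices and degenerate inputs

* Shortest paths by vectorized Floyd–Warshall (n = 19); clustering by triangle
  counting via the cube of the adjacency matrix. Both are cross-checked
  against loop-based oracles (and igraph) in the test suite, including
  exhaustively over every graph on ≤ 6 nodes.
* The band-pass filter is a 4th-order Butterworth applied forward–backward
  (zero phase); the upper edge is clipped just below Nyquist when the
  sampling rate makes 100 Hz unattainable.
* EDF input is resampled to 256 Hz by polyphase resampling when the source
  rate differs; the EDF writer quantizes at 0.01 µV/bit.
* Epochs shorter than one 2-s window are an input error; a recording shorter
  than one epoch yields an empty schedule, not an error.
* All randomness (noise, random references, cohort draws) is seed-controlled;
  identical configuration and seed reproduce results bit-for-bit.

## Known limitations

* The shared-frequency rule cannot distinguish genuine coupling from a common
  driver or volume conduction; this is a property of the method itself, not
  of the implementation.
* The G(n, m) reference is resampled per distinct (n, m) with a fixed seed
  per analysis; with `n_rand = 50` the reference mean carries Monte-Carlo
  error of a few percent, which propagates into C_rel and L_rel.
* The sum-of-ranks composite excludes subjects with no non-degenerate seconds
  (no defined C_rel/L_rel); in cohorts dominated by iso-electric recordings
  the composite is computed on the remaining subjects.
* At desk-scale cohort sizes (10 + 10) the exact rank-sum p-value is bounded
  below by 2/C(20,10) ≈ 1.1 × 10⁻⁵, whereas a t statistic on a cleanly
  separated metric can fall below that bound; the composite's advantage over
  single metrics is therefore less categorical than in a 56-subject cohort.

## A worked example

```{r, eval = FALSE}
library(sfnet)

cfg <- default_config(seed = 1, out_dir = "cohort")
run_simulate(cfg)   # EDF files + metadata + manifest
run_analyze(cfg)    # per-epoch network metrics
rep <- run_report(cfg)

subset(rep$contrasts, window_h == 72)
rep$roc[["72"]]$sens_at_full_spec
```
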