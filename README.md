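# dyadvr

Trajectory analysis for dyadic fight-like interaction between two zebrafish
in a closed-loop virtual-reality arena.

Two head-fixed adult fish each swim through a shared circular VR space
(radius 100 units) in which they see a 3D avatar of the other; every
30-minute trial leaves a frame-aligned log (10 Hz) of each fish's position,
heading, forward speed and turning speed. `dyadvr` turns those paired logs
into the complete behavioral readout of the paradigm: who approaches whom,
who bites, which eye each fish uses to watch its opponent, how strongly the
pair is attracted, and in which direction behavioral information flows —
plus a discrete-event simulator of the shock protocol that motivates the
fight, and a synthetic trajectory generator so that every stage of the
pipeline can be tested against known ground truth.

## The statistics at the core

With the opponent's relative bearing θ ∈ (−180°, 180°] (negative = left),
frames are labeled LEFT (θ ∈ [−135°, −30°)), BINOCULAR (θ ∈ [−30°, 30°]),
RIGHT (θ ∈ (30°, 135°]) or BLIND. From the frame counts N(·):

- **Eye percentages** — LEP = 100·N(left)/D, FBVP = 100·N(binocular)/D,
  REP = 100·N(right)/D with the common denominator
  D = N(left) + N(right) + N(binocular); they always sum to 100.
- **Left eye index** — LEI = (N(left) − N(right)) / (N(left) + N(right)),
  monocular frames only; +1 is exclusive left-eye use.
- **Near rate** — percentage of frames with inter-fish distance ≤ 50 units;
  **center occupancy** — percentage of frames inside the 70-unit inner
  circle (half the arena's area).
- **Attraction** — (mean(d_shuffled) − d_real) / mean(d_shuffled), where
  d_shuffled is the mean inter-fish distance after randomly permuting one
  fish's position frames (10 shuffles); positive = closer than chance.
- **Approach episodes** — peak-to-valley spans of the mutual-distance
  series in which the distance keeps falling, the approacher is the faster
  fish on average, and the target stays inside its ±90° front cone; ties in
  speed are assigned to neither fish.
- **Bites** — rising-edge collisions of the mouth with the opponent's
  mid-body at an inclination within ±75° of the perpendicular to the
  opponent's body axis; a multi-frame collision counts once.
- **Transfer entropy** — T(P→Q) = H(Q_t | Q_hist) − H(Q_t | Q_hist, P_hist)
  (plug-in estimate, bits, history L = 1 frame) on three symbolizations:
  the 4-symbol merged ethogram (signs of frame-to-frame speed and heading
  change), and 5-level percentile-binned speed and turn (5/35/65/95%
  cuts). ΔTE = T(P→Q) − T(Q→P) is the net flow.
- **Group comparisons** — Wilcoxon signed-rank (within-fish conditions) and
  rank-sum (between groups) with the standardized mean difference
  E = (μ₁ − μ₂)/σ, σ taken over both samples pooled.

The shock protocol: both fish get 0.5 V for 300 ms every second from trial
start; a bite delivers 4 V for 100 ms to the bitten fish and suspends the
biter's periodic stimulus for 2 minutes.

## Worked example

```r
library(dyadvr)
cfg   <- arena_config()                       # geometry + protocol defaults
trial <- generate_dyad(sim_params(n_frames = 6000, seed = 11,
                                  attraction_gain = 0.05,
                                  coupling_gain = 0.6),
                       cfg, condition = "shock")
trial_metrics(trial, cfg, seed = 11)
```

```
Trial metrics for 'pair1' (shock)
  mean mutual distance 43.67, attraction 0.3763, near rate 63.4%
  approaches 196, bites 13
  fish a: center 73.0%, attack posture 18.1%, LEP/FBVP/REP 37.6/7.1/55.3, LEI -0.191
  fish b: center 70.5%, attack posture 19.0%, LEP/FBVP/REP 36.5/6.6/56.9, LEI -0.217
  TE (merged ethogram) a->b 0.2531, b->a 0.0213 bits
```

The simulated pair was built attracted (gain 0.05) and speed-coupled a→b
(gain 0.6), and the metrics recover exactly that: attraction is well above
the independent-walk value of ≈ 0, nearly two thirds of frames are "near",
and the merged-ethogram transfer entropy is an order of magnitude larger in
the a→b direction than the reverse. Each fish's eye percentages sum to 100
by construction.

Episode-level output and the shock schedule driven by the detected bites:

```r
eps <- detect_approaches(trial, cfg)
head(proximity_split(eps, cfg), 3)
#>   approacher start_t end_t remaining_distance terminal_bite proximity
#> 1          b       3    45           29.42055         FALSE   neither
#> 2          b      67    84           14.08431         FALSE      high
#> 3          a     122   136           16.21878         FALSE      high

stimulus_summary(simulate_stimulation(detect_bites(trial, cfg),
                                      600000, cfg))$a
#>   voltage on_ms       duty
#> 1     0.5 40000 0.06666667
#> 2     4.0   600 0.00100000
```

Fish a was bitten 6 times (six 100-ms 4-V transients) and earned enough
2-minute relief windows from its own bites that its mild-stimulus duty
fraction dropped from the no-bite 0.30 to 0.067.

Real logs are read with `read_trial()` (long-form CSV:
`frame,fish_id,x,y,heading,speed,turn`), batches with `analyze_trials()`,
and group tables compared with `compare_metrics()`.

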