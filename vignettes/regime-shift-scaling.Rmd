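---
title: "Methods: size-duration scaling of ecological regime shifts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: size-duration scaling of ecological regime shifts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecoshift)
```

## The statistical model

The package's central object is the allometric scaling law between the
spatial extent of a system and the time its regime shift takes:

$$\log_{10} D = a + b\,\log_{10} A + \varepsilon,
\qquad \varepsilon \sim N(0, \sigma^2),$$

with duration $D$ in years, area $A$ in km², fitted by ordinary least
squares (`fit_power_law()`). Base-10 logarithms are used throughout
because both axes of the empirical problem span many decades (areas
roughly $10^0$–$10^7$ km², durations $10^0$–$10^3$ yr). The exponent
$b$ is dimensionless and invariant to the unit of area; only the
intercept $a$ shifts under rescaling, which the test suite checks.

A fit is classified (`classify_fit()`) as *positive* if $b > 0$,
*sub-linear* if the point estimate $b < 1$, and *significant* if the
two-sided t-test of $b = 0$ falls below $\alpha$ (default 0.001).
Sub-linearity is judged on the point estimate, not a confidence bound,
matching how the classification is used in the literature this package
supports.

Predictions (`predict_duration()`) back-transform the t-based interval
on the log scale. Both confidence (mean-trend) and prediction
(new-observation) intervals are available; the **prediction interval is
the default** because, for published headline estimates of the form
"~49 years (95% CI 10–260)" for a $5.5 \times 10^6$ km² system, the
quoted width is consistent with residual-level spread rather than
mean-level spread. This is an interpretive choice and is recorded here
deliberately; users wanting the narrower mean-trend band can request
`interval = "confidence"`.

Two sensitivity analyses probe the robustness of the fitted law.
`jackknife_fits()` refits after deleting each record in turn (42 fits of
41 records for the canonical table; residual df $n-3$ each).
`monte_carlo_fits()` multiplies every duration by an independent draw,
uniform on $[0.5, 1.5]$ by default, and refits; areas are left
untouched because compiled area estimates are far more reliable than
duration estimates. The uniform form of the error distribution is an
assumption — the convention in the source analyses states only the
50–150% range — and both bounds are arguments.

## The synthetic record table

`generate_records()` draws tables with known ground truth so the whole
pipeline is testable without any external data: $\log_{10} A$ uniform
over a configurable range (default $[0, 7]$; log-uniform because the
empirical compilations cover decades of area roughly evenly, which
linear-uniform sampling would not emulate), $\log_{10} D$ linear in
$\log_{10} A$ with Gaussian residuals, and environment labels drawn
multinomially (default marine : freshwater : terrestrial = 25 : 13 : 4).
Defaults are $n = 42$, slope $0.221$, intercept $0.20$ (anchored so a
$5.5 \times 10^6$ km² system falls near 49 yr), residual sd $0.55$.

With these defaults the expected $R^2$ is about $0.40$
($b^2 \mathrm{var}(\log_{10} A) / (b^2 \mathrm{var}(\log_{10} A) +
\sigma^2)$ with $\mathrm{var} = 49/12$); a residual sd near $0.46$
would centre $R^2$ on 0.49. We keep 0.55 as the documented default —
the generator is a structural stand-in, not a replica, and slope
recovery (the property the tests assert) does not depend on the split.
The tuning arithmetic ships in `tools/tune_residual_sd.R`.

What the generator deliberately does **not** emulate: heteroscedastic
duration uncertainty across environments, correlation between
environment and area, measurement rounding, and any clustering of
related case studies. Tests passing on synthetic tables therefore
validate the estimators and plumbing, not conclusions about real
ecosystems.

## Extracting shift durations

For simulators that start in a stable regime (the wolf–sheep model),
the start of a shift is located by a two-segment breakpoint search
(`find_breakpoint()`): all admissible splits of the series into two
intercept-only segments are scored by pooled residual sum of squares
and the minimiser is returned. Piecewise-constant segments (rather than
segmented trends) encode the a-priori model of exactly two regimes — a
pre-collapse plateau and a collapsed plateau. Numerical choices: each
segment must contain at least `ceil(min_seg_frac * n)` points with
`min_seg_frac = 0.15` (the conventional trimming default in structural
change analysis; exposed as an argument because the source analyses do
not state theirs), ties resolve to the earliest split, and the search
is exact (cumulative-sum arithmetic, cross-checked in the tests against
a brute-force enumeration on a thousand random series).

End rules are model-specific (`detect_wsp_shifts()`,
`duration_unstable_start()`): wolf and sheep shifts end at the first
tick of zero abundance, the grass shift when grass covers every cell;
the automaton's single shift ends at the first tick from which the
alive-cell count stays unchanged for 100 consecutive steps (a
count-based rule: configurations that change while conserving their
count, such as a lone blinker, register as stable — this mirrors the
stop rule the automaton experiments define); the network shift ends
when the dominant language saturates; the plankton shift when
zooplankton reach zero. Models that start unstable take tick 0 as the
shift start. Degenerate cases are resolved explicitly: a channel that
*starts* in its collapsed state reports `no_shift` rather than a
zero-length shift, and if the breakpoint falls after the end condition
(a pathologically short collapse) the start is clamped to the end tick
and the event flagged. Runs that never meet their end condition are
`no_shift` and are omitted from scaling fits (`filter_shifted()`).

## The simulators

**Wolf–sheep–grass (`wsp_run()`).** A stochastic grid model: animals
move with a random heading (displacement `mobility` cells, torus
wrap-around), pay `move_cost` energy per tick, eat (sheep consume a
grassy cell, gaining `sheep_gain`; each wolf consumes one co-located
sheep, gaining `wolf_gain`), die when energy drops below zero, and
reproduce with fixed per-tick probability, the offspring receiving half
the parent's energy. Eaten cells regrow after `grass_regrowth_time`
ticks. Within a tick, agents act one at a time in freshly shuffled
order (move, eat, die, reproduce), then grass countdowns decrement.
Defaults are the widely documented settings of the standard library
model (sheep gain 4, wolf gain 20, wolf reproduction 5%, 100 sheep and
50 wolves on a 51×51 world, initial energies uniform on $[0, 2 \times
\mathrm{gain})$), with sheep reproduction fixed at 7% so the system is
unstable and can express its three shifts: wolf extinction, sheep
extinction, progression to full grassland. The initial grass state
(each cell grassy with probability 0.5, otherwise a uniform countdown)
is our documented choice where no convention exists. The core is
compiled (Rcpp) and draws from R's RNG, so runs are bit-reproducible
under a seed. `grass_regrowth_time = 0` (instant regrowth) is allowed
because the published module-size sweep enumerates 101 regrowth values.

**Cellular automaton (`gol_run()`).** Synchronous birth-on-3 /
survive-on-2-or-3 updates on a torus; the von Neumann variant keeps the
same thresholds on the reduced 4-cell neighbourhood, so the
neighbourhood size — the model's fluidity — is the only thing that
changes. A 35% random initial density is inherently unstable and decays
toward a stable count.

**Language-adoption network (`lc_run()`).** Nodes speak language L1 or
L2; every tick, each L2 node samples one neighbour uniformly and adopts
its language; L1 is dominant and can never be lost, so the L1 count is
non-decreasing and the terminal states are all-L1 (the shift) or all-L2
(no shift, only reachable with no initial L1 speakers). Networks are
wired as a random recursive spanning tree (guaranteeing connectivity)
plus uniformly random extra links up to the requested count, with the
effective link count floored at $n - 1$. The update is synchronous
across L2 nodes, and 10% of nodes start with L1 by default — both
documented choices where the original modification is not public.
Degree heterogeneity is measured as the population standard deviation
of node degrees.

**Two-compartment plankton model (`sh_run()`).** Zooplankton $Z$ graze
algae $A_1$ with a saturating (Monod) response while refuge algae
$A_2$ are predation-free; both compartments grow logistically toward
carrying capacity $K$ (the size proxy) and exchange a volume fraction
$d$ per unit time:

$$\dot A_1 = r A_1 (1 - A_1/K) - g Z \frac{A_1}{A_1 + h} + d (A_2 - A_1)$$
$$\dot A_2 = r A_2 (1 - A_2/K) + d (A_1 - A_2)$$
$$\dot Z = e g Z \frac{A_1}{A_1 + h} - m Z$$

Constants: $r = 0.5$, $g = 0.4$, $h = 10$, $e = 0.6$, $m = 0.15$,
$d = 0.05$, all configurable. Integration is fixed-step RK4
(`dt = 0.01`, recorded per unit time step); a continuous flow never
reaches exactly zero, so extinction is operationalised by an absorbing
threshold `z_eps = 1e-6`. The default initial state is algae at
capacity with a unit zooplankton inoculum, $K$ defaults to 10 so the
reference system sits inside the extirpation regime (see Limitations).
Halving `dt` moves reported durations by less than one step, and the
trajectories are cross-checked against an independent adaptive
integrator in the tests.

## Experiments and their presets

`preset()` encodes the published sweep designs. Where the tabulated
design and the narrative description disagree, the presets follow the
table and expose the alternative reading: world-size sweeps use axes
0–100 in steps of 2 (51 × 51 grid points × 100 repeats = 260,100 runs;
`variant = "methods"` gives the 1–99 reading), the module-size sweep
enumerates 6 module heights × 101 regrowth values × 100 repeats =
60,600 runs (a narrative figure of 930,000 runs for this sweep is not
reconstructible from any printed grid and is recorded in the preset's
notes), and the carrying-capacity sweep runs $K = 1..100$ once (the
tabulated count of 101 runs is likewise not constructible from a unit
grid on 1–100). Grid points with zero-sized worlds are attempted and
recorded as error rows rather than silently dropped, so the attempted
run counts match the published arithmetic exactly.

Wolf–sheep sweeps vary the grass regrowth time 1–100 across the
repeats of each grid point and enter it as an additive covariate in the
log–log fit, so the effect of the swept variable is assessed at a given
disturbance rate. Where a run yields several channel durations
(wolves, sheep, grass), the shifted rows are pooled into one fit.
Durations of zero (flagged instantaneous collapses) drop out of the
log–log fit, as do non-positive predictor values (the $d = 0$ point of
the exchange sweep, measured but not loggable).

`run_experiment(spec, scale)` thins both the grid (each axis by
$\sqrt{\mathrm{scale}}^{1/\#\mathrm{axes}}$, keeping the range
endpoints) and the repeat count (by $\sqrt{\mathrm{scale}}$), so total
runs scale by roughly `scale`. Per-run seeds are a stable hash of
(master seed, experiment id, grid values, repeat), making any subset of
runs independently reproducible. The test suite and the acceptance
script use desk-scale replicates sized to run in minutes on one CPU:
size sweeps on 10–100-cell worlds in steps of 10 with 10 repeats
(1,000 runs), node sweeps to 300 nodes, and the two deterministic
plankton sweeps at full published resolution. These sizes are the
package's chosen trade-off between statistical power and a suite a
user can run routinely.

## Known limitations

* **The plankton reconstruction stabilises where the original
  destabilised.** The two-compartment equations above are a
  reconstruction — the original experiments' exact equations were never
  published. Under this reconstruction the predation-free refuge is
  strongly stabilising: zooplankton persist for every $K$ above the
  subsistence threshold $h m / (e g - m) \approx 16.7$, for any
  exchange fraction $d \in [0, 1]$ and any reasonable initial state we
  probed. Consequently the carrying-capacity sweep only produces
  extirpations on the $K \lesssim 16$ branch, where duration diverges
  as the threshold is approached, making the fitted exponent
  super-linear (about 1.19) rather than sub-linear; and the exchange
  fraction is nearly neutral (durations flat in $d$), so the fluidity
  sweep shows no negative effect. The package reports what the
  reconstructed model actually does.
* **Synchronous language adoption saturates fast.** With monotone
  synchronous adoption on a connected random recursive tree, absorption
  takes on the order of the tree depth plus a logarithmic coupon
  effect, so the node sweep's exponent is small and positive (about
  0.3), not super-linear as reported for the original network
  experiments; and adding links speeds mixing slightly (a small
  negative link effect rather than none). No synchronous monotone
  dynamic on a connected graph can stretch absorption to thousands of
  ticks at these sizes, so we attribute the difference to the original
  modification's unpublished update scheme and keep the per-tick
  dynamics the model documentation describes.
* The automaton's count-based stop rule cannot distinguish a genuinely
  stable configuration from one whose oscillations conserve the alive
  count (period-2 oscillators with unequal phase counts keep a run
  alive until the horizon; those runs are `no_shift`).
* Modular runs hold early-stopped sub-worlds at their final counts;
  for the automaton this inherits the count-based stop rule's
  assumption that a stopped module's count would have stayed constant.
* The empirical compilation of real shifts is not redistributable with
  the package; all shipped numbers for the empirical pipeline are
  computed on synthetic tables with known truth, and the documented CSV
  schema accepts a real table wherever one is available.
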