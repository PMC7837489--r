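---
title: "Models and methods behind photokin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind photokin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photokin)
```

photokin quantifies how ambient light shapes fish behavior and gene
expression. This vignette is the package's own account of the models it
implements, the parameters that matter, the numerical conventions chosen
where the underlying assay descriptions are silent, and what the synthetic
data do and do not establish. It states no empirical result that the test
suite and `scripts/acceptance.R` do not themselves compute.

## Light fields

**Photon flux.** Assay light levels are usually reported as a "sum of
photons" next to a measured emission spectrum. Given spectral irradiance
$E(\lambda)$ in W·m⁻²·nm⁻¹ on a sampled wavelength grid, `photon_flux()`
computes

$$N = \int E(\lambda)\,\frac{\lambda}{hc}\,d\lambda
\quad [\text{photons·m}^{-2}\text{s}^{-1}],$$

with $hc = 1.98645\times10^{-25}$ J·m. Spectrometer exports are tabulated,
so the integral is evaluated by the trapezoidal rule over the full measured
range — the standard choice for tabulated spectra; no integration rule or
wavelength bounds are ever quoted alongside published photon sums, so this
convention is documented here rather than inferred. A single-sample
(monochromatic) spectrum cannot be integrated and requires an explicit
bandwidth. Flux is linear in irradiance, and neutral-density attenuation is
plain multiplication (`scale_intensity()`), which is how a full screen at
$2.2\times10^{13}$ photons·m⁻²·s⁻¹ dimmed to 35% yields
$0.77\times10^{13}$.

**Michelson contrast** between a dot and its background,
$(L_{max}-L_{min})/(L_{max}+L_{min})$, is dimensionless and exactly
invariant to a common rescaling of both luminances — which is why screen
dimming (both luminances scaled together) changes the photon flux but
barely changes the contrast (0.93 at the standard 35% setting's measured
luminance pair).

**Schedules** are ordered, contiguous, half-open intervals
$[t_0, t_1)$ labeled with a light condition, so every time point belongs
to exactly one interval and interval durations add up exactly. An
acclimation phase (5 min of darkness before the photokinesis blocks)
carries a flag and is excluded from analysis aggregation unless requested.
Two canned constructors cover the standard paradigms:
`photokinesis_schedule()` (5 min dark, then 3 × (30 min light + 30 min
dark): 3 h of analysis time) and `diel_schedule()` (2 days of 8 h dark +
16 h light, starting at lights-off, origin ZT 16).

## Dot stimuli and avoidance scoring

Dot diameters are converted from screen pixels to degrees of the larval
visual field with the exact visual-angle formula
$\theta = 2\arctan(s/2D)$ ($s$ physical diameter, $D$ viewing distance).
Published assay descriptions defer the formula to prior work without
reproducing it; the exact form is used here as the documented convention
(configurable via the pixel pitch and distance arguments), and it
round-trips with its inverse to $10^{-9}$ degrees.

A trial presents 7 blocks of 6 dots, one size per block, ascending or
pseudo-randomly ordered with a 19-s inter-block gap. "Pseudo-random" is
implemented as a uniform seeded shuffle of the block sizes, with no further
constraints — none are specified anywhere. The seven default sizes
(5, 10, 20, 30, 40, 60, 80°) are a plausible ladder spanning prey-like to
predator-like angles; published figures show such a range only on axes, so
the ladder is configurable and never asserted against any external value.

Each presentation is scored `approach`, `avoidance`, or `neutral`, and the
avoidance index of a subject at a size is

$$AI = \frac{n_{avoid} - n_{approach}}{n_{total}} \in [-1, 1],$$

with neutrals counted in the denominator ("total number of dots
presented"), so neutral outcomes dilute the index toward zero without ever
flipping its sign, and swapping the approach/avoidance labels negates it.
Cohort tuning curves compute per-subject AI first and then average across
subjects (mean ± SEM) — matching the per-fish presentation of such data —
rather than pooling events. **Total avoidance** is the trapezoidal area of
AI against size *in degrees* (not block index), computed per fish and then
summarized, again because per-fish box plots are the downstream use; the
area over the mean curve coincides with the mean of per-fish areas whenever
all fish cover all sizes.

## Locomotor activity

`distance_series()` turns a tracked trajectory into the quantity the
tracking software reports: distance moved per time bin (10-s bins for
photokinesis, 1-min for diel analyses), aligned to the schedule origin.
Steps between consecutive frames are assigned to the bin containing the
step midpoint; bins are half-open, so the assignment is unambiguous.
Tracking dropouts up to a 1-s tolerance are bridged by the straight-line
step between flanking frames; longer gaps contribute no distance and flag
every bin they touch, and flagged bins are excluded from window means while
still being counted in coverage reports. Total distance is conserved: the
sum over bins equals the sum of raw step lengths (up to excluded gaps).

The **AUC** of an interval is the *sum* of its bin values (units mm), since
each bin already holds a distance; a trapezoid option exists for
comparability but is not the default. Interval boundaries must sit on bin
edges — a misaligned request is an error, never a silent partial bin — which
makes AUC exactly additive over partitions. Per-condition totals pool all
intervals sharing a light condition ("entire light versus dark intervals"),
with per-interval metrics still available; pooling is the documented
reading of AUC-by-condition figures, and the per-interval output covers the
alternative.

The **normalized fast dark-photokinesis response** is the mean per-bin
distance in the first 120 s after a light-to-dark transition divided by the
mean per-bin distance over the last 5 min of the darkness preceding that
light interval — in the standard paradigm, the dark acclimation. Division
(not subtraction) is used: the point of the normalization is to compare
response *rates* across genotypes with different baselines, and a ratio is
invariant under any common rescaling of distances such as a camera
recalibration. A zero baseline yields a flagged `NA`, not an error, because
an immobile-at-baseline fish is data, not a malfunction.

**Lights-on windows**: for every dark-to-light transition of a diel
schedule, the AUC over the first 30 and 90 min of light. Windows are
nested by construction, and a window longer than its light interval is an
error.

## The statistical decision tree

`compare_groups()` reproduces the two-sample test-selection procedure used
throughout this assay literature:

1. **Normality gate.** D'Agostino–Pearson $K^2$ on each group. The test's
   moment transforms are only defined for $n \ge 8$; with fewer
   observations in either group the comparison routes directly to
   Mann–Whitney, and the bypass is recorded in the decision trace. (The
   source procedures are silent about this case; defaulting to the
   distribution-free test is the conservative completion.)
2. **Variance gate.** For two normal groups, a two-tailed F-test
   ($F = s^2_{larger}/s^2_{smaller}$, $p = \min(1, 2P(F \ge f))$) decides
   between the unpaired Student t (equal variances) and Welch t
   (Welch–Satterthwaite df). At equal group sizes and exactly equal sample
   variances the Welch df collapses to $n_1 + n_2 - 2$ and both tests
   coincide — an identity the test suite asserts. (Welch p ≥ Student p is
   *not* generally true and is not asserted.)
3. Both gates use α = 0.05. No α for these gates is stated in the
   procedures this mirrors; 0.05 is the conventional choice and is
   configurable (`alpha_gate`).

The $K^2$ implementation follows the published skewness (D'Agostino 1970)
and kurtosis (Anscombe–Glynn 1983) z-transforms; it was cross-checked
during development against an independent implementation
(`scipy.stats.normaltest`) and frozen fixtures keep it honest to 12
decimal places. Its null rejection rate under Gaussian samples, and that of
the whole decision tree, is Monte-Carlo calibrated in the tests to
$0.05 \pm 0.015$.

**Mann–Whitney.** The two-tailed p is the doubled smaller tail probability
of $U$ under the permutation null, capped at 1. Whenever
$\binom{n+m}{n} \le 2\times10^5$ (every $n+m \le 12$ case and many more),
the null is enumerated exactly over rank assignments using midranks, so
ties are exact too; tie-free samples up to $n, m \le 50$ use the exact
closed-form $U$ distribution; everything else falls back to the normal
approximation with midrank tie correction and no continuity correction.
A literal "enumerate when $nm \le 400$" rule would require
$\binom{40}{20} \approx 10^{11}$ assignments at $n=m=20$; the
combination-count gate is the feasible reading, and the exact coverage is a
superset of what small-sample assays need. An independent brute-force
oracle (pairwise-comparison $U$, full enumeration) verifies the exact
branch over seeded batteries of 200 sample pairs.

Stars follow the boundary-inclusive mapping
`* ≤ 0.05, ** ≤ 0.01, *** ≤ 0.001, **** ≤ 0.0001`; all p-values are
two-tailed. No multiple-testing correction is applied by default, matching
the source procedures.

## qPCR quantification

Technical replicates are averaged on the Ct scale (the duplicate-well
design), then $\Delta Ct = \overline{Ct}_{target} -
\overline{Ct}_{reference}$ with *beta-actin* as the default reference and
relative expression $2^{-\Delta Ct}$. Amplification efficiency is fixed at
2.0 per cycle (intron-spanning assays, no efficiency reported; the
`efficiency` argument exposes it). Fold changes divide by the *geometric*
mean of the control (wild-type) group — standard ΔΔCt practice — which
anchors the control group at fold 1 and makes every fold invariant to a
global Ct offset (plate effects); both $2^{-\Delta Ct}$ and folds are
emitted, since "relative mRNA level" plots can be either. Circadian
peak/trough calls are the argmax/argmin over raw sampled timepoints with
no smoothing (published arrows mark sampled curve features); ties break to
the earliest time and are flagged, and a constant series is flagged as
having no extremum.

## The synthetic-data generator

The generator exists so that every analysis stage is testable without raw
tracking data; it is a stated world, not a fit to any dataset.

**Swim model.** A rest/move two-state continuous-time Markov chain. The
rest-to-move rate depends on the light condition (defaults: 0.04 s⁻¹ in
darkness, 0.10 s⁻¹ in light — fish of this type swim less in the dark);
the move-to-rest rate is 1.0 s⁻¹ (about one-second bouts); bout speeds are
log-normal (meanlog log 20 mm/s, sdlog 0.35); headings diffuse at
1.5 rad/√s, and the arena is a 35-mm square (a 6-well plate well).
Long-run move occupancy is $r_{on}/(r_{on}+r_{off})$ and the expected
distance rate is occupancy × mean speed (`swim_expectations()`), which the
tests verify by Monte-Carlo within 3 standard errors. A mutant genotype
multiplies the condition-specific rest-to-move rates; because rest
dominates ($r_{on} \ll r_{off}$), a 1.5× multiplier produces an AUC ratio
of $\frac{1.5 r_{on}}{1.5 r_{on}+r_{off}} / \frac{r_{on}}{r_{on}+r_{off}}
\approx 1.47$, and it is this closed-form value the recovery experiment is
compared against.

Arena walls are emulated by folding the unconstrained path into the arena
rectangle (triangle-wave reflection). A frame-to-frame step crossing a wall
is recorded as the chord, not the bounce path — exactly the truncation a
video tracker produces — so closed-form distance checks run in a large
arena where bounces are negligible.

**Avoidance model.** Logistic size tuning on log dot size:
$P(avoid) = L\,\sigma(a(\ln\theta - \ln\theta_0))\,h^k$ with ceiling
$L = 0.9$, slope $a = 3$, threshold $\theta_0 = 25°$, habituation
$h = 0.9$ per prior exposure to dots ≥ 40°, and
$P(approach) = A(1-\sigma(\cdot))$ with $A = 0.4$; the remainder is
neutral. Habituation to early large dots is what shifts a pseudo-random
curve relative to an ascending one; with $h = 1$ the orders are exactly
equivalent, which the tests assert. `expected_avoidance()` exposes the
closed-form expected AI per size (habituation counts accumulated along the
plan), and simulated cohorts converge to it within 3 SE.

**qPCR plates.** $Ct = base_{ct} - \log_2(expression) + N(0, \sigma)$ with
$\sigma = 0.15$ cycles of technical noise, duplicates sharing a sample's
expression, and 0.2 log2 units of biological scatter. Fold-change recovery
is unbiased on the log2 scale (asserted over 500 simulated plates); the
fold itself carries the usual small convexity bias of exponentiating noisy
logs, which is why the unbiasedness test works on log2 folds.

**Seeding.** A single master seed fans out to per-subject substreams (an
integer hash of the subject index and genotype), so cohorts are
order-independent and bit-reproducible; the caller's RNG state is always
restored.

**What a green test establishes — and what it does not.** The simulator
produces the *statistical structure* the analyses assume: light-modulated
two-state activity, size-tuned categorical outcomes, Ct noise. It does not
emulate the transient kinetics of the real dark-photokinesis surge (the
two-state rates change instantaneously at light transitions, with no decay
over continued darkness), visually guided pursuit, wall-following, or
startle kinematics. Green pipeline tests therefore establish correctness of
the computations and recoverability of configured effects, not behavioral
realism.

## Computational scaling choices

Two deliberate scale-downs keep the default test and acceptance runs inside
desk-scale budgets, neither affecting what is measured:

* The 200-cohort recovery experiment simulates at 5 frames/s instead of the
  tracker's 60 frames/s. Per-frame displacement is speed/frame-rate, so
  binned distances, the dark/light AUC ratio, and the test decision are
  frame-rate invariant; only compute changes.
* Module-level Monte-Carlo property tests use smaller batteries (60 pairs,
  100 fish) than the acceptance criteria (200 pairs, 200 fish), which run
  at full size in `test-acceptance.R` and `scripts/acceptance.R`.

## Known limitations

* The visual-angle formula and the seven-size ladder are conventions, not
  measured values; both are configurable.
* The F-test gate is itself normality-sensitive; it is only ever applied
  after the normality gate passes, mirroring the procedure it implements.
* The exact Mann–Whitney branch is bounded by the $2\times10^5$-assignment
  enumeration gate; beyond it, tied data fall back to the corrected normal
  approximation.
* `total_avoidance()` requires at least two dot sizes per subject (a
  single size has no area) and errors rather than guessing.
* The dark-response baseline is the darkness preceding the analyzed light
  interval; schedules without such darkness are rejected rather than
  silently substituting another window.
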