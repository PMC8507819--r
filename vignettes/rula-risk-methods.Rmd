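---
title: "Automated RULA scoring and time-weighted ergonomic risk statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated RULA scoring and time-weighted ergonomic risk statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rulatime)
```

## The problem

Dental professionals work for hours in near-static, strongly flexed seated
postures, and musculoskeletal disorders are endemic in the profession. The
Rapid Upper Limb Assessment (RULA) is the standard observational instrument
for grading such postural load: posture bands for the upper arms, lower
arms, wrists, neck, trunk and legs are scored, combined through three
lookup tables (A: arm/wrist; B: neck/trunk/legs; C: grand score), and
adjusted for muscle use (static holds or repeated action) and force. The
grand score runs from 1 (acceptable) to 7 (investigate and implement change
immediately).

Applied frame by frame to joint-angle time series from inertial motion
capture, RULA stops being a worst-posture snapshot and becomes an exposure
measure. `rulatime` implements that analysis chain:

1. **Frame-wise scoring** of joint-angle recordings (24 Hz analysis rate,
   decimated from the 240 Hz acquisition rate) on both body sides.
2. **Time-in-score statistics**: the relative time spent in each score
   value; the *relative average risk score over time* (rel. av. RST),
   $\mathrm{RST} = \sum_v v \cdot \hat p_v$ where $\hat p_v$ is the
   fraction of frames at score $v$ (identically the mean frame score); and
   the *ergonomic risk potential*
   $\mathrm{ERP} = \mathrm{RST}/\max(\text{score}) \times 100\,\%$, which
   makes outcomes with different maxima (7 for the grand score, 6 for
   neck/trunk/upper arm/wrist, 3 for the lower arm) comparable.
3. **Comparison design**: Friedman tests across the four dental workplace
   concepts (DWCs) within occupation, Conover-Iman pairwise post-hocs with
   Bonferroni-Holm correction, and Mann-Whitney U tests between dentist (D)
   and assistant (DA) within each concept.
4. A **semi-Markov posture simulator** that generates paired D/DA cohorts
   with known ground truth, so every stage is testable without access to
   the original motion-capture recordings.

## Scoring conventions

The worksheet's verbal categories need numeric commitments before a script
can apply them; these are the package's choices, all configurable through
`rula_config()`:

* **Sign conventions.** Flexion positive, extension negative; wrist
  deviation is an absolute radial/ulnar angle. Motion-capture exports with
  other conventions need a per-channel sign map before import.
* **Band boundaries are closed on the lower-risk side**: 20° of upper-arm
  flexion scores band 1, not band 2. The worksheet figure is silent on
  boundaries; fixing them makes results reproducible.
* **Worksheet adjustments** ("twisted", "side bending", "deviated",
  "abducted") use symmetric absolute thresholds, default 10° for neck/trunk
  rotation and side-bend and wrist deviation, 45° for upper-arm abduction
  (strict inequalities). Supplied flag columns always win over derived
  flags.
* **Wrist reporting score.** Steps 3 and 4 are combined for reporting as
  posture + twist, which yields the documented step maximum of 6. Table A
  is still indexed by the separate posture and twist scores — the combined
  value is a reporting outcome only.
* **Trunk score 1** requires being seated, trunk supported, and within a
  ±10° neutral band; any measured wrist flexion leaves the wrist neutral
  band (default half-width 0°), the conservative choice for continuous
  joint-angle data.
* **Muscle use** (+1 to each table score) is operationalised for
  continuous data: a frame is *static* when every driving angle channel
  (upper-arm, lower-arm and wrist flexion for group A; neck and trunk
  flexion for group B) stayed within 5° over the full trailing 60 s
  window, and *repeated* when the driving table score crossed bands at
  ≥ 4/min over the trailing window. Frames with less than one full window
  of history cannot be static (a hold shorter than the window is not a
  hold), while the repetition rule is a rate and uses the available
  prefix. Hold detection is evaluated at 1 s resolution for linear cost.
* **Force/load** defaults to 0: dental instruments weigh well under 2 kg
  and are held intermittently.
* **Legs** default to supported (score 1): all four workplace concepts are
  seated with both feet on the floor.
* The reporting **grand score per frame is the worse of the two sides**;
  per-side grand scores are also available.

## Statistics

Per subject and outcome, the frame scores reduce to median, IQD
(Q3 − Q1, linear-interpolation quantiles, `type = 7`), rel. av. RST and
ERP. Group cells aggregate per subject first — median/IQD of the
subject-level medians and the mean of subject-level rel. av. RST — because
the reported spread statistics are spreads *across subjects*, not frames.
Rounding (half-up, two decimals) happens only at the reporting layer.

The concept comparison uses the tie-corrected Friedman statistic
$\chi^2 = (k-1)\sum_j (R_j - n(k+1)/2)^2 / (A - nk(k+1)^2/4)$ with
$A = \sum_{ij} r_{ij}^2$, referred to $\chi^2_{k-1}$; an exact enumeration
mode over all $(k!)^n$ within-block permutations exists for small cohorts.
Conover-Iman post-hocs use
$t = (R_i - R_j)\big/\sqrt{2n(A-B)/\big((n-1)(k-1)\big)}$ with
$B = \sum_j R_j^2/n$, on $(n-1)(k-1)$ degrees of freedom, implemented from
the formula. Mann-Whitney U uses mid-ranks, exact enumeration of all
labelings for combined $n \le 12$ (valid under ties), and a tie- and
continuity-corrected normal approximation otherwise.

Two multiplicity choices were genuinely open and are fixed as: Holm within
the 6 pairwise concept contrasts of one outcome, and Holm within the 9
outcomes of one concept for the occupation tests — the families the annotation style of the
field's risk tables implies. Conover-Iman p-values are computed
unconditionally but reported alongside the Friedman gate, and a contrast is
only "favored" when both the gate and the Holm-adjusted p pass α = 0.05.
All tests are two-sided, with direction reported separately.

## What the simulator emulates — and what it does not

Recordings are semi-Markov trajectories over a small library of posture
states (`dental_posture_states()`): dominant close-up treatment work,
instrument reaching, short observation pauses, forward trunk-lean work and
a rare neck-neutral posture. Explicit exponential dwells (means 25–90 s)
rather than per-frame transitions matter because the muscle-use rule
depends on hold durations. The default library was designed once so that
the scored cohort reproduces the qualitative exposure profile of real
cooperative dental work: the grand score saturates (score 7 for ~95–97% of
frames), lower arms and wrists carry the highest step-score ERP, the neck
an intermediate one, upper arms and trunk the lowest, with small
concept-dependent shifts.

Angle noise is decomposed into a per-dwell posture offset (sd 3°) plus
small within-hold jitter (sd 0.5°). The decomposition is deliberate: a held
posture wanders slowly, while white frame-level noise of sd 3° would sweep
an ~18° range over a minute and could never satisfy the 5° static-hold
tolerance — the static muscle-use rule would be unreachable. State means
are placed ≥ ~8° from band boundaries so dwell offsets rarely hop bands.
Flags are drawn once per dwell.

The designed concept effect mirrors the one concept effect consistently reported for real dental cohorts: the
12 o'clock concept relieves the dentist's neck. For dentists in DWC 4 the
neck-neutral state's occupancy log-weight rises by +2.2, lowering expected
neck rel. av. RST by ≈ 0.25 score units, the size such concept effects
reach in practice. The magnitude was fixed after an up-front power simulation at the
study scale (75 pairs, 300 s tasks): +1.5 (≈ 0.1 units) was detected
inconsistently, +2.2 was detected in every replicate; it was frozen before
the validation suite was written. Per-subject random occupancy effects
(log-weight sd 0.3) are shared across a subject's four tasks, so
within-subject contrasts stay paired.

Each generated recording carries a ground-truth ledger: its realized state
occupancy and the *implied expected* rel. av. RST per outcome, computed in
closed form — per-channel Gaussian band probabilities combined through the
actual lookup tables, with muscle-use indicators taken from the engine run
on the noiseless designed trajectory. This is an independent probability
oracle for the engine: the scored cohort must match it to within
Monte-Carlo error (the suite allows 3 standard errors with an absolute
floor of 0.002 score units, the resolution below which rare band-hop
events cannot be distinguished from zero in finite recordings).

What the simulator does **not** model: biomechanically coupled joint
angles (channels are independent within a state), task structure beyond
occupancy (no treatment protocol sequencing), inter-subject differences in
posture *angles* (only occupancy varies), sensor drift, or soft-tissue
artifacts. Passing tests therefore validate the scoring and statistics
machinery and the recovery of designed exposure structure — they do not
certify accuracy on any particular motion-capture system's output.

## Numerical and degenerate-input choices

* Timestamps must advance by 1/rate within 1 µs; larger gaps are integrity
  errors, never silently spanned. Decimation (e.g. 240 → 24 Hz) keeps every
  k-th frame without anti-alias filtering — scores are threshold functions
  and the motions are slow, so filtering would only blur band crossings.
* The CSV writer prints 17 significant digits, so recordings round-trip
  bit-exactly.
* All-tied Friedman blocks give $\chi^2 = 0,\ p = 1$; two identical
  conditions give a Conover-Iman statistic of 0 and p = 1.
* Exact Mann-Whitney two-sided p is $2\min(P(U \le u), P(U \ge u))$ capped
  at 1.
* Cohorts below two pairs skip the comparison stage with a warning instead
  of failing the whole run.
* Problem sizes in the validation suite: the worksheet-oracle equivalence
  runs 10^5 random frames on a 5° grid; the null-calibration check uses
  2000 simulated 15-subject cohorts at the summary level; parameter
  recovery runs the full 75-pair, 300 s study scale once.

## Known limitations

* The combination rule for the combined wrist score and the exact flag
  automation of the original motion-capture scoring scripts are not
  publicly documented; the choices here are documented above and configurable, but
  absolute score levels can shift under other conventions.
* The chi-square reference for the Friedman gate is slightly conservative
  at small n because ranks are discrete; the family-wise error of the
  gated post-hoc chain sits below the nominal 5% rather than at it.
* ERP compresses outcomes with different maxima onto one scale; it is a
  reporting convenience, not a calibrated probability of harm.
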