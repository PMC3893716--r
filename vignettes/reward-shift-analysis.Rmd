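---
title: "Modelling reward-shift sensitivity and risky choice in a two-port operant task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling reward-shift sensitivity and risky choice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskshift)
```

## The behavioral design

`riskshift` models a two-port operant task for rats. A centrally placed lever
produces one of three cues: a left light (forced-choice left), a right light
(forced-choice right), or both lights (free-choice). Forced trials guarantee
that the subject keeps sampling both reward ports; free-choice trials measure
preference. The full protocol a subject runs through is:

1. **Pavlovian conditioning** — five sessions of cue-port pairings. In
   sessions 1–2 reward is eventually obtained regardless of the first
   response; from session 3 it is contingent on a correct first response.
   The original sessions were limited to 60 minutes; the package has no
   timing model, so a configurable fixed trial count (default 60 trials per
   session) replaces the duration limit.
2. **Baseline lever pressing** — six sessions at two boluses per side,
   used for forced-choice accuracy (180 trials each: 60 free-choice,
   60 forced-left, 60 forced-right, the structure of every later session
   unless stated).
3. **Large shifts** — an upshift session (2 → 4 boluses on the side the
   subject chose on a minority of the first 21 free-choice trials), a full
   follow-up session at the shifted sizes (a discrimination measure), then a
   downshift session (the 4-bolus side → 1). These 180-trial sessions shift
   after the 21st free-choice trial.
4. **Small shifts** — after two retraining sessions at three boluses per
   side, a downshift session (3 → 2 on the side *opposite* the large-shift
   side; 240 trials: 80/80/80), a discrimination session (3 vs 2), an
   upshift session (the 2-bolus side → 4, giving a 3-vs-4 contrast), and a
   final discrimination session (3 vs 4). All shifts trigger after 21
   free-choice trials.
5. **Risk aversion** — three conditions in which a "safe" port always pays
   2 boluses while a "risky" port pays 1 or 7: risky-better
   (75%/25%, mean 2.5), even (5/6 and 1/6, mean exactly 2) and safe-better
   (90%/10%, mean 1.6). Each condition runs 3 training + 2 test sessions,
   swaps the risky side once, and repeats (10 sessions per condition).
   Half of each cohort starts with risky-better and half with safe-better;
   the even condition always runs second.

`build_protocol()` lays this out per subject; `validate_plan()` asserts the
structural invariants (session counts, the train/test/swap pattern, the
counterbalancing). Trial types within a session are a uniformly random
permutation of the fixed pool, so per-type totals are exact.

## The agent

Each subject is a delta-rule learner over per-port action values $Q_L, Q_R$
in bolus units. After obtaining $r$ boluses on the chosen side,
$\delta = r - Q$, and $Q \leftarrow Q + \alpha^+\delta$ for $\delta \ge 0$,
$Q \leftarrow Q + \alpha^-\delta$ otherwise. Free choices are softmax with
inverse temperature $\beta$ (per bolus); forced trials err with a fixed
`lapse` probability (errors yield no reward and, by default, no update — an
update toward zero is available via `update_on_forced_error`). Pavlovian
responding tracks an associative strength $v \in [0,1]$ with
$P(\text{correct}) = 0.5 + 0.5v$ and a Rescorla–Wagner update
$v \leftarrow v + \alpha_{pav}(1 - v)$, applied on every trial in the
non-contingent sessions and only after correct trials thereafter.

With $\alpha^- > \alpha^+$, the rare large payoff of the risky port is
underweighted relative to the frequent small one, so the agent's asymptotic
value for the risky side sits below its expected value: risk aversion emerges
from the learning asymmetry with utility strictly linear in boluses. No
curvature parameter is used.

### Value carry-over and phase boundaries

Action values persist from session to session **within** a protocol phase —
in particular across the small-shift run (downshift → discrimination →
upshift → discrimination), where no retraining intervenes and the upshift
baseline must reflect the previously learned 3-vs-2 contrast. At phase
boundaries where the protocol interposes (re)training to a stable baseline,
values are re-initialized **to the incoming baseline schedule's per-side
values** (e.g. 3/3 before the small shifts, 2/2 before each risk block). This
models the completed retraining directly rather than simulating it from
arbitrary starting values; it matters because an agent with a very small
$\alpha^+$ cannot re-learn values upward within a realistic number of
retraining trials, and carrying stale values forward would silently erase
the downshift contrast the protocol is designed to measure.

### Default cohorts and their calibration

`default_cohort_config()` defines 11 "cLH-like" and 13 "WT-like" subjects.
Per-subject parameters are drawn from per-group normal distributions and
clipped to their legal ranges:

| parameter | cLH-like (mean ± sd) | WT-like (mean ± sd) | units |
|---|---|---|---|
| $\alpha^+$ | 0.002 ± 0.001 | 0.065 ± 0.005 | per prediction error |
| $\alpha^-$ | 0.18 ± 0.03 | 0.012 ± 0.003 | per prediction error |
| $\beta$ | 1.0 ± 0.08 | 1.0 ± 0.08 | per bolus |
| $\alpha_{pav}$ | 0.005 ± 0.002 | 0.015 ± 0.005 | per trial |
| lapse | 0.05 ± 0.02 | 0.12 ± 0.03 | probability |

These are **calibration choices of the simulator, not estimates from any
animal**. Two of them deserve justification:

- *Rates are small.* The shift metrics are block-based: the downshift delta
  is read at block 2, by which point forced trials alone have delivered
  roughly fifty samples of the shifted side. With textbook rates
  ($\alpha \approx 0.1\!-\!0.3$) both cohorts fully converge before the
  scored block and the group contrast vanishes; the rates are therefore set
  so the control group is still mid-transition when the blocks are scored,
  while the biased group's $\alpha^-$ has already carried it to asymptote.
- *The control group is mildly optimistic* ($\alpha^+ > \alpha^-$). A single
  symmetric control rate cannot be simultaneously slow enough to remain
  mid-transition at downshift block 2 and fast enough to show a clear
  upshift response by block 1. Giving the control group a positive learning
  bias resolves both orderings and is consistent with control subjects
  switching faster after upshifts than downshifts (positive bias scores).
  A side effect is a strongly risk-seeking control cohort; only the
  *ordering* of the groups' risky choice is interpreted.

The cLH-like group additionally conditions more slowly (smaller
$\alpha_{pav}$) and lapses less on forced trials (smaller `lapse`),
reproducing the slower Pavlovian acquisition and higher forced-choice
accuracy of the modelled line.

## Metrics

- **Block preferences** (`block_preferences`): free-choice blocks of
  21/20/20/19 trials for 240-trial small-shift sessions. The block partition
  of the 180-trial large-shift sessions (60 free-choice) is not specified by
  the design, so the package reuses 21/20/19 (baseline/b1/b2, no block 3);
  large shifts are never used for bias scoring. Raw block preference is
  divided by baseline preference, so the baseline block is identically 1. A
  zero baseline preference makes the normalization undefined: the subject's
  values are returned as `NA` with a warning and excluded downstream, never
  an exception.
- **Learning bias** (`learning_bias`): $\Delta U - \Delta D$ with
  $\Delta U$ the signed block-1 change toward the upshifted side and
  $\Delta D$ the signed block-2 change away from the downshifted side, both
  on the normalized scale (consistent with normalized block figures); a raw
  scale option is exposed. Both deltas may be negative if a subject drifts
  the "wrong" way; faster upshift than downshift switching gives a positive
  score.
- **Running preference** (`running_preference`): an 11-trial centered window
  over free-choice trials; at session edges the window truncates (shrinks)
  rather than dropping trials, keeping one value per free-choice trial, and
  truncated positions are flagged.
- **Risky-choice scores** (`risky_choice_scores`): per condition, the
  unweighted mean over the four test sessions of the risky-side free-choice
  fraction; `average_risky` averages the three conditions.
- **Accuracy series** (`accuracy_series`): per-session Pavlovian accuracy
  (five values) and pooled forced-choice accuracy over the six baseline
  sessions.

## Statistics

`mixed_anova()` fits the classical repeated-measures decomposition via
`stats::aov` with `Error(subject/(within))` strata after checking the design
for balance: between effects test against subjects-within-groups, each
within effect and its group interactions against the matching
effect-by-subject stratum. No sphericity correction is applied
(Greenhouse–Geisser is out of scope). The shift analysis includes the
baseline block as a level of the block factor even though it is constant 1
on the normalized scale; a zero-variance level contributes degrees of
freedom without destabilizing the decomposition, and the tests verify this.
Whether the original analysis used normalized or raw preferences for the
ANOVA is not recoverable; both scales are available. `student_t()` is the
pooled-variance two-sample test (two-sided throughout; degenerate
zero-variance samples are flagged rather than raised) and `pearson_r()` the
product-moment correlation with the $t$-transform p value.

## What the simulator does and does not emulate

Simulated logs have the statistical structure the analysis assumes: two
cohorts with distinct learning asymmetries, trial-by-trial choice feedback,
exact trial pools, mid-session shift epochs, counterbalanced risk
conditions, and acquisition curves. They do **not** emulate: reaction times
or any session timing (inter-trial intervals, 60-minute limits, lever
retraction), lever-press training, satiety or motivation drift, perseveration
or side stickiness beyond what value learning produces, or individual
differences beyond independent normal parameter draws. Passing tests on
synthetic cohorts therefore demonstrate that the pipeline recovers the
mechanism it assumes, not that real rats obey this mechanism. One visible
consequence: simulated baseline preference for the to-be-upshifted
(2-bolus) side is low (~0.25–0.3), so normalized upshift preferences are
large and heavy-tailed — the metric definitions are honored as printed, and
their sampling noise at n = 11/13 is why the replication checks are
evaluated as pass *rates* over many seeded cohorts.

## Numerical and reproducibility choices

- Ties in the 21-trial preference used to pick the large-upshift target
  cannot occur (21 is odd); the code still breaks a hypothetical tie toward
  left.
- Softmax probabilities saturate to 0/1 for $|\beta \Delta Q| > 35$.
- Forced-trial side counts are drawn from the whole-session pool; no
  rebalancing occurs after the shift trigger (the pool applies to the whole
  session).
- The master seed drives three independent stages: plan counterbalancing,
  per-subject parameter draws, and per-subject child seeds for simulation,
  so logs are bit-reproducible from config + seed. All internal seeding
  preserves the caller's RNG state.
- Problem sizes in the test suite: oracle checks use 4–8 subject constructed
  tables; property sweeps use 200 agents per parameter point; the
  group-ordering battery runs 100 cohorts of 24 subjects with the Pavlovian
  and baseline phases disabled (they do not enter those four checks, and the
  random streams of later phases are unaffected); the type-I calibration
  uses 1,000 Gaussian null tables of 24 subjects.

## Known limitations

- The learning-bias score inherits the variance of a ratio with a 21-trial
  denominator; for sides with weak baseline preference it is heavy-tailed.
- The mixed ANOVA uses sequential sums of squares via `aov`; with a single
  between factor and balanced within cells this matches the classical
  decomposition, but unbalanced *within* data are rejected rather than
  approximated.
- Agents have no trial-history effects other than value: no win-stay bias,
  no autocorrelated lapses, no cue salience differences.
- The "even" risk condition always runs second, as in the modelled protocol;
  its position is not counterbalanced.
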