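---
title: "Methods: models, conventions and numerical choices in vmicro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and numerical choices in vmicro}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records the modelling assumptions, conventions and numerical
decisions behind `vmicro`, so that every constant and formula in the package
has a stated rationale.

## 1. The pyramid model

A slide image of width $W$ and height $H$ pixels (height-major numeric
array in $[0,1]$ with three channels, the orientation `png::readPNG`
returns) is published as a pyramid of zoom levels $z = 0, \dots, z_{max}$
with

$$z_{max} = \max\!\left(0,\; \left\lceil \log_2 \frac{\max(W, H)}{T} \right\rceil\right), \qquad T = 256.$$

Level $z_{max}$ is the native image; level $z$ has dimensions
$\lceil W / 2^{z_{max}-z} \rceil \times \lceil H / 2^{z_{max}-z} \rceil$ and
is cut into $\lceil \cdot / T \rceil$ tiles per axis, addressed
`{z}/{x}/{y}.ext` with the origin at the top-left — the XYZ layout
web-map clients consume directly. `planPyramid()` computes $z_{max}$ with an
integer doubling loop rather than `log2()` so exact powers of two never fall
victim to floating-point (e.g. $W = 4096$ must give $z_{max}=4$, not 5).

For a square image with $W = H = T\cdot 2^k$ the total tile count has the
closed form $(4^{k+1}-1)/3$; the tests check this, and check every planned
count against a brute-force halving enumeration on a grid of awkward sizes
(255, 257, 1023, 1025, …).

**Downsampling.** Each coarser level is the 2×2 area mean of the level
below, with odd trailing rows/columns averaged over the pixels that exist
(a count-corrected `rowsum`), so brightness is conserved and no phantom
black borders appear. Tests compare a whole downsampled level against an
independent double-loop oracle to within one 8-bit step.

**Edge tiles.** Partial tiles at the right/bottom edges are padded to a
full $T\times T$ with the background colour, never cropped or emitted at
odd sizes. Clients can then assume a constant tile size; the manifest
records the true level dimensions so assembly can trim the padding.

**Fidelity.** The default output is JPEG quality 85 — the usual
bandwidth/quality point for photographic microscopy content. The tests
assert PSNR ≥ 40 dB at quality 95, a standard "visually lossless"
threshold. A `lossless = TRUE` mode writes PNG and must round-trip
pixel-exactly; since PNG is 8-bit, this contract only holds for 8-bit
quantized inputs (see §6 on the synthetic generator).

**Memory.** The tiler holds one full level in memory at a time. That is the
right trade at desk scale (a few thousand by a few thousand pixels); truly
gigapixel sources would need strip-based streaming, which is out of scope
and noted as a limitation.

## 2. Collaborative annotation and vote-driven removal

Markers carry normalized positions ($x, y \in [0,1]$) and the zoom level at
creation, so they are resolution-independent. Voting is deliberately simple
and fully reversible:

* one vote per (voter, marker), re-voting replaces the previous vote;
* score = upvotes − downvotes over current votes;
* a marker is visible to the community iff score ≥ −5, and always visible
  to its own author.

Because visibility is a pure function of the current score, a
"removed" marker returns the moment enough votes change — no state machine,
no tombstone until a course reset. Authors are allowed to vote on their own
markers; forbidding it adds bookkeeping without changing the equilibrium
(one self-upvote shifts the threshold by one, symmetrically for everyone).

Tag-cloud weights use the log bucketing
$w = 1 + \lfloor 4 \ln(1+c) / \ln(1+c_{max}) \rfloor$ clamped to $[1,5]$,
so a single dominant tag cannot flatten all others to weight 1.

**Course reset.** The yearly reset removes student markers and all votes,
retains faculty markers, and optionally bulk-hides the faculty set
(`hideFaculty = TRUE`) so instructors can re-release annotations
progressively during the new course. Removals are tombstoned so that
clients syncing across the reset converge.

**Synchronization.** `changedSince()` reports created/updated/removed
markers since a client's last checkpoint. The checkpoint is a monotone
integer store revision, not a wall-clock timestamp: clocks skew and tie,
whereas a revision gives an exact replay guarantee, which the tests
exercise by replaying random edit sequences through the delta stream and
comparing the reconstruction to the store.

## 3. Exams

Per-student forms are drawn uniformly, one slide per question from that
question's approved exam-tier pool, inside `withSeed()` — the draw is a
pure function of (exam, students, seed) and leaves the caller's RNG state
untouched. Pool slides are sampled independently across questions and
students (with replacement across students), matching how practicals are
actually run: two neighbours may get the same kidney slide, but neither can
predict it. Uniformity is checked with a chi-square test over 3,000
students.

Grading records a credit in $[0,1]$ per question, quantized to
`creditQuantum` (default 0.5 — full/half/no credit, the common practical
convention); the paper score is $\sum_q \text{credit}_q \cdot \text{points}_q$.
Quantum compliance is checked to within $10^{-9}$ so that e.g. 0.75 with a
0.25 quantum is not rejected by floating-point noise.

## 4. Usage analytics

* **Windows are half-open.** A view at exactly 12:00 is *outside* a
  10:00–12:00 lab window; half-open intervals tile the day without double
  counting.
* **Rounding is half-away-from-zero** (`roundHalfAway`), the convention of
  course reports (73.75 → 73.8), not banker's rounding; an epsilon nudge
  guards against representations like 46.875 stored as 46.87499….
* **Spread uses the sample SD** ($n-1$), since a cohort is treated as a
  sample of cohorts.
* **Dwell time** is estimated from the gap to a user's next event, capped
  at 30 minutes (a longer gap means the session ended, not a 3-hour stare),
  with each user's final event backfilled by their median gap. Single-event
  users are excluded — one timestamp carries no duration information. The
  cap censors genuine long inter-session gaps, so recovery is only tested
  on single-session-per-student logs, where the estimator lands within 10%
  of the generating mean. On multi-session logs the estimator is biased
  upward by capped between-session gaps; that is inherent to gap-based
  dwell estimation, not a defect of the implementation.
* **Welch from summaries.** Archived cohort results often survive only as
  (mean, SD, n). `welchFromSummary()` computes
  $t = (m_1-m_2)/\sqrt{s_1^2/n_1+s_2^2/n_2}$ with Welch–Satterthwaite
  degrees of freedom and returns a standard `htest`. It agrees with
  `stats::t.test` to $10^{-9}$ when fed the exact moments of raw samples.
  Note that a test recomputed from *rounded* summaries will not exactly
  reproduce a statistic originally computed from raw scores — with inputs
  like (80.1, 5.38, 165) vs (81.8, 11.9, 164) the recomputed $t$ is
  −1.668; an archived value of −1.69 from the unrounded data is consistent
  with that, so the tests bracket rather than pin such values.

## 5. Rounding and reporting conventions

Percentages that must sum to a whole are computed independently and then
rounded; with two categories and `decimals = 0` the rounded shares can sum
to 99 or 101 in edge cases. The package reports both raw counts and rounded
shares so downstream text can choose; the tests assert the conservation of
raw counts, not of rounded shares.

## 6. What the synthetic generators emulate — and what they do not

`synthSlide()` scatters rotated ellipses in two stain tones (nuclear purple
≈ haematoxylin, cytoplasmic pink ≈ eosin) on a pale background, adds
Gaussian noise with `noiseSd = 0.005` (about one 8-bit grey level, the
scale of scanner sensor noise), clamps to $[0,1]$ and quantizes to 8 bits.
The quantization matters: real scanner output is 8-bit, and the lossless
round-trip contract (§1) is only meaningful for 8-bit data. The images are
*texturally* plausible targets for a tiler and compressor; they are not
histologically meaningful — no tissue architecture, no diagnostic content.

`synthViewlog()` emits session-structured view events: per-student session
counts, gamma-distributed (shape 4) intra-session gaps with a configurable
mean dwell, sessions placed inside or outside a lab window with probability
`pInWindow`, and an evening concentration parameter for the out-of-window
mass. An `exactCounts` mode instead draws independent timestamps with an
exact in/out split, for fixtures whose window shares must be exact by
construction. What it does **not** model: weekday/weekend structure,
exam-week surges, or correlated slide choice within a session.

`synthCohort()` draws truncated-normal scores on $[0,100]$ by rejection —
the truncation is why a generated cohort's moments only approximate the
requested ones, and why tests compare against the *drawn* cohort's mean
with a separate 3-standard-error check against the target.

Problem sizes used in tests and in `scripts/acceptance.R`
(2048 × 1536 fidelity images, 3,000-student uniformity checks,
2,000-simulation type-I error runs) are the package's own choices,
balancing statistical resolution against a few-second runtime.

## 7. Why the design is open and file-based

Every store serializes to line-oriented JSON or CSV, every algorithm is an
exported R function, and the CLI is a thin shim over those functions. The
point is auditability: a course team can read the exact formula that
removed a marker, re-run the grade export, or recompute a usage report from
the raw log, with no opaque service in between. The same property is what
makes the package testable — each contract above has a direct oracle test.

## 8. Limitations

* Whole-level-in-memory tiling: not suitable for multi-gigapixel sources
  without a streaming front end.
* Gap-based dwell estimation is biased upward on multi-session logs (§4).
* The annotation store is single-writer per process; the revision-based
  sync contract assumes one authoritative store, not concurrent replicas.
* Synthetic slides are texture stand-ins, not histology.
* The Welch-from-summary test inherits the precision of its summary inputs.

No empirical quantity is asserted in this vignette beyond what the test
suite and `scripts/acceptance.R` recompute.
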