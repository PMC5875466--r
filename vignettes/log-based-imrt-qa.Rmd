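---
title: "Log-file-based IMRT delivery QA: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Log-file-based IMRT delivery QA: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynaqa)
```

## The problem

In sliding-window IMRT the dose a patient receives is shaped by two opposed
banks of MLC leaves moving continuously while the beam is on. Conventional
patient-specific QA measures each plan on a phantom before treatment, which
costs machine time and — because it compares doses in a phantom, not in the
patient — is hard to interpret clinically. The MLC controller, however,
already writes a complete record of every delivery: per-bank log files with
the cumulative fractional MU ("dose index"), the segment number, and the
planned and recorded position of every leaf, sampled every 55 ms.

`dynaqa` turns that record into a patient-dose QA verdict: it reconstructs
the delivered control-point sequence from the logs, re-renders the delivered
fluence and a forward dose distribution with exactly the same engine used
for the reference plan, and grades the differences. Because both plans go
through the same dose engine, any difference isolates what the delivery did
to the plan; it deliberately says nothing about patient setup, machine
calibration offsets (logs are blind to encoder miscalibration) or absolute
output, all of which need their own QA.

## Data model and file dialects

Positions live on a signed leaf-travel axis X in mm at the isocenter plane:
bank A approaches from $-X$, bank B from $+X$, the aperture of pair $k$ is
the open interval $(A_k, B_k)$, and a closed pair has $A_k = B_k$ (no
sentinel values). The default geometry is a Millennium-style 120-leaf
carriage: 60 pairs, the central 40 pairs 5 mm wide, the outer 2 × 10 pairs
10 mm wide.

Two text dialects are defined in full so the toolkit is self-contained
(vendor formats describe the same content but their exact layout is not
republished here; the control-point dialect is a documented stand-in):

* **Control-point sequence ("dva") files** — `key = value` header
  (`File Rev`, `Plan ID`, `Beam ID`, `Total MU`, `Gantry`,
  `Number of Fields`), then per control point an `Index` in $[0,1]$ and
  `Leaf 1A` … `Leaf 60B` positions in cm with three decimals (0.01 mm).
  The writer is canonical: write–read–write reproduces files byte for byte.
* **Delivery logs** — one file per bank: a header (field id, bank, total
  MU, gantry, hold tolerance, snapshot count, and the planned
  segment-boundary meterset fractions), then one CSV row per 55 ms
  snapshot: time, dose index (an integer scaling of fractional MU by
  25000), segment number, beam-on flag, planned positions in 0.01 mm
  integer units and recorded positions quantized to 0.01 cm — the finite
  recording precision of real MLC controllers. The planned boundary
  metersets are carried in the header because the controller switches
  segment exactly when the dose index crosses them; reconstruction needs
  them and should not have to guess them from the sampling.

## Reconstruction

The delivered sequence is rebuilt as one control point per planned segment
boundary. Within a segment every planned leaf trajectory is linear in
fractional MU, so the planned position at a boundary is obtained by
per-segment least squares of the planned samples against fractional MU —
exact up to the 0.01 mm storage precision. In *actual* mode the delivered
deviation is added as the segment mean of recorded − planned over beam-on
snapshots.

This estimator was chosen over two tempting alternatives:

* interpolating between the last snapshot of one segment and the first of
  the next lands on the kink of the piecewise-linear trajectory; with
  ~0.0055 meterset fraction between snapshots and slope changes of order
  100 mm per unit fraction in modulated fields, it errs by 0.1–0.2 mm;
* least squares of the *recorded* staircase evaluated at the segment end
  amplifies the 0.05 mm quantization noise through endpoint leverage
  (observed worst case ≈ 0.06 mm).

The mean-deviation form has no leverage: its error is bounded by the mean
of per-sample quantization errors (≤ 0.05 mm, in practice ≈ 0.02 mm), it
recovers a constant systematic offset exactly, and it averages zero-mean
jitter down by $1/\sqrt{n}$. Its assumption — that the delivered deviation
is constant within a segment — is precisely the error class log-based QA is
designed to catch. Beam-hold snapshots are excluded; degenerate segments
fall back to snapshot means; collisions created by estimation are pinched
to the pair midpoint with a warning.

In *planned* mode the deviation term is dropped, which round-trips the
original plan and measures the conversion accuracy itself: simulate an
error-free delivery, reconstruct, and every position returns within
0.01 mm and every DVH metric within 0.1% (the package's tests and
`scripts/acceptance.R` recompute this).

## Fluence

`compute_fluence()` renders MU-weighted open time on a regular isocenter
grid (default 1 mm over ±200 mm). For each control-point interval the tips
move linearly in meterset fraction and each pixel accrues
$\Delta\mathrm{MU}$ times the exact time fraction it spends inside the
aperture. The pixel's area-weighted coverage is a difference of two clipped
linear functions of time, each of which integrates in closed form via
$\mathrm{relu}(z)^2/2$, so no time subsampling is involved; a brute-force
renderer with 1000 substeps per interval agrees within 0.1% of the maximum
and serves as the independent oracle in the tests. Rows map to leaf pairs
with area weighting across pair boundaries. Leaf transmission is a single
configurable factor (default 0); tongue-and-groove, rounded leaf ends and
head scatter are not modelled — the comparisons this package makes are
between two maps rendered with the same model, so shared blurring terms
cancel at first order.

## Gamma analysis

`gamma_analysis()` implements the standard dose-difference /
distance-to-agreement composite: per reference pixel the minimum over
displacements $r$ within $3\times$DTA of
$\sqrt{\Delta D^2/\Delta d_c^2 + |r|^2/\mathrm{DTA}^2}$, with the evaluated
map sampled by bilinear interpolation on a 0.1 mm displacement grid. Dose
normalization is global ($\Delta d_c$ = criterion × reference maximum) and
pixels under a low-dose threshold (default 10% of the reference maximum)
are excluded from the passing rate; both are configurable because published
passing rates rarely state them. The search visits displacements by
increasing radius and retires a pixel as soon as its current gamma cannot
be beaten by a larger displacement, which makes the exact search cheap for
well-matched maps. An exhaustive double-loop oracle checks agreement within
0.01 gamma in the tests.

## Dose engine, DVH metrics and chamber dose

The forward engine is a deliberately simple parallel-beam model:
$D(v) = \sum_b \mathrm{MU}_b\, F_b(u, y)\, e^{-\mu\,d(v)}$ with $F_b$ the
beam's fluence at the ray's isocenter-plane coordinates, $d$ the geometric
depth from the phantom surface, and $\mu = 0.005\,/\mathrm{mm}$, a 6 MV-like
effective attenuation. No scatter, buildup or heterogeneity corrections are
modelled. This is not a clinical dose algorithm and is never compared to
one; it is used *identically* for the reference and the reconstructed plan,
so metric differences are attributable to the delivery alone — the same
differential logic that justifies reusing a clinical TPS algorithm for both
plans in practice. The reference plan is scaled to 100% at the isocenter
and the same factor is reused for the reconstructed plan so ratios are
meaningful; a reference plan with no isocenter fluence is refused.

DVH curves are cumulative with 0.1% bins; D98% and D2% (near-minimum and
near-maximum target dose, the quantities recommended for target reporting)
are read off the curve by linear interpolation, and Dmean is the voxel
mean. Point metrics are therefore only defined to the binning resolution;
halving the bin moves them by less than 0.05%. `chamber_dose()` averages
voxels inside a sphere (default radius 3.1 mm, the radius of a 0.125 cm³
active volume), emulating how a small ionization chamber reads out.

## Error injection and the delivery simulator

Three systematic error families reproduce a classic validation design:
symmetric opening expansions (1, 2, 4 mm total), single-bank outward shifts
(0.5, 1, 2 mm), and dropped segments emulating a transient controller
fault. Two readings of the wording behind them are made explicit: an
*expansion* skips closed pairs (expanding a closed pair would create an
aperture the plan never had), while a *bank shift* moves every leaf of the
bank, closed pairs included. Dropped segments keep the surviving meterset
indices (no renormalization): the aperture travels directly between the
surviving control points while their MU budget is still delivered, which is
what a controller skipping data does and why this error barely moves the
total dose.

`simulate_delivery()` emulates the controller: 55 ms snapshots, dose index
advancing at the nominal dose rate (default 600 MU/min; 300 is the other
clinical setting), planned positions interpolated at the current fractional
MU, delivered positions = planned + per-bank systematic offset + zero-mean
Gaussian jitter, colliding pairs pinched as a hardware interlock would, and
recorded positions quantized to 0.01 cm. If any leaf strays beyond a hold
tolerance (default 2 mm — controller dynamics are not modelled further) the
dose index freezes and the snapshot is flagged beam-off. All randomness is
seeded. The pre-quantization trajectory is attached to the record as ground
truth for validation. The fixture generator builds seeded sliding-window
plans (5 beams at 72° spacing, 100 MU and 25 control points per beam,
sweeping a modulated aperture across the central 100 mm) with three
presets: `ramp` (constant 10 mm gap — its plateau fluence
$\mathrm{MU}\cdot g/L$ is a closed form used by the oracle tests),
`pyramid` (analytic cross-pair profile), and `random` (smooth seeded
modulation emulating clinical fields). The phantom preset is a 200 mm
homogeneous cube at 2 mm voxels with a cylindrical target and two
cylindrical OARs, all disjoint and deterministic.

What the simulator does *not* emulate bounds what passing tests prove:
there is no servo dynamics, no gravity dependence, no correlated leaf lag,
and the phantom is homogeneous. Green round-trip tests show the pipeline's
numerics are faithful; they do not certify a clinical dose algorithm.

## QA statistics

* `rms_leaf_errors()` — per-leaf RMS of planned − recorded over beam-on
  snapshots (holds excluded), with the plan-level maximum; the summary
  leaf-travel QA programs tabulate.
* `pearson_correlation()` — product-moment correlation (via `stats::cor`)
  of paired dose-change ratios; both $r$ and $r^2$ are reported because
  published "R²" values are sometimes the coefficient itself. The bundled
  ten-error validation table gives $r = 0.9992$, $r^2 = 0.9985$ from the
  printed three-decimal ratios.
* `confidence_limit()` — $|\overline{d}| + 1.96\,s_d$ with the sample
  (n−1) SD; at one-decimal reporting the n vs n−1 choice is immaterial.
  For the bundled 20-case clinical audit the limit is pooled across all 60
  differences (3 metrics × 20 cases) because a single published value is
  reproduced that way; per-metric limits can be computed from
  `audit_differences()`.
* `compare_plans()` — reconstructed − original metric differences with a
  strict action-level rule: a difference of exactly the level (default
  1.0%) passes, consistent with deliveries described as "always within"
  the level.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` rerun two seeded studies chosen
to exercise the full pipeline while completing in seconds on one CPU: (i) a 5-beam sliding-window
plan, error-free delivery, planned-mode reconstruction and full dose/DVH
comparison on the cube phantom (9 metric differences, all ≤ 0.1%); and
(ii) ten modulated fields delivered with 0.01 cm recording quantization and
0.2 mm SD jitter, reconstructed in actual mode and compared to the
delivered ground-truth fluence with 3%/3 mm gamma at a 10% threshold (mean
passing rate ≥ 99.9%). The absolute dose-change ratios of the ten-error
experiment (e.g. 1.038 for a 1 mm expansion) depend on a specific clinical
plan and dose algorithm and are not reproduced; their direction and
monotonicity are (integral fluence strictly increases across 1/2/4 mm
expansions), and the printed ratio table itself ships as a fixture.

## Worked example

```{r example, eval = FALSE}
plan <- make_sliding_window_plan(5, "random", seed = 7)
records <- lapply(seq_along(plan$beams), function(i)
  simulate_delivery(plan$beams[[i]], seed = 100 + i))
names(records) <- vapply(plan$beams, `[[`, character(1), "beam_id")
report <- run_qa(plan, records)
print(report)
```

## Known limitations

Fixed-gantry fields only (no arc reconstruction); 2D fluence gamma (no 3D
gamma); homogeneous phantom; no absolute dosimetry — doses are percent of
prescription throughout; log trustworthiness (MLC calibration, dose-index
integrity) must be assured by a separate machine-QA program, as for any
log-based method.
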