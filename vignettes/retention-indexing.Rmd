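---
title: "Retention-time indexing with NAPS: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retention-time indexing with NAPS: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napsri)
```

## The problem

Retention times (RTs) in reversed-phase LC–MS drift between columns,
instruments, gradients and flow rates, which makes retention — an
information channel orthogonal to accurate mass and fragmentation — hard to
use across laboratories. Gas chromatography solved this decades ago with
retention *indices*: a compound's retention is expressed relative to a
co-analysed homologous series of reference standards, cancelling the
system-specific warp of the time axis.

`napsri` implements this idea for reversed-phase LC–MS using
N-alkylpyridinium-3-sulfonates (NAPS). These zwitterions carry a permanent
positive (pyridinium) and negative (sulfonate) charge, so their retention is
essentially pH-independent and they ionise in both ESI polarities; a
homologous C1–C20 alkyl series provides twenty anchors spanning the
gradient. The homologue with an n-carbon chain is assigned the retention
index

$$\mathrm{RI}(n) = 100\,n,$$

so the scale runs from 100 to 2000.

## The calibration model

Given anchors $(\mathrm{RI}_i, \mathrm{RT}_i)$, a query retention time RT
bracketed by anchors $i$ and $i+1$ is indexed by linear interpolation

$$\mathrm{RI} = \mathrm{RI}_i +
  (\mathrm{RI}_{i+1} - \mathrm{RI}_i)\,
  \frac{\mathrm{RT} - \mathrm{RT}_i}{\mathrm{RT}_{i+1} - \mathrm{RT}_i},$$

the default method of `ri_calibration()`. Two smooth alternatives fit a
single interpolant through all anchors: a natural cubic spline and Akima's
piecewise-cubic method. The linear formula is affine-invariant — rescaling
or shifting the whole time axis (the dominant effect of changing flow rate
or dwell volume) leaves the index unchanged — which is the mathematical core
of cross-system normalisation, and a property the package verifies to
1e-9 relative in its tests.

Assumptions worth keeping in mind:

* the anchors and the analytes experience the *same* warp of the time axis
  (same column chemistry and eluents);
* anchor RTs are strictly increasing — guaranteed by construction after the
  co-elution collapse described below;
* between anchors the warp is smooth enough for the chosen interpolant.

### Early-eluting anchors and the overshoot pathology

Under typical gradients the C1–C3 homologues elute in or near the void
volume with nearly identical RTs. Two consequences:

1. **Anchor collapse.** `make_anchors()` folds anchors closer than
   `min_rt_gap` (default 0.01 min) into the highest-carbon member, which
   also tolerates tiny jitter-induced order inversions among co-eluting
   anchors. Larger inversions abort with an error, since they indicate a
   corrupted run rather than noise.
2. **Spline overshoot.** The abrupt change from near-zero to growing anchor
   spacing makes the natural cubic spline overshoot in the early region
   (it must keep a continuous second derivative through the pile-up);
   Akima's local slopes are designed to damp exactly this, and linear
   bracketing is immune. `compare_methods()` quantifies the disagreement;
   on the package's reference anchor set the cubic deviates from linear by
   ~46 index units in the early region versus ~14 for Akima. Below roughly
   RI 750 the three methods therefore disagree systematically, and indices
   from different fitting functions must not be mixed in one library.

Robust indices additionally require elution after the C3 anchor: converted
values at or below `usable_ri_min` (default 300) are flagged
`below_usable`. Conversion itself never fails — out-of-range queries are
linearly extrapolated from the terminal segment and flagged — so batch jobs
complete and the flags preserve auditability.

### Numerical choices

* **Cubic boundary condition**: natural (zero second derivative at the
  ends). Implementations of "a cubic spline" differ in their defaults; the
  natural condition is fixed here because it reproduces collinear anchors
  exactly, which is the behaviour a calibration should have on an ideally
  linear system.
* **Akima**: the 1970 slope formula with the standard two-point quadratic
  endpoint extension; tied slope-difference weights fall back to the 50/50
  average. The implementation is cross-checked against an independent one
  (`pracma::akimaInterp`) in the test suite.
* **Inversion** (`ri_to_rt()`): algebraic for the linear method; for
  splines, root bracketing on the fitted interpolant to |ΔRI| < 1e-6.
  Inversion is only defined where the interpolant is monotone — inside the
  cubic's overshoot fold the map is not one-to-one and the package raises
  an error naming the offending segment instead of silently returning one
  of several roots.
* **Reporting**: indices are kept at full precision internally and
  conventionally rounded to integers for display.
* **Bracketing policy**: sample blocks are bracketed by NAPS injections
  before and after; the default "average" policy averages the two anchor
  RTs per homologue (averaging the anchors, not two separately computed
  indices — the two differ only in nonlinear segments, and anchor averaging
  is the cheaper and more transparent choice).

## RI libraries

`build_ri_library()` indexes every replicate run with that run's own
bracketing calibration and only then averages — RT drift between replicates
(column ageing, eluent batches) is absorbed by the per-run calibration
rather than inflating the library dispersion. Dispersion is the sample
(n−1) standard deviation, since replicates sample run-to-run variability.
Entries with mean RI ≤ 300 stay in the library but are marked unusable.
Positive- and negative-mode detections of one compound are separate entries
keyed by (compound, adduct, polarity); a compound-level view is a join.

## Annotation

Matching is two-stage and deliberately simple: accurate mass within an
absolute tolerance (default 0.005 Da, inclusive at the boundary; a ppm mode
is available but mutually exclusive), then an optional index filter
(default ±10 RI units). The index is orthogonal to m/z, so the second stage
removes isobars and isomers: the bundled worked example — a feature at m/z
139.0389 with RI 513 against a library containing the three C7H6O3
hydroxybenzoic-acid isomers at RIs 511 and 561 — drops from three m/z-only
candidates to the single correct one.

Relative errors are reported as
$100\,|\mathrm{ref} - \mathrm{obs}|/\mathrm{obs}$ with the *observed*
(query-system) value in the denominator; this convention was fixed by
checking it against the worked-example table the package ships, where the
reference-denominator variant fails several cells. Reported precision is
one decimal below 10% and integer above.

## Ion suppression

Because NAPS are doubly charged, co-injecting them can suppress co-eluting
analytes. The module pairs features between a spiked and an unspiked
injection (greedy one-to-one by |Δm/z| then |ΔRT|, defaults 0.005 Da /
0.1 min — deterministic and auditable) and reports spiked intensity as a
percentage of unspiked within ±0.20 min of each NAPS apex (window edges
inclusive; a feature in two overlapping windows goes to the nearer apex).
Only apexes with RI > 300 are evaluated: the C1–C3 standards sit in the
void-volume crowd where suppression is confounded with everything else.
100% means no effect, below 100% suppression, above 100% enhancement; pairs
with zero unspiked intensity are flagged undefined and excluded from
summaries.

## The simulator

Every distributional claim in the package is tested against synthetic data
from a gradient-elution simulator, so no instrument data is required. The
retention model is linear solvent strength (LSS),
$\log_{10} k = \log k_w - S\varphi$, integrated exactly segment-by-segment
over a piecewise-linear gradient delayed by the dwell time, with
$t_0 = V_0/F$; a flat program recovers the isocratic closed form
$t_R = t_0(1+k)$. LSS is the simplest model that makes cross-flow-rate RT
warps smooth and realistic — exactly the regime retention indexing claims
to normalise.

Key defaults (all changeable through `simulate_study()`'s config):

| parameter | default | why |
|---|---|---|
| reference system | 0.3 mL/min, V0 0.21 mL, dwell 0.12 mL; 2 min at 5% B, ramp to 99.9% in 15 min, 3 min hold | a typical UHPLC polar-metabolomics method |
| flow panel | 0.20/0.25/0.35/0.40 vs 0.30 mL/min | brackets the reference by ±33% |
| NAPS LSS params | log kw = −2.9 + 0.5 n, S = 2.5 + 0.25 n | C1–C3 emerge at the void during the hold, C20 near gradient end; methylene increment constant |
| analyte panel | 50 compounds, log kw ~ −1 + 6.5·Beta(1.2, 1.8), S = 3.5 + 0.4 log kw | polar-skewed, as metabolite collections are on RP |
| RT jitter | Gaussian, sd = max(0.002, 0.0025·RT) min | see below |
| intensity noise | log-normal, sd 0.1 (log10) between replicate runs; 0.03 between back-to-back technical injections | run-to-run vs injection-to-injection variability |
| suppression kernel | Gaussian, 50% at apex for a 1:20 spike, amplitude ∝ 1/dilution, sd 0.08 min | NAPS peaks span ~0.2 min |

**Why proportional RT jitter.** A flat jitter (say 0.02 min everywhere)
misrepresents chromatography: void-volume peaks reproduce to a few
thousandths of a minute while mid-gradient peaks drift tens of
milli-minutes. Near the void the anchors are unavoidably compressed
(~0.1 min between C4 and C5 under any physically smooth homologous series
whose C1–C3 co-elute), so the local RT→RI slope approaches 1000 index
units/min; a flat 0.02-min jitter there would imply early-index replicate
RSDs around 5% and cross-condition index deviations of 10% — behaviour no
working LC system shows. The proportional model (0.25% of RT, floored at
0.002 min) equals 0.02 min at a typical mid-run RT of 8 min and keeps
simulated replicate index RSDs well inside the ≲6% band expected of real
replicate libraries.

**What the simulator does and does not emulate.** It produces apex-level
feature tables: retention shifts across flow rates (RTs +~50% at
0.20 mL/min, −~25% at 0.40), the C1–C3 pile-up, replicate scatter, and
dilution-scaled suppression. It does *not* model peak shapes, column
chemistry or temperature effects, matrix-specific suppression magnitudes,
detector saturation, or MS/MS — so passing tests demonstrate the
*normalisation machinery* works under smooth warps and realistic noise,
not that any particular biological matrix behaves this way.

## Problem sizes

The shipped tests and the acceptance script run the flow panel with
50 analytes × 5 flow rates, replicate libraries from 3–4 runs, and
suppression experiments with 1200 matrix features × 3 dilutions — sizes at
which all summary statistics (medians, RSD maxima, binned profiles) are
stable across seeds while the whole suite completes in seconds.

## Known limitations

* Indices transfer only between systems sharing separation chemistry; the
  package normalises the time axis, not selectivity changes.
* Below RI ≈ 300 (void volume) no robust index exists; between 300 and
  ~750 the interpolation methods disagree systematically, so a library and
  its queries must use the same method.
* The spline methods are not invertible inside an overshoot fold;
  `ri_to_rt()` refuses rather than guesses.
* The negative-mode diagnostic fragment is reported at its theoretical
  mass (79.9574); ToF instruments commonly print 79.9579, a ~0.5 mDa
  discrepancy most plausibly due to calibration near the low-mass edge.
* Annotation is deliberately tolerance-based with no scoring; combining RI
  agreement with MS/MS similarity into a consensus score is out of scope.
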