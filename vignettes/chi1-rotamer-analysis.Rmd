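---
title: "Diagnosing pH-induced rotameric destabilization from chi1 dihedral series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing pH-induced rotameric destabilization from chi1 dihedral series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chisno)
```

## The scientific problem

Classical molecular dynamics cannot model pH explicitly: a simulation box
of protein plus water contains no free protons, and fixed-topology force
fields cannot form or break bonds.  The widely used workaround is to fix
the ionization state of every titratable side chain at topology level to
match a chosen pH, run otherwise identical simulations under each
assignment, and compare the resulting conformational ensembles.  For a
papain-family cysteine protease carried from neutral to stomach-like
acidity, the relevant comparison turns out to live at the finest structural
level: the rotameric state of the catalytic histidine's side chain,
summarized by its χ1 torsion angle.  At neutral pH the histidine sits
stably in the catalytically competent (in-site) rotamer; once protonated it
repeatedly swings out of the active site, which plausibly suspends
catalysis even though the fold is intact.

`chisno` implements the quantitative side of this diagnosis: circular
normalization of χ1 series, a distribution-overlap statistic with a
replicate-reproducibility selection rule, rotamer-state occupancy and
violation counting, and the discrete charge-scheme bookkeeping.  This
vignette records the model assumptions, the tunable parameters, and the
design decisions that were genuinely open.

## Protonation schemes and net charge

Three discrete assignments are supported, named for the conditions they
emulate:

| scheme    | Asp | Glu | His       | Lys | Arg |
|-----------|-----|-----|-----------|-----|-----|
| `pH7`     | −1  | −1  | 0         | +1  | +1  |
| `pH2_all` | 0   | 0   | +1        | +1  | +1  |
| `pH2_his` | −1  | −1  | 0, except the designated catalytic His at +1 | +1 | +1 |

`pH2_his` is a virtual construct: it isolates whether protonating the
catalytic histidine alone reproduces the acidic-pH behavior.  All other
residues — including every cysteine (the catalytic Cys is modeled
protonated and uncharged; its possible thiolate form would require separate
force-field work) and the chain termini — contribute zero.  That termini
and cysteines are uncharged is an inference, not something the charge
roster states explicitly, but it is the unique assignment under which the
roster's printed totals for the wild type (−15, +11, −14) and for every
point mutant follow exactly from the per-residue table; `chisno` fixes it
package-wide.  Net charge is additive, so mutant charges follow from
single-residue deltas (`V277D` shifts the pH 7 charge by −1, `V277H`
shifts the pH 2 "all" charge by +1, `V277A` shifts nothing).

Sequences use *precursor numbering*: the mature chain starts after a
115-residue signal-plus-propeptide segment, so chain position `i` carries
label `i + 115` and the catalytic triad sits at 138/275/295.  The packaged
FASTA (`synthetic_mature_fasta()`) is a synthetic stand-in with exactly the
mature enzyme's ionizable composition and landmark residues; it exists
because the charge arithmetic should be testable from FASTA input without
redistributing the biological sequence.

No pKa prediction or fractional (Henderson–Hasselbalch) charge is
attempted; the schemes are deliberately the discrete assignments used in
the simulations being post-processed.

## Circular normalization: doubling and stacking

χ1 is periodic, and the common `[-180°, 180°)` convention cuts one rotamer
well (the *trans* well near ±180°) in half.  `stack_angles()` duplicates
every angle at `a` and `a + 360` and keeps one contiguous 360° window.
The window boundary is placed at the centre of the widest empty arc of the
data on the mod-360 circle — "doubling and stacking" as usually practised
does not pin down where the cut goes, so the cut-placement rule is this
package's decision; placing it in the emptiest region guarantees that no
populated well is split, for any data.  Two details follow from making this rule
total:

* the window is shifted by a multiple of 360° so the smallest stacked angle
  lies in `[0, 360)`, which makes the representation canonical (data already
  away from the seam are returned unchanged, and stacking is idempotent);
* when two distributions must share a binning — every S_NO comparison —
  the cut is computed once from their *pooled* angles and applied to both,
  otherwise different cut points could manufacture artificial non-overlap.

## The S_NO statistic

For two binned, unit-area χ1 densities on identical edges,

$$ S_{NO}(p,q) \;=\; \frac{\sum_i |p_i - q_i|}{\sum_i (p_i + q_i)}
   \;=\; 1 - \sum_i \min(p_i, q_i)\,\Delta , $$

the "integral of non-overlapping": 0 for identical distributions, 1 for
disjoint ones, and one minus the overlap coefficient in between.  The
equality of the two forms for unit-area histograms is exercised in the test
suite against a brute-force `sum(pmin())` oracle on random histograms.

Choices that the definition leaves open, and what this package fixes:

* **Bin width: 5° (72 bins).**  Resolves the narrower well (σ ≈ 9°, so
  ≥ 3 bins across ±1σ) while keeping per-bin counts reasonable for
  1000-frame series.  Halving the width moves S_NO by well under 0.05 on
  smooth data at n ≥ 10⁴ (tested), so conclusions do not hinge on it.
* **Histogram, not kernel, densities.**  Matches how the distributions are
  drawn and inspected; a smoothed variant would add a bandwidth parameter
  without changing the selection outcomes this statistic feeds.
* **Counts vs unit-area densities.**  For equal-length trajectories the
  "respective sum" denominator is the same either way; `chisno` fixes
  unit-area densities so unequal-length series are still comparable.
* **Replicate pairing: matched by index** (replicate *i* of condition A
  vs replicate *i* of condition B), because replicates originate from
  matched starting models; `all_pairs` (the 3×3 Cartesian product) is
  available as an option.  With three replicates, matched pairing yields
  the three pairs behind the "2 of 3 pairs" selection rule and behind the
  mean ± s.d. aggregation used for variant comparison.
* **Selection rule: strictly greater than 0.5, in at least 2 of 3 pairs.**
  The strict inequality is deliberate (`S_NO > 0.5`), and the threshold and
  pair counts are config-exposed (`select_responsive()`).

## Rotamer states and violation events

`classify_states()` assigns each frame to one of a set of disjoint angular
windows (circular containment, so windows may straddle any cut), defaulting
to in-site 190° ± 45° and out-of-site 285° ± 45°.  The well *positions and
spreads* (190° ± 9°, 285° ± 12°) are physical observations; the
*classification halfwidth* is an analysis choice, set generously at 45° so
that frames several σ from a well centre still classify correctly while the
windows stay disjoint (95° apart > 45° + 45°).  Frames outside every
window are `"other"`, and occupancies always partition to 1.

A **violation event** is a maximal run of consecutive non-native frames
(the run may pass through several non-native states) lasting at least
`min_dwell`.  The source analyses mark sustained excursions by eye; no
operational dwell threshold exists to copy, so the default is 1 ns —
long enough to ignore single-frame flicker at a 0.1-ns sampling interval,
short relative to the 100-ns trajectories being emulated.  A run of frames
`i..j` is assigned duration `t_j − t_i + dt` with `dt` the median frame
spacing (each frame stands for one sampling interval); a 10⁻⁹-ns slack
absorbs floating-point noise at exact-threshold comparisons.  Violation
counts are non-increasing in `min_dwell` (tested), and match brute-force
run enumeration on random traces (tested).

## The synthetic trajectory generator

`sample_regime()` draws a hidden state sequence from a Markov chain (one
state per rotamer well, per-frame row-stochastic switching matrix) and
emits each frame's angle from its state's von Mises well, with
κ = 1/σ_rad² — the standard circular analog of a Gaussian well of spread
σ.  Defaults emulate the study design being stood in for: 1000 frames at
0.1 ns (a 100-ns trajectory), three replicates per condition, wells
190° ± 9° (in-site) and 285° ± 12° (out-of-site).

The acidic-like regime needs switching rates, and none are published — the
kinetics of the histidine flip were never quantified.  The package default
is `p_out = 0.10`, `p_in = 0.05` per frame, giving stationary out-of-site
occupancy 2/3 and mean dwell times of 1 ns (in-site) and 2 ns
(out-of-site).  Two considerations fixed this point.  First, for
well-separated wells S_NO between a pure in-site distribution and a mixture
is approximately the mixture's out-of-site occupancy, so an occupancy
comfortably above the 0.5 selection threshold is what "often exits the
active site" must mean for a residue the selection rule is expected to
flag; 2/3 also keeps the indicative S_NO of a single replicate pair in the
0.6–0.7 range rather than saturating at 1.  Second, the switching must be
fast enough that a 1000-frame trajectory's occupancy concentrates near its
stationary value (autocorrelation ρ = 1 − p_out − p_in = 0.85 gives an
occupancy standard error of ≈ 0.05), because the generator's defaults are
study conditions for the whole test suite, not per-test dials.  These rates
are chosen for statistical testability; they are not a kinetic model of the
real side chain, whose excursions are rarer and longer-lived.

Per-series seeds are derived deterministically from one base seed (and kept
below 2³¹), so datasets are bit-reproducible; ground-truth hidden states
and responsiveness flags are always retained for oracle tests.

What the generator deliberately does **not** emulate: force-field physics,
solvent, correlated motion between residues, drift or aging within a
trajectory, non-uniform frame spacing, and any coupling between a
residue's χ1 and the rest of the structure.  Passing tests on synthetic
data therefore demonstrate that the *statistics* behave as specified — not
that any particular enzyme behaves any particular way.  The study-scale
quantities from the real trajectories (an indicative S_NO of 0.89 for the
histidine, a 17-residue responsive set, a variant minimum of
0.38 ± 0.32, one-vs-six violation marks) depend on the deposited MD data
and are not reproduced here; the test suite instead checks their
property-level counterparts: the pipeline isolates a planted responsive
residue among 19 unresponsive ones, and high-switching ("wild-type-like")
kinetics outrank low-switching ("stabilized-mutant-like") kinetics in both
mean S_NO and violation counts.

## Numerical and degenerate-input conventions

* von Mises sampling uses the Best–Fisher (1979) acceptance–rejection
  scheme; κ below 10⁻¹⁰ falls back to the uniform circle.
* Empty series, non-increasing time grids, malformed numeric rows (reported
  with their line number), mismatched density edges, overlapping rotamer
  windows, non-stochastic transition matrices and wild-type mismatches in
  mutations all raise classed conditions (`chisno_*_error`) rather than
  producing silent results.
* Readers accept any strictly increasing time grid; nothing assumes uniform
  spacing except the frame-duration convention above, which uses the median
  spacing for robustness.
* Ionizable counts given without a sequence cannot verify that the
  `pH2_his` target is a histidine; the sequence route checks it and raises
  a consistency error otherwise.

## Problem sizes in the shipped tests

The suite generates everything at run time: single-well parameter recovery
and chain-moment checks at 10⁴ frames; the end-to-end selection check at
20 residues × 2 conditions × 3 replicates × 1000 frames; the
responsiveness-separation property over 20 base seeds; overlap-oracle
properties over a few hundred random histograms.  These sizes make every
stochastic assertion comfortably stable under its stated statistical bound
while the whole suite stays fast.

## Known limitations

* Classification is threshold-based; no hidden-Markov or kinetic model is
  fitted to the traces, so dwell-time estimates inherit the window
  geometry.
* S_NO has no attached significance test; the fixed-threshold selection
  rule is reproduced as defined, without multiple-testing control.
* The pipeline consumes extracted angle series only; it does not read
  binary trajectories or compute dihedrals from coordinates.
* The charge model is discrete by design and says nothing about coupled
  titration or pKa shifts.
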