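---
title: "Methods: factorial LFA development on a liquid-handling robot"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: factorial LFA development on a liquid-handling robot}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfaforge)
```

`lfaforge` models the software side of a robotic LFA development platform:
turning a factorial experimental design into validated pipetting worklists
for an eight-channel liquid handler, and strip photographs into per-strip
test-line signals and screen-level rankings. This vignette documents the
models, the tunable parameters, and the design decisions taken where the
problem admitted several reasonable answers.

## Factorial designs and run splitting

A design is a list of factors (antibody panels, sample matrices,
concentration series in µg/mL), a replicate count, and exclusion
predicates. Enumeration is the Cartesian product of factor levels, minus
excluded assignments, times replicates, in a fixed order: the first
declared factor varies slowest, then level order, then the replicate index.
Condition ids are readable strings
(`capture=MAb001;detection=MAb002;matrix=ag1;rep=1`) rather than hashes, so
two worklists generated from the same design diff cleanly.

Exclusions are deliberately not a predicate language. Two forms cover the
screens this tool is for: a conjunction of per-factor level tests, and an
"all named concentration factors are zero" primitive. The latter encodes
the one practically important case — a concentration grid over several
antibodies whose all-zero corner is not a meaningful mixture: a
4 × 4 × 4 grid minus that corner leaves 63 assignments, 252 strips at four
replicates. Because the excluded corner is a modelling choice rather than a
law, the exclusion is configurable, not hard-coded.

Runs are filled strictly in enumeration order at the deck's capacity (sum
of holder capacities, e.g. six 16-strip holders = 96), giving exactly
`ceiling(n / capacity)` runs. Replicates of one assignment are adjacent in
enumeration order, so they land in the same run whenever the capacity does
not cut between them; this adjacency is best-effort, because we found no
packing rule that both preserves the exact ceiling count and guarantees
co-location for arbitrary replicate counts. Randomised run order is
available only as an explicit seeded shuffle.

## Mixture planning

Working solutions are planned from single-component stocks by exact mass
balance: `V_c = c_target · V_final / c_stock` per component, diluent
making up the remainder, so `Σ c_stock V = c_target V_final` holds to
relative 1e-9 (in practice to machine precision) and volumes sum exactly
to the final volume. Infeasibility is reported as one of three distinct
errors: a target above its stock concentration, component volumes
exceeding the final volume, or insufficient stock volume. Multi-component
stocks are rejected rather than solved as a linear system; the screens
addressed here use single-analyte stocks, and accepting them silently
would hide ambiguous sourcing.

Two choices deserve a note:

* **Diluent as a stock.** The buffer is a distinguished stock whose
  concentration is zero for every component, so a recipe's transfers and
  its diluent share one representation in worklists.
* **Exact volumes, separate quantization.** Recipes carry exact volumes.
  `quantize_recipe()` rounds to the instrument's resolution (default
  0.1 µL — a typical small-volume air-displacement resolution; no
  authoritative value exists for an arbitrary robot) and reports the
  relative concentration error the rounding introduces, instead of baking
  rounding into the planner.

Serial dilutions carry a redundancy: the fold per step and the carryover
volume are linked by `carryover = volume_per_step / fold`. The function
accepts both, derives the carryover by default, and treats an inconsistent
explicit pair as an error rather than silently trusting one of them.

## Worklist scheduling

A protocol is an ordered list of steps: liquid dispenses (reagent or
sample) with a volume, destination well, minimum delay after the previous
step's start, liquid class and a per-batch gantry duration; and imaging
steps with a target time after the sample dispense (1800 s and 2100 s for
the common 30- and 35-minute reads — a parameter, not a pair of modes) and
a symmetric tolerance (default ±60 s).

Expansion yields one transfer per (condition, liquid step) and one imaging
event per (condition, image step), plus preparation transfers for any
reagent backed by a mixture recipe (on-deck preparation is the default; a
pre-prepared mix is simply passed as a stock). Batching groups transfers
that share step, source labware class, volume and liquid class into
batches of at most eight, one channel each, in event order — so 13
compatible transfers become batches of 8 and 5, and two volumes never
share a batch. Imaging events are grouped by the batch that dispensed
their strips' samples: strips pipetted together have coinciding imaging
deadlines and are photographed together.

Scheduling is non-preemptive earliest-deadline-first on a single gantry.
Imaging batches get deadline `sample_time + target + tolerance` and
release `sample_time + target − tolerance`; liquid batches have infinite
deadlines and releases from the per-strip delay chain and any preparation
precedence. Ties break by release, then step index, then batch id, making
the schedule a pure function of its inputs. When the chosen batch cannot
start yet, a ready batch that fits entirely into the idle gap runs first.
If an imaging batch would miss its window the scheduler aborts and
proposes a smaller run size, scaled by how far the window was overrun.
Time zero is the first batch start and all times are integer seconds when
the protocol's durations are — reproducible diffs were worth more to us
than sub-second fidelity, since tip handling and washing are collapsed
into the per-batch durations anyway. Those default durations are
placeholders for a generic instrument and are flagged as such in the
example protocol config.

The emitted CSV dialect is fixed:
`run,batch,channel,action,source_labware,source_pos,dest_holder,dest_slot,dest_well,volume_ul,liquid_class,scheduled_start_s,condition_id`,
one row per transfer or imaging event, imaging rows with blank
volume/source. `read_worklist(write_worklist(x))` reproduces the event
table field-for-field.

Validation is deliberately a second, independent code path:
`simulate_worklist()` replays the CSV-level events against the protocol,
checking per-strip step order and delays, imaging windows, single-gantry
batch overlap and running stock balances, and returns violations as report
rows rather than exceptions. The test suite asserts the closure property —
everything the scheduler emits simulates clean — on hundreds of randomly
generated protocols and run sizes, and separately that tampered worklists
and over-drawn stocks are caught.

## Test-line densitometry

The signal of a strip is the height of the width-averaged intensity peak
at the test line above the local background:

1. **Width-averaged profile.** Mean converted pixel value across the strip
   width at each position along the flow axis, within a given roi
   (0-based, half-open; the roi is provided by the deck layout or
   one-strip-per-file cropping — strip-edge detection is out of scope).
   Color images are converted by inverted Rec.601 luminance
   (`255 − (0.299 R + 0.587 G + 0.114 B)`), so a dark line on white
   nitrocellulose reads as high signal; a single-channel option exists,
   and grayscale input is used as-is with an optional inversion.
2. **Peak location.** Argmax of a 3-px moving-average of the profile,
   restricted to `expected ± half_width`. The light smoothing suppresses
   single-pixel noise without materially biasing where the peak lies; the
   window is configurable. Ties resolve toward the expected position, and
   a perfectly symmetric tie (or a flat window) returns the expected
   position itself.
3. **Baseline.** A straight line through the medians of two flanking
   windows (`line_halfwidth` = 8 px, `flank_width` = 10 px by default),
   evaluated across the profile. Medians make the anchors robust to
   specks; the linear form removes constant and linear illumination
   gradients exactly, which is also why adding a constant to every pixel
   changes the signal by less than 1e-6.
4. **Signal.** The unsmoothed, baseline-corrected profile value at the
   located peak, clipped at zero; the unclipped value is kept for
   diagnostics. Clipping encodes that a test line cannot have negative
   analyte signal, while the diagnostic value preserves evidence of
   over-subtraction.

No published description of the original analyzer's estimator exists at
this level of detail; the flank-median/linear-interpolation estimator is
this package's own documented choice, validated against synthetic ground
truth: on strips with known amplitude, sloped background and pixel noise,
recovered-vs-true amplitude regresses with slope within a few percent of
one (the 3-px smoothing only selects the peak; the height readout is
unsmoothed, so the Gaussian peak is not attenuated).

## Synthetic ground truth

`render_strip()` draws `background + slope·x + A·exp(−(x−c)²/2σ²)` along
the flow axis, constant across width, plus iid Gaussian noise, clipped to
bit depth, reproducibly from a seed. Gaussian (not Poisson) noise is used
because camera-scale 8-bit intensities are far from the shot-noise regime
that would make the distinction matter; σ = 3 px and widths of ~30 px
match a ~3 mm strip imaged at modest resolution.

`simulate_screen()` generates pair-screen tables: latent capture and
detection affinities (Unif(0.05, 0.8)), pair strength = their product, a
saturating Michaelis–Menten-shaped response (`vmax` = 60 over `km` = 1 on
top of a blank level of 8) — chosen as the simplest monotone-saturating
form, with an optional hook-effect term (off by default) for the
high-dose decline sometimes seen in concentration grids. A configurable
fraction of detection antibodies cross-reacts with a second antigen, and
a handful of planted pairs are made strongly selective (strength 5 → mean
signal 58, S/N 7.25 against the blank level — comfortably above the
S/N ≥ 5 regime the recovery tests target). Replicates share the condition
mean; blank and replicate noise default to sd 1.5.

What the generator does *not* emulate bounds what passing tests show:
there is no flow physics, no membrane heterogeneity, no inter-strip
striping variation, no lighting field, no perspective distortion.
Recovery results on synthetic strips demonstrate that the estimators are
correct and unbiased under their stated model, not that the model captures
every failure mode of real nitrocellulose.

## Screen analytics

Blank subtraction is per antibody pair: the pair's antigen-matrix
replicate mean minus the same pair's blank mean, so blanks map to exactly
zero. S/N likewise uses the pair-specific blank as N (a plate-wide blank
is available as an option; descriptions of plate-based screens are
ambiguous between the two, and the pair-level form is the more
conservative against per-pair background differences). Heatmaps are
replicate means per capture × detection cell, raw and blank-subtracted —
both are emitted, since published heatmaps rarely say which they show —
with missing cells flagged, never imputed.

Cross-reactivity ranking sorts pairs by descending target-antigen
blank-subtracted signal and filters pairs whose off-target signal exceeds
a threshold, default 3× the blank replicate sd estimated from the table.
The output is a ranked report plus the full scatter table; the final
pick-k-pairs decision is left to the scientist, because real
down-selections weigh factors (shared detection antibodies, reagent
availability) that are narrative, not algorithmic. Method comparison uses
the standard Pearson correlation with the t-transform p-value; its
correctness is asserted analytically (affine case, R = 1) and by Monte
Carlo against a known shared-variance ground truth. Published clinical
correlation values for robot-vs-human and LFA-vs-plate comparisons depend
on laboratory data that is not deposited anywhere and are therefore not
reproduction targets for this package.

## Problem sizes and numerical conventions

The validation suite uses sizes chosen to exercise every code path at
desk scale: mass balance on 1000 random mixtures (conservation to
relative 1e-9); scheduler closure on 200 random protocols and run sizes up
to the 96-strip deck; imaging recovery on 200 strips with amplitudes
Unif(5, 50), background slopes ±0.1 unit/px and pixel noise sd 2; and
planted-pair recovery on 100 seeded 16 × 16 × 3 × 2 screens. Tolerances:
volume identities to 1e-9 µL relative; time comparisons to 1e-9 s
(schedules are exact integer arithmetic in practice); imaging windows to
their configured ±60 s.

## Known limitations

* Single-gantry model: the eight channels parallelise within a batch, but
  batches serialise; overlapping aspirate/dispense pipelining is not
  modelled.
* No dead-volume or viscosity modelling; liquid classes are opaque labels
  passed through to the worklist.
* The imaging roi must be supplied (deck layout or per-file); strips are
  not detected in raw deck photographs.
* Dose–response fitting (4PL) and limit-of-detection estimation are out of
  scope; the analytics stop at ranked screening metrics.
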