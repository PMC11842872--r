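---
title: "Models and methods behind chromakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromakin)
```

`chromakin` analyses single-molecule tracking experiments on chromatin-
binding proteins (cohesin, CTCF) and simulates cohesin-mediated loop
extrusion. This vignette is the package's account of the underlying models,
the assumptions they make, the numerical choices taken where the design was
genuinely open, and what the synthetic-data tests do and do not demonstrate.

## Illumination schemes and tracking

A scheme is an ordered cycle of (exposure, readout, dark) events; frame
timestamps are exact cumulative sums, so any analysis depending on the
pattern is reproducible to machine precision. Dark times are classified by
duration — short (default 0.05–1 s, typically 0.2 s) versus long (≥ 1 s,
typically 4 s) — rather than by position in the cycle, so the same
classification code serves interlaced (ITM) and burst-augmented (TACO)
schemes.

Linking is greedy nearest-neighbour, the algorithm class of the trackers
used for this kind of data. Each localization claims the nearest unclaimed
track head within a user-set radius; ties are broken deterministically
(input order within a frame, lowest track id among equidistant heads).
Greedy assignment is adequate at single-molecule densities; a global
assignment would only matter when molecules approach within one radius, a
regime the analyses avoid by design. Tracking radii are explicit parameters
(defaults: 0.8 µm for continuous movies); per-condition radii in a real
experiment are calibrated so that all conditions share one per-frame loss
probability, and that calibrated value (default 0.0025) travels with the
survival datasets rather than being re-fit.

Jump distances are capped at 10 per track and jumps across gap frames are
discarded, preventing long-lived bound molecules from dominating the
jump-distance distribution.

## Brownian-mixture fits of jump distances

The cumulative distribution of jump distances r over one frame interval dt
is modelled as a mixture of 2D Brownian components,
CDF(r) = Σ A_i (1 − exp(−r² / (4 D_i dt))), ΣA_i = 1. The slowest
component collects genuinely bound molecules; its apparent coefficient D₁
absorbs localization error and slow chromatin motion, so no separate error
term appears in the model. The two faster components approximate the
anomalous diffusion of free nuclear proteins. The empirical CDF is binned
at 1 nm over 747 bins (both configurable) and fit by unweighted least
squares; amplitudes are parameterized by stick-breaking logits and
coefficients on the log scale, so the constraints hold by construction. The
optimizer (BFGS) is restarted from five deterministic initializations
spanning the plausible decade range of coefficients and the best residual
kept; all-identical jumps are rejected as degenerate rather than fit.

Model order is chosen with the AIC difference
ΔAIC = (2k₂ + n ln RSS₂) − (2k₃ + n ln RSS₃), k₂ = 3, k₃ = 5 free
parameters after the sum constraint, n = bin count; positive values prefer
three components. A caveat this package's own tests document: the binned
CDF has strongly correlated residuals, so the statistic is anti-conservative
for the simpler truth — on synthetic two-component data the third component
absorbs enough correlated noise that ΔAIC is usually positive. The
statistic is implemented as published and is reliable in the direction it
is used (recognising three-component data); treating a negative value as
proof of two components would be unsafe, and the acceptance suite records
this honestly.

Parameter uncertainties are standard deviations over refits on 500 random
subsets of 80% of the jumps (both configurable).

## ITM/TACO binding classes

A track survives a dark interval when detections flank it, optionally
within a confinement radius (detections need not be in adjacent frames — a
molecule missed in one exposure still survived the surrounding darks).
Classes are disjoint: `long` survived ≥ 2 long dark times (> 8 s by
pattern construction, not as a free parameter), `short` survived ≥ 1 short
but no long dark time, `spot` is a single detection, and `grey` (exactly
one long dark time) is excluded from both named classes but kept in the
denominator. The two published counting conventions — short defined as "one
long or no long dark time" versus "lasted one short dark time" — give
identical fractions once the denominator is written out (both equal the
total track count, and each numerator is the strict class), so no
convention switch is provided.

TACO mobility takes, per qualifying track, the mean jump distance over its
first complete gap-free 10-frame burst, discarding later bursts so
long-lived molecules are not overrepresented.

## Survival-time inversion (rate spectra)

Bound-molecule survival times from several time-lapse conditions are
inverted jointly on a log-spaced grid of dissociation rates (default
10⁻³–10¹ 1/s, 50 per decade; grid density is a resolution choice, not a
model claim). The model for condition c with frame-to-frame cycle Δ_c is
S_c(t) = Σ A^e_i exp(−k_i t) (1 − p_loss)^(t/Δ_c): dissociation acts per
unit time, loss (photobleaching + tracking error) per detected frame, and
two conditions with sufficiently different dark times decouple the two.
Events must span ≥ 3 frames (shorter ones are indistinguishable from
diffusing molecules), so each empirical survival function is conditioned on
reaching its first observable time; the inversion therefore iterates a
per-condition conditioning scale alongside a nonnegative least-squares
solve on the stacked, log-binned survival functions, each condition
weighted equally after normalization.

Two numerical choices matter. First, no spectral smoothing (Tikhonov) term
is used; uncertainty is assessed by resampling (500 × 80% of events)
instead, and clusters are read as contiguous support regions. Second, grid
rates that decay essentially to zero before the first observable frame of
every condition are unidentifiable — their design columns are numerically
null, and a plain NNLS may park arbitrarily large amplitudes there for
infinitesimal residual gain, poisoning the event normalization. The solver
therefore selects the minimum-norm NNLS solution through a tiny damping
term (10⁻⁴ by default). This is stabilization of a rank-deficient system,
not regularization of the spectrum shape: identifiable amplitudes are
unchanged at this magnitude.

Event spectra (fractions of binding events) convert to state spectra
(fractions of molecules bound at a snapshot) by dividing each amplitude by
its rate and renormalizing. The residence summary splits the grid at
0.1 1/s — the boundary between the short- and long-bound classes seen in
ITM — and averages rates on each side weighted by state amplitudes
(event-weighted and unweighted averages are available; the published
description is ambiguous on this point, and state weighting matches the
interpretation of the spectrum as "molecules bound at a snapshot").

## Equilibrium two-class binding and search times

Unspecific and specific binding are two decoupled mass-action reactions.
Site concentrations never appear explicitly: the pseudo-first-order
association rate k*_on = k_off·p_b/p_f absorbs them, so everything is
computed from measured fractions and dissociation rates. Bound fractions
predicted from rates, p_b,s = (k*_s/k_s) / (k*_s/k_s + k*_u/k_u + 1),
round-trip exactly with the fraction-derived rates — a machine-precision
identity the tests assert. The facilitated-diffusion search time counts
N = 1/A^e_s unspecific encounters before a specific hit,
τ = N/k*_on,u + (N−1)/k_off,u; for cohesin, whose search mechanism is
unknown, the direct estimate τ = p_f/(k_off,s·p_b,s) is used instead.
Stage comparisons use τ_eff = τ·V_nuc/N_mol normalized to a reference
stage, so only relative molecule counts and volumes are needed; absolute
copy-number calibration is out of scope. Nuclear volumes for round nuclei
come from the largest cross-section assuming a sphere. Uncertainties use
first-order (delta-method) propagation with central-difference derivatives.

## Center-border distance (CBD)

Nuclear outlines are hand-drawn polygons at the first, middle and last
frame; each is resampled to 64 vertices by arc length and rotationally
aligned to its predecessor by the cyclic shift minimizing summed vertex
distance (vertex correspondence is otherwise undefined), then interpolated
linearly per frame. A track contributes only its initial position. CBD is
the ratio of the centroid distance of the point to the centroid distance of
the border along the same ray (outermost crossing for non-convex
outlines); values ≤ 1.02 are clamped to 1 (segmentation noise), values
beyond are excluded. Histograms use five equal-width CBD bins normalized by
ring area (∝ i² − (i−1)²) and then by the maximum bin, with √N counting
errors carried through both normalizations.

## Loop-extrusion lattice engine

The chromosome is a 1D chain of beads (1 or 10 kb). Per update: (1) each
extruder unloads with probability p_unload; (2) each surviving extruder
moves each non-stalled leg outward one bead, stalling temporarily at beads
occupied by other legs and permanently at impermeable CTCF sites and chain
ends; (3) loading is attempted on every free candidate pair (neither bead
occupied, CTCF, or a chain end) with probability p_load. The update order
(unload → step → load) is fixed and documented; it affects only
single-update edge cases. Extrusion speed is emergent — one bead per leg
per update gives a loop-growth rate of 2 × resolution / update interval,
i.e. 0.5 kb/s at 1 kb beads and 4 s updates. The lattice time mapping makes
one update 4 s at 1 kb resolution and 10 s at 10 kb resolution.

Macroscopic rates map onto the lattice as p_unload = Δt/residence and
p_load = rate[Mb⁻¹min⁻¹] × chain[Mb] × (Δt/60 s) / n_candidate_pairs, so
the configured association rate is honoured at any resolution. Realized
lifetimes are geometric with mean Δt/p_unload; at low density the mean
extruder count follows the loading-flux × residence product, while at high
density mutual blocking raises occupancy above it — the tests check the
former quantitatively and the structural invariants (leg ordering, no
shared beads, loops nested or disjoint) after every update of long runs.

Orientation-dependent CTCF permeability is not modelled (sites are strictly
impermeable); chain ends are hard boundaries.

## Contact maps, P(s), and pile-ups

The primary contact backend is an effective-contour model: each sampled
loop configuration defines a graph with unit backbone edges plus a unit
shortcut across each extruder; the effective separation d_eff is the
shortest-path distance and P ∝ max(d_eff, 1)^(−1.5), the contact exponent
of an ideal (theta-solvent) coil. This surrogate preserves exactly the
loop-topology signal that P(s) and pile-up analyses probe, at desk scale; a
faithful molecular-dynamics treatment of the same system is far beyond a
single-CPU budget, and the package's reduced overdamped Langevin bead-spring
backend (harmonic bonds, Lennard-Jones volume interactions, per-step
displacement cap for stability when extruder bonds are imposed) is provided
for small chains where a 3D cross-check is wanted. Its Lennard-Jones
theta-solvent coefficients must be supplied by the caller.

P(s) is the mean contact probability per diagonal, optionally log-binned;
local slopes use centered finite differences on log-log values after a
3-point moving average, and range slopes use ordinary least squares of
log P on log s. Observed/expected maps divide each diagonal by its own mean
(self-normalized); pile-ups average O/E windows of ±100 kb around CTCF
sites, skipping sites too close to chain ends, and the insulation score is
the mean O/E contact between loci on opposite sides of the piled-up site.
BED input is 0-based half-open; a site maps to the bead containing its
midpoint.

## The synthetic-data generator

The generator emulates: a three-state continuous-time Markov chain
(free ⇌ short-bound, free ⇌ long-bound) with exponential waiting times;
diffusion with a per-state coefficient, where the displacement variance
over an inter-frame interval integrates the coefficient along the state
path (so a molecule that unbinds during a 4 s dark time moves accordingly —
using the state at the interval start would freeze it artificially);
reflecting confinement in a circular nucleus; isotropic Gaussian
localization error; and a single per-detected-frame Bernoulli loss merging
photobleaching and tracking error, mirroring how the loss probability is
calibrated in the real pipeline. Binding positions can be radially biased;
placement follows density ∝ bias(CBD)·CBD, the ring-area element of a
disk.

What it does not emulate: image formation (PSF, pixelation), nuclear drift
and shape change, out-of-focus loss and 2D projection of 3D motion (both
uncorrected in the analysis, as they affect all stages alike), anomalous
diffusion beyond the mixture approximation, and state-dependent
detectability. Passing parameter-recovery tests therefore demonstrates the
correctness of the estimators under the stated model, not robustness to
every imaging artefact.

Defaults reflect the study conditions: 11.7 ms continuous frames, 0.2 s/4 s
ITM dark times, 501.7 ms time-lapse frames with 4013.6 ms darks, loss
probability 0.0025 per frame, dissociation rates spanning 10⁻³–10¹ 1/s,
bound fractions of a few to ~30%, and nuclear radii of 5–10 µm.

## Problem sizes and tolerances in the test suite

Recovery tests use 5×10⁴ jumps for diffusion fits (bound fraction within
±0.03), 10⁴ binding events per condition for spectrum inversion (slow
residence time within 20%), 10⁴ points for the flat-CBD χ² control, 10⁵
validated updates for the extrusion invariants, and a 5 Mb chain at 10 kb
resolution for the stage-contrast pile-up. These sizes are chosen so the
statistical power matches the asserted tolerances on a single CPU; the
machine-precision assertions (kinetic round trip, unit mappings, bare-chain
scaling slope) are size-independent.

## Known limitations

* The lattice engine is 1D; compartmentalization, chromatin stiffness and
  locus mobility are outside its scope.
* The effective-contour contact model fixes the −1.5 contact exponent
  rather than deriving it from polymer dynamics.
* The spectrum inversion reports event amplitudes only up to the
  identifiability limit set by the ≥ 3-frame conditioning; rates faster
  than roughly the inverse first observable time are not constrained by
  the data.
* ΔAIC model selection on binned CDFs is anti-conservative toward the more
  complex model (see above).
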