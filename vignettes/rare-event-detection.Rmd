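---
title: "Detecting rare conformational events in contact dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting rare conformational events in contact dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rednmf)
```

## The model

A protein's conformational state is encoded, frame by frame, in which
residue pairs touch. `rednmf` works entirely on that representation: the
binary contact tensor (R, R, n) at a 3.5 Å all-atom cutoff, flattened to a
feature-by-time matrix **I** (R², n) and smoothed along time with a
centered moving average. The smoothed matrix is approximately non-negative
low-rank: a handful of contact *archetypes* (conformational states) mixed
with time-varying weights. Non-negative matrix factorization

$$ I \approx W H,\qquad W \in \mathbb{R}_{\ge 0}^{R^2 \times c},\;
   H \in \mathbb{R}_{\ge 0}^{c \times n} $$

recovers both: columns of **W** are archetypes (weighted residue-pair
sets), rows of **H** say when each archetype dominates. Because both
factors are non-negative, the parts are directly interpretable — a weight
in **W** is a contact's contribution to a state, never a cancellation.

Two structural facts make this work. First, contact maps are sparse and
largely constant: the backbone band and stable cores go into one
*stationary* component with a flat weight trace, leaving the other
components free to encode change. Second, fast fluctuations (a side chain
rattling in and out of contact) average under the smoothing window to an
intermediate, roughly constant occupancy — also absorbed by the stationary
component — while a genuine state change survives as a coherent 0→1 swing
across many features at once. A *rare event* is then visible as a pair of
interlocking humps in **H**: one component's weight falls while the next
one rises through the same frames.

## Parameters that matter

* `cutoff_A` (3.5 Å, inclusive): the contact definition, over all atoms
  including hydrogens by default (`atom_scope = "heavy"` for models built
  without hydrogens). Distances are plain Euclidean; there is no
  periodic-boundary minimum-image correction, so trajectories must be
  wrapped with the protein whole. This is a stated limitation.
* `window_frames` (125): the smoothing window. The canonical pairing is
  125 frames ≈ 30 ns at a 0.24 ns parse interval; what matters is that the
  window is long against contact flicker and short against the spacing of
  true transitions. Windows are truncated (not padded) at both trajectory
  ends so no frames are dropped.
* `frame_interval_ns` (required, never inferred): published event
  bookkeeping sometimes uses a different frame↔time scale than the parse
  interval (e.g. 0.24 ns per parsed frame, but frame 620 ↔ 1488 ns, i.e.
  2.4 ns, in event tables). The tool therefore refuses to guess and takes
  the interval as explicit configuration everywhere times are rendered.
* `k` (6 protein mode / 3 ligand mode): the rank. It is a user choice, as
  in any unsupervised decomposition: a good starting point is the expected
  number of transitions plus one for the stationary component; re-running
  with k ± 2–3 and comparing events is cheap and recommended. Too small a
  rank merges consecutive states; too large splits one state across
  near-duplicate components — both visible in the weight plot.
* Event thresholds: `cv_threshold` (0.15) for calling stationary
  components; `rise_fraction` (0.5) for event boundaries;
  `min_duration_frames` (25, one fifth of the canonical smoothing window)
  to suppress flicker events; dominance re-smoothing window (11 frames).

## Numerical choices

**Initialization.** NNDSVD: deterministic non-negative starting factors
from the leading c singular triplets, each singular vector split into
positive and negative parts with the dominant part kept. The plain variant
(zeros left at zero) is the default; a mean-filled variant is available by
flag. Determinism here makes the whole fit reproducible bit-for-bit —
there is no random restart anywhere.

**Solver.** HALS coordinate descent: each H row and W column in turn is
set to the exact non-negative minimizer with the others held fixed. The
alternative multiplicative-update scheme was evaluated and rejected: it
cannot revive entries that the plain NNDSVD start sets to exactly zero
(multiplicative zero-locking), and on the synthetic benchmark this left one
planted archetype unrepresented in roughly half the replicates. HALS has
no such trap, and the (penalty-free) objective decreases monotonically.
After every iteration each W column is rescaled to unit maximum with the
inverse factor on its H row; the product WH is untouched, reported weights
become comparable across components, and — important for the penalized
mode below — the scale of W is pinned.

**Convergence.** Iterations stop when the objective decrease falls below
`tol` (1e-6) times the objective at initialization (the convention used by
scikit-learn's NMF), or at `max_iter` (2000). Measuring the decrease
against the initial objective rather than the current one gives `tol` a
data-independent meaning and avoids burning thousands of iterations
polishing noise.

**Ligand mode penalties.** For the (R, n) ligand-contact matrix the
objective gains `sparsity_weight · Σ W` (L1, defaults 0.1) and
`smoothness_weight · Σ_t (H_{·,t+1} − H_{·,t})²` (defaults 1.0). The exact
functional form and weights are this package's declared choice — the
penalties' purpose (few residues per binding mode, smooth mode weights) is
standard, their published form is not. The L1 penalty is only meaningful
with the per-iteration unit-max normalization above: without a scale pin,
W can shrink toward zero while H grows to compensate, reducing the penalty
indefinitely without changing the fit. The smoothness term couples each H
row along time; its row update solves a symmetric tridiagonal system
(Thomas algorithm) before projection onto the non-negative orthant. With
both weights zero the mode reduces exactly to the plain factorization.

**Event boundaries.** The dominance trace is the per-frame argmax of the
lightly re-smoothed non-stationary H rows (ties to the lower component
index). For a switch A→B with crossover t\*, the event is bounded by the
`rise_fraction` level of each component's local hump: the start is the last
frame before t\* at which B was below `min + rise_fraction·(max − min)` of
its *rising flank* (extrema over [start of A's run − window, t\*]), the end
is the first frame after t\* at which A falls below the same fractional
level of its *falling flank* ([t\*, end of B's run + window]). Scoring each
hump on its own flank is deliberate: with extrema taken over the joint
window, two equal-amplitude interlocked humps cross exactly at their shared
half level, and every event would collapse to ~2 frames. Dominance runs or
event intervals shorter than `min_duration_frames` are discarded as
flicker. Published event frame ranges are read off weight plots by eye;
exact reproduction of such ranges is not claimed — containment of the true
transition inside the event interval is the tested contract.

**Helix axes.** Bend and wobble angles need a segment axis. A plain
principal-component axis is biased by the fractional helical turn of a
finite segment (several degrees for 10–15 residues — enough to read a 10°
bend into a perfectly straight helix), so the axis is instead built from
second differences of consecutive Cα positions, whose pairwise cross
products all point along the axis exactly for an ideal helix of any length;
near-collinear input falls back to the principal direction. The wobble
angle is the signed azimuth of the post-segment axis about the pre-segment
axis, measured right-handed from the projection of the pivot-Cα direction
(seen from the pre-segment centroid). The reference convention of the
original proline-kink literature is not fully restated in print; this
convention is declared, fixed, and documented — absolute wobble values are
comparable within the tool, and differences over time (the quantity of
interest) are convention-independent.

**Degenerate inputs.** A straight helix (bend < 1e-3°) has no defined
azimuth: wobble is reported as 0 with a `degenerate` flag. An all-zero H is
rejected. Systems without lipids pass the cavity lipid-exclusion vacuously
(with a message). Exact weight ties in rankings break lexicographically by
residue pair.

## What the synthetic generator emulates — and what it does not

`generate_contact_series` builds the stated benchmark world: a shared
contact scaffold (diagonal, |i−j| ≤ 2 backbone band, a stable random core)
plus per-state contact sets, i.i.d. per-entry contact flicker at
`flip_noise_rate`, and linear cross-fades over `ramp_frames` (50) around
each planted transition so transitions are rare but not instantaneous. The
default benchmark — R = 40, n = 1500, five archetypes, four transitions,
5% flicker, 125-frame smoothing, k = 6 — is the world the acceptance
benchmark runs in; an autocorrelated (two-state Markov) flicker mode
provides a harder variant. `generate_toy_trajectory` realizes a planted
tensor geometrically (contacts at 3.0 Å, non-contacts ≥ 6 Å, one
pseudo-atom per residue) so the file-reading and contact-building layers
are exercised end to end; geometric realization restricts each residue to
at most one simultaneous off-diagonal contact.

What the generator does *not* emulate: spatially correlated noise between
neighboring pairs, gradual drift within a state, partial/aborted
transitions, revisits to earlier states, force-field physics, or
periodic-boundary artifacts. A green recovery benchmark therefore
establishes that the chain detects planted, well-separated collective
transitions under independent flicker — not that it would resolve, e.g.,
two overlapping transitions or a slow continuous drift. The cavity scenes
and kinked helices are constructive fixtures: they place waters and rotate
helix segments so the correct answer is known by construction, which
validates the metric implementations, not their biological interpretation.

## Design choices where the design was open

* **Frame/residue indexing**: 0-based internally and in all returned frame
  numbers (components are 1-based, the R convention); residue indices are
  rendered 1-based, or as Ballesteros–Weinstein labels when a map is
  supplied, only in reports. Event intervals are half-open [start, end).
* **Self-contacts and the near-diagonal band** are kept in the feature
  matrix by default: they are constant, so the stationary component absorbs
  them, and keeping the full R² layout preserves the historical matrix
  shape. `upper_triangle` flattening halves the memory and is recommended
  for new work.
* **Full-atom contact scope by default** (hydrogens included), matching the
  common VMD `within`-selection practice the contact definition comes from.
* **Superposition** fits and scores the same atom set (Kabsch); which
  structure is held fixed is irrelevant to the RMSD and not otherwise
  distinguished.
* **XTC reading is out**: no reader exists in this R stack and the format's
  compressed XDR encoding is not worth hand-rolling; DCD and multi-model
  PDB are supported, and the synthetic module writes DCD.
* **Water counting, not volume**: cavity capacity is quantified by the
  membership count of water oxygens under the stated radii (15 Å of the
  2.43 Cα or 8 Å of the 6.33 Cα, minus the 5 Å lipid shell and the 12 Å
  sphere around the 3.39 Cα), a robust proxy that needs no surface
  triangulation.

## Known limitations

No change-point statistics or significance testing of events; no automatic
rank selection; no minimum-image distances; no side-chain rotamer
classification (pair distances stand in for rotamer-switch comparisons).
Contact building is O(atoms²) per frame in plain R — fine for desk-scale
systems and the benchmark, slow for full-size membrane systems, where
pre-computed contact stores (`write_features`/`read_features`) let the
factorization be re-run without recomputing contacts.
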