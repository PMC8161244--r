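# rednmf — rare event detection in MD trajectories by non-negative matrix factorization

Long molecular-dynamics trajectories of conformationally complex proteins —
G-protein-coupled receptors in particular — bury their mechanistically
interesting content in noise: the collective, function-related
conformational transitions are *rare events*, outnumbered by vast numbers of
fast fluctuations that sample individual degrees of freedom without changing
the conformational state. `rednmf` detects those rare events directly from
residue-contact dynamics and reports which residue pairs drive each one,
together with companion structural metrics (intracellular-cavity hydration,
helix bend/wobble angles, residue-pair distances, TM-domain RMSD) used to
interpret the events functionally.

The package is aimed at computational structural biologists analysing
all-atom MD of membrane receptors, but nothing in the method is specific to
GPCRs beyond the Ballesteros–Weinstein residue addressing convenience.

## Method

1. **Contacts.** For every trajectory frame, a binary residue contact map:
   residues *i*, *j* are in contact when any interatomic distance is
   ≤ 3.5 Å (inclusive). Stacking frames gives a binary tensor of shape
   (R, R, n), flattened to the feature matrix **I** of shape (R², n) with
   entries in {0, 1}.
2. **Smoothing.** Each feature trace is replaced by its centered moving
   average over a sliding window (canonically 125 frames ≈ 30 ns at a
   0.24 ns parse interval). Fast contact flicker averages toward an
   intermediate occupancy, while rare persistent transitions keep their full
   0→1 swing.
3. **Factorization.** Non-negative matrix factorization
   **I** ≈ **W H**, with **W** ≥ 0 (R² × c) holding *structural archetypes*
   (weighted contact sets characterizing conformational states) and
   **H** ≥ 0 (c × n) their *temporal weights*. Initialization is
   deterministic NNDSVD; the solver is HALS coordinate descent on the
   Frobenius objective ½‖I − WH‖²_F, so identical inputs give bit-identical
   factors. One component with a flat, substantial weight trace is the
   *stationary* component — the contacts that never change.
4. **Events.** A rare event is a handoff of dominance between two
   components: one archetype's weight falls while the next one rises
   through the same frames ("interlocking humps"). Each event is reported
   with its frame interval, crossover, component pair, and the top-k
   residue pairs of the incoming archetype.
5. **Ligand mode.** The same machinery on the (R, n) ligand–protein contact
   matrix with c = 3 and extra penalties (L1 sparsity on **W**, temporal
   smoothness on **H**) resolves binding-mode changes of the ligand.

Every stage is testable without MD data through a synthetic module that
plants archetype transitions, cavity scenes, and kinked helices with known
ground truth.

## Worked example

A synthetic benchmark trajectory: 40 residues, 1500 frames, five contact
archetypes visited in sequence (transitions planted at frames 300, 600,
900, 1200), 5% per-frame contact flicker.

```r
library(rednmf)

g   <- generate_contact_series(R = 40, n = 1500, n_states = 5,
                               flip_noise_rate = 0.05, seed = 1)
I   <- smooth_contacts(flatten_tensor(g$tensor), window_frames = 125)
fit <- red_nmf(I, k = 6)
summary(fit)
#> NMF fit: k = 6, 12 iterations
#>   ||I - WH||_F = 23.9963  (relative 0.0356)
#>   component temporal weights:
#>  component   mean      cv stationary
#>          1 0.9831 0.00849       TRUE
#>          2 0.2037 1.81000      FALSE
#>          3 0.1946 1.86000      FALSE
#>          4 0.1927 1.78000      FALSE
#>          5 0.1934 1.77000      FALSE
#>          6 0.1904 1.79000      FALSE

detect_events(fit)
#> Rare conformational events: 4 detected (stationary component: 1)
#>   outgoing incoming start_frame crossover_frame end_frame
#> 1        3        4         268             301       332
#> 2        4        6         569             601       633
#> 3        6        5         868             900       931
#> 4        5        2        1166            1199      1232
```

Component 1 absorbs the stationary contact scaffold (near-zero coefficient
of variation); the four dominance handoffs bracket the four planted
transition frames. `top_features(fit, 4)` then lists the residue pairs
whose contacts form when component 4 takes over, and
`event_report(events, frame_interval_ns = 2.4)` renders frame intervals as
trajectory times (frame 620 ↔ 1488 ns at that interval). `plot(fit)` draws
the component weight traces.

For real data, `run_pipeline()` goes from a PDB + DCD pair (plus an
optional two-column Ballesteros–Weinstein map) to an artifact bundle of
weight traces, events, feature rankings, viewer selection strings and
provenance; `run_metrics()` computes per-frame cavity water counts, helix
wobble angles and residue-pair distances from the same inputs.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package's headline benchmark from scratch: it regenerates
the synthetic world above for 20 independent seeds, runs the full
contacts → smoothing → factorization → event-detection chain on each, and
scores recovery of the planted transitions against the generator's ground
truth, writing the results file to `--out`.
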