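---
title: "fluctnet: methods, models and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fluctnet: methods, models and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluctnet)
```

## What the package computes

`fluctnet` analyses *paired* coordinate ensembles of a receptor — one run
in the active state and one in the inactive state per ligand, across a
panel of ligands with known pathway efficacies (E_max, % of a reference
full response). The hypothesis it operationalises is that the short-term
fluctuation *difference* between states, not the full transition pathway,
carries the efficacy signal: atoms whose active-minus-inactive fluctuation
difference correlates with E_max across the panel form an efficacy-linked
network, and region means over that network score new ligands.

The pipeline is: load/superpose ensembles → per-atom RMSF and per-pair
PCC → ΔRMSF, ΔPCC per ligand → Pearson screen against efficacy (per
pathway) → network extraction and visual reduction → region-mean scores
and efficacy bands.

### The pair statistic

PCC is the root of the *sum* of the 9 squared components of the 3×3
Pearson correlation submatrix between two atoms' coordinate deviations.
The "root mean square" reading (divide by 9 before the root) differs only
by the constant factor 3; it is exposed as
`compute_pair_correlation(..., pcc_normalization = "mean")` because the
constant rescales any threshold applied to PCC values downstream. All
defaults use the sum form, under which a self-pair lies in [√3, 3] and any
non-degenerate pair in [0, 3].

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `correlation_threshold` | 0.6 | – | the fixed panel-correlation screen defining network membership |
| `correlation_mode` | `absolute` | – | see below |
| `distance_cutoff` | 12 | Å | candidate couplings must be spatially proximal on a reference structure |
| superposition fit set | backbone heavy atoms (N, CA, C, O) | – | matches common trajectory-tool convention and the backbone-RMSD state monitors |
| equilibration discard | frames spanning 20 ns (`default_discard()`) | frames | equilibration removal is frame-count based, not time-lookup based |
| E_max preprocessing | clip at 100 % | % | assay responses above the reference are treated as full response; inverse agonists carry an assumed 0, the reference full agonist 100 |
| β-arrestin bands | ≥ 50 / 10–50 / < 10 | % E_max | the fixed banding rule of the assay scale |
| G-protein bands | > 99.14 strong; ≤ 20 weak | % E_max | see "Open design decisions" |

**Why `absolute` correlation.** The screen is stated as "correlation more
than 0.6", but in the data this package models, high-efficacy ligands have
*small* active-state fluctuation in the dominant region — the
score–efficacy relation is negative. A signed screen would select nothing
there. Magnitude-based selection is the only reading consistent with both
the screen and the sign of the region scores; `signed_positive` is kept
for sensitivity analysis.

**Which coordinates define "within 12 Å".** The analysis needs one
deterministic, ligand-independent reference so the candidate pair list is
common across the panel. The pipeline uses the panel average of the
inactive-state mean structures; any user-designated structure can be
substituted at the `enumerate_candidate_pairs()` level.

## The synthetic generator

No reference MD trajectory dataset is publicly available for this
receptor system, so the generator is a first-class module, not a fixture.
Each run is

> reference + isotropic Gaussian noise (σ, default 0.3 Å)
> + a(t) ∘ w (the planted collective mode),

where `w` is a fixed per-atom weight pattern supported on the planted
atoms (default: the 20 Cα atoms of the last two toy-receptor segments) and
`a(t) ∈ R³` is a per-frame latent amplitude, one independent component per
Cartesian axis, drawn at the programmed amplitude. The inactive amplitude
is constant (1.0 Å); the active amplitude is `a0 + slope·E_max/100`
(defaults 1.0 and −0.8, floored at 0), so the state difference is a
monotone function of efficacy. The default slope is negative to mirror the
observed direction (strong agonists quench the active-state mode), and its
sign is configurable so both correlation modes are exercised.

Three numerical choices make the ground truth exact rather than
approximate:

1. **Per-axis latents, not one scalar.** A single scalar latent makes
   *every* non-degenerate component of the 3×3 correlation block ±1,
   forcing PCC = 3 for a planted pair. With one independent latent per
   axis the block is diagonal (±1 on the diagonal, 0 off it), so a planted
   pair at zero noise has PCC = √3 — the self-pair value, i.e. "as coupled
   as an atom is with itself", which is the behaviour a planted coupling
   should have.
2. **Sample-orthogonalised, exactly scaled latents.** The three latent
   columns are centred, orthogonalised and scaled to the exact target
   amplitude in-sample, so at σ = 0 the closed forms hold to machine
   precision: RMSF_i = √3·A·|w_i| and PCC = √3 for planted pairs. At
   σ > 0 the closed forms are
   RMSF_i = √(3(σ² + A²w_i²)) and ρ_same-axis =
   A²w_i w_j / √((σ²+A²w_i²)(σ²+A²w_j²)), verified in tests within 3
   standard errors using delta-method SEs.
3. **Rigid-orthogonal pattern.** `w` is projected orthogonal to the
   rigid-body modes of the reference (zero net translation and torque),
   so least-squares superposition removes rigid motion without absorbing
   part of the planted mode or smearing an anti-correlated image of it
   onto the non-planted atoms — which would otherwise manufacture false
   positives proportional to the planted amplitude.

Random streams are derived per (ligand, state) from the master seed by a
counter scheme, so a ligand's ensembles are bit-identical whether generated
alone or inside a panel, and panels are reproducible end to end.

**What the generator does *not* emulate:** bonded geometry, excluded
volume, membrane anisotropy, time correlation (frames are i.i.d.),
multiple or localised modes, and state-dependent mean-structure change
(active and inactive share one reference). A green recovery test
establishes that the statistics, screens and bookkeeping are implemented
correctly on data satisfying the model's assumptions — it says nothing
about whether real trajectories satisfy them, and network sizes measured
on real sub-microsecond MD trajectories are not reproducible from this
package.

## Numerical choices

- **Averages use denominator T** (plain ensemble means), including inside
  variances. At T ≥ 1300 the difference from T−1 is far below analysis
  tolerance, but it must be pinned for the oracle tests, which agree with
  the production code to 1e-10.
- **Zero-variance axes** produce correlation components defined as 0
  (never NaN) plus a per-pair degeneracy flag; pairs degenerate in either
  state of any ligand are excluded from screens but remain visible in the
  serialized tables. This keeps every downstream screen total while
  preserving auditability.
- **Superposition** is a two-pass least-squares (Kabsch) fit: frames to a
  pass-1 target, then to the pass-1 time average. The pass-1 target
  defaults to frame 1; it can be any structure via `target=`. Because the
  per-axis-normalised correlation components are *basis-dependent*, the
  pipeline aligns each ligand's active run to its inactive run's average,
  so ΔPCC is differenced in a shared coordinate basis. Fitting to the run
  average (not a crystal reference) minimises the fluctuation attributed
  to rigid motion; whether the original tooling fitted to the crystal or
  the average is not stated, and the choice is documented here.
- **Rotations are proper**: the Kabsch solution is sign-corrected to
  determinant +1, and degenerate (collinear) fit selections are rejected
  via the singular-value spectrum.
- **Undefined correlations** (zero panel variance) propagate as `NA` and
  are never selected.
- **Tie-breaks / ordering**: selections are reported in ascending atom
  index; pair lists are unique with i < j; visual edges merge on
  (endpoints, colour class) with weight = merged count.

## Open design decisions

- **G-protein efficacy bands.** Only the β-arrestin banding is stated
  numerically. The G-protein strong band is anchored at the reference full
  agonist (isoprenaline, 99.14 %), strict inequality, so on the clipped
  panel 7 ligands are strong and isoprenaline itself is moderate; the
  weak/none band defaults to E_max ≤ 20 %, which places the weak partial
  agonist and both inverse agonists in it and the 43 % partial agonist in
  the moderate band. Both bounds are arguments of `classify_efficacy()`
  because the source grouping is given only as figure colouring and is
  internally ambiguous.
- **Display rule placement.** The "different secondary structures" rule is
  applied only to substituted (one-fluctuating) edges, matching the stated
  rule's placement; both-fluctuating edges are always exported.
- **No side-chain symmetry correction** (swapping of chemically
  equivalent atoms) is applied before fluctuation analysis; the toy
  receptor has no symmetric side chains, and for real inputs any such
  correction is assumed done upstream.
- **XTC/DCD readers** are not provided: no offline-capable binary
  trajectory reader exists in the supported dependency set, and
  multi-model PDB is the mandatory interchange format. The loader contract
  (atom-count check, equilibration discard, ≥ 2 retained frames) is format
  agnostic should a reader be added.

## Limitations

- PDB coordinates carry 3 decimal places; file round trips are exact only
  to 1e-3 Å. In-memory pipelines are full precision.
- Pair statistics are computed via a dense covariance of the involved
  atoms; panels of a few hundred atoms and a few thousand frames run in
  seconds to minutes on one CPU, but all-pair analyses of full-size
  receptors (~2000 heavy atoms) would need blocking.
- No statistical uncertainty is attached to Δ values (the analysis is
  defined on point values), and no multiple-testing correction is applied
  to the 0.6 screen — the screen's null selection rate (~2.3 % per atom at
  a 14-ligand panel) is instead verified against the analytic Pearson null
  tail in the acceptance suite.
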