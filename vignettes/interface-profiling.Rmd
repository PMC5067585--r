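---
title: "Profiling dimer-interface contacts in structural ensembles"
author: "EnsembleContacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling dimer-interface contacts in structural ensembles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EnsembleContacts)
```

# The problem and the model

Tyrosine-phosphorylated STAT5A dimerizes through reciprocal
phosphotyrosine(pY694)–SH2 domain binding. In an ensemble model of the
dimer fragment (SH2 domain, residues 589–687, plus the C-terminal tail:
linker 688–693, phosphotyrosine motif (PTM) 694–706, nTAD 707–714, on each
of two chains), the biologically meaningful output is not any single
structure but the *occupancy* of each residue-pair interaction: the
percentage of frames in which the pair satisfies a geometric contact
criterion. Highly occupied pairs (e.g. the pY694–R618 salt bridge) are
interpreted as load-bearing interactions; low occupancies mark transient
support. Contacts partition into three interface classes — intermolecular
PTM–SH2 (1), intermolecular PTM–PTM (2) and intramolecular PTM–SH2 (3) —
and because the dimer is nominally two-fold symmetric, interfaces 1 and 3
exist once per orientation, which makes a quantitative asymmetry measure
possible.

`EnsembleContacts` implements that analysis as a deterministic pipeline
over a `StructuralEnsemble`: a fixed atom topology (identical
`(chain, residue, atom)` sequence in every frame) with per-frame
coordinates in nanometres. Multi-model PDB is the interchange format; one
`MODEL`/`ENDMDL` block is one frame.

# Contact criteria and their parameters

All thresholds live in a single `ContactThresholds` object; inequalities
are strict (`<`), matching the "below"/"smaller than" convention the
criteria come from.

| criterion | default | unit | role |
|---|---|---|---|
| `hbondDist` | 0.35 | nm | donor–acceptor heavy-atom distance |
| `hbondAngle` | 30 | degrees | hydrogen–donor–acceptor angle at the donor |
| `hydrophobicDist` | 0.5 | nm | side-chain centre-of-mass distance |
| `saltBridgeDist` | 0.4 | nm | minimum N⁺···O⁻ heavy-atom distance |

The hydrogen-bond and hydrophobic cut-offs are standard
simulation-analysis values; the salt-bridge criterion is our own choice
(the Barlow–Thornton 0.4 nm N⁺/O⁻ convention), adopted because the source
analysis names salt bridges as a category without defining one, and
because it keeps salt bridges distinct from the 0.35 nm/30° hydrogen-bond
class. It is configurable for users who prefer a 0.45 or 0.5 nm variant.

Chemistry (which atoms donate, accept, carry charge, form rings, or belong
to side chains) is data, not code: an editable TSV covering the 20 amino
acids plus phosphotyrosine (PTR, acceptors O1P/O2P/O3P, negative group
{O1P, O2P, O3P, P}, aromatic ring, no side-chain hydroxyl donor).
Decisions embedded in the default table:

* **Histidine** is listed as donor *and* acceptor at ND1/NE2; it only
  gains a positive charge group via `defaultChemistry(protonatedHis =
  TRUE)`. Protonation states are an input assumption — the package does
  not predict them.
* **Side-chain membership**: heavy atoms are enumerated per residue;
  hydrogens follow the PDB position-letter convention (HB*/HG*/HD*/HE*/
  HZ*/HH* are side chain, H/HN/H1–3/HA* are backbone). Hydrogens are
  *included* in the centre of mass when present, since "centre of mass"
  states no exclusion; with explicit-hydrogen ensembles this shifts COMs
  by a few hundredths of a nm at most.
* **Glycine** has an empty side chain and can never appear in a
  hydrophobic contact.
* Unknown residue codes soft-fail: they are excluded from detection with a
  warning rather than aborting an ensemble (strict mode turns missing
  donor hydrogens into errors).

**Aromatic contacts** are defined as the hydrophobic-criterion pairs in
which both residues carry a ring, with the ring-centroid distance also
under the 0.5 nm cutoff (that centroid distance is what is reported).
Requiring both keeps the aromatic set a subset of hydrophobic-eligible
pairs *and* keeps every reported distance below its governing threshold;
no ring-plane angle term is applied, because the quantity being reproduced
is an occupancy of hydrophobic-type contacts, not a π-stacking geometry
classification. For phosphotyrosine-ring packing (the N642/K644 type of
contact) the whole-side-chain COM is the default; ring-only analysis is
available by editing the chemistry table.

Two residue-level conventions matter downstream: residue identity is
`(chain, res_seq, i_code)` with numbering taken as-is (STAT5A numbering in
all defaults), and every event stores its pair in canonical
(chain, number) order so the event multiset is unique and independent of
atom input order.

# Occupancy, interfaces, asymmetry

`accumulateOccupancy()` counts, per (pair, kind), the number of distinct
frames containing at least one qualifying event — two simultaneous
hydrogen bonds in one frame count that frame once — and reports
`100·n_present/n_frames`. Pairs never observed are not enumerated (the
candidate universe is unbounded). A persistence label splits records at a
configurable 25% cutoff; the published vocabulary calls 5.4% "transient"
and ≥41% "large persistence" without naming a boundary, so the label is
reported alongside the raw occupancy and is never load-bearing.

`assignInterface()` applies the three-class scheme with nTAD grouped into
the tail: different chains with one residue in PTM∪nTAD and one in SH2 →
interface 1; both in PTM∪nTAD → 2; the same-chain tail–SH2 case → 3; any
linker residue → `linker`; everything else `other`. nTAD is grouped with
the PTM because the C-terminal tail percolates across the interface as one
unit (F706's neighbours sit right at the PTM/nTAD boundary).

`asymmetryScore()` matches interface-1 (or -3) records across the two
orientations by (kind, tail residue, partner residue) and returns the mean
absolute occupancy difference over the union of matched pairs, missing
partners counting as 0%. The underlying observation is qualitative
("local structural asymmetry"), so the metric is our design choice: it is
0 exactly for a mirrored profile, is invariant under chain relabelling,
and a single 100% vs 97% pair yields 3.0 — the scale of the score is the
scale of the occupancies themselves.

# Clustering and convergence diagnostics

* **Superposition** is classic Kabsch (SVD with a determinant guard, so
  the rotation is always proper). `rmsdSeries()` fits every frame to the
  reference before measuring; the default selection is the backbone
  defined as N, CA, C, O. Cβ is deliberately excluded — "backbone" with Cβ
  is the other common convention, and users comparing against it can pass
  their own selection. No mass weighting by default, as none is implied by
  "backbone RMSD".
* **Clustering** is GROMOS neighbour counting: pairwise post-fit RMSD, the
  frame with most neighbours within the cutoff becomes a centroid, it and
  its neighbours are removed, repeat. Default cutoff 0.2 nm on backbone
  atoms — the standard scale for "most representative structure" claims —
  with ties broken toward the lowest frame index so results are
  deterministic. The representative structure is the centroid of the
  largest cluster, reported with its coverage so a "more than half of the
  sampled conformations" statement is checkable. Equilibrated-window
  selection (e.g. the last quarter of a trajectory) is a user-supplied
  frame range, not auto-detected.
* **Covariance analysis** superposes frames to the ensemble mean with a
  single fit-to-mean iteration (fit to frame 1, average, refit — the
  standard practice; full iterative convergence changes third decimals at
  most and is not worth the extra pass), then diagonalizes the 3N×3N
  positional covariance. The eigenvalue sum equals the total positional
  variance (trace conservation), which the tests assert to 1e-9.
* **Cosine content** of mode *i* follows Hess:
  `c_i = (2/T)·(∫ p(t)·cos(iπt/T) dt)² / ∫ p(t)² dt`, evaluated by
  trapezoidal integration on the uniformly spaced series and clamped into
  [0, 1] (Cauchy–Schwarz guarantees the bound analytically; the clamp only
  absorbs rounding). Values near 1 mean the projection looks like random
  diffusion (unconverged sampling); near 0 means fluctuation about an
  equilibrium. There is no published numeric target for this quantity here
  — the reference analysis reports it only as "close to 0" — so the tests
  check the closed-form cases (pure cosine → 1, constant → 0,
  mode-mismatch → ≈0) and the rank property that random walks score far
  above white noise.

Degenerate inputs are typed errors: fewer than 3 or collinear atoms for a
superposition, all-zero series for cosine content, empty frame windows,
out-of-range mode counts.

# Variant mapping

The interface catalog records the named SH2-domain pockets: the
phosphotyrosine pocket {R618, K600, S620, S622, T628, N642, K644}, the
pY+1 (V695) pocket {W631, W641, L643} and the hydrophobic acceptor
interface for F706 {W631, F633, W641, L663, Y665, L666}.
`annotateVariant()` places a position (589–714) into its region and
interface: pocket residues → interface 1 (hydrophobic-interface residues →
3), PTM positions → interface 2 except pY694/V695 (interface 1) and F706
(the interface-3 donor). Cohort frequencies are recomputed from carrier
counts with half-up rounding to one decimal; the built-in table stores
counts, never percentages, and one inconsistent printed frequency (I699L,
2.0% vs 1/94 and 1/68) is flagged in its note column rather than silently
resolved. STAT5B numbering equivalences are kept as free-text notes only.

# What the synthetic generator does and does not emulate

`generateContactEnsemble()` builds two-chain multi-model ensembles in
which each designed pair occupies its own spatial station (5 nm apart):
present frames place the interacting groups at 80% of the governing
threshold, absent frames at 150%, with ≤0.005 nm rigid per-residue jitter.
The margin bands mean detection is *exact*, not statistical — recovered
occupancies equal designed occupancies with zero error, and that is the
point: the generator tests the detection/aggregation machinery, not the
physics. Designed geometry also fixes the induced contacts: a charged pair
under 0.4 nm necessarily satisfies the 0.5 nm COM criterion, and an
aromatic pair's ring centroid coincides with its side-chain COM, so the
truth table lists those induced hydrophobic schedules explicitly. Residue
builds are minimal idealized fragments (a hexagonal ring, single-atom side
chains, a donor with one hydrogen); reproducibility is byte-exact for a
given spec and seed.

What it does **not** emulate: force-field realism, correlated motions,
solvent, crowding (real frames have thousands of near-threshold distances,
not margin-banded ones), missing hydrogens, alternate locations, or
wrapped periodic images. Passing the recovery tests therefore shows the
pipeline is correct and deterministic; it says nothing about whether a
particular MD ensemble is converged or well-modelled — that is what the
RMSD/cosine-content diagnostics are for on real data. Random stress frames
(`generateRandomFrame()`) complement the designed ones: residues with full
polar-hydrogen builds scattered at realistic density, compared
event-by-event against an exhaustive brute-force scan.

The cluster fixture distorts a base conformation along a
rigid-motion-free direction (refitting between scaling iterations) to a
designed post-fit RMSD separation and wobbles frames with Gaussian noise
(σ = wobble/2.5 per coordinate) so within-group pairwise RMSD stays below
2·wobble; it requires `wobble < separation/4` so groups cannot blur.

# Problem sizes and runtime choices

The validation suite runs at deliberately small scale: 100 random frames
of 5–50 residues for the detector–oracle comparison, 500-frame designed
ensembles for occupancy recovery, 50–60 frames for symmetry and clustering
fixtures, 1000-point series for the convergence closed forms. These sizes
make every check exact or analytic while keeping the whole suite in the
minutes range on one core; the pipeline itself is vectorized per frame and
scales linearly in frames (clustering is quadratic in the window length,
as pairwise-RMSD methods are).

# Known limitations

* PDB only (fixed-width v3.3); no mmCIF or binary trajectory formats —
  convert with standard tools first.
* No periodic-boundary imaging: inputs are assumed whole molecules; an
  extent sanity check warns when coordinates look wrapped or mis-scaled.
* No π-stacking geometry classes, cation–π or water-mediated bridges.
* The asymmetry score and the salt-bridge criterion are package-defined
  conventions (documented above), not community standards frozen
  elsewhere; both are parameterized.
* Variant annotation is positional: it maps residues onto interfaces and
  pockets but makes no stability or pathogenicity predictions.
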