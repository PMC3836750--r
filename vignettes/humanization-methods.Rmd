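---
title: "Epitope-scanning humanization and CDR-RMSD key-residue analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epitope-scanning humanization and CDR-RMSD key-residue analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abscan)
```

## The problem

A rodent monoclonal antibody binds its human target through six
hypervariable loops (CDRs) held in place by four framework segments
(FR1–FR4) per chain. Humanization must remove the framework's
immunogenic, rodent-specific residues without disturbing the CDR
conformation. `abscan` implements a two-filter strategy: substitute only
framework residues that are *antigenic* (epitope scanning), then revert
the few substitutions that measurably deform the CDRs (key-residue
analysis by CDR RMSD). This vignette records the model, its assumptions,
the tunable parameters, and the numerical and design decisions behind the
implementation.

## Region delimitation

Positions are 1-based sequential indices into each translated chain —
the same convention the substitution tables use (a light-chain position
106 exists, which rules out insertion-coded numbering). CDR/FR
delimitation is *anchor-based*, not profile-based: the first conserved
cysteine (expected near position 22–23), the second conserved cysteine
(before the J segment) and the J-anchor motif (`WG.G` on heavy chains,
`[FW]G.G` on light chains) are located first; fixed per-scheme offsets
from those anchors then place the CDR boundaries. The offset table
(`cdr_boundary_rules()`) renders the published Kabat, Chothia and IMGT
definitions into sequential coordinates: for example Kabat L-CDR1 starts
one residue after the first cysteine with length 11, IMGT CDRs start four
residues after the first and one after the second cysteine, and the
Kabat/Chothia heavy CDR3 starts three residues after the second cysteine
(the two intervening residues, typically A-R, belong to FR3 under those
schemes but to CDR3 under IMGT). An HMM-based numberer would handle
unusual indels better; for the antibodies this workflow targets the
anchor rules are deterministic, auditable, and — crucially — overridable:
a manual `region_map` (TSV of position → region) always wins, and every
downstream function accepts it. When anchors cannot be found the
delimiter refuses rather than guesses.

Which scheme feeds the scans is a required parameter defaulting to IMGT
(the convention used to box CDRs in variable-domain sequence figures);
nothing downstream depends on that choice structurally, and all three
schemes are first-class.

`X` (unknown) residues parse but are inert: an X position is never
rodent-unique, and any probe window containing an X is skipped rather
than force-flagged — an unknown residue is missing evidence, not evidence
of antigenicity.

## Epitope scanning

Let the query chain be mapped onto the columns of a human template
alignment (see below). With column profile $P_c$ = the multiset of
non-gap residues observed at column $c$:

* **Rodent-unique test.** FR position $p$ with residue $a$ is
  rodent-unique iff $a \notin P_{m(p)}$.
* **Linear scan.** Every `window_length = 6` consecutive FR positions
  form a probe (one step per cycle; probes never straddle a CDR). The
  probe is a possible linear epitope iff **no single template** matches
  it at all columns with at most `max_mismatches = 0` mismatches, a
  template gap counting as a mismatch. Requiring the match within one
  template is the strict reading of matching a peptide against individual
  human sequences — it is what makes the 6-residue neighbourhood of a
  position matter, since a position whose residue occurs in *some* human
  sequence can still sit in a window that no *single* sequence matches.
  The lenient per-column union is available as
  `match_mode = "column_union"` because the matching tolerance of the
  original description is ambiguous; the mismatch allowance is likewise a
  knob.
* **Conformational scan.** Every unordered FR pair $(i, j)$ is flagged
  iff the minimum distance over constituent atoms is below
  `pair_distance_cutoff = 5` Å **and** no single template carries both
  residues at the two columns. "Constituent atoms" defaults to heavy
  atoms (hydrogens excluded; MD-derived models would otherwise make the
  result protonation-dependent); a Cα-only mode exists. All FR pairs are
  scanned, not only pairs of already-identified rodent-unique residues.
  Sequence-adjacent pairs ($|i-j| \le 1$) are excluded by default — the
  linear scan owns them — and the exclusion is configurable.
* **Substitution proposal.** The union of rodent-unique positions flagged
  by either scan is substituted with the *column consensus*: the most
  frequent residue of $P_{m(p)}$, ties broken alphabetically, gaps never
  chosen. Conformational-pair members that individually occur in human
  templates are dropped, keeping the invariant that every proposed
  position fails the membership test. The consensus is a reproducible
  surrogate for the expert choice among human residues; with the exact
  20-template sets and their manual alignment edits unavailable, the
  published per-position choices cannot be re-derived mechanically, so
  the proposal logic is tested against planted fixtures instead.

Template sets are managed as alignments (aligned FASTA or Clustal
`.aln`; `-` and `.` gaps normalized). The query is placed into the MSA by
a pairwise Needleman–Wunsch alignment (BLOSUM62, gap open 10, extend 0.5
— blastp-like defaults, configurable) against a single *anchor* template
(highest-scoring by default), composed through the anchor's gap
structure. Re-running a progressive MSA with the query would be neither
reproducible nor faithful to a manually adjusted alignment; the manual
column-mapping TSV override covers the cases where the pairwise route is
wrong. The pairwise engine is Biostrings' `pairwiseAlignment`, whose
tie-breaking among co-optimal alignments is deterministic; optimality of
the score is what the tests pin down (against exhaustive enumeration on
short strings), since co-optimal paths are interchangeable downstream.

## CDR RMSD and key residues

Similarity of two structures is measured after optimal rigid-body
superposition by

$$\mathrm{RMSD} = \sqrt{\tfrac1N \sum_{i=1}^N \lVert r_i - r_i^0\rVert^2}$$

with the rotation from the Kabsch SVD construction, reflection excluded
(determinant +1). Degenerate inputs — fewer than 3 points, collinear
point sets — are errors, not warnings. `cdr_rmsd()` pools the Cα atoms
of all six CDRs of both chains, superposes *on the CDRs themselves* and
reports the residual; fitting on the loops directly asks "can the mutant
CDRs be rigidly laid on the parental ones?", which is the question the
key-residue call needs. An FR-fit/CDR-measure mode is provided for the
alternative convention. Cα-only is the default atom set; the RMSD of a
loop backbone is what the 1.0/1.5 Å conventions below were calibrated
against.

Thresholds: a mutant with CDR RMSD < 1.0 Å is annotated *identical* (the
conventional same-structure cutoff); a mutant with RMSD ≥ 1.5 Å marks its
position as a **key residue** to be back-mutated. Antigen binding is
conformation-sensitive enough that deviations above 1.5 Å — even below
the classical 2.0 Å "different structure" line — risk measurable affinity
loss, hence the stricter threshold. Because single-point mutants cluster
near these boundaries, the threshold is a parameter and the report always
contains the full, sorted RMSD table so near-threshold calls are
auditable rather than silent.

When per-mutant structures come from MD, the package consumes the
trajectory, never runs it. `rmsd_series()` gives the RMSD-versus-time
curve against a reference frame; `detect_balance()` declares the series
balanced from the earliest index after which *every* sliding window is
flat: |least-squares slope| ≤ `slope_tol` = 0.02 Å/ns and SD ≤ `std_tol`
= 0.15 Å, window defaulting to 10 % of the run. No convergence criterion
accompanies the original RMSD-curve description; these defaults were
fixed once against the synthetic saturating fixtures and are exposed as
parameters. `average_structure()` then averages coordinates over the
balanced range after per-frame superposition. Where both sides of a
comparison are trajectories, the default is average-structure versus
average-structure (the per-mutant number is a property of two structures,
not a time average of a fluctuating quantity); time-resolved RMSD remains
available through `rmsd_series()`.

## Humanization bookkeeping

`apply_substitutions()` refuses any record whose parental residue
disagrees with the table (`expected R at L:66, found K`), which catches
sequence/table desynchronization — the dominant practical failure mode.
Back-mutation reverts key positions to the table's rodent residue;
applying a table and then reverting all of its positions is an exact
round trip, and the test suite holds that as a property over random
fixtures. The humanization rate is
$100\,(n_\mathrm{FR} - n_\mathrm{back}) / n_\mathrm{total}$, rounded
half-up to one decimal to match the precision the rates are quoted at
(600/663 → 90.5; (600−5)/663 → 89.7). The packaged substitution tables
for the 1-17-2 rat anti-human DEC-205 antibody (20 light-chain and 10
heavy-chain records, plus the key residues L38, L43, L45, L71, H77) ship
as plain TSV under `inst/extdata/`.

Disulfide bookkeeping pairs cysteines *sequentially within each domain*
(variable/constant, split at a per-chain boundary): first with second,
third with fourth; an odd leftover is reported, never fatal. For the
canonical Fab cysteine lists this yields the four intradomain bonds.

## Synthetic fixtures: what they do and do not show

All tests run offline on generated data (`make_sequence_fixture()`,
`make_structure_fixture()`, `make_trajectory_fixture()`), deterministic
under a fixed seed. Defaults mirror the study conditions: 20 human
templates per chain, IMGT delimitation, 5 ns trajectories stored every
5 ps (1000 frames), a 1.5 Å plateau RMSD, 30-mutant key-residue panels
with 5 planted hits. The generators emulate the *logical* structure of
the inputs — template sets that agree with the query except at planted
positions, idealized Cα traces (3.8 Å spacing on a helical curve),
mutants whose CDR-fit RMSD is calibrated to a requested magnitude within
0.05 Å, drifting trajectories with a known changepoint and Gaussian
coordinate noise (σ = 0.05 Å by default). They do **not** emulate real
antibody germline diversity, alignment gaps from true indels, side-chain
rotamers, correlated MD fluctuations, or physically realistic loop
geometry. Green tests therefore certify the algorithms — membership
logic, window matching identical to an exhaustive oracle, superposition
optimality, planted-truth recovery with sensitivity and specificity 1 —
not the biological accuracy of any particular humanization, which always
depends on the quality of the template set and the mutant structures
supplied.

Test problem sizes are deliberately small: toy scan instances up to 30
residues × 6 templates (where brute-force oracles are exact and fast),
100 random point sets against 10,000 random rigid motions for the
superposition optimality check, and 1000-frame trajectories of 40
residues for balance detection. These sizes make the oracles exhaustive
and the suite quick while exercising every code path at realistic
variable-domain dimensions (the sequence fixtures themselves are
full-length V domains of 107/118 residues).

## Known limitations

* Anchor-based delimitation assumes canonical variable domains; heavily
  engineered or truncated chains need a manual region map.
* No insertion-coded position labels (100A); sequential numbering only.
* One anchor template mediates the MSA mapping; a badly chosen anchor
  (override available) shifts columns for all scans.
* The conformational scan is intra-chain; inter-chain FR pairs are not
  enumerated.
* The consensus replacement ignores position-specific chemistry
  (e.g. Vernier zones); it proposes, a human decides.
* Balance detection is a descriptive flatness test, not a statistical
  changepoint model; series that drift slower than `slope_tol` forever
  will pass.
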