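---
title: "Profiling amyloid aggregates for conformational epitope accessibility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling amyloid aggregates for conformational epitope accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epiturn)
```

## The model

An oligomer-specific antibody against amyloid-β (Aβ) must discriminate
between assemblies of a peptide whose sequence is identical in monomers,
oligomers and fibrils. The discriminating signal is conformational. `epiturn`
formalizes the structural reading of that signal as three per-chain criteria
evaluated on a static aggregate model:

1. **Turn sharpness.** The epitope residues (default 25–29, the GSNKG turn)
   must form a sharp turn, measured as the Cα(25)–Cα(29) distance. A cyclized
   mimotope of the epitope spans about 5.6 Å; published sharp-turn aggregate
   models span up to ~7.9 Å, wide turns cluster around 9.5–13.3 Å, and
   non-turn (extended) conformations at 13.4 Å and above.
2. **Key-lysine availability.** The K28 side chain must be solvent-exposed
   *and* free: in fibril models it is typically sequestered in a salt bridge
   with D23 of the same or a neighboring chain, or with the C-terminal
   carboxylate of A42.
3. **Clearance.** In fibrils, equivalent epitope turns stack ~4.8 Å apart
   along the fibril axis; a binding pocket cannot engage a turn that is
   crowded by its neighbors. We require the epitope-turn Cα centroid to be at
   least a clearance radius away from every other chain's equivalent
   centroid.

An aggregate is **positive** when at least `min_chains` chains (default 1)
pass all three criteria. The conjunction rule is one defensible formalization
of a narrative judgement: published characterizations occasionally weigh the
criteria against each other (for example, a prefibrillar oligomer with sharp
turns is still judged negative on crowding and lysine-engagement grounds);
the conjunction reproduces those calls without introducing weights we could
not justify. The per-chain criteria trace is always emitted so a user can
apply a different aggregation.

## Parameters and defaults

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `sharp_max` | 8.5 | Å | published sharp exemplars span 5.55–7.8 Å, wide exemplars start at 9.47 Å; the boundary sits between the clusters |
| `wide_max` | 13.5 | Å | "no sharp turn" exemplars run 13.4–15.04 Å; see the note below |
| `probe` | 1.4 | Å | water-probe convention for solvent-accessible surface area |
| `n_points` | 960 | – | sampling error for an isolated atom is below 1% at this density |
| `exposure_threshold` | 20 | Å² | lysine side-chain (CB–NZ) area; an engaged or buried lysine falls well below, a free one well above |
| `clearance` | 10 | Å | fibril-like 4.8 Å stacking must fail, dispersed oligomer turns (tens of Å) must pass |
| `hbond` | 3.5 | Å | heavy-atom donor–acceptor cutoff |
| `hydrophobic` | 5.0 | Å | side-chain carbon–carbon, both residues apolar |
| `ionic` | 6.0 | Å | charged-group minimum distance; also the salt-bridge screen for K28 |
| `aromatic_min`/`aromatic_max` | 4.5 / 7.0 | Å | ring-centroid band |
| `aromatic_sulphur` | 4.3 | Å | CYS SG / MET SD to ring centroid |
| `cation_pi` | 6.0 | Å | LYS NZ or ARG guanidinium centroid to ring centroid |
| `high_occupancy` | 0.6 | fraction | boundary for the qualitative high/low occupancy label |

The 13.5 Å `wide_max` default places a 13.4 Å span in the *wide* class rather
than *extended*. Both classes are "not sharp", which is the distinction the
classifier consumes; the wide/extended boundary only affects reporting. All
values are exposed in `classifier_config()` and echoed into every report.

### Design choices in the detectors

- **Hydrogen bonds.** Only the 3.5 Å heavy-atom cutoff is well established
  for this workflow; angle conventions differ between tools. We apply a
  donor–H–acceptor ≥ 120° test *only* when explicit hydrogens are attached to
  the donor, so hydrogen-free crystal structures are judged on distance alone
  while grossly non-linear geometries are rejected when hydrogens exist.
- **Donor/acceptor typing** is shipped as data (backbone N donor except
  proline, backbone O/OXT acceptor, standard side-chain N/O roles, hydroxyls
  and histidine ring nitrogens in both roles). Sulfur is excluded from both
  roles.
- **Histidine** is excluded from the cationic set by default (pH 7
  protonation), switchable with `include_his`.
- **Tyrosine** counts as apolar for hydrophobic contacts (the convention of
  the standard interaction calculators); its hydroxyl still hydrogen-bonds.
- **Termini.** The first residue's amine is cationic and the last residue's
  O/OXT anionic for ionic detection — this is what lets a C-terminal
  carboxylate sequester K28. Termini are not cation-π donors.
- **ARG cation-π position** is the CZ/NH1/NH2 centroid (a common convention;
  not dictated by the workflow we reproduce).
- Only **cross-interface** pairs are reported; intra-selection contacts never
  appear.
- **Occupancy** is keyed per atom/group pair, so two distinct hydrogen bonds
  between the same residues are separate rows; `rollup = TRUE` aggregates per
  (residue pair, kind). All pairs observed in *any* frame are counted — the
  original workflow identified pairs on the last frame and then measured
  their distance series, which can drop transient pairs absent from the last
  frame; counting all observed pairs is the reproducible superset.
- Some interaction kinds were originally evaluated only on the final frame of
  a simulation. We compute every kind frame-wise and let reporting select the
  last frame (`cmd_fingerprint(..., frames = "last")`), which subsumes both
  readings.

## The synthetic-structure generators

The generators stand in for docked antibody–antigen complexes and MD
trajectories, which cannot be produced at desk scale. They emulate exactly
the features the analyses consume:

- `make_turn_peptide(span)` places the epitope Cα atoms on a circular arc
  with 3.8 Å virtual bonds bent to the requested span (any span up to the
  4-step maximum of 15.2 Å), with a full lysine side chain pointing outward
  from the turn, and optionally an aspartate carboxylate planted within
  salt-bridge range of the lysine amine.
- `make_contact_interface(contacts)` plants each requested contact at its own
  site, 30 Å from the next, using residue-type pairs chosen so a contact of
  one kind cannot co-trigger a detector of another kind at the same site
  (for example HIS–PHE for aromatic–aromatic, because histidine is aromatic
  but not apolar). Isolated spacer residues terminate each chain so terminus
  charges never contaminate a site. A planted salt bridge implies, by
  definition, its hydrogen-bond and ionic components.
- `make_occupancy_trajectory` displaces the mobile residue 15 Å in
  contact-absent frames (beyond every cutoff plus 2 Å), under either an
  explicit frame mask (occupancy is then exact by construction) or a
  Bernoulli presence probability.
- `make_multimer_stack` translates chain copies along one axis, so the
  epitope-centroid spacing equals the requested spacing exactly; 4.8 Å
  emulates fibril stacking.
- `make_random_interface` scatters randomly oriented residue templates in two
  facing slabs; nothing is planted, and detector output is compared against
  independent brute-force oracles on whatever geometry results.

What the generators do **not** emulate: chemically valid bond geometry,
side-chain rotamer statistics, secondary structure, or force-field energies.
A green test therefore establishes that the geometric criteria and detectors
are implemented correctly and consistently — not that the thresholds are
optimal for any particular experimental structure, and not any claim about a
real antibody's affinity. Likewise, the published turn spans of deposited
structures are reproduced on synthetic stand-ins built *to* those spans
(this environment has no access to the deposited coordinates), which
validates the measurement, not the deposition.

Every generator is deterministic under its seed (byte-identical PDB output)
and isolates its RNG stream, so adding a fixture never perturbs existing
ones.

## Numerical choices

- **Kabsch superposition** uses the SVD solution with sign correction of the
  smallest singular vector, so reflections are never returned. Inputs with
  fewer than 3 atoms or collinear coordinates are rejected rather than
  silently handled. The tests verify optimality against a
  quaternion-parameterized numerical minimizer to 1e-6.
- **LRMSD** aligns every frame to frame 1 over the selection; **RMSF** is
  taken about the mean position after aligning on a (possibly different)
  alignment selection, defaulting to all Cα atoms — this separation is what
  makes the closed-form single-oscillating-atom case exact.
- **SASA** uses a deterministic golden-spiral point set, so results are
  reproducible to the bit on the same input; rotation invariance holds only
  to sampling tolerance (a few percent on small atoms). Hydrogens are
  excluded from both the reported atoms and the occluder set so structures
  with and without explicit hydrogens are comparable. Unknown elements are an
  error unless a fallback radius is supplied.
- **Alternate locations** keep the highest-occupancy conformer, ties broken
  by file order. Author residue numbering and insertion codes are preserved
  verbatim and form residue identity; HETATM residues parse like any other.
- **PDB coordinates** are written at 3-decimal fixed width; values outside
  the representable range are a format error, not a silent truncation.
- Degenerate requests fail loudly everywhere: empty frame ranges, single
  frames for RMSF, infeasible turn spans, planted distances outside a kind's
  detectable range.

## Known limitations

- The classifier consumes a single static model (the first frame of a
  trajectory); it does not average verdicts over frames.
- No binding-energy estimation, docking, electrostatics, or
  secondary-structure assignment — the package evaluates geometric
  accessibility criteria only.
- The published per-chain turn spans for one two-fold-symmetric fibril entry
  are inconsistent with the same source's quoted range for that entry; we
  report per-chain values and do not reconcile the range.
- mmCIF and binary trajectory formats are out of scope; multi-MODEL PDB is
  the trajectory format.
- Whether the original qualitative "solvent-exposed" calls used any
  quantitative area criterion is unknown; the 20 Å² threshold is this
  package's own, documented and configurable.
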