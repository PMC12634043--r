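---
title: "Topology generation by graph matching: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology generation by graph matching: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgweaver)
```

## The model

cgweaver treats a molecule as an undirected graph: particles (atoms or
coarse-grained beads) are nodes carrying attributes — only the atom name,
residue name and residue number are mandatory; element, charge, mass,
position (nm), particle type and secondary structure are optional — and
edges are bonded connectivity.  Everything the pipeline does is a graph
operation: partitioning a structure into molecules is connected-components;
recognizing a residue is subgraph matching against a canonical template;
mapping between resolutions is covering the graph with fragment pairs;
adding inter-residue interactions is pattern matching with link templates;
and the elastic network's residue minimum distance is a shortest-path
length on the residue graph.  Bonded interaction terms (bonds, angles,
dihedrals, constraints, exclusions, virtual sites) are kept separate from
the edge set: their parameters are carried verbatim and never interpreted
numerically, except where an operation's definition requires geometry
(elastic-network generation measures distances).

Force-field knowledge lives in data, not code: *blocks* are the canonical
graphs of residues or monomeric repeat units with their intra-fragment
interactions, *links* are patterns adding interactions across residue
boundaries, *modifications* are deltas to canonical residues (protonation
states, tautomers, post-translational modifications, termini), and
*mappings* pair a fragment at two resolutions with a weighted particle
correspondence.  New chemistry therefore needs new data files, not code
changes, and the same pipeline produces coarse-grained or all-atom
topologies (the latter through identity mappings).

## The pipeline

`run_pipeline()` chains six stages:

1. **Read** a PDB or GRO structure (first model, highest-occupancy
   altloc, Å converted to nm at parse time).
2. **Bond inference and partitioning** by one of three strategies —
   interatomic distance against scaled covalent radii, canonical atom
   names within residues plus sequential link patterns, or CONECT
   records — followed by connected components.  Chains joined by a
   disulfide are one molecule; an unbonded cofactor is a separate one.
3. **Identify and repair**: each residue is compared against the block
   selected by its residue name (through an alias table that resolves
   CHARMM/AMBER-style protonation names).  Names are corrected, missing
   heavy atoms added as coordinate-free nodes, extra atoms resolved
   against the modification library; chain termini get the force field's
   terminal modifications.
4. **Resolution transformation**: mappings cover the molecule
   (largest residue scope first), beads get positions as weighted means
   of their source atoms, edges follow mapped source bonds, and
   intra-fragment interactions are copied from the target blocks.
5. **Create topology**: links add inter-residue bonds, angles and edits;
   later links override earlier ones on the same particles.
6. **Post-processing and writing**: optional elastic network, then
   deterministic GROMACS `.itp`/`.top`/`.gro` output — written only if
   the warning ledger is clean (below).

## Graph matching

Residue recognition needs attribute-aware subgraph isomorphism.  The
matcher is a VF2-style recursive search: pattern nodes are ordered by
candidate rarity and degree (rarest, most-constrained first), candidates
must satisfy the node predicate, already-matched neighbours must map onto
target edges, and results are reported in a deterministic order (sorted by
the matched target ids).  The default node predicate compares elements
when both are known and falls back to atom names, which keeps the pipeline
robust to the inconsistent atom naming of real structure files.  Subgraph
isomorphism is NP-complete, but the graphs here are residues and small
fragments (a dozen heavy atoms), so worst-case behaviour is immaterial;
the common clean-residue case bypasses the search entirely through a
name-equality fast path that still verifies elements and connectivity.

When a residue is damaged — missing atoms *and* unexpected atoms, swapped
elements, broken or spurious bonds — no full embedding exists in either
direction, and the repair falls back to a maximum common induced subgraph,
computed as a maximum clique of the modular product graph (via igraph).
Ties between maximum correspondences are broken by the number of exact
atom-name agreements and then by the lowest lexicographic assignment, so
repair is reproducible.  Whatever the correspondence leaves unmatched
becomes missing/extra atoms, which either resolve to modifications or end
up in the warning ledger.

Modification resolution searches for a set of modifications whose added
atoms exactly cover the residue's extra atoms, with anchors on canonical
atoms; the minimal set wins, ties broken by name.  Residue names that
already encode a state (e.g. a protonated histidine under its
CHARMM/AMBER name) short-circuit this search through the alias table:
an exact residue-name hit wins over graph-based detection.

## The warning ledger

Every diagnostic is a typed entry (`unrecognized-residue`,
`unexpected-atoms`, `missing-atoms`, `missing-coordinates`, `ss-failure`,
`empty-selection`, `io`, `general`) with residue context.  Output files
are written only when the number of unignored warnings does not exceed
`maxwarn` (default 0); categories can be ignored selectively.  The point
is high-throughput safety: a corrupted residue can stop the run, or be
consciously waved through, but can never slip into a topology silently.
Renames performed by repair are informational entries and never block.

## Elastic network

The elastic network is pure post-processing: harmonic bonds (GROMACS bond
type 6, which generates no exclusions, so the network cannot perturb the
nonbonded topology) between eligible beads, default the backbone bead,
within `[lower_cutoff, upper_cutoff]` whose residue-graph distance is at
least the residue minimum distance (RMD) and which share an EN unit
(`molecule`, `chain`, `all`, or declared resid `region`s).  Defining the
RMD as a graph distance means residues joined by a disulfide bridge are
close in the graph and are excluded by the same rule as sequence
neighbours.  EN bonds never become graph edges, so partitioning and graph
distances are unchanged — the network is a bias, not chemistry.

Parameter defaults: `upper_cutoff` 0.9 nm, `lower_cutoff` 0 nm, force
constant 700 kJ mol⁻¹ nm⁻², RMD 3, unit `molecule`; all overridable.  The
RMD of 3 is part of the protein model (it keeps the network from competing
with backbone bonds, angles and dihedrals) and should not normally be
changed; the cutoffs and force constant are this package's declared
defaults in the conventional range for such biases.  Equilibrium lengths
are the measured distances rounded to 10⁻⁵ nm so output is byte-stable.

## The demonstration force field

The bundled `demo-aa`/`demo-cg` pair and its mappings exist so that every
pipeline stage is exercisable without distributing any published parameter
set: a reduced amino-acid alphabet (GLY, ALA, CYS, both His tautomers,
TYR), a protonated-His and a phospho-Tyr modification, charged terminal
modifications, a PEO repeat unit and linear/branched polyethylene units,
plus links for backbone bonds and angles (with a helical secondary-
structure override), the disulfide bridge, and polymer backbones.  Bead
definitions follow the coarse-graining convention of grouping roughly two
to five heavy atoms per bead (a property the test suite asserts for every
bundled mapping).  Particle types and bonded parameters are illustrative,
not validated simulation parameters.

## The fixture generator

`make_structure()` builds deterministic synthetic structures: linear and
cyclic peptides, a two-chain disulfide-bridged dimer (the classic
two-chains-one-molecule case), a six-unit cyclic polyether (crown-ether
topology), branched polyethylene, and a protein with disordered tails
around a structured core (for region-limited networks).  Geometry is
idealized — standard bond lengths, planar placement, tetrahedral detail
omitted — because the generator's job is to make distance-based bond
inference reproduce the intended molecular graph exactly, not to be
physically realistic.  Passing tests on these fixtures therefore
demonstrates graph-level correctness (recognition, repair, mapping,
linking, network rules), and says nothing about conformational realism,
crystallographic noise, or force-field quality on real data.

Corruption classes emulate the failure taxonomy seen in high-throughput
conversion of predicted-structure databases: dropped atoms, whole side
chains removed (so a bead has no source coordinates), scrambled atom
names, a nitrogen/oxygen element swap, ring atoms displaced far enough to
break bond inference, and a spurious C-beta on glycine.  Each corrupted
fixture records ground truth (which residues were damaged) in its
manifest, and `robustness_suite()` checks the ledger against it: no
corrupted residue may pass unflagged, and no clean fixture may warn.

## Numerical choices and degenerate inputs

* Distance criterion: an edge when d ≤ 1.2 × (sum of Cordero covalent
  radii); 1.2 is the conventional tolerance.  Hydrogens are capped at one
  bond, to the closest heavy atom.  Unknown elements fall back to the
  carbon radius.
* Altloc policy: highest occupancy, ties to the alphabetically first
  altloc; insertion codes are part of the composite residue key.
* Hydrogens: crystal structures without hydrogens are valid input, so
  absent hydrogens in otherwise complete residues are missing-but-
  unwarned by default (`strict_h` turns warnings on).  Hydrogens carry
  zero mapping weight unless a mapping assigns one explicitly.
* Missing positions are never invented: repair adds coordinate-free
  nodes, bead positions are estimated from the atoms that are present
  (with a warning), beads with no positioned source atoms stay
  coordinate-free, and writers emit a (0,0,0) sentinel only on request
  and always with a ledger entry.
* Bead attribute inheritance: the residue contributing the largest total
  mapping weight wins, ties to the lowest resid.
* Duplicate interactions: a term of the same kind over the same particle
  tuple (up to reversal) replaces its predecessor, so link application is
  idempotent and file order is precedence.
* Virtual sites are evaluated in dependency order (site-on-site chains
  allowed, cycles are an error), carry zero mass, and are excluded from
  elastic-network selection.
* Secondary structure is accepted as an external annotation (string or
  file); `"auto"` uses the trivial all-coil fallback but first verifies
  that backbone coordinates are complete, since a real assignment
  algorithm would need them — missing backbone coordinates are an error,
  mirroring how such structures fail in practice.

## Problem sizes used in the tests

The test suite runs entirely on generated data: the robustness suite uses
just over 600 variants (about 100 per corruption class plus clean
controls of every fixture kind, peptides of 6–8 residues); the
isomorphism oracle comparison uses 200 random graph pairs with patterns
of 2–5 nodes against targets of up to 12; the elastic-network oracle uses
100 random coordinate sets of up to 120 beads.  These sizes give exact,
exhaustively checkable comparisons against brute-force oracles while the
whole suite stays fast; all quantities checked are size-independent
properties (zero silent conversions, set equality with an oracle, exact
round trips), not statistics that improve with n.

## Known limitations

* No geometry reconstruction: missing atoms are detected, not rebuilt.
* The `names` bond-inference strategy only uses finite-offset link
  patterns; bonds that need geometry (disulfides between arbitrary
  residues) are found by the distance or CONECT strategies.
* mmCIF, trajectories, periodic imaging and non-GROMACS topology formats
  are out of scope; `#include` lines in itp input are recorded, not
  followed.
* Cross-molecule elastic bonds (unit `all`) cannot live in an itp and are
  written under `[ intermolecular_interactions ]` in the `.top`.
* The bundled force field is a demonstration set; users supply real
  parameter libraries through the documented fragment, mapping and `.rtp`
  readers.
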