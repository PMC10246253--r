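---
title: "Building quaternary structural proteomes with oligoscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building quaternary structural proteomes with oligoscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoscape)
```

## The problem

A genome annotation names genes; a proteome does its work as folded,
usually oligomeric, protein complexes arranged in space.  oligoscape
bridges the two for a gram-negative bacterium such as *E. coli*: starting
from (i) a table of protein complexes with their gene copy-number
stoichiometries, (ii) a catalog of coordinate files — experimental
bioassemblies and predicted models of varying trustworthiness — and (iii)
per-gene sequence, topology, and compartment metadata, it determines the
best quaternary structural representation of every complex, assigns every
residue to one of nineteen subcellular compartments with explicit membrane
geometry, overlays mutations and functional domains in 3D, and converts
model-predicted complex-formation fluxes into volumetric and membrane-area
demands.

This vignette explains the models and procedures, the tunable parameters
and their defaults, the numerical choices, and what the synthetic-data
generator does and does not emulate.

## From structure files to pseudo-structures

A coordinate file is reduced to entities (unique polymer sequences) and
their chains.  mmCIF entity identifiers are honoured; PDB-format files
carry no entity records, so chains are grouped by exact sequence equality
— a conservative, deterministic fallback.  Residues are renumbered
1-based and sequential per chain; author numbering is retained only as a
lookup column, because every downstream mapping (features, mutations,
topology) is sequence-positional.

Sequence searches can map one entity to several candidate genes.  A
*pseudo-structure* resolves this ambiguity: an assignment of exactly one
gene to each entity, which fixes a gene stoichiometry (an entity with
chains A, B, C assigned gene *g* is the homotrimer `{g: 3}`).  All
assignments are materialized by a depth-first walk of the per-entity
candidate lists, in sorted order, so the output equals the Cartesian
product and is reproducible.  Each pseudo-structure is scored by the
identity of its entity-gene alignments averaged with amino-acid weights
(`copies x gene length`), i.e. by the fraction of the complex's residues
each mapping accounts for.  Per structure file, only the best-scoring
pseudo-structure per distinct gene stoichiometry is kept; identical
stoichiometries from *different* files are all kept, because the matcher
should see every file.

Two numerical guards apply.  Alignment identity is computed against the
*gene* length, not the alignment length, so identity doubles as structural
coverage; a perfect model of half a gene scores 0.5.  And when the
candidate product for one file exceeds 10,000 combinations, each entity's
list is pruned to its top five candidates by identity before enumeration —
a bound chosen to keep pathological search spaces small without affecting
realistic files, where one or two candidates per entity are the norm.

Threading models bring a specific artifact: long extended tails and
linkers that inflate apparent coverage.  Before alignment these are
trimmed: a residue is *string-like* when its CA has fewer than 3 CA
contacts within 8 Å among residues at least 3 apart in sequence, and
maximal runs of at least 10 consecutive string-like residues are removed
iteratively to a fixed point.  The criterion is a deterministic proxy for
"unfolded region"; it is isolated behind one function (`trim_itasser()`)
precisely because other reasonable criteria exist, and the parameters (3
contacts, 8 Å, separation 3, run length 10) are arguments, not constants.

Homology models pass a fail-safe quality gate: a SWISS-MODEL record fails
when GMQE < 0.5, the normalized QMEAN z-score < −4, the quaternary
reliability QSPRD < 0.5, or gene identity < 0.7 — and also when any of
those metrics is simply missing.  Unknown quality must not silently pass,
since failing evidence is *removed* rather than down-weighted downstream.

## Structure-guided stoichiometry curation

When a gene annotated (or assumed) monomeric shows oligomeric structural
evidence, the annotation, not the structures, is usually what is wrong.
Only PDB bioassemblies and SWISS models can witness oligomerization
(threading and single-chain deep-learning models are monomeric by
construction), and QC-failing SWISS evidence is discarded first.  The
remaining evidence falls into five mutually exclusive cases:

* **I** — PDB and SWISS agree on a single homomeric stoichiometry:
  automatic update.
* **II** — exactly one passing SWISS model, homomeric, no PDB evidence:
  automatic update.
* **III** — homomeric evidence involving SWISS that conflicts (several
  stoichiometries) or is ambiguous (several SWISS models): manual review.
* **IV** — homomeric evidence only from the PDB: manual review.
* **V** — heteromeric evidence only: manual review.

Two boundary readings deserve a note.  "Agreement" in Case I means the
*identical* stoichiometry signature, not merely "both oligomeric".
And Case II is read literally as exactly one passing SWISS observation;
several SWISS models agreeing on one stoichiometry go to manual review via
Case III — a conservative choice, since automatic updates rewrite targets
that drive everything downstream.  Manual review is an input table, never
an interactive prompt, so runs are reproducible.  Evidence sets mixing
homomeric and heteromeric observations are classified on their homomeric
part; purely heteromeric evidence, from any source, is Case V.

## Matching structures to complexes

For each (possibly reannotated) target, the matcher finds *every* multiset
of pseudo-structures whose gene stoichiometries sum exactly to the target.
Over-coverage is disallowed — a tetramer file cannot stand in for a dimer
target; excess copies are the curation module's business — and a part may
repeat, which is how a homotetramer is rebuilt from one monomeric model.
The search runs on the remaining-demand state with memoization and a
canonical non-decreasing part order, so it equals exhaustive enumeration
(this is asserted against a brute-force oracle in the test suite) while
staying polynomial in practice; targets exceeding 50,000 explored states
are abandoned and reported rather than left running.

Among the matches, the representative is chosen by an ordered policy:

1. a single-structure match whose sole part is an AlphaFold-Multimer model
   wins outright (such models were quality-screened when generated);
2. otherwise a single-structure match with quality above 0.70 wins —
   quaternary structure is worth more than a few identity points;
3. otherwise the trade-off rule: maximum quality, ties broken by fewer
   parts, then source priority (PDB > SWISS > AF-Multimer > AlphaFold >
   I-TASSER), then lexicographically.

Step 3 codifies a preference that is genuinely underdetermined — how much
sequence identity buys back a lost quaternary arrangement.  The rule here
is deterministic, monotone in quality, and respects the two anchored
preferences of steps 1–2; permuting the input can never change the winner.

Targets with no complete match are emitted as de novo prediction requests
with subunit sequences in stoichiometric ratio, flagged eligible below
2000 total amino acids (the practical bound for current multimer
predictors); larger complexes need a manually chosen sub-complex split.
Invoking a predictor is out of scope: the request FASTA and manifest are
the interface.

## Membrane geometry and the nineteen compartments

Candidate membrane structures are flagged by keyword rules over four
metadata sources: UniProt features (`TOPO_DOM`, `TRANSMEM`, `INTRAMEM`),
GO terms (`membrane`, `transport`, `abc`, `wall`, `periplasm`), EcoCyc
locations (`membrane`, `periplas`, `transport`, `secretion`,
`extracellular`, `wall`), and model subsystems (`membrane`, `transport`,
`abc`, `wall`, `periplasm`, `envelope`, `murein`); matching is
case-insensitive substring.

Membrane-crossing residues — transmembrane span termini, which sit at the
leaflet surfaces — are parsed from three sources and mapped through the
gene-chain alignments to every subunit copy.  UniProt `TRANSMEM` termini
are labeled by the nearest topological domain (or alternated when none is
annotated, with span *i* running from side `(i odd ? 1 : 2)` to the
opposite side).  DeepTMHMM-style topology strings give membrane runs whose
termini inherit the label of the nearest soluble run; soluble runs
alternate between two orientation-agnostic leaflet labels.  This
alternation is applied to *all* non-membrane spans — the source format
does not say how cytoplasm-side spans between two passes should be
labeled, and alternation is the only assignment consistent with a
membrane's two-sidedness.  OPM-style output provides coplanar dummy
membrane atoms split by the sign of their z-coordinate, used directly as
leaflet support points; when dummy atoms are absent a segment table is
accepted, termini split by CA z-sign.  OPM coordinates are assumed to be
in the same frame as the catalog structure (the synthetic generator writes
them that way); re-superposition of an externally re-oriented file is not
implemented.

Each leaflet plane is a total-least-squares fit (centroid plus smallest
principal direction).  For more than four support points an iterative
leave-one-out refinement runs: every point is provisionally removed, the
plane refit, the removal with the least residual accepted, and iteration
stops when the variance of point-plane distances improves by less than 5%
(relative) or the group would shrink to four points.  This absorbs termini
of mis-annotated spans, the dominant error mode of curated topology.  A
pair of planes is a *viable* membrane slab when the angle between normals
is strictly below 35°, the mean inter-plane gap along the averaged normal,
evaluated at the embedded CA positions, lies in the inclusive band 12–45
Å, and the convex-hull areas of the embedded residues projected into both
planes are strictly below 10,000 Å².  Strict versus inclusive bounds
follow the literal reading of the thresholds ("less than 35", "between 12
and 45"); thickness is defined as that mean gap because the slab may be
slightly wedge-shaped, in which case no single plane distance exists.
When several sources yield viable slabs, deference goes to OPM, then
UniProt, then DeepTMHMM — structure-based evidence over curation over
sequence-only prediction.

Residues are then split at half-thickness from the slab mid-plane into the
embedded region and two bulbs.  Bulbs are oriented by majority overlap
with UniProt topological-domain spans; if one side resolves and the other
does not, the unresolved side takes the complementary label across a
single membrane.  Failing UniProt, a manual orientation table applies;
failing both, orientation is unknown.  Membrane identity follows the bulb
labels — an extracellular side implies the outer membrane, a cytoplasmic
side the inner membrane — then gene-level annotation, and a protein that
resolves neither is placed in the unresolved membrane-associated
compartment (15).  An unoriented membrane protein with no annotation
defaults to the inner membrane, by far the likelier class in a
gram-negative cell.  Proteins without a viable slab fall back to keyword
groups over the combined metadata: membrane+cytoplasm gives 11,
membrane+periplasm 5 or 7 (outer or inner association), membrane alone 18,
single soluble groups 12 / 6 / 1, and everything else — including
ambiguous non-membrane combinations — the unassigned class 19.  The
assignment is total by construction: every residue of every structure
receives exactly one identifier.

Dual-membrane complexes (the efflux-pump class spanning both membranes)
are supported only through per-subunit manual-table assignment; automatic
multi-slab detection is a known limitation.

## Annotation in three dimensions

Sequence-positional items — functional features, laboratory-evolution and
long-term-evolution mutations, allele occurrences — map through the
alignments to *every* chain copy, so a position in a homodimer yields two
structural residues; on a proteome whose typical state is dimeric this is
exactly the 2:1 ratio between unique proteomic and genomic positions.
Unmapped positions are reported, never dropped.

Distances are CA–CA throughout, matching the membrane and interface
conventions; disulfide detection alone uses Sγ atoms (CA fallback,
flagged) with a strict 3 Å bound.  Interfaces are residues within a
threshold (3, 5, 7.5 or 10 Å) of any CA on a different chain.  Mutation
severity is the Grantham distance, bundled as a transcription of the
published table and cross-checked in the tests against a recomputation
from the underlying composition/polarity/volume formula (a few published
cells differ from the formula by one unit, one historical cell by more;
the published table is authoritative).  Substitutions above 100 are
classed moderate-to-severe.  The proximity cutoff "one amino-acid length"
is interpreted spatially as 3.8 Å, the canonical CA–CA spacing, with a
sequence-offset mode (±1 residue) available; both the mode and the cutoff
are parameters.  When a mutated position has several structural copies,
the minimum distance over copies is reported — "nearest" semantics.

## Geometry and spatial allocation

A subunit's volume is the volume of the convex hull of its atoms (CA
fallback), computed by a quickhull implementation validated against
analytic solids to 1e-9 relative and invariant under rigid transforms at
the same tolerance; the protein volume is the *sum* over subunits, not a
joint hull, so loosely packed complexes are not credited with void volume.
A membrane protein's footprint projects all subunit hull vertices into
each leaflet plane and takes the larger 2-D hull area — bulbs limit
packing, so the wider side governs.  Projection of the whole protein
rather than only the embedded region follows the sum-of-vertices
definition; an embedded-only mode is exposed for comparison.

Complex-formation fluxes from a genome-scale model multiply each complex's
volume and footprint and are distributed to genes in proportion to
copy-number stoichiometry (the mode that keeps complexes recognizable in
treemap-style displays); an amino-acid-size-proportional mode is provided
as the physically truer alternative.  Conservation is exact: per complex,
gene allocations sum to volume x flux.

## The synthetic proteome and what passing it means

`make_synthetic_proteome()` writes every input the pipeline reads — gene
FASTA, target table, coordinate files with manifest and candidate pairs,
SWISS metrics, UniProt-style features, DeepTMHMM-style topology, an
OPM-style file with dummy atoms, mutation and flux tables — plus a truth
bundle recording what was planted.  Backbones are idealized CA traces:
serpentine lattice globules at 3.8 Å spacing, transmembrane helices at 1.5
Å rise with termini placed exactly on the planted leaflet planes (z = ±15
Å, a 30 Å slab), and cube-corner subunits with analytic hull volumes.  The
default bundle holds 20 annotated complexes plus expected-monomer genes
planted to trigger each curation case, a heterodimer matched by one file,
a complex coverable only by combining monomeric models, and an unmatched
complex that must fall through to a de novo request.  Identical seeds give
byte-identical bundles; coordinate noise is available but defaults to 0 so
planted truths are exact.

These fixtures emulate the *decision structure* of real data — ambiguous
candidates, conflicting oligomeric evidence, partial coverage, three
topology sources, keyword metadata of varying specificity — but not its
physics: no side chains beyond Sγ stubs, no misfolded models, no
disagreement between topology sources, no alignment gaps or paralogy.
Passing the suite therefore demonstrates that the algorithms implement
their definitions exactly and reproducibly, not that the thresholds are
optimal for any particular organism's data.

Problem sizes in the test and acceptance runs were chosen to exercise
every code path at comfortable desk scale: 1,000 random planes (σ = 0.5 Å
noise, 20–60 support points) with 500 outlier trials for the fit study,
100 seeded instances against each exhaustive oracle (targets up to 6
subunit copies, catalogs up to 8 parts, up to 4 entities x 3 candidates),
and the 20-complex proteome (~1,700 residues) run end to end twice for
bitwise comparison.

## Known limitations

Beyond those noted inline: symmetry-operator expansion of asymmetric units
is not performed (bioassemblies are expected pre-expanded, one file each);
candidate gene-structure pairs are an input rather than the product of a
sequence search; compartment 15's exact semantics are modeled as
"membrane-associated, unresolved"; and conflicting stoichiometries for the
same complex from different curations are kept as distinct targets for
human resolution rather than merged.
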