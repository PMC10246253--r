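# oligoscape

Quaternary structural proteomes in three dimensions: from protein-complex
gene stoichiometries and a catalog of structure files to a residue-level
map of a proteome — its oligomeric states, its subcellular compartments
with explicit membrane geometry, its mutations and functional domains in
3D, and the physical space its expression program demands.

## Who this is for

Structural systems biologists working with a bacterial proteome (the
conventions target a gram-negative cell with inner and outer membranes)
who have:

* a table of complexes with gene copy-number stoichiometries (curated
  annotations and/or genome-scale-model gene-protein-reaction rules),
* coordinate files: PDB bioassemblies, homology models with quality
  metrics (GMQE / QMN4 / QSPRD), threading models, and deep-learning
  models with per-residue confidence in the B-factor column,
* per-gene metadata: sequences (FASTA), UniProt-style features and
  topological domains, GO / EcoCyc-style compartment keywords,
  DeepTMHMM-style and OPM-style membrane topology,
* optionally, mutation tables and complex-formation fluxes from a
  metabolism-and-expression model.

## The method in brief

**Pseudo-structures.** Each structure file is reduced to entities (unique
polymer sequences) and chains.  A *pseudo-structure* assigns exactly one
gene per entity, recreating the file's chain stoichiometry (entity with
chains A, B, C and gene *g* ⇒ homotrimer `{g: 3}`); all assignments are
enumerated and scored by alignment identity averaged with amino-acid
weights,

```
quality = Σₑ copiesₑ · lenₑ · identityₑ / Σₑ copiesₑ · lenₑ
```

with identity computed against the gene length so it doubles as coverage.

**Curation.** Genes assumed monomeric but with oligomeric structural
evidence are triaged into five cases (PDB+SWISS agreement; a single
passing SWISS model; conflicts; PDB-only homomeric; heteromeric-only);
the first two update the stoichiometry automatically, the rest go to a
manual-review table.

**Matching.** An exact multiset-cover search finds every combination of
pseudo-structures summing to a target stoichiometry (parts may repeat; no
over-coverage), then a deterministic policy picks the representative:
AlphaFold-Multimer singles first, then singles with quality > 0.70, then
a quality / part-count / source-priority trade-off.

**Membrane geometry.** Membrane-crossing residues from UniProt, DeepTMHMM
and OPM are fitted with total-least-squares leaflet planes (iterative
leave-one-out outlier removal, 5% variance stop).  A slab is viable when
the plane angle < 35°, the thickness is 12–45 Å, and the embedded
cross-section < 10,000 Å²; viable sources defer OPM > UniProt >
DeepTMHMM.  Bulbs are oriented by topological-domain majority (or a
manual table) and every residue lands in one of 19 compartments
(embedded, bulb, associated, soluble, unknown-orientation, unassigned).

**Annotation and allocation.** Mutations and domains map through the
alignments to every chain copy (a homodimer doubles each position);
severity is the Grantham distance (> 100 ⇒ moderate-to-severe),
interfaces are CA pairs across chains at 3 / 5 / 7.5 / 10 Å, disulfides
are Sγ pairs within 3 Å.  Subunit volumes are convex hulls; the membrane
footprint is the larger of the two plane projections; complex-formation
fluxes distribute volume and area to genes in proportion to copy number.

## Worked example

```r
library(oligoscape)

b <- make_synthetic_proteome("demo/bundle", seed = 42)
cfg <- default_run_config()
for (k in names(b$paths)) if (k %in% names(cfg)) cfg[[k]] <- b$paths[[k]]
cfg$out_dir <- "demo/out"
res <- run_pipeline(cfg)
#> [oligoscape] 31 genes, 28 targets (7 expected monomers)
#> [oligoscape] 31 structures parsed
#> [oligoscape] 31 pseudo-structures after deduplication
#> [oligoscape] 2 stoichiometries reannotated
#> [oligoscape] 22 complexes matched, 6 queued for de novo prediction
#> [oligoscape] 1686 residues assigned to compartments
#> [oligoscape] 22 geometric profiles computed
```

The matching report shows the three ways a complex is represented — one
file, a combination of files, or a de novo request:

```r
read.delim("demo/out/matches.tsv")[c(11, 15, 8), 1:5]
#>     complex_id representation n_parts quality                      parts
#> 11    CPX_HET1         SINGLE       1       1             S_HET1/gHA+gHB
#> 15  CPX_MULTI1          MULTI       3       1 S_MC/gMC&S_MC/gMC&S_MD/gMD
#> 8  CPX_DENOVO1           NONE       0      NA
```

`CPX_HET1` is covered by one heterodimeric file; `CPX_MULTI1`
(`gMC:2,gMD:1`) needs the gMC monomer model twice plus the gMD model; and
`CPX_DENOVO1` has no complete cover, so a prediction request FASTA is
written under `demo/out/de_novo/`.  The two reannotations are the planted
Case I and Case II genes whose monomer targets became a tetramer and a
dimer.

The membrane summary shows the fitted slabs — all at the planted 30 Å
thickness, with the OPM-backed structure deferring to OPM and one protein
left unoriented:

```r
read.delim("demo/out/membrane_summary.tsv")[c(15, 16, 18, 23), ]
#>    structure_id membrane_candidate viable  source thickness oriented
#> 15    S_CPX_IM1               TRUE   TRUE UNIPROT        30     TRUE
#> 16    S_CPX_IM2               TRUE   TRUE     OPM        30     TRUE
#> 18    S_CPX_OM1               TRUE   TRUE UNIPROT        30     TRUE
#> 23  S_CPX_UNOR1               TRUE   TRUE UNIPROT        30    FALSE
```

Compartment totality — every one of the 1,686 residues receives exactly
one identifier (9 = embedded inner membrane, 12 = cytoplasm, 16–17 =
unknown-orientation bulbs, 19 = unassigned):

```r
table(read.delim("demo/out/compartments.tsv")$compartment)
#>    1    2    3    4    5    6    7    8    9   10   11   12   16   17   18   19
#>   27   15   84   10   27   54   27   30  252   20   27 1007   15   10   27   54
```

And the spatial allocation: the cube-subunit complex has the analytic
hull volume 1000 ų, so at formation flux 2.0 its gene receives a volume
flux of 2000; the membrane protein additionally receives its footprint
times flux as area demand:

```r
read.delim("demo/out/allocation.tsv")
#>   complex_id gene_id copies translation_flux volume_flux area_flux
#> 1  CPX_CUBE1   gCUBE      1             2.00    2000.000        NA
#> 2 CPX_DIMER1      gH      2             1.00     438.976        NA
#> 3    CPX_IM1    gIM1      1             1.25   19344.299  585.3213
```

A thin CLI wrapper (`inst/scripts/oligoscape`) exposes the same two
operations as `oligoscape fixtures --dir ... --seed ...` and
`oligoscape run --config config.yaml`.

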