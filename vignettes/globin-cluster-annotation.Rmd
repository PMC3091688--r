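---
title: "Annotating hemoglobin gene clusters: methods and design notes"
author: "globinscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating hemoglobin gene clusters: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(globinscan)
```

## The problem

Teleost hemoglobin genes sit in dense chromosomal clusters in which α and β
subunit genes alternate and are transcribed toward each other (tail-to-tail:
α on the negative strand, β on the positive strand).  Each gene has the
canonical vertebrate globin architecture — three exons, two introns with GT
donor and AG acceptor dinucleotides — and the clusters additionally contain
pseudogenes: copies disabled by missing exons, broken splice sites,
frameshifts, premature stops, or lost start/stop codons.  In Atlantic salmon
a subset of the functional β genes encode non-Bohr hemoglobins, whose oxygen
affinity is insensitive to pH; they are recognisable from the protein
sequence alone.

`globinscan` re-implements this annotation problem as a reusable pipeline:

1. **find** candidate exons by translated search against exon templates,
2. **chain** compatible exon hits into gene models,
3. **refine** exon boundaries against the genomic sequence,
4. **classify** each model as putatively functional or pseudogene, and
   β proteins as Bohr or non-Bohr,
5. **lay out** the cluster (order, strand, alternation, tail-to-tail motifs)
   and assign names of the form `SsaChr6β2` / `SsaChr6βψ1`,
6. optionally compare clusters across species by flanking-gene synteny,
   dot-plot/windowed identity, and a distance-based clade check.

A synthetic-cluster generator with exact truth tables makes every stage
testable without any external download.

## Classification rules

A refined gene model is **putatively functional** only if all three
criteria hold:

1. exactly three exons and two introns;
2. exons of appropriate sizes: canonical GT..AG junctions, start codon at
   the head of exon 1 and stop codon at the tail of exon 3, each exon
   peptide within ±2 residues of its template length, and no internal stop
   or frameshift in the spliced translation;
3. a translated chain length of 143 residues for α, or 147/148 for β
   (terminal stop never counted).

Any failure makes the model a pseudogene; the failed criteria and the
specific defect labels are preserved for audit.  A functional β gene is
**non-Bohr** iff all three hallmarks hold: 147 residues including the
initiator methionine, C-terminal phenylalanine (the Bohr effect is largely
mediated by the C-terminal histidine it replaces), and alanine at position
93.  Hallmarks are conjunctive: a 147-residue β chain ending in histidine is
an ordinary Bohr hemoglobin, not an error.

Two conventions are deliberately explicit because the length rule is stated
with the initiator methionine included while the numbering convention for
position 93 is not:

* `nonbohr_position_includes_met` (default `TRUE`) counts position 93 from
  the initiator methionine, parallel to the length hallmark; set it to
  `FALSE` to count on the mature chain.
* The α length of 143 is likewise interpreted as the full translation
  including the initiator methionine, by parallel reading of the β rule.

All constants live in `classifier_config()` and are pinned one-by-one in
the test suite.

## The finder

**Templates, not profiles.**  Candidates are searched with plain exon
exemplars (peptide + CDS per exon, per subunit variant) scored by
alignment.  With a single exemplar per exon a probabilistic profile
degenerates to alignment anyway, and exemplars keep the reference bundle a
pair of FASTA files any user can curate or regenerate.

**Search.**  Each template peptide is seeded by exact 5-mer matches against
the six-frame translation of the sequence, seed diagonals are clustered
(gap > 45 nt starts a new locus), and each locus is extended with a
Smith–Waterman alignment (BLOSUM62, gap open 11 / extend 1 — the standard
protein scoring used by BLAST).  A hit is kept when identity ≥ 0.5 **and**
score ≥ 0.3 × the template self-score; globin paralogs within a cluster
exceed 80% identity, so these thresholds are permissive for true copies
while random spacer translation cannot reach them.

**Chaining.**  Hits chain when they share strand and subunit, exon indices
strictly increase in transcription order, and gaps lie within intron bounds
(default 40–10 000 bp; a skipped exon admits two introns plus 400 bp).
Chains are scored by summed hit score minus a weak length prior of 10 per
kb of intron gap.  The prior matters: neighbouring genes of the same
subunit can sit within the maximal intron length of each other, and without
it a chain can stitch exons from adjacent paralogs whenever one copy's exon
scores slightly higher.  Ten points per kb is far below any exon's score at
the maximal intron length, so a genuine long intron is never forfeited —
only ties between a compact and a straddling interpretation are broken
toward the compact one.  Chains are claimed greedily by descending score;
leftover hits overlapping a claimed model are discarded instead of seeding
fragments of already-explained loci.  Partial chains become pseudogene
candidates with `missing_exon` defects.

**Refinement.**  Each exon's template CDS is re-aligned
(nucleotide global–local, match 2 / mismatch −3, gap open 5 / extend 2) to
the ±20 nt neighbourhood of its hit, giving exact boundaries even across
small indels.  Boundaries then shift within ±12 nt only if that places the
canonical splice dinucleotide (or the start/stop codon within ±2 codons)
*without reducing* the position-wise identity of the spliced CDS to the
template — a sharp criterion, because an erroneous shift desynchronises
every downstream codon.  Frameshifts are read off the exon length modulo 3
relative to the template; in-frame length changes beyond ±2 codons become
`length_violation`.

**Determinism.**  There is no randomness in the finder; ties in alignment
are resolved by the alignment engine deterministically, and candidate
boundary shifts are scanned smallest-|shift|-first.

## Cluster layout and naming

Genes are ordered 5'→3' by forward coordinate.  Strand expectations
(α −, β +) are applied *up to global cluster orientation*: the orientation
of an assembled BAC/contig is arbitrary, so violations are counted under
whichever of the two orientations fits the majority of genes, and the
chosen orientation is reported.  Alternation violations are adjacent
same-subunit pairs (pseudogenes included by default, since the alternating
pattern extends through them; a flag excludes them).  Tail-to-tail motifs
are adjacent pairs whose 3' ends face each other.  For multi-contig inputs
the pipeline never asserts a unique inter-contig order; numbering continues
in file order and the layout is per contig.

## Synteny, homeology and the clade check

Cluster typing is presence/absence of two signature flanking-gene sets
(Cluster 1: UPF0171/C16orf35, Rhomboid family member 1, DOCK6, ELAV-like
protein 3, MPG; Cluster 2: Aquaporin-8, Rho-GTPase-activating protein),
counted on canonicalised names with a small synonym table; the label goes
to the strictly larger hit set and ties are `ambiguous`.  Raw counts rather
than weights, because the biological argument is qualitative
presence/absence.

The dot plot reports exact word matches (default word 15, step 1; forward
and reverse-complement channels flagged separately), and windowed identity
anchors the two sequences on the dominant dot-plot diagonal and globally
aligns corresponding windows (default 1 kb), reporting matches per
alignment column.  Word 15 keeps anchor density high at a few percent
divergence while suppressing random 4^-15 noise.

Clade questions are answered with pairwise alignment distances
(1 − identity of a free-end-gap global alignment; gaps count as
mismatches) and neighbor joining, with monophyly defined on the unrooted
tree: a leaf set is a clade iff some edge bipartitions it exactly.  A
distance method suffices because the question being asked is topological —
does the non-Bohr set form a clade — not a posterior probability; no
rooting claims are made.  Negative NJ branch lengths are clamped to zero
with a warning.

## The synthetic generator

`generate_cluster()` emulates the statistical structure the analysis
assumes: alternating tail-to-tail α/β three-exon genes with canonical
GT..AG introns, intergenic spacer at configurable GC, planted
pseudogenization defects, and non-Bohr variants.  Defaults mirror the
composition of the chromosome-6 salmon cluster: 6 functional α, 6
functional β of which 2 non-Bohr, 2 α pseudogenes, 3 β pseudogenes — 17
genes in alternating order, β first.  Remaining defaults are chosen once as
field-realistic values: 5% template divergence (recently duplicated globin
paralogs are >90% identical), introns of 150–500 bp (fish globin introns
are compact), spacers of 2.5–4.5 kb (placing 17 genes in ≈85 kb, the scale
of the sequenced cluster), GC 0.42.

Three generator rules keep truth tables exact:

* **Shielding** — background divergence never touches rule-critical sites
  (start/stop codons, splice dinucleotides, β hallmark codons) and never
  creates a stop codon in a functional gene, so a planted status cannot
  silently flip.
* **One stream** — a single seeded random stream per run; identical
  configurations are byte-identical.
* **Self-check** — before returning, every planted gene's spliced CDS is
  re-derived from the emitted sequence by coordinate lookup and compared
  with the construct; functional genes must additionally translate cleanly.

Planted defects are concrete: `missing_exon` drops exon 2;
`bad_splice_donor`/`bad_splice_acceptor` mutate one dinucleotide;
`internal_stop` rewrites one in-frame exon-2 codon to TAA; `frameshift`
deletes a single base mid-exon-2; `no_start`/`no_stop` mutate the terminal
codons; `length_violation` inserts three in-frame codons.  Every defect
label the classifier can emit is producible.

What the generator does **not** emulate — and therefore what passing tests
do not establish about real data: repetitive elements and low-complexity
sequence (real BAC assemblies are repeat-rich; the finder relies on score
thresholds and 3-exon chaining instead of masking), sequencing/assembly
error, allelic contigs, deeply decayed gene footprints below the exon score
threshold, non-globin genes in the flanks, and realistic codon usage or
evolutionary correlation structure (mutations are i.i.d.).  Homeolog pairs
are a mutated copy of one cluster, not two clusters evolved down a tree.

## Problem sizes and runtime choices

The test suite and acceptance script run full-scale chromosome-6-like
clusters (≈85 kb, 17 genes) across 20 seeds for the recovery property, and
compact clusters (4–8 genes, ≈1–2.5 kb spacers) for unit-level end-to-end
checks; homeolog comparisons use ≈25–35 kb pairs with 1 kb windows.  Oracle
comparisons use 200 random peptide pairs (length ≤ 40), 50 random additive
matrices of 5–12 taxa, and exhaustive bipartition enumeration on trees of
≤ 10 leaves.  These sizes keep a full run in the low minutes on one CPU
while exercising the pipeline at the scale of the real clusters.

## Reproduction runs

`run_reproduce()` executes the full pipeline on locally supplied copies of
the two deposited cluster assemblies (GenBank GQ898924, chromosome 3;
GQ898925, chromosome 6).  The tool never downloads; records must be fetched
once by the user.  The packaged reference bundle is synthetic and suffices
for pipeline mechanics; a faithful reproduction requires templates curated
from published salmon globin clones (e.g. the X97284–X97289 series), which
cannot be redistributed here.  GenBank feature tables are ignored by
design: the pipeline re-derives all annotation from sequence.

## Known limitations

* Two adjacent genes of the same subunit closer than the minimum intron
  length apart could in principle be merged; in practice globin clusters
  space genes by kilobases.
* Pseudogenes more decayed than a single planted defect (e.g. exon
  remnants below the score threshold) are reported only while at least one
  exon still clears the exon acceptance threshold; deeper remnants are
  deliberately not called.
* The α-D globin lineage is outside the scope of the templates and is not
  detected.
* Windowed identity assumes a single dominant collinear diagonal; it is
  not a general-purpose whole-genome aligner.

## A worked micro-example

```{r example}
ref <- make_templates(seed = 1)
cfg <- simulation_config(seed = 1, n_alpha_functional = 2, n_beta_bohr = 1,
                         n_beta_nonbohr = 1,
                         pseudogene_plan = data.frame(subunit = "beta",
                                                      defect = "frameshift"),
                         intergenic_length_range = c(800L, 1500L))
gen <- generate_cluster(cfg, ref)
res <- annotate_cluster(gen$seq, ref = ref, chromosome_label = "Chr6")
res$layout
res$counts$total
compare_to_truth(res$genes, gen$truth)$all_match
```
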