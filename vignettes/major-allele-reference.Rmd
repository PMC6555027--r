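---
title: "Constructing and using a major-allele reference: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and using a major-allele reference: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(majorref)
library(dplyr)
```

This vignette records how the package's procedures are defined, which
parameters matter, and why the open design choices were settled the way they
were. It is the companion to the function reference: the reference says
*what* each function returns, this document says *why*.

## The normalization model

A population VCF assigns each alternate allele a frequency AF — the fraction
of population chromosomes carrying it. A position where some ALT has
AF > 0.5 is a position where the assembly carries the population *minor*
allele. Normalization replaces exactly those alleles:

1. **Classification.** Every record is placed in one of five classes — SNP,
   INDEL, mixed SNP+INDEL site, MNP, SV — from its raw REF/ALT shapes
   (`classify_variant()`). The classes drive reporting and per-class output
   files; SVs are counted but never replaced, because population catalogues
   rarely resolve them to base precision and replacing them would entangle
   the annotation migration.
2. **Selection.** `select_major_alleles()` extracts, per record, the single
   ALT with AF strictly above the threshold (default 0.5). Strictness
   matters: at AF = 0.5 neither allele is a majority, and replacement would
   be arbitrary. Two alleles above 0.5 cannot coexist (frequencies sum to at
   most 1), so that situation is treated as corrupt input
   (`IMPOSSIBLE_FREQUENCIES`), not resolved silently. With a user-lowered
   threshold below 0.5 the highest-AF qualifying allele is taken.
   AF comes from the INFO field when present and is otherwise derived from
   genotype columns as alternate-allele count over called alleles; records
   with neither are skipped, warned about, and tallied — silently inventing
   frequencies would bias everything downstream.
3. **Minimal representation.** Each selected REF/ALT pair is trimmed to its
   minimal VCF form (common suffix, then common prefix, one anchor base
   retained). This makes substitutions pure in-place replacements and
   indels pure gaps, which in turn gives the chain builder a canonical block
   structure.
4. **Conflict resolution.** Overlapping edits (e.g. a SNP inside a deleted
   span, the planted structure of mixed sites) cannot all be applied.
   `resolve_colocated()` keeps, greedily from the highest AF down, every
   edit that does not overlap an already-accepted one. Ties prefer the SNP
   over the INDEL (the smaller, safer change), then the leftmost position.
   The procedure is deterministic and idempotent, and every drop is logged
   with the identity of the winning edit — replacements in a reference
   genome should be auditable, not silent.

`apply_edits()` then rewrites each chromosome in one left-to-right pass,
validating every REF against the genome (case-insensitively — soft-masking
is annotation, not sequence). Replacement text is written in uppercase and
surrounding case is preserved; `uppercase_all` reproduces a fully unmasked
output. Complex substitutions (both sides longer than one base, lengths
differing) are applied natively. `verify_edits()` independently re-checks
every logged span and every inter-edit segment before anything else consumes
the log.

## Coordinates: the edit log is the alignment

Because every edit is recorded with its span on both assemblies, the
old/new alignment needs no sequence comparison: `build_map()` reads it off
the log. Substitution edits (`delta == 0`) stay inside aligned blocks — a
pairwise assembly alignment tolerates mismatches — while every
length-changing edit breaks the blocks, its minimal inserted or deleted
bases left unaligned. Complex substitutions become double-sided gaps
(unaligned on both axes); that is the canonical chain representation of a
region with no base-level correspondence, and positions inside one lift as
`UNMAPPED` rather than to an arbitrary neighbour.

The chain file (`build_chain()`/`write_chain()`) uses the UCSC dialect with
target = new assembly and query = old, matching the naming convention of a
`NewToOld.over.chain` that lifts new-assembly coordinates back to the old
frame; `swap = TRUE` writes the reverse orientation. Two triplet-level
choices are deliberate:

* adjacent edits produce consecutive `(size, dt, dq)` entries with an
  intermediate block of size 0, never a merged gap — merging would erase the
  distinction between "insertion next to deletion" and "substitution block";
* the score field is the total aligned base count. Chain consumers ignore
  the score, but it must be present; aligned bases is a reproducible,
  meaningful filler.

`lift_vcf()` lifts POS only and leaves REF/ALT untouched: a lifted record
describes the same event in another frame, and rewriting its alleles to the
target genome would destroy exactly the information (swapped REF/ALT at
replaced sites) that the comparator later reconciles. A deletion whose
anchor maps but whose REF span crosses a gap is lifted with a
`span_warning` flag rather than discarded — the conservative reading when
the event itself straddles the assembly difference.

Cross-validation (`concordance_check()`) lifts every position twice: through
the directly constructed map and through generic walking of the chain-file
triplets, demanding agreement including `UNMAPPED` outcomes. The test suite
adds a third, external route (`rtracklayer::liftOver` on the written chain
file) and a per-base replay oracle that reconstructs the alignment
literally, base by base.

## Annotation migration

Gene models (genePred-extended, 15 or 16 columns with an auto-detected
leading `bin`) are migrated in three steps:

1. **Liftover of boundaries.** A boundary falling in a region deleted from
   the new assembly snaps toward the feature interior — starts snap right,
   ends snap left — and the model is flagged. Interior snapping never
   enlarges a feature across a gap, which outward snapping would. A model
   entirely inside a deleted region is reported `UNMAPPED_MODEL`.
2. **Intron collapse.** An intron is removed, and its flanking exons merged,
   when its *lifted* length is at most `min_intron` (default 0), **or** when
   its *pre-lift* length was at most the threshold. The first clause handles
   the spurious-intron case: a 2–8 bp insertion in the old assembly that was
   annotated as an intron disappears when the major-allele deletion removes
   it, leaving a zero-length lifted intron. The second clause handles the
   mirror case of an exon split in two by bases missing from the old
   assembly: the pieces abut pre-lift (intron length 0), the restoring
   insertion lands between them, and the merged exon absorbs the inserted
   bases. The default of 0 merges only introns the edits themselves
   eliminate; `min_intron` above 0 additionally merges residual 1..N bp
   introns for curation-style use.
3. **Frame recomputation.** Walking exons in transcription order (reversed
   on the minus strand), each coding exon's frame is the cumulative CDS
   length of its predecessors modulo 3; non-coding exons get −1. The
   operation is a fixpoint, so re-running migration cannot drift.

Validation mirrors how an annotation database build checks itself: every
transcript is extracted from the new genome (spliced, reverse-complemented
as needed) and compared exactly, case-insensitively, against the reference
mRNA set; every coding model is translated (standard code, first coding
exon's frame as start offset, `N` → `X`, trailing stop dropped, internal
stop truncating with a flag) and compared against the reference protein set,
ignoring a terminal `*`. Transcripts absent from the reference sets are
`SKIPPED` and excluded from the percentages. Models that still mismatch
after collapse and frame repair are labelled `UNFIXED` and written
unchanged: the remaining cases in real data required subjective manual
curation, which a library should surface, not imitate.

## Call-set comparison

Both sets are prepared identically: strict filtering (`qual > 10`,
`dp > 3` — strict inequalities, missing depth fails), parsimony
normalization (suffix trim, prefix trim to anchor, left-alignment through
repeat context; idempotent), and decomposition into allelic primitives.
Equal-length REF/ALT pairs become one SNP per differing base. Length-changing
complex records follow a unit-cost global alignment; on ties the traceback
prefers deletion over substitution over insertion, which yields the
conventional "SNP plus one simple INDEL" reading of a complex substitution
rather than a longer all-SNP-plus-gap decomposition. The decomposition of a
length-changing record conserves its unit-cost edit distance (tested against
an independent oracle); the per-base rule for equal-length records is a
definition, not an optimality claim.

Matching is per class. SNPs match on chromosome + position (position mode)
or additionally on the allele pair, where `{ref, alt}` compared as an
unordered pair reconciles the REF/ALT swaps that the lifted-but-unrewritten
records produce at replaced sites. INDELs match when their REF intervals,
padded by `indel_window` (default 0 — pure overlap), intersect; pairing is
one-to-one, greedy by nearest position with a leftmost tie-break. The
report gives, per class, totals, common and unique counts and
`fp_pct`/`fn_pct` at a configurable number of decimals (default 2; 3
matches the exome-style tables).

## The synthetic scenario generators

`sim_genome()`, `sim_population_vcf()`, `sim_gene_scenario()` and
`sim_callsets()` generate every input the toolkit consumes, deterministically
per seed and without touching the caller's RNG stream. Their defaults are
the package's study conditions:

* genomes of tens to hundreds of kilobases over 2–3 chromosomes with ~2%
  soft-masked runs — large enough that thousands of edits and tens of
  thousands of lifted positions are exercised, small enough that the whole
  suite runs in about a minute;
* an AF spectrum with a configurable fraction of records above 0.5 (drawn
  uniformly on (0.52, 0.95)), a spike near 1 emulating assembly sequencing
  errors (0.985–1), and sub-threshold records on (0.02, 0.48). Fractions
  are achieved *exactly* (chosen by count, not by coin flip), so manifests
  state precisely which records selection must return;
* planted structure for every edge the algorithms must handle: multi-allelic
  sites, mixed SNP+INDEL records, co-located conflict pairs with a known
  winner, symbolic SVs, genes with 2–8 bp spurious introns coinciding
  exactly with major deletions, split exons restored by major insertions
  (both strands), and call-set pairs with exact planted common/unique/swap/
  overlapping-indel counts.

What the generators do **not** emulate: linkage structure, realistic allele
frequency spectra, sequencing error in the calls themselves, mapping
artefacts, N-gaps and alternate haplotypes. Passing tests therefore
demonstrate that the algorithms are correct on inputs with the declared
structure — not that a real population catalogue is free of records these
rules mis-handle (malformed frequencies and unknown contigs are rejected
loudly for that reason).

## Numerical and edge-case conventions

* Internal coordinates are 0-based half-open; all VCF I/O is 1-based; the
  chain format is 0-based half-open per its specification.
* Selection threshold comparisons are strict (`>`), as are both call
  filters.
* A frequency vector summing slightly above 1 is tolerated to 1e-6.
* Edits inside IUPAC-ambiguous or N bases mismatch unless the edit's REF
  matches literally.
* FASTA output is wrapped at 60 columns; headers are copied verbatim.
* Problem sizes in the shipped tests: brute-force selector equivalence at
  10^4 records; per-base replay equivalence on ~10 kb genomes; liftover
  concordance on a 120 kb genome with ~2,000 applied edits and ~12,000
  lifted positions; everything chosen so the full suite stays fast while
  still crossing the scales at which off-by-one and offset-accumulation
  errors appear.

## Known limitations

* Structural variants are never replaced; records with symbolic alleles are
  classified, counted and carried through reports only.
* Liftover never crosses strand flips, inversions or inter-chromosomal
  events — the edit model cannot produce them.
* Genotype-level concordance (GT comparison) and multi-sample VCFs are out
  of scope for the comparator; it works on sites.
* The annotation repair codifies the two mechanical cases (spurious intron,
  split exon). Transcripts needing judgement beyond that surface as
  `UNFIXED`.
* `pos == 1` indels cannot be extended leftward during normalization and are
  returned at their minimal (unshifted) representation.
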