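---
title: "circkit: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circkit: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circkit)
```

## The problem

Circular RNAs (circRNAs) arise from back-splicing: a downstream donor (5')
splice site is joined to an upstream acceptor (3') splice site, producing a
covalently closed transcript. In RNA-seq data the only direct evidence for
a circRNA is a read that spans the head-to-tail junction, which aligners
report as a *chimeric alignment* — two read segments mapping in an order
inconsistent with a linear transcript. Individual circRNA callers disagree
substantially in both detection and quantification, because they differ in
alignment strategy, splice-motif restrictions, maximum junction span and
reliance on annotation. circkit implements a consolidated pipeline: union
the candidates, filter artifacts with explicit rules, then recount support
for every surviving junction from one chimeric-alignment source so that
quantification is consistent across the catalog.

## Coordinate conventions

All internal coordinates are 0-based half-open with explicit strand, the
BED convention. This is a deliberate harmonization: the supported input
dialects disagree (caller BED files are 0-based; GTF, chimeric-junction and
SJ tables are 1-based), and readers do all conversion at the boundary. For
a junction `[start, end)` the circularized span runs from the first base of
the acceptor exon to the last base of the donor exon; on the plus strand
the donor dinucleotide is read at `[end, end+2)` and the acceptor
dinucleotide at `[start-2, start)`, with both read through the reverse
complement on the minus strand. Exact agreement of coordinates after
normalization is required when merging candidate sets from multiple
sources; near-misses within 2 nt are flagged as diagnostics rather than
merged, because neither source can be assumed authoritative.

## The filter cascade

Candidates survive when all four rules hold, applied in a fixed order so
that per-rule rejection tallies are reproducible (a candidate is tallied
under the first rule it fails):

1. **Span**: genomic distance `end - start` at most 100 kb. The bound is
   inclusive (`<= 100000`) and configurable; the source descriptions use
   "at most" and "less than" interchangeably, and we fix the inclusive
   reading.
2. **Motif**: the splice-site pairing must be GT/AG or GC/AG (GU/AG and
   GC/AG on the RNA); anything else, including motifs containing N, is
   rejected.
3. **Multi-gene**: candidates whose span overlaps two or more genes that
   are themselves disjoint in genomic extent are rejected as likely
   chimeric artifacts. Candidates overlapping several *mutually
   overlapping* genes are kept and later labeled `ambiguous` — the two
   situations receive distinct treatment on purpose.
4. **Support**: at least 2 coordinate-distinct back-splice reads in at
   least one sample. Distinctness is positional: within a sample, reads
   sharing (contig, strand, both segment positions, both CIGARs) count
   once. Deduplicating on mapping position rather than read sequence is
   robust to sequencing errors in otherwise identical PCR copies.

Downstream abundance metrics use *all* reads (duplicates included); only
the presence threshold uses distinct reads. The high-confidence subset
additionally requires at least 5 back-splice reads in at least 2 samples.

## Abundance metrics

For each junction and sample, with `b` back-splice reads and `l` the mean
of the unique linear-junction read counts at the two splice sites:

* `RPM = b / library_size * 1e6` — library-size normalized back-splice
  support. Per-sample library sizes are always used.
* `CLR = b / (l + 1)` — circular-to-linear ratio. The pseudocount
  stabilizes the denominator only; that is the natural reading of
  "divided by the linear-junction reads after adding a pseudocount of 1",
  and a both-sides variant is available as a flag for sensitivity
  analysis.
* `percent circularized = 100 * b / (b + l)` — the relative abundance of
  the circular isoform at its junction; undefined (NA) when both counts
  are zero. The two metrics are algebraically linked:
  `pct = 100 * (b/l) / (1 + b/l)` for `l > 0`, which the test suite
  verifies to 1e-9.

Both metrics ignore transcript isoforms that skip the circularized exons
entirely, which can overestimate relative circRNA abundance; this is an
acknowledged limitation of junction-local quantification, not of the
implementation.

Host-gene expression is reported in TPM with reads from exons internal to
a circRNA omitted, so that circRNA-derived coverage does not inflate the
host estimate. By default the internal exons' lengths are also removed
from the effective gene length: omitting reads but not length would bias
the host TPM downward. The length exclusion is configurable because only
the read omission is externally specified.

## Annotation

Parental-transcript assignment tries transcripts of the single overlapping
gene in priority order: canonical transcripts with both boundaries on
annotated splice sites, then non-canonical with both, then canonical with
one side, then non-canonical with one side; remaining ties break by longer
CDS, then lexicographic transcript id. When no transcript has any matching
boundary but exons still overlap the span, the largest-overlap transcript
is used as a labeled fallback (`boundary_matches = 0`) rather than leaving
the record unassigned — the ranking of "best parental transcript" among
imperfect matches is not externally specified, so the tie-break is a
documented package choice, not inferred intent. Canonical status comes
from a GTF `tag` containing "canonical" or a user-supplied transcript list,
since canonical sets (e.g. UCSC knownCanonical) are assembly-specific.

The circRNA's internal structure is conservatively assumed to include all
parental-transcript exons between the back-splice sites; internal
alternative splicing is not modeled. Junctions with no exon overlap are
intronic (inside a gene) or intergenic; spans overlapping more than one
mutually overlapping gene are `ambiguous`.

The exon-rank spectrum normalizes the frequency of rank `r` among
acceptor (or donor) sites by the number of genes with at least `r + 1`
exons — a gene needs at least one exon downstream of the donor for
back-splicing at rank `r` to be observable. A gene's exon count is taken
as the maximum over its transcripts.

## Flanking-sequence analyses

Reverse-complementary sequence in flanking introns (the hallmark of
inverted-repeat-driven circularization) is scored by Smith–Waterman local
alignment of the 500-nt window upstream of the left boundary against the
reverse complement of the 500-nt window downstream of the right boundary,
with match +1, mismatch −1, gap opening 10 and gap extension 4 (the
alignment itself is delegated to `Biostrings::pairwiseAlignment`, the same
machinery the original analysis used; the substitution scores are package
defaults because none were externally specified, and all four parameters
are exposed). A junction is flagged complementary at ≥ 85% identity over
≥ 40 aligned columns, both configurable. Windows are intron-side only,
truncated at contig ends with a warning; windows shorter than 10 nt give
an NA marker.

Repeat-pair orientation (e.g. inverted Alu pairs) considers *all*
cross-side pairs of family repeats within the windows: `inverted` when any
pair lies on opposite strands, `same` when pairs exist and all agree,
`none` when either side is empty. Whether the nearest pair or any pair
decides orientation is not externally specified; "any pair, inverted
dominates" is our documented choice, consistent with the biological
reading that one inverted pair suffices for pairing.

Crosslink sites (e.g. iCLIP) merge transitively at gaps of at most 8 nt.
Metaprofiles average per-position signal across junctions in
strand-aware windows (default 250 nt intron + 50 nt exon per side; the
1000-nt variant is a parameter); positions beyond contig ends contribute
zero while the junction still counts, so the sum of positional means times
the junction count equals the total overlapped signal exactly on integer
inputs. Profile smoothing is presentation-layer and out of scope.

## Differential-expression preparation

The DE module builds a combined count matrix: raw gene counts (genes with
at least 10 total reads) stacked with raw back-splice counts of eligible
circRNAs, so an external negative-binomial engine (e.g. DESeq2) estimates
library sizes and dispersions from both. All rows are allowed to influence
size-factor estimation. circRNA rows use coordinate-derived ids with a
reserved `circ|` prefix, collision-free with gene ids. Eligibility applies
the 5-reads-in-2-samples rule within each sample group (cell line).
Results join back by id with a three-state status — significant,
not significant, untested — so that untested circRNAs are never silently
conflated with non-significant ones. The model fit itself is deliberately
not reimplemented.

## The simulator: what a green test establishes

`simulate_genome()` + `plant_circ_evidence()` state a small world: one
contig, 20 multi-exon genes (4–8 exons of 100–300 nt, introns 400–1500 nt,
strands alternating), every intron carrying a canonical GT..AG motif (10%
GC donors), 30 planted circRNAs at internal exon boundaries with 2–10
distinct back-splice reads per sample, PCR duplicates at rate 0.2
(coordinate-identical copies), linear junction support of 5–50 unique
reads per intron, 4 samples in two conditions with 1e6 mapped reads each,
and 5 artifacts per category: spans above 100 kb (planted with valid
motifs beyond the last gene so only the span rule fires), non-canonical
motifs (TT..TT planted so random sequence cannot rescue them), junctions
bridging consecutive disjoint plus-strand genes, and single-read support.
Where the underlying study fixes a value (thresholds, window sizes, the
duplicate concept) the simulator uses it; the remaining ranges are chosen
once at what a short-read rRNA-depleted library plausibly yields at gene
scale, and are not tuned against test outcomes.

Evidence is represented at the junction level (chimeric and SJ records),
where the pipeline's scope begins; no FASTQ or sequencing-error model is
included, and expression realism (dispersion, GC bias, mappability) is
explicitly not emulated. A green end-to-end test therefore establishes
that the detection arithmetic, filter semantics, duplicate handling and
metric formulas are exact on evidence of the stated shape — not that the
pipeline's sensitivity on real alignments matches any published figure.
Real headline counts from deep sequencing runs are not reproducible at
this scale and are not targeted.

## Numerical and degenerate-input choices

* Strand-conflicting and cross-contig chimeric records never form
  junctions; they are tallied, not fatal.
* Chimeric overhang = the smaller per-segment sum of aligned read bases
  (CIGAR M/=/X ops); the default threshold 15 matches the alignment-time
  chimeric overhang minimum.
* `clr_shift` (fold change of mean CLR between conditions) returns `Inf`
  for 0 → positive and 1 for 0 → 0.
* Ranks in the exon-rank spectrum whose denominator is zero (no gene has
  enough exons) are omitted with a warning rather than reported as
  division by zero.
* Genes whose every exon is circle-internal get TPM 0 with a warning.
* The catalog TSV writes a typed header so `read_catalog(write_catalog(x))`
  is the identity, and rows are always in canonical
  (contig, start, end, strand) order regardless of input order.

## Known limitations

* Internal exon structure is inferred, never measured: alternative
  splicing inside the circle is invisible to junction-level evidence.
* The multi-gene rule and ambiguity label use gene extents, not exon
  structure, so read-through transcription can masquerade as a multi-gene
  artifact.
* Linear support counts unique SJ reads only by default; multi-mappers
  are available behind a flag but conflate paralogous junctions.
* The simulator's determinism claim is per-platform R RNG determinism
  with integer draws; it holds across the platforms R supports with the
  default RNG.
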