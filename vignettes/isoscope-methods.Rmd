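---
title: "Methods: structural annotation of full-length transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural annotation of full-length transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(isoscope)
```

isoscope implements the structural-annotation stages that sit between raw
long-read (Iso-Seq-style) circular consensus reads and a transcript-level
annotation: full-length non-chimeric (FLNC) read classification, isoform
collapse and filtering, gene-locus assignment and novelty calling,
alternative-splicing (AS) event classification, alternative-polyadenylation
(APA) site detection, fusion-transcript calling, and lncRNA candidate
screening. This vignette records the models, the parameters that matter, and
the design decisions taken where the underlying procedures are conventionally
under-specified.

All genomic intervals inside the package are 0-based half-open; the format
readers and writers convert to the 1-based inclusive conventions of GFF3,
SAM and BED at the file boundary.

## Read classification

A sense-oriented full-length read is modelled as

```
5' primer + transcript insert + poly(A) tail + revcomp(3' primer)
```

`classify_reads()` tries both orientations, scoring an ungapped primer match
near each terminus, and keeps the orientation with fewer total mismatches; a
tie is reported as `ambiguous_orientation` and classified non-full-length.
Primer matching is an ungapped scan allowing `max_mismatch` mismatches
(default 2 for ~30 nt primers) over a small window of terminal offsets
(default 8). Ungapped matching is deliberate: CCS indel rates are low enough
at typical pass numbers that an alignment-based matcher would add cost
without changing calls on the supported inputs.

The poly(A) tail rule (`detect_polya()`) is: the tail is the longest
terminal suffix of at least `min_len` bases (default 20) whose **every**
5'-anchored prefix has an A-fraction of at least `min_purity` (default 0.8).
The prefix condition makes the tail start on an A and prevents the window
from swallowing arbitrary upstream sequence just because a long pure tail
follows it; isolated substitution errors inside the tail are tolerated once
enough As have accumulated. Both defaults are configurable; they were chosen
so that error-free synthetic tails of 20-60 nt are always found and the rule
has an obvious position-by-position brute-force equivalent used as the test
oracle.

A read is **FL** when the 5' primer, the 3' primer and a tail are all
present; **FLNC** additionally requires no internal primer hit (any of the
four primer strings/orientations, same mismatch allowance) at least
`chimera_margin` bp (default 50) from both trimmed ends. The margin
operationalizes "non-chimeric" without double-counting the terminal primers
themselves. Trimming removes the 3' primer, then the tail, then the 5'
primer.

`summarize_libraries()` tallies per-library CCS / primer / poly(A) / FL /
FLNC counts and appends a pooled row; the pooled FLNC percentage is the
pooled FLNC/CCS ratio. All printed percentages in the package round half-up
to 2 decimals — the convention of published sequencing reports; base R's
round-half-to-even would differ in the last digit on exact halves.

## Isoform collapse and filtering

The junction chain of a spliced alignment is its ordered list of intron
intervals. Multi-exon alignments with identical `(chrom, strand, chain)`
collapse into one isoform whose span is the maximal extent of its reads and
whose support is the read count. Mono-exonic alignments merge (transitively)
when their 3' ends lie within `mono_end_tol` bp (default 50) and their spans
overlap; the 5' end is left free because 5' truncation is expected from
degradation and incomplete cDNA synthesis, while the 3' end is anchored by
the poly(A) site.

**Degradation filter.** An isoform is removed when a same-strand isoform
exists whose chain contains the victim's chain as a proper 3'-anchored
suffix (genomic suffix on `+`, genomic prefix on `-`) and whose span
contains the victim's 5' end. A mono-exonic victim has the empty chain,
which is a suffix of everything, so it must additionally lie within the
longer isoform's 3'-terminal exon (extended by `mono_end_tol`) — otherwise
any short transcript inside a long gene span would be swallowed. This rule
cannot distinguish a genuine intron-retention variant of the *5'-most*
intron from a degraded copy (both have a suffix chain anchored at the same
3' end); the synthetic generator therefore never builds that variant, and on
real data such isoforms are conservatively treated as degraded, a known
limitation shared by span-based collapse tools.

**Retention rule.** A collapsed isoform is kept when it has at least two
supporting reads, or a single read with alignment identity strictly above
`pid_cut` (default 0.99), or every junction supported by short-read junction
evidence or the reference annotation (logical OR per junction). The
all-junctions rule is not applied vacuously to mono-exonic isoforms — an
unsupported singleton with no junctions would otherwise always pass.

**Loci.** Two isoforms belong to one gene locus when they share chrom and
strand and their spans overlap by at least `min_overlap` (default 0.2) of
the *shorter* span. Using the shorter span makes the relation symmetric, and
loci are its connected components (transitive closure); both choices are the
minimal consistent reading of a pairwise overlap criterion, and the
implementation is cross-checked against a brute-force transitive closure in
the tests.

**Novelty.** Reference transcripts are grouped into reference loci with the
same rule. An observed locus is novel when no reference locus passes the
overlap predicate against it on the same strand; a multi-exonic isoform is
novel unless its chain exactly matches a reference transcript on the same
chrom/strand, and a mono-exonic isoform unless a mono-exonic reference
transcript passes the overlap predicate. Exact junction matching (no fuzz)
is intentional: approximate matching belongs to the AS-event layer.

## AS event classification

Events between two isoforms of one locus fall into ten categories: SKIP /
MSKIP (one / two-or-more consecutive cassette exons of one isoform inside a
single intron of the other, flanking splice sites agreeing), IR / MIR (one /
two-or-more consecutive introns of one isoform inside a single exon of the
other), AE (two overlapping introns sharing exactly one splice site), and
X-prefixed approximate variants emitted when the structural pattern matches
but corresponding splice-site coordinates differ by 1..`fuzz` bp (default
10; with `fuzz = 0` no X-type can occur, an invariant the tests assert).

Two details are deliberate:

* Only internal boundaries — actual splice sites — are compared. Transcript
  termini are not constrained, because 3' ends scatter with poly(A) site
  choice and 5' ends with degradation; requiring TSS/TES agreement would
  misclassify exact retentions of terminal-adjacent introns as approximate.
* A SKIP or IR detection *claims* the flanking intron pairs it used, and
  claimed pairs are excluded from AE matching. Otherwise every skip would
  also be reported as an AE between its flanking intron and the merged
  intron. Unclaimed overlapping intron pairs are matched greedily by
  smallest total boundary difference, each intron used at most once.

`classify_pair()` is symmetric in its arguments (verified property), and
`summarize_as_events()` reports both raw per-pair counts and counts
deduplicated per locus by `(type, region)`, since published totals rarely
state their deduplication. Events are attributed to the libraries shared by
both isoforms of the pair (falling back to the union when the isoforms were
seen in disjoint libraries).

## APA detection

Per gene and strand, read 3' ends (the final transcribed base; block end on
`+`, block start on `-`) are clustered greedily: scanning ends in ascending
position, a new cluster opens when the next end is more than `group_window`
bp (default 5) from the current cluster's representative, where the
representative is the modal position so far (ties resolved to the most
3'-distal position for the strand). Clusters with fewer than `min_support`
reads (default 2) are discarded; survivors are accepted in descending
support order (ties most-3'-distal first), skipping any candidate within
`exclusion` bp (default 15) of an already accepted site. The scan order,
representative and tie-breaks are choices — the underlying greedy scheme is
conventionally left unspecified — fixed here so the output is deterministic
and order-invariant, and mirrored by an independent oracle in the tests.
Accepted sites of one gene are therefore always more than `exclusion` bp
apart, and raising `min_support` can only remove sites (both asserted).

## Fusion calling

A read with two or more alignment segments is a candidate fusion when (a)
its segments overlap two or more annotated genes, every same-chromosome gene
pair at least `min_distance` bp apart (default 10 kb; nearest annotated
boundaries; different chromosomes always pass), (b) each per-gene merged
coverage exceeds `min_seg_cov` (default 0.10) of the trimmed read, (c) the
combined coverage exceeds `min_total_cov` (default 0.99), and (d) at least
`min_pe` (default 2) paired-end read pairs span the junction. Paired-end
support arrives as a per-read count table rather than being recomputed from
short-read alignments — the criterion is a threshold on evidence produced by
any short-read pipeline. Every rejected multi-segment read is retained in
the candidate table with the list of violated criteria, so audits and
threshold sweeps need no re-run. Read-level candidates collapse to "fusion
gene" events by unordered gene set; both counts are reported because
published totals can refer to either level.

## lncRNA screening

A transcript is a lncRNA candidate when it has no hit in any of the four
protein databases (NR, Swiss-Prot, COG, KOG — supplied as a table; database
searching itself is out of scope), a coding-potential score below
`cp_cutoff`, and length at least 200 bp. The default cutoff 0.364 is a
published CPAT convention for vertebrate models and is prominently
configurable; a precomputed boolean `coding_call` column bypasses the score
entirely. Candidates are classified positionally against the annotation
with this precedence: intergenic (no gene-span overlap), intronic (fully
inside an intron of some transcript, either strand), sense / antisense
(exonic overlap, same / opposite strand), other (remaining partial-overlap
configurations). Intronic is tested before sense/antisense so that full
containment in an intron wins over a partial exonic overlap elsewhere;
"other" is an explicit fallback that the synthetic data cannot reach (with
hull-defined gene spans a candidate cannot cross a gene boundary without
touching an exon) but real annotations with disjoint exon islands can.

## The synthetic-data generator

`simulate_isoseq()` builds a toy genome (2 chromosomes of 500 kb by
default), 20 gene models of 1-8 exons (exons 120-400 bp, introns
300-1500 bp), 2-4 isoforms per gene produced by cycling through the ten AS
variant types with anchors chosen so that no variant chain is a 3'-anchored
suffix of another isoform's chain (that signature is reserved for
degradation) and terminal introns stay intact, 1-3 poly(A) sites per gene
spaced 60 bp, and 2-5 reads per isoform. Reads carry the configured primers
and a 20-60 nt poly(A) tail; half are emitted reverse-complemented. A
configurable fraction are 5'-degraded copies (multi-exon sources only, the
cut always past at least one junction, so the degraded chain is a proper
suffix), classification artifacts (a missing primer or tail, or an internal
primer), or two-gene fusion chimeras built from the 5' half of one
transcript and the 3' half (with its poly(A)) of a partner on another
chromosome — or, at a low rate, the same chromosome at >= 12 kb, to exercise
the distance criterion. Per-read 3' ends scatter around the chosen poly(A)
site with a configurable SD (default 2 bp), implemented by moving the
terminal exon edge so that alignments always reconstruct the read sequence
exactly at zero error. Poly(A) sites are assigned to reads round-robin
within a gene so per-site support stays even and site recovery is a
deterministic property of the configuration rather than of sampling luck.

Randomness uses one root seed with per-stage child seeds, so adding a stage
never perturbs earlier stages, and identical configurations produce
byte-identical output files. Substitution errors (rate `per_base_error`)
are confined to the transcript insert; primers and tails stay clean so that
classification outcomes remain a function of the declared artifact class.
Each isoform is guaranteed at least one full-length read so that its chain
is observable — without this, an isoform whose reads were all degraded
would surface as a spurious unfiltered suffix isoform.

Positional lncRNA test intervals (intergenic / intronic / sense /
antisense by construction) are emitted in the ground truth without reads;
sense/antisense intervals anchor on the first genomic exon, which no AS
variant removes, so the intended class is unambiguous under the classifier's
precedence. Noncoding genes that do produce reads are placed intergenically
so locus recovery stays exact.

The generator emulates structure, not error processes: there are no realistic
PacBio error profiles, no quality values, no expression-level or
tissue-specific biases (reads draw library labels uniformly), and no
polymerase/subread layer. Passing tests on this data therefore demonstrate
the correctness of the structural rules — grouping, filtering, interval
algebra, thresholds — not robustness to real-world noise, which is governed
by the identity/support thresholds upstream.

## Problem sizes, determinism and degenerate inputs

The test and acceptance runs use 12-30 genes, roughly 100-900 reads and
seeds fixed in code — sizes at which every oracle (exhaustive enumeration,
transitive closure, brute-force scanning) is affordable and the whole suite
runs in minutes on one CPU. Empty inputs are legal everywhere and yield
empty, correctly-typed outputs (an empty read set runs the full pipeline to
a zero-count manifest). All aggregations are permutation-invariant; ids are
assigned by sorted genomic position, never input order. Ties are broken
deterministically and documented at each rule above. `category_shares()`
accepts an externally stated total for tables whose categories do not
exhaust it — for such tables shares need not sum to 100, which is reported
as computed rather than patched.

## Known limitations

* The degradation filter conflates 5'-most intron retention with
  degradation (see above).
* Locus assignment by span overlap can chain distinct genes through a
  bridging isoform (transitive closure is deliberate but greedy).
* AE events are matched greedily by boundary distance; pathological isoform
  pairs with many equally-distant alternative boundaries could be matched
  differently than by an exhaustive optimal matching.
* The lncRNA filter is only as good as the supplied evidence table; the
  package ships no coding-potential model.
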