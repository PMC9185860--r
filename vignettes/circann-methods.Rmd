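---
title: "circann: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{circann: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Circular RNAs (circRNAs) arise by backsplicing: a downstream splice donor is
joined to an upstream splice acceptor, producing a covalently closed circle.
A backsplice caller (e.g. CIRI2) reports each event as a genomic interval
plus a strand; archived databases (circBase, circRNADb) report the same
molecules under incompatible accession schemes. Three practical problems
follow, and `circann` addresses each:

1. **Nomenclature.** A junction interval is meaningless to a biologist until
   it is expressed as a pair of exons on a concrete transcript. `circann`
   assigns every junction a *representative reference transcript* and a
   backsplice exon pair M/N, and names the circle `SYMBOL_eM-eN`.
2. **Coding potential.** Because the molecule is a circle, translation can
   run through the backsplice junction, possibly repeatedly, and in some
   cases never terminate. `circann` enumerates all maximal ORFs of the
   circular sequence and classifies them by how often they cross the
   junction: `0C`, `1C5'`, `1C3'`, `2C`, `edlsC` (endless).
3. **Context.** Junction calls from subcellularly fractionated RNA-seq
   (cytoplasm, nucleoplasm, chromatin-associated, polysome) are turned into
   per-junction presence profiles, archive memberships are reconciled by
   exact coordinate keys, and the results are rendered as deterministic
   transcript-track and protein-domain SVG plots.

Everything operates on one internal coordinate convention: 0-based,
half-open, on the forward genomic strand. Conversions happen only in the
readers and writers (GTF and CIRI2 are 1-based inclusive; BED is already
0-based half-open). A junction is identified everywhere by the exact key
`(contig, start, end, strand)`; no fuzzy matching happens at the
reconciliation layer, so set comparisons are deterministic and symmetric.
Tolerant matching lives in exactly one place, the transcript-matching step.

## Representative transcript selection

A transcript matches a junction when the circle's 5' end falls within a
tolerance of some exon's transcript-5' boundary (the acceptor side) and the
3' end within tolerance of some exon's transcript-3' boundary (the donor
side), with acceptor ordinal M ≤ donor ordinal N. On the minus strand the
genomic-left junction end maps to the donor side. Offsets are signed in
transcript orientation and recorded per end; the circle is later assembled
with these offsets applied, so the sequence reflects the junction's actual
coordinates, not the annotated boundaries.

Candidates are ranked lexicographically:

1. total offset (ascending) — junction fit comes first, because an
   ill-fitting transcript cannot define a meaningful exon pair;
2. CCDS status (tagged transcripts first) — a curated coding annotation is
   the strongest available prior on which isoform is "the" reference;
3. commonness (descending) — the number of the gene's junctions that the
   transcript matches, computed in a first pass over all junctions. This
   serves the goal of describing all of a gene's backsplice events with the
   minimal number of reference transcripts, so exon-pair labels from the
   same gene are comparable;
4. exon count (descending); 5. transcript length (descending);
6. transcript id (ascending), which makes the order total and the
   assignment deterministic.

The criterion order was a genuinely open design choice — reasonable sources
order fit, conservation/CCDS, exon count and length differently — and it is
exposed as a parameter (`criteria` of `rank_and_assign()`). "Conservation"
is deliberately not scored: no operational definition is available to this
package, and a silent proxy would be worse than an explicit absence.

Defaults: `tolerance = 2` nt (typical aligner wobble at splice boundaries),
junction grouping for commonness by `gene_id` (symbols collide). Single-exon
transcripts are eligible references; a circle may have M = N.

## The circular ORF model

The circle of length L is represented with position 0 at the first base of
the acceptor exon and the junction between positions L−1 and 0. ORFs use the
standard genetic code: start ATG only, stops TAA/TAG/TGA, stop codon
included in the reported length. The scan unrolls four copies of the circle
plus two bases and walks all three frames with the maximal-ORF convention
(an ORF starts at the first ATG after a stop). The window size is what makes
the endlessness rule sound: after 3L nt a reading returns to the same circle
position in the same frame, so a start anywhere in the first copy that meets
no stop within 3L nt provably never terminates, and a full 3L-nt lookahead
from any first-copy position needs 4L + 2 characters.

Junction crossings follow a closed form: an ORF starting at `s` with length
`len` crosses `floor((s + len − 1) / L)` times. Finite ORFs with three or
more crossings keep their count but are labelled `2C` (no further class
exists in the five-class vocabulary). Endless ORFs are reported as one
minimal period of the repeating peptide with `length_nt = 0` and
`crossings = Inf`. Both conventions are verified against an independent
brute-force reference (`orf_scan_reference()`) that walks codons one at a
time, counts passages explicitly, and translates through a plain codon
table; the test suite requires exact agreement on a thousand random circles
spanning both L mod 3 classes.

One subtlety surfaced by the property tests deserves a note. The
maximal-ORF convention on an *unrolled* circle is scan-origin dependent for
ATGs that precede the first in-frame stop: their suppressing upstream ATG
may lie across the origin. Rotating the circle can therefore legitimately
add or remove such first-window ORFs, and in stop-free frames the emitted
endless start is the linearly first ATG. The rotation-covariance test hence
asserts exact covariance on the *cyclically anchored* ORFs (start is the
first ATG after the preceding in-frame stop of the cyclic reading), exact
preservation of anchored junction-avoiding `0C` ORFs, and
cyclic-equivalence of endless period peptides. The engine-vs-reference
equivalence is unaffected, since both implementations share the unrolled
convention by construction.

### Novelty against the parental frame

Whether a single-crossing ORF gains a novel N or C terminus is decided
against the parental CDS projected onto the circle. A codon is *parental*
iff it lies inside a projected CDS interval, does not straddle the junction,
and is in frame with the annotated reading. For one-crossing ORFs: parental
pre-junction segment with novel post-junction segment ⇒ `1C3'` (novel C
terminus); the reverse ⇒ `1C5'`; both parental (an in-frame junction) keeps
`1C3'` with the qualifier `frame-preserving` and no novelty; neither
parental — or a noncoding host — keeps `1C3'` with qualifier
`no-parental-frame` and both termini novel. The qualifiers deliberately do
not introduce new classes, so the five-class vocabulary stays intact. A
segment counts as parental when it has at least one codon and all of its
codons (including the stop, excluding any junction-straddling codon) are
parental. Zero-crossing ORFs are indistinguishable from linear ORFs of the
host and get no novelty; `2C` and `edlsC` ORFs are novel at both ends.
ORF-to-protein alignment is pure coordinate arithmetic (parental codons are
exact copies by construction); the stop codon encodes no residue and is
excluded from both the residue interval and the overhang counts.

The geometric 5'/3' decision rule is the main modelling assumption here: a
pure-geometry alternative (which side of the junction the ATG sits on)
coincides with the parental-frame rule whenever the host has an annotated
CDS overlapping the circle in frame, but differs for noncoding hosts, where
the parental-frame rule degrades explicitly to a qualifier instead of
guessing.

### Parameters

| parameter | default | unit | meaning |
|---|---|---|---|
| `tolerance` | 2 | nt | per-end slack when matching junction ends to exon boundaries |
| `min_reads` | 2 | junction reads | CIRI2 rows below this support are dropped |
| `min_peptide` | 20 (pipeline), 1 (tests/fixture) | aa | shortest finite peptide reported; endless ORFs are never dropped |

`min_peptide = 20` suppresses spurious micro-ORFs in real annotation runs;
the synthetic fixture runs with 1 so that its deliberately tiny designed
peptides (down to 2 aa) are visible to the tests.

## What the synthetic fixture emulates

`fixture_spec()` / `generate_fixtures()` build a complete dataset on one
toy contig (~2 kb): an Ensembl-dialect GTF with CCDS tags, a genome FASTA,
one CIRI2-style table per subcellular compartment, circBase-like and
circRNADb-like dumps with accession schemes, a protein domain table, a
ready-to-run config, and a ground-truth JSON. Ground truth is computed by
blueprint bookkeeping and the brute-force reference scan at generation time,
never by the annotation engine, so pipeline tests are non-circular.

The designed content: six single-junction genes realising each ORF scenario
(`0C`, `1C5'`, `1C3'` on the minus strand, `2C`, `edlsC`, and an ATG-free
circle), a three-isoform gene hosting 9/2/1 exon pairs (the shape of a gene
where no single reference transcript fits all backsplice events), a
commonness gene where a shared transcript must beat a rival with more exons,
and archive-only junctions populating all seven regions of the three-set
database Venn. Designed scenario sequences guarantee *exactly one* ORF per
circle by construction (single ATG, controlled stop placement), which the
generator re-verifies with the reference scan before writing anything.

What the fixture does **not** emulate: read-level sequencing noise and
alignment artifacts (junction tables are emitted directly — calling is out
of scope), genome-scale gene density, overlapping isoform structures beyond
the designed cases, assembly mismatches between archives (callers must
harmonize assemblies; there is no liftover), and realistic exon/intron
length distributions. Passing tests therefore demonstrate the correctness
of the annotation logic under clean inputs, not robustness to caller noise.

## Numerical and degenerate-input choices

* Circles shorter than 3 nt are rejected; L ∈ {3..8} is allowed in the API
  though the designed scenario constructions require L ≥ 9.
* Strandless BED rows are rejected rather than guessed — circle sequence
  depends on strand.
* Offsets may extend a circle past its annotated exon boundary into the
  intron (the junction is the observation; the annotation is the prior);
  an offset that would consume an entire terminal exon is an error.
* Boundary ties during matching are broken toward the smaller exon ordinal;
  assignment ties are impossible because transcript ids are unique.
* Merging junction records never sums read support across sources; support
  stays per source label.
* All output tables are sorted on the junction key, and the SVG writer uses
  fixed-format coordinates, so identical inputs give byte-identical files.

## Problem sizes

The test suite and the acceptance script run entirely on generated data:
one thousand random circles with L between 9 and 300 for the
engine-vs-reference equivalence, a few hundred randomized property cases
per invariant, and the ~2 kb fixture contig with 24 junctions for the
pipeline checks. The full suite completes in well under a minute on a
single CPU.

## Known limitations

* No conservation scoring, IRES prediction, miRNA-sponge annotation, or
  translation-efficiency modelling.
* No GFF3 input and no chromosome-alias resolution; Ensembl-dialect GTF
  only.
* Archive reconciliation assumes all inputs share one genome assembly.
* The ranking reproduces a defensible, configurable order over the
  documented criteria; other orders are selectable but not auto-tuned.
* Endless-ORF peptides are reported as one minimal period; downstream
  consumers must treat them as infinite repeats, not finite peptides.
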