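# circann

Backsplice-junction annotation, rolling-circle ORF prediction and
visualization for circular RNAs, in R.

Circular RNAs (circRNAs) form when a downstream splice donor backsplices to
an upstream splice acceptor. Callers report these events as bare genomic
intervals, and the major archives (circBase, circRNADb) identify the same
molecules under incompatible accession schemes — so two basic questions,
*"which exons of which transcript does this circle use?"* and *"is this
circle in that other database?"*, are surprisingly hard to answer. A third
question is unique to the circular topology: an open reading frame can run
through the backsplice junction, once, twice, or forever.

`circann` answers all three:

* **Representative transcript and exon-pair nomenclature.** Each junction
  `(contig, start, end, strand)` is matched against Ensembl-style gene
  models (junction ends within a tolerance, default 2 nt, of annotated exon
  boundaries) and assigned one transcript by a deterministic lexicographic
  ranking: junction fit (total offset) → CCDS status → *commonness* (how
  many of the gene's junctions that transcript matches — minimising the
  number of reference transcripts per gene) → exon count → length →
  transcript id. The circle over exons M..N of gene *SYMBOL* is named
  `SYMBOL_eM-eN`.
* **Circular ORF enumeration and crossing classes.** The circle of length
  *L* is unrolled (4 copies + 2 bases) and scanned in all frames with the
  maximal-ORF convention (first ATG after a stop; stops TAA/TAG/TGA; stop
  codon counted in the length). Crossings of the junction follow the closed
  form `floor((start + length − 1) / L)`, giving the classes `0C`, `1C5'`,
  `1C3'`, `2C`; if no stop occurs within 3·L nt the reading has returned to
  its own start in frame and the ORF is *endless* (`edlsC`), reported as
  one minimal period of its repeating peptide. Single-crossing ORFs gain a
  novel N or C terminus depending on which side of the junction matches the
  parental CDS in frame. A deliberately naive brute-force scanner
  (`orf_scan_reference()`) serves as an independent reference
  implementation; the test suite requires 100% agreement on a thousand
  random circles.
* **Localization, reconciliation, plots.** Junction calls from fractionated
  RNA-seq (cytoplasm, nucleoplasm, chromatin, polysome) become per-junction
  presence profiles; archive dumps are reconciled by exact coordinate keys
  into Venn partitions; and deterministic SVG plots show transcripts (red)
  with their circRNAs (green = ORF predicted, blue = none) and
  circRNA-derived ORFs aligned to the parental protein with its domains.

A seeded synthetic-fixture generator (`generate_fixtures()`) produces a
complete toy dataset — genome, GTF, CIRI2-style junction tables per
compartment, archive dumps, domain table, config, and oracle-computed
ground truth — so the entire pipeline runs and is tested without any
external data.

## Worked example

```r
library(circann)

fixdir <- file.path(tempdir(), "demo")
generate_fixtures(fixdir)                  # writes genome, GTF, junction tables, config
res <- annotate_run(file.path(fixdir, "config.yml"),
                    out_dir = file.path(fixdir, "out"))
#> junctions: 24 distinct after merging 6 input table(s)
#> assigned: 21 / 24 junctions (tolerance 2 nt)
#> ORFs: 41 total (0C: 18, 1C3': 12, 1C5': 1, 2C: 1, edlsC: 9)
#> wrote outputs to /tmp/.../demo/out
```

24 distinct junctions survive merging the four compartment tables and two
archive dumps; 21 lie on annotated transcripts and get an exon pair, and 3
archive-only junctions in intergenic space stay unassigned. The five
designed scenario circles come out with one ORF each:

```r
res$orfs[res$orfs$name %in% c("CIRZERO_e2-e3", "CIRFIVE_e2-e3",
                              "CIRTHREE_e2-e3", "CIRTWO_e2-e3",
                              "CIRENDLESS_e2-e3"), ]
#>   name             start length_nt crossings class novel_n novel_c peptide
#> 1 CIRZERO_e2-e3        0         9         0 0C    FALSE   FALSE   MK
#> 2 CIRFIVE_e2-e3        9         9         1 1C5'  TRUE    FALSE   MA
#> 3 CIRTHREE_e2-e3       3         9         1 1C3'  FALSE   TRUE    MP
#> 4 CIRTWO_e2-e3         0        24         2 2C    TRUE    TRUE    MKKNEKK
#> 5 CIRENDLESS_e2-e3     0         0       Inf edlsC TRUE    TRUE    MAA
```

Reading the rows: the `0C` ORF never touches the junction and is
indistinguishable from a linear ORF of the host gene; the `1C5'` ORF starts
9 nt into a 12-nt circle, crosses once, and only its post-junction half is
parental, so its N terminus is novel; the `2C` ORF on a 10-nt circle needs
24 nt — two full passes — before reaching a stop; and the `edlsC` ORF on a
stop-free frame never terminates, so only its repeating unit `MAA` is
reported (`length_nt = 0`, `crossings = Inf`).

Reconciling de novo calls with the two archive dumps partitions the 24
junctions into all seven Venn regions:

```r
venn_run(file.path(fixdir, "config.yml"), "databases")
#>   region                    n_sets count
#> 1 circbase                       1     1
#> 2 circrnadb                      1     1
#> 3 denovo                         1     6
#> 4 circbase&circrnadb             2     1
#> 5 denovo&circbase                2     8
#> 6 denovo&circrnadb               2     4
#> 7 denovo&circbase&circrnadb      3     3

plot_run(file.path(fixdir, "config.yml"), "PTPX",
         out_dir = file.path(fixdir, "plots"), result = res)
# -> PTPX_transcripts.svg: 3 red transcript rows hosting 9, 2 and 1 circRNAs
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/circann.R` (subcommands `annotate`, `venn`, `plot`, `fixtures`).

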