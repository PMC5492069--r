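# hbugkit

Downstream annotation and expression triage for de novo insect
transcriptomes, built around the analysis performed for the harlequin bug
(*Murgantia histrionica*) developmental/sex RNA-Seq survey (2nd instar, 4th
instar, adult female, adult male; one library each). The upstream heavy
machinery — assembly, BLAST, HMMER, RSEM — is out of scope; `hbugkit`
implements the bespoke downstream computations that turn those tools'
tabular outputs into results, as tested, reusable functions:

* **Transcript QC** — exact-homopolymer poly-A/T tail clipping, a ≥ 200 bp
  length filter, and purging of transcripts with Strong/Moderate
  vector-screen matches (VecScreen-style terminal/internal score ladders).
* **Homology tiering** — the gold/silver/bronze annotation-confidence
  partition from protein alignment summaries. Gold requires query ≥ 300 nt,
  a single HSP against a subject ≥ 100 aa, positives/hit ≥ 0.75 and
  hit/subject ≥ 0.90; silver requires query ≥ 100 nt with subject coverage
  ≥ 0.75; bronze relaxes coverage to ≥ 0.30.
* **Gene-family calling** — GST/COE-style membership from the top HSP by a
  five-way AND rule (bit ≥ 75, subject ≥ 100 aa, hit/subject ≥ 0.90,
  hit/query ≥ 0.75, positives/hit ≥ 0.80), plus six-frame longest-ORF
  extraction, exact-identity protein dedup, best-hit clustering for P450
  triage and genome locus-mapping summaries.
* **GO-Slim annotation** — pfam2go mapping and resolution of fine-grained
  GO terms to their *penultimate ancestors*: the direct children of the
  aspect root lying on at least one `is_a` path from the term to the root.
* **Replicate-free expression contrasts** — TPM
  (`TPM_i = (c_i/l_i) / Σ_j (c_j/l_j) × 10⁶`), read-group pooling by
  summed counts, log2 fold-changes with sentinel semantics
  (`undefined`, `+inf`, `-inf`), a 5-TPM floor, per-direction ranking and
  sex-pattern classification. With a single library per condition these
  ratios are suggestive, never inferential — no DE testing is attempted.
* **Synthetic data** — a ground-truth generator (transcripts with planted
  tails/vector segments, tier-engineered alignment tables, Poisson counts
  with planted fold-changes and zero-expression edge cases, a rooted
  three-aspect toy ontology) so every stage is testable without downloads.
* **Pipeline driver** — `runPipeline()` over a YAML config, plus a thin
  `inst/scripts/hbugkit` command-line wrapper
  (`simulate|qc|tier|family|goslim|contrast|run`).

## Worked example

Rank the bundled 2nd-vs-4th-instar TPM pairs and total the sequencing
volumes:

```r
library(hbugkit)

t3 <- read.delim(hbugExtdata("stage_contrast_tpm.tsv"))
blk <- t3[t3$contrast == "2nd:4th", ]
rankContrast(blk$gene, blk$tpm_num, blk$tpm_den,
             contrastConfig("4th:2nd", topK = 2))
#>                                              id  tpmNum tpmDen  log2fc direction
#> 1  adult-specific cuticular protein ACP-20-like  253.24   7.24  5.1284        up
#> 2          uncharacterized protein LOC106688964 1055.89  42.45  4.6366        up
#> 3           heat shock 70 kDa protein cognate 4    8.17 334.68 -5.3563      down
#> 4 acyl-CoA Delta(11) desaturase-like isoform X1    7.17 287.99 -5.3279      down
```

The strongest nymphal up-regulation (log2FC 5.1284, a cuticular protein at
253.24 vs 7.24 TPM) and down-regulation (−5.3563, an Hsp70 cognate) fall
straight out of the printed TPM pairs; both TPM values clear the 5-TPM
floor, so neither row is filtered.

```r
summarizeVolumes(read.delim(hbugExtdata("sequencing_volumes.tsv")))$totals
#>    raw_pairs    raw_bases   norm_pairs   norm_bases
#>    859278074 171855614800     54445986  10889197200

classifyTier(queryLen = 300, nHsps = 1, subjectLen = 100,
             hitLen = 90, positives = 68)
#> [1] "gold"

formatLog2fc(log2FoldChange(c(253.24, 0, 6.35), c(7.24, 0, 0)))
#> [1] "5.1284"    "undefined" "+inf"
```

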