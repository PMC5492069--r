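---
title: "Methods: downstream triage of a de novo insect transcriptome"
author: "hbugkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: downstream triage of a de novo insect transcriptome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbugkit)
```

# Scope and assumptions

`hbugkit` covers the downstream, desk-scale computations of a
single-replicate insect RNA-Seq survey: four whole-insect libraries (2nd
instar, 4th instar, adult female, adult male) assembled de novo, with
transcripts then cleaned, tiered by homology evidence, screened for
detoxification gene families, annotated via Pfam/GO, and contrasted on the
TPM scale. The package consumes the *tabular outputs* of the upstream
tools (BLAST-style alignment summaries, Pfam hit tables, count vectors);
it never runs the searches themselves. Two consequences shape the design:

* With one library per condition there is no dispersion estimate, so
  expression contrasts are descriptive log2 ratios with explicit sentinel
  states rather than statistical tests.
* Every rule is a deterministic function of its input table, so each stage
  can be validated against an independent brute-force oracle and against a
  generator that plants known truth.

# Transcript QC

Cleanup runs in a fixed order: clip residual poly-A/T tails, drop
transcripts shorter than `minLength`, purge vector contamination.

**Tail clipping** (`clipPolyAT`) removes one maximal run of ≥
`minTailRun` (default 5) consecutive `A` from the 3' end and `T` from the
5' end. Runs are exact homopolymers — a mismatch or an `N` terminates the
run — and clipping is applied once per end. Exactness buys idempotence
(`clip(clip(x)) = clip(x)`), which the suite checks on 1,000 random
tail-decorated sequences; a mismatch-tolerant trimmer would not have that
property and the benefit on assembled (not raw-read) sequences is
marginal.

**Length filter**: `minLength = 200` nt, applied *after* clipping. The
ordering is a genuine design choice — a 210 nt transcript with a 15 nt
tail is 195 nt of real sequence, and keeping it would let tail length
decide retention. The threshold is configurable and the order is recorded
in the run manifest.

**Vector screening** (`categorizeVectorMatch`, `purgeContaminated`)
classifies matches as Strong/Moderate/Weak/None from an alignment score
and the match's position. A match is *terminal* when it begins within
`terminalWindow = 25` nt of either end. The default score ladders are the
published NCBI VecScreen ones (terminal: Strong ≥ 24, Moderate 19–23,
Weak 16–18; internal: Strong ≥ 30, Moderate 25–29, Weak 23–24): the
screening tool fixes the scheme but the thresholds must still be
overridable and logged, so they live in `qcConfig()`. Only Strong and
Moderate matches cause removal; purging is idempotent by construction.
Match intervals are 0-based half-open in the input TSV (the native habitat
of such tables) and converted internally.

# Homology tiering

`classifyTier` implements the three-tier confidence partition with
precedence gold > silver > bronze:

* gold — query ≥ 300 nt, exactly 1 HSP, subject ≥ 100 aa,
  positives/hit ≥ 0.75, hit/subject ≥ 0.90;
* silver — query ≥ 100 nt, hit/subject ≥ 0.75;
* bronze — query ≥ 100 nt, hit/subject ≥ 0.30;
* otherwise untiered.

Choices the rule statement leaves open, resolved here:

* *Positive fraction* is `positives / hitLen`, matching BLAST tabular
  `positive` semantics.
* *Best hit* per transcript is the highest bitscore, ties broken by the
  lexicographically lowest subject id. The data give no grounds for any
  particular tie-break; determinism is what matters, both for testing and
  for reproducible reruns.
* Silver/bronze impose no single-HSP requirement, and coverage uses the
  best single hit's aligned length — HSPs are never merged. Merging would
  need positional bookkeeping the summary tables do not carry.
* Query lengths are post-QC transcript lengths in nucleotides; no /3
  conversion is applied since the 300/100 floors are stated on the
  transcript.

The suite checks the classifier against a plain if/else re-derivation on
10,000 random summaries, plus monotonicity: growing the hit never demotes
a transcript.

# Gene-family calling

`callFamily` decides membership from the query's top HSP against a curated
family protein set by a five-way AND: bitscore ≥ 75, subject ≥ 100 aa,
hit/subject ≥ 0.90, hit/query ≥ 0.75, positives/hit ≥ 0.80. Queries are
longest-ORF translations, so `qlen` is in amino acids. Failed criteria are
recorded per non-member, which makes threshold sensitivity auditable.
Raising any threshold can only remove members — asserted as a property.

`longestOrf` defines an ORF as the longest stop-free codon stretch in any
of the six frames, starting at any codon — no start codon required, since
assembled fragments routinely truncate 5' ends. Ambiguous codons translate
to `X` and do not end a stretch, and initiator-codon translation rules are
disabled so internal codons translate uniformly (`TTG`/`CTG` are L, not
M). The implementation is validated against an O(n²) enumeration of all
codon-aligned substrings.

Supporting operations mirror the survey's bookkeeping: exact-identity
protein dedup (first occurrence kept), best-hit clustering with
within-group ordering by descending query length (the "sort by best hit"
step of P450 triage), and locus-mapping summaries (aligned-protein and
distinct-locus counts).

# GO-Slim by penultimate ancestors

The ontology is held as a rooted `is_a` DAG per aspect
(`OntologyGraph`), read from an OBO subset (`id`, `name`, `namespace`,
`is_a`; obsolete terms dropped with a warning, `alt_id` ignored). Only
`is_a` edges are traversed — `part_of` and other relations are not
represented, a documented limitation of the slimming scheme itself.

`resolveGoSlim(term)` returns every direct child of the aspect root that
lies on at least one `is_a` path from the term to the root; a term that is
itself a child of the root resolves to itself, and multiple penultimate
ancestors are all retained (set semantics). Implementation note: because
ancestry is transitive, the slim set is exactly the ancestors of the term
(term included) whose parent list contains the root — no path enumeration
is needed. The test suite nevertheless compares against exhaustive path
enumeration on random DAGs of up to 50 terms, and the class validity
methods enforce acyclicity (via igraph), single roots, root reachability
and aspect-closed edges, so malformed inputs fail at construction.

Pfam accession matching ignores version suffixes (`PF00067.20` ≡
`PF00067`). Distinct-term tallies are emitted per aspect both before and
after slimming, and slim tallies are also emitted per transcript — the two
tallies answer different questions and the cost of keeping both is nil.

# Expression contrasts

`computeTpm` uses the simplified estimator
`TPM_i = (c_i/l_i)/Σ_j(c_j/l_j) × 10⁶` with effective length equal to
transcript length — no fragment-length correction and no EM multi-mapping
resolution. This diverges from RSEM's estimator by design: at desk scale
the package consumes plain count vectors, and every column still sums to
10⁶ (asserted to ±10⁻³).

**Pooling** (`poolGroups`) forms the nymph (2nd + 4th) and adult
(female + male) groups by *summing counts and renormalising*, because the
survey pooled reads. Pooled TPM equals the depth-weighted — not the
arithmetic — mean of member TPMs; the suite constructs an unequal-depth
counterexample where the two differ by more than 10⁴ TPM.

**log2 fold-changes** carry three sentinel states with fixed output
spellings: both TPMs zero → `undefined`, zero denominator → `+inf`, zero
numerator → `-inf`. Sentinels keep TSVs machine-readable and make the
zero-expression edge cases explicit instead of silently dropping rows.

**Floor**: `tpmFloor = 5` with `floorMode = "filter_min_both"` as the
default — a transcript is ranked only when both contrasted TPMs reach the
floor, which is consistent with every ranked example row having both TPMs
≥ 5 and which keeps sentinels out of rankings. A `"clamp"` mode
(`max(tpm, floor)`) is retained because "floor" can be read either way;
the mode used is logged per run. Ranking is by decreasing finite |log2FC|
with ties broken by id, so it is invariant to input row order.

**Sex patterns** (`classifySexPattern`): a *dominant-expressed* call needs
both sexes ≥ 5 TPM and ≥ 2-fold differential; a *specific* call needs the
low sex < 0.5 TPM and the high sex ≥ 3 TPM. The 0.5/3.0 cut-offs are
package defaults chosen once — roughly "absent" vs "clearly detected" on
the TPM scale — and are configurable; the two rules are mutually exclusive
by construction (a TPM cannot be both < 0.5 and ≥ 5).

# Synthetic data: what it emulates, and what it does not

The generator (`simConfig`, `simulateTranscripts`, `simulateAlignments`,
`simulateFamilyHits`, `simulateCounts`, `simulateOntology`,
`writeFixtures`) produces every downstream input with known truth.
Defaults define the standing test conditions: 200 transcripts with
tail-free cores of 300–2,000 nt, poly-A/T tails on 30% (5–30 nt), planted
vector decoy segments on 10%, tier mix 0.3/0.3/0.3/0.1, mean depth 500
counts per transcript per sample, 5% zero-expression plants.

Construction guarantees replace distributional hope wherever a round-trip
must be exact:

* cores start with `C` and end with `G`, so a core never extends a planted
  tail and clipping recovers the core exactly;
* vector segments are drawn from three bundled decoy sequences (not a real
  vector database — nothing is downloaded) and planted internally with a
  score realising a chosen Strong/Moderate/Weak category;
* alignment rows are engineered to satisfy exactly the true tier's rule
  and fail all stricter ones; ~20% of tiered transcripts also get a
  low-bitscore decoy hit to exercise best-hit selection;
* family rows pass all five thresholds for members and fail exactly one,
  randomly chosen, criterion for non-members;
* counts are Poisson with per-transcript means proportional to
  `TPM target × length`, log-normal baseline (median 50, sdlog 0.5)
  shared across samples, fold-changes applied to the numerator group's
  target. Poisson is sufficient because nothing downstream estimates
  dispersion; zero plants are exact zeros;
* the toy ontology builds each aspect in levels below its root, each term
  drawing parents only from the level above, making acyclicity and root
  reachability construction guarantees.

What passing these fixtures does *not* show about real data: no read-level
error model, no fragment-length or multi-mapping effects (the TPM
estimator is exact on these inputs by construction), no mismatch-bearing
tails or chimeric vector junctions, and alignment tables whose rows sit
cleanly on one side of each threshold rather than crowding the boundaries.
The fixtures validate the *rules*, not the upstream measurement process.

# Determinism and problem sizes

Every stochastic function takes a seed through its config and derives
stage-specific streams from it; identical configs give byte-identical
fixtures and pipeline outputs, asserted at file level. The default suite
uses 10,000-row oracle comparisons for the classifiers, 1,000 random
clip fixtures, random DAGs up to 50 terms, and 150–200-transcript
round-trips at depth 500 — sizes at which every oracle remains exhaustive
or exactly enumerable while the full suite stays comfortably fast on one
CPU. `scripts/acceptance.R` re-runs the same computations from scratch
against the installed package and emits its results as JSON.

# Known limitations

* The vector-screen categoriser consumes match tables; it does not align
  against a vector database.
* GO slimming ignores non-`is_a` relations, and terms are counted with
  set semantics per transcript.
* The TPM estimator is the simplified one described above; absolute
  values for multi-mapping-heavy transcripts will differ from an EM-based
  estimator's.
* Expression contrasts are unreplicated ratios; the package deliberately
  offers no significance machinery to put on top of them.
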