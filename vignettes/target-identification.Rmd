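---
title: "Identifying miRNA target sites from CLIP and PAR-CLIP reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying miRNA target sites from CLIP and PAR-CLIP reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Argonaute CLIP and PAR-CLIP experiments sequence short RNA fragments that
were crosslinked to the miRNA-loaded silencing complex. Mapped back to
3'UTRs, pile-ups of these fragments mark candidate miRNA binding sites. In
PAR-CLIP, 4-thiouridine incorporated into nascent transcripts is read as
cytosine by reverse transcription at crosslinked positions, so reads carry
diagnostic T-to-C substitutions. Those substitutions are both signal — they
pinpoint the crosslink — and a nuisance, because a read with several
conversions no longer aligns under a small mismatch budget.

`cliptar` implements a six-stage pipeline around this trade-off:

1. **Adapter trimming.** The 3' adapter is cut at the leftmost position
   where its prefix matches the read suffix (overlap ≥ 5 nt, mismatch rate
   ≤ 10%). Reads shorter than 15 nt after trimming, or containing `N`, are
   discarded.
2. **Quality control.** Trailing bases with phred < 20 are stripped;
   reads falling below 15 nt are discarded; identical sequences are
   collapsed into one record with a multiplicity count.
3. **C-to-T reversion** (PAR-CLIP only). For each cytidine in a read, one
   variant is generated with exactly that C reverted to T; a read with *c*
   cytidines yields 1 + *c* sequences, all of which are aligned.
4. **Alignment.** Ungapped, substitution-only, forward-strand alignment of
   every variant to the 3'UTR set with at most one mismatch, via an exact
   k-mer/pigeonhole index. Variant hits are reconciled back to the
   original read: at the chosen locus, every read-C-over-reference-T
   difference is a conversion (even one absorbed by the mismatch
   allowance), and only the remaining differences count as mismatches.
5. **Clustering.** Per UTR, single-linkage clusters of reads overlapping
   by ≥ 1 nt. A cluster must contain at least five reads
   (multiplicity-weighted), and in PAR-CLIP mode at least 20% of its reads
   must carry a conversion.
6. **Target identification and statistics.** Cluster windows are scanned
   for canonical seed matches (8mer, 7mer-m8, 7mer-A1; strict
   Watson-Crick), interactions are ranked by evidence, and per-position
   conversion profiles with a one-tailed regional Student's *t* test
   summarise where conversions fall relative to the seed.

Why revert one C at a time instead of simply allowing two mismatches?
Allowing a second free mismatch admits all twelve substitution types at
every position, inflating both false placements and search cost. The
reversion expansion only admits the one substitution PAR-CLIP actually
produces (T-to-C), and only one per read; a second conversion is absorbed
by the ordinary one-mismatch allowance. The worked expansion of
`AATGCTCAATGGCGA` into four sequences is shown on `?expand_c_to_t`.

## Site types and the position convention

A mature miRNA pairs its seed (positions 2-7, counted from its 5' end)
with the target 3'UTR. On the mRNA, reading 5'→3', a site is the reverse
complement of the seed, and the canonical types are:

* **8mer** — reverse complement of miRNA positions 2-8, followed by an A
  opposite miRNA position 1 (8-nt site, positions 1-8);
* **7mer-m8** — reverse complement of positions 2-8 without the A (7-nt
  site, positions 2-8);
* **7mer-A1** — reverse complement of positions 2-7 plus the position-1 A
  (7-nt site, positions 1-7).

Types are assigned exclusively and maximally: a locus that satisfies the
8mer definition is reported once, as an 8mer. G:U wobble pairs are not
accepted.

Throughout the statistics, *site position k* means the UTR nucleotide
pairing miRNA position *k*: position 1 is the 3'-most site nucleotide on
the mRNA and positions increase toward the mRNA 5' side. Positions 1-7
cover the seed-paired region; positions 8-14 (the "effector" region,
3'-adjacent to seed pairing on the miRNA and largely non-complementary)
are where PAR-CLIP conversions concentrate. For a 7mer-m8 site, which has
no paired position-1 base inside the site interval, position 1 is the base
immediately 3' of the interval.

## Ranking without context scores

Interaction ranking uses the documented evidence hierarchy: validated
interactions first (from a user-supplied two-column table standing in for
a curated MTI database), then miRNA expression (missing values rank
lowest), then seed strength (8mer > 7mer-m8 > 7mer-A1), then cluster read
support, with `(utr_id, site_start, mirna_id)` as a deterministic
tie-break. TargetScan-style context scores are features of an external
scoring system and are deliberately not re-derived here; the ranking
fields that replace them are all computed by the pipeline itself.

## The regional t statistic

`region_ttest()` compares the per-position pooled conversion ratios of
positions 1-7 against 8-14: a two-sample, equal-variance Student's *t*
with the one-tailed alternative that the effector region converts more.
The sampling unit is the *position* (seven pooled ratios per region), not
the site: pooling stabilises the per-position ratios, and seven-vs-seven
is the natural unit when the question is "where along the site do
conversions fall". Positions whose reference base is not T are undefined
(`NaN`) and excluded; a region with fewer than two defined positions
yields a flagged, not silently missing, result. The statistic is computed
in closed form so that the zero-variance case is well defined (equal
constant regions give *t* = 0, *p* = 0.5).

`stratified_tests()` repeats the test on site subsets defined by UTR
conservation (C/N) and seed length (7 = both 7mer types, 8 = 8mer),
optionally restricted to the most highly expressed miRNAs. The
conventional cut in genome-wide analyses is the top ~102 expressed
miRNAs; on small simulated panels `top_k` should simply be the panel
size or left `NULL`.

## The synthetic-data generator

`simulate_dataset()` builds a complete PAR-CLIP experiment with known
ground truth:

| parameter | default | meaning |
|---|---|---|
| `n_utrs`, `utr_length_range` | 30, 400-800 nt | random UTR panel |
| `gc_fraction` | 0.5 | base composition (so P(T) = 0.25) |
| `n_mirnas`, `mirna_length` | 10, 22 nt | random miRNAs, unique seeds |
| `n_sites_per_utr` | 2 | implanted seed-complementary sites |
| `site_type_mix` | 0.4/0.3/0.3 | 8mer / 7mer-m8 / 7mer-A1 |
| `reads_per_site_range` | 10-30 | reads covering each site, jittered starts |
| `read_length_range` | 20-32 nt | trimmed-insert-scale read lengths |
| `background_read_count` | 200 | reads uniform over the UTRs |
| `conv_prob_seed_region` | 0.05 | per-T conversion rate, positions 1-7 |
| `conv_prob_effector_region` | 0.40 | per-T conversion rate, positions 8-14 |
| `conv_prob_background` | 0.02 | per-T conversion rate elsewhere |
| `seq_error_rate` | 0.001 | uniform substitution error |
| `adapter_readthrough_fraction` | 0.3 | reads running into the 3' adapter |

Sites are implanted by writing an 8-nt block whose first and last bases
are fixed so the match type is exactly the intended one; blocks sit at
least 30 nt apart and at least 14 nt from the UTR 5' end so the whole
position 1-14 window lies on the UTR. Conversion is an independent
per-T Bernoulli draw at the positional rate — the simplest model that
makes the regional alternative literally true. Quality strings decay
toward the 3' end with occasional sub-threshold tails so quality trimming
does real work; a fraction of reads runs through into the adapter, as in
real short-insert libraries.

What the generator does **not** emulate: PCR duplication structure beyond
what collapsing needs, RNA secondary structure, per-read crosslink-count
models, splicing, and non-uniform background coverage. Passing tests
therefore demonstrate correctness of the pipeline's logic under a clean
generative model, not performance on any particular biological library.

`simulate_region_profile()` draws pooled profile counts directly from the
same regional model; it is used for the t-test calibration and power
experiments, where replicating thousands of full read-level runs would add
nothing but time.

## Numerical and design choices

* Internal coordinates are 0-based half-open; reports are 1-based
  inclusive; cluster BED output follows the BED convention.
* Phred offset defaults to 33, with 64 available for legacy data.
* All sequences are stored as DNA; miRNA FASTA may be RNA (U → T).
* "Minimum overlap" clustering is single linkage at ≥ 1 nt, the weakest
  consistent reading, configurable upward via `min_overlap`.
* Collapsed multiplicities count toward the five-read rule and the
  conversion fraction: collapsing is a compression step and must not
  change the biology.
* Placement ties break deterministically: fewest true mismatches, most
  conversions, smallest `(utr_id, offset)`; a read mapping equally well to
  several loci keeps the single tie-broken placement.
* The mapping stage accepts a `workers` argument; work is split into
  chunks with a fixed merge order, so results are identical for any
  worker count.
* Test and calibration problem sizes (30-UTR panels, 1000-replicate null
  calibration, 200-replicate power runs) were chosen as the smallest
  instances at which the properties under test are statistically
  meaningful.

## Known limitations

* **Mappability censoring.** A read with three or more conversions cannot
  map under one reversion plus one mismatch, and such reads carry
  disproportionately many conversions. The pooled effector-region ratio
  measured by the pipeline therefore sits a few percentage points below
  the true generative rate (at the defaults, roughly 0.33-0.37 observed
  versus 0.40 generative). This is a property of the reversion method
  itself — the same censoring affects any fixed-budget aligner — and is
  visible in the package's own recovery checks.
* Only substitutions are modelled; indel-bearing reads are unmapped.
* Seed matching is strict Watson-Crick; 6mer and offset-6mer sites,
  wobble seeds and compensatory 3' pairing are out of scope.
* Conservation enters only as a per-UTR flag supplied by the user; no
  alignment-based conservation scoring is performed.
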