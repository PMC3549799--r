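# cliptar

Identification of miRNA target sites from CLIP and PAR-CLIP sequencing
reads, for researchers analysing Argonaute immunoprecipitation libraries
against 3'UTR references.

CLIP-seq captures the RNA fragments bound by the miRNA-loaded silencing
complex; clusters of mapped fragments on a 3'UTR mark candidate miRNA
binding sites. PAR-CLIP additionally leaves a diagnostic T→C substitution
in reads at crosslinked positions — strong evidence of a genuine binding
site, but also a mapping obstacle, since a read with several conversions
no longer aligns under a small mismatch budget. `cliptar` resolves this
with a *single-C reversion* strategy: each read with *c* cytidines is
expanded into 1 + *c* sequences (the original plus one variant per C with
that C reverted to T), all of which are aligned ungapped with at most one
mismatch. One conversion is repaired by the reversion, a second is
absorbed by the mismatch allowance, and only the one substitution type
PAR-CLIP actually produces is ever admitted.

The pipeline: 3' adapter trimming and quality filtering (discard < 15 nt
or ambiguous reads, strip 3' tails with phred < 20, collapse duplicates) →
C-to-T reversion expansion (PAR-CLIP mode) → exact k-mer/pigeonhole
alignment to 3'UTRs → single-linkage read clustering (≥ 5 reads; in
PAR-CLIP mode ≥ 20% of reads converted) → canonical seed-match scanning
(8mer, 7mer-m8, 7mer-A1) with evidence ranking (validated > expression >
seed strength > read support) → per-position T-to-C conversion profiles
and a one-tailed Student's *t* test comparing site positions 1–7 (seed-
paired) against 8–14 (the crosslink-enriched effector region), optionally
stratified by UTR conservation and seed length.

A synthetic PAR-CLIP generator (`simulate_dataset()`) with a ground-truth
table makes every stage testable without any external downloads.

## Worked example

```r
library(cliptar)

cfg <- sim_config(seed = 7)                  # synthetic PAR-CLIP experiment
d   <- simulate_dataset(cfg)
res <- run_pipeline(d$reads, d$utrs, d$mirnas, mode = "parclip",
                    preprocess = preprocess_params(adapter = cfg$adapter),
                    expression = d$expression, validated = d$validated)
res$summary
#>             metric value
#>           reads_in  1360
#>  discarded_adapter     0
#>  discarded_quality     0
#>    reads_surviving  1360
#>   unique_sequences  1344
#>       mapped_reads  1290
#>     unmapped_reads    70
#>     clusters_total   180
#>      clusters_pass    55
#>     sites_reported    61
```

1290 of 1360 reads map (the remainder carry more T→C conversions than one
reversion plus one mismatch can repair); 55 of 180 read clusters pass the
five-read and 20%-conversion filters, yielding 61 ranked target sites:

```r
head(res$sites, 3)
#>  utr_id mirna_id site_start site_end seed_match_type read_support
#>  utr005  mir-006        397      404         7mer-A1           18
#>  utr011  mir-006        519      526         7mer-A1           12
#>  utr027  mir-002        272      279         7mer-m8           22
#>  conversion_read_fraction validated rank
#>                 0.2777778      TRUE    1
#>                 0.4166667      TRUE    2
#>                 0.3181818      TRUE    3
```

Experimentally validated interactions rank first; coordinates are 0-based
half-open internally and 1-based inclusive in the TSV report. The
conversion profile separates the two site regions sharply — position 4
(seed-paired) converts in ~3% of covering reads, position 11 (effector)
in ~36%:

```r
res$ttest[c("t", "p_value")]
#> t = 29.47, one-tailed p = 7.26e-13
as.data.frame(res$profile)[c(4, 11), ]
#>  position converted covering     ratio
#>         4        10      357 0.0280112
#>        11        72      199 0.3618090
```

A thin command-line front end wraps the same functions:

```sh
Rscript inst/scripts/cliptar simulate --seed 7 --out sim/
Rscript inst/scripts/cliptar run --mode parclip --reads sim/reads.fastq \
    --utrs sim/utrs.fa --mirnas sim/mirnas.fa \
    --adapter TGGAATTCTCGGGTGCCAAGG --expression sim/expression.tsv --out out/
```

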