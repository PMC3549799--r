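#' Run the full CLIP/PAR-CLIP target-identification pipeline
#'
#' Executes the six stages in order: adapter trimming, quality trimming
#' and collapsing; (PAR-CLIP only) single-C reversion expansion; ungapped
#' one-mismatch alignment to the 3'UTR references with reconciliation back
#' to the original read; single-linkage read clustering; read-support and
#' (PAR-CLIP only) conversion-fraction filtering; seed-match target
#' identification and evidence ranking; and per-position T-to-C conversion
#' statistics. Outputs are deterministic for identical inputs, for any
#' `workers` value.
#'
#' @param reads reads table or path to a FASTQ file.
#' @param utrs UTR table or path to a 3'UTR FASTA.
#' @param mirnas miRNA table or path to a mature-miRNA FASTA.
#' @param mode `"parclip"` (reversion and conversion filter active) or
#'   `"clip"`.
#' @param preprocess [preprocess_params()].
#' @param cluster [cluster_params()].
#' @param max_mismatch alignment mismatch budget (default 1).
#' @param seed_k aligner k-mer length (default 10).
#' @param flank UTR flank scanned for seeds beyond the cluster span.
#' @param P conversion-profile length (default 14).
#' @param strata stratum labels for [stratified_tests()].
#' @param top_k optional top-expressed-miRNA restriction for the
#'   stratified tests.
#' @param conservation optional conservation table or TSV path (applies
#'   when `utrs` is a FASTA path or lacks flags).
#' @param expression optional expression table or TSV path.
#' @param validated optional validated-MTI table or TSV path.
#' @param phred_offset FASTQ quality encoding (33 or 64).
#' @param out_dir optional directory for TSV/BED outputs (`sites.tsv`,
#'   `clusters.bed`, `clusters.tsv`, `profile.tsv`, `strata.tsv`,
#'   `summary.tsv`); partial outputs are removed on failure.
#' @param workers number of deterministic mapping chunks.
#' @param verbose emit progress messages.
#' @return list with `summary` (stage counts), `mapped`, `clusters`
#'   (filtered), `clusters_all`, `sites` (ranked), `profile`, `ttest`,
#'   `strata`.
#' @export
run_pipeline <- function(reads, utrs, mirnas, mode = c("parclip", "clip"),
                         preprocess = preprocess_params(),
                         cluster = cluster_params(),
                         max_mismatch = 1L, seed_k = 10L, flank = 0L,
                         P = 14L, strata = default_strata(), top_k = NULL,
                         conservation = NULL, expression = NULL,
                         validated = NULL, phred_offset = 33L,
                         out_dir = NULL, workers = 1L, verbose = FALSE) {
  mode <- match.arg(mode)
  say <- function(...) if (verbose) message("[", mode, "] ", ...)
  if (is.character(reads)) reads <- read_fastq(reads, phred_offset)
  if (is.character(utrs)) utrs <- read_utr_fasta(utrs, conservation)
  else if (!is.null(conservation)) {
    if (is.character(conservation)) conservation <- read_conservation_tsv(conservation)
    utrs$conserved <- conservation$conserved[match(utrs$utr_id, conservation$utr_id)]
  }
  if (is.character(mirnas)) mirnas <- read_mirna_fasta(mirnas)
  if (is.character(expression)) expression <- read_expression_tsv(expression)
  if (is.character(validated)) validated <- read_validated_tsv(validated)
  if (nrow(utrs) == 0L) stage_stop("align", "empty reference set")

  say("preprocessing ", sum(reads$multiplicity), " reads")
  pp <- tryCatch(preprocess_reads(reads, preprocess),
                 error = function(e) stage_stop("preprocess", conditionMessage(e)))
  say(pp$reads_surviving, " reads survive trimming (",
      pp$unique_sequences, " unique sequences)")

  index <- tryCatch(build_utr_index(utrs, seed_k),
                    error = function(e) stage_stop("align", conditionMessage(e)))
  mp <- tryCatch(map_reads(pp$reads, index, mode, max_mismatch, workers),
                 error = function(e) stage_stop("align", conditionMessage(e)))
  say(sum(mp$mapped$multiplicity), " reads mapped, ", mp$unmapped, " unmapped")

  cl_all <- tryCatch(build_clusters(mp$mapped, cluster),
                     error = function(e) stage_stop("cluster", conditionMessage(e)))
  cl <- filter_clusters(cl_all, cluster, parclip_mode = mode == "parclip")
  say(nrow(cl_all$clusters), " clusters, ", nrow(cl$clusters),
      " pass filters")

  sites <- tryCatch(find_seed_matches(cl, utrs, mirnas, flank),
                    error = function(e) stage_stop("target_id", conditionMessage(e)))
  sites <- rank_mtis(sites, validated, expression)
  say(nrow(sites), " target sites")

  profile <- tryCatch(site_conversion_profile(sites, cl$members, utrs, P),
                      error = function(e) stage_stop("stats", conditionMessage(e)))
  ttest <- suppressWarnings(region_ttest(profile))
  strat <- tryCatch(
    stratified_tests(sites, cl$members, utrs, strata = strata,
                     expression = expression, top_k = top_k, P = P),
    error = function(e) stage_stop("stats", conditionMessage(e)))

  summary_df <- data.frame(
    metric = c("reads_in", "discarded_adapter", "discarded_quality",
               "reads_surviving", "unique_sequences", "mapped_reads",
               "unmapped_reads", "clusters_total", "clusters_pass",
               "sites_reported"),
    value = c(pp$reads_in, pp$discarded_adapter, pp$discarded_quality,
              pp$reads_surviving, pp$unique_sequences,
              sum(mp$mapped$multiplicity), mp$unmapped,
              nrow(cl_all$clusters), nrow(cl$clusters), nrow(sites)),
    stringsAsFactors = FALSE)

  result <- list(summary = summary_df, mapped = mp$mapped, clusters = cl,
                 clusters_all = cl_all, sites = sites, profile = profile,
                 ttest = ttest, strata = strat)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- file.path(out_dir, c("sites.tsv", "clusters.bed", "clusters.tsv",
                                  "profile.tsv", "strata.tsv", "summary.tsv"))
    ok <- FALSE
    on.exit(if (!ok) unlink(paths), add = TRUE)
    write_site_report(sites, paths[1])
    write_cluster_bed(cl$clusters, paths[2])
    tsv <- function(x, p) utils::write.table(x, p, sep = "\t", quote = FALSE,
                                             row.names = FALSE, col.names = TRUE)
    tsv(cl$clusters, paths[3])
    tsv(as.data.frame(profile), paths[4])
    tsv(strat, paths[5])
    tsv(summary_df, paths[6])
    ok <- TRUE
  }
  result
}
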