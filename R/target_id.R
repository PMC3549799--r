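#' Scan clusters for canonical miRNA seed matches
#'
#' For each surviving cluster and each miRNA, the UTR window
#' `[span_start - flank, span_end + flank)` is scanned for the reverse
#' complement of the miRNA seed. Site types follow the canonical
#' definitions, assigned exclusively and maximally:
#' * 8mer: reverse complement of miRNA positions 2-8, followed on the mRNA
#'   by an A opposite miRNA position 1 (site = positions 1-8, 8 nt);
#' * 7mer-m8: reverse complement of positions 2-8, position-1 nucleotide
#'   not A (site = positions 2-8, 7 nt);
#' * 7mer-A1: reverse complement of positions 2-7 with an A opposite
#'   position 1, not extending to an m8 match (site = positions 1-7, 7 nt).
#'
#' Pairing is strict Watson-Crick (no G:U wobble). Target-site position 1
#' is the 3'-most nucleotide of the site on the mRNA.
#'
#' @param clustering filtered clustering from [filter_clusters()].
#' @param utrs UTR table.
#' @param mirnas miRNA table (see [read_mirna_fasta()]).
#' @param flank nt of UTR sequence beyond the cluster span to scan
#'   (default 0: the seed must lie within the span).
#' @return site table: `utr_id`, `cluster_id`, `site_start`, `site_end`
#'   (0-based half-open), `mirna_id`, `seed_match_type`, plus the cluster's
#'   `read_support` and `conversion_read_fraction`.
#' @export
find_seed_matches <- function(clustering, utrs, mirnas, flank = 0L) {
  clusters <- clustering$clusters
  empty <- data.frame(utr_id = character(), cluster_id = character(),
                      site_start = integer(), site_end = integer(),
                      mirna_id = character(), seed_match_type = character(),
                      read_support = integer(),
                      conversion_read_fraction = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(clusters) == 0L || nrow(mirnas) == 0L) return(empty)
  core6 <- revcomp(substr(mirnas$sequence, 2L, 7L))   # rc of seed 2-7
  m8c <- comp_base(substr(mirnas$sequence, 8L, 8L))   # base pairing position 8
  rows <- list()
  for (ci in seq_len(nrow(clusters))) {
    u <- match(clusters$utr_id[ci], utrs$utr_id)
    useq <- utrs$sequence[u]
    L <- nchar(useq)
    win_s <- max(0L, clusters$span_start[ci] - flank)
    win_e <- min(L, clusters$span_end[ci] + flank)
    if (win_e - win_s < 6L) next
    window <- substr(useq, win_s + 1L, win_e)
    for (mi in seq_len(nrow(mirnas))) {
      hits <- gregexpr(paste0("(?=", core6[mi], ")"), window, perl = TRUE)[[1]]
      if (hits[1] == -1L) next
      for (h in as.integer(hits)) {
        q <- win_s + h - 1L                      # 0-based core6 start on UTR
        has_m8 <- q - 1L >= 0L &&
          substr(useq, q, q) == m8c[mi]          # base at 0-based q-1
        has_a1 <- q + 6L < L &&
          substr(useq, q + 7L, q + 7L) == "A"    # base at 0-based q+6
        no_a1_base <- q + 6L >= L                # position-1 nt off the UTR end
        if (has_m8 && has_a1) {
          type <- "8mer"; s <- q - 1L; e <- q + 7L
        } else if (has_m8 && (no_a1_base || !has_a1)) {
          type <- "7mer-m8"; s <- q - 1L; e <- q + 6L
        } else if (has_a1) {
          type <- "7mer-A1"; s <- q; e <- q + 7L
        } else next
        if (e <= win_s || s >= win_e) next       # must intersect the window
        rows[[length(rows) + 1L]] <- data.frame(
          utr_id = clusters$utr_id[ci], cluster_id = clusters$cluster_id[ci],
          site_start = s, site_end = e,
          mirna_id = mirnas$mirna_id[mi], seed_match_type = type,
          read_support = clusters$read_support[ci],
          conversion_read_fraction = clusters$conversion_read_fraction[ci],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(empty)
  sites <- do.call(rbind, rows)
  sites <- sites[!duplicated(sites[c("utr_id", "cluster_id", "mirna_id",
                                     "site_start", "site_end")]), , drop = FALSE]
  sites <- sites[order(sites$utr_id, sites$site_start, sites$mirna_id), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites
}

seed_type_strength <- function(type) {
  match(type, c("8mer", "7mer-m8", "7mer-A1"))  # 1 = strongest
}

#' Rank miRNA-target interactions
#'
#' Experimentally validated interactions go on top; the remainder are
#' ordered by miRNA expression (missing treated as lowest), then seed-match
#' strength (8mer > 7mer-m8 > 7mer-A1), then cluster read support, with
#' (utr_id, site_start, mirna_id) as the deterministic tie-break. Ranks are
#' assigned 1..n with no gaps.
#'
#' @param sites site table from [find_seed_matches()].
#' @param validated optional validated-MTI table (`mirna_id`, `utr_id`) or
#'   path to one.
#' @param expression optional expression table (`mirna_id`, `expression`)
#'   or path to one.
#' @return the site table with `validated` (logical), `expression`
#'   (numeric, `NA` when unknown) and `rank` columns, sorted by rank.
#' @export
rank_mtis <- function(sites, validated = NULL, expression = NULL) {
  if (is.character(validated)) validated <- read_validated_tsv(validated)
  if (is.character(expression)) expression <- read_expression_tsv(expression)
  sites$validated <- if (!is.null(validated) && nrow(validated)) {
    paste(sites$mirna_id, sites$utr_id) %in%
      paste(validated$mirna_id, validated$utr_id)
  } else rep(FALSE, nrow(sites))
  sites$expression <- if (!is.null(expression) && nrow(expression)) {
    expression$expression[match(sites$mirna_id, expression$mirna_id)]
  } else rep(NA_real_, nrow(sites))
  expr_key <- ifelse(is.na(sites$expression), -Inf, sites$expression)
  ord <- order(-as.integer(sites$validated), -expr_key,
               seed_type_strength(sites$seed_match_type),
               -sites$read_support,
               sites$utr_id, sites$site_start, sites$mirna_id)
  sites <- sites[ord, , drop = FALSE]
  sites$rank <- seq_len(nrow(sites))
  rownames(sites) <- NULL
  sites
}
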