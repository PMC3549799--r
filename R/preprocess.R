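#' Preprocessing parameters
#'
#' Parameters for adapter trimming, 3' quality trimming and length /
#' ambiguity filtering of raw reads.
#'
#' @param adapter 3' adapter DNA string; `""` disables adapter trimming.
#' @param min_length minimum read length after trimming; shorter reads are
#'   discarded (default 15 nt).
#' @param qual_threshold phred threshold for 3'-end quality trimming:
#'   trailing bases with phred strictly below this are removed (default 20).
#' @param min_adapter_overlap minimum read/adapter overlap (nt) required to
#'   call an adapter match at the read 3' end (default 5).
#' @param max_adapter_mismatch_rate maximum fraction of mismatches allowed
#'   in the overlapping region (default 0.1).
#' @return a `preprocess_params` list.
#' @export
preprocess_params <- function(adapter = "", min_length = 15L,
                              qual_threshold = 20L,
                              min_adapter_overlap = 5L,
                              max_adapter_mismatch_rate = 0.1) {
  adapter <- toupper(adapter)
  stopifnot(min_length >= 1L, qual_threshold >= 0L, min_adapter_overlap >= 1L,
            max_adapter_mismatch_rate >= 0, max_adapter_mismatch_rate <= 1)
  structure(list(adapter = adapter, min_length = as.integer(min_length),
                 qual_threshold = as.integer(qual_threshold),
                 min_adapter_overlap = as.integer(min_adapter_overlap),
                 max_adapter_mismatch_rate = max_adapter_mismatch_rate),
            class = "preprocess_params")
}

# leftmost 0-based position where the adapter prefix matches the read
# suffix with overlap >= min_ov and mismatch rate <= max_rate; NA if none.
find_adapter_start <- function(bases, adapter, min_ov, max_rate) {
  la <- nchar(adapter)
  n <- nchar(bases)
  if (la == 0L || n < min_ov) return(NA_integer_)
  br <- charToRaw(bases)
  ar <- charToRaw(adapter)
  for (j in 0:(n - min_ov)) {
    ov <- min(la, n - j)
    mm <- sum(br[(j + 1L):(j + ov)] != ar[seq_len(ov)])
    if (mm <= max_rate * ov + 1e-9) return(j)
  }
  NA_integer_
}

#' Trim 3' adapters and filter short/ambiguous reads
#'
#' Truncates each read at the leftmost position where the adapter prefix
#' aligns to the read suffix (overlap >= `min_adapter_overlap`, mismatch
#' rate <= `max_adapter_mismatch_rate`; full internal adapter occurrences
#' are also trimmed). After trimming, reads shorter than `min_length` or
#' containing any `N` are discarded.
#'
#' @param reads reads table (see [sequenced_reads()]).
#' @param params [preprocess_params()].
#' @return list with elements `reads` (surviving, trimmed reads) and
#'   `discarded` (raw read count removed, multiplicity-weighted).
#' @export
trim_adapter <- function(reads, params = preprocess_params()) {
  n <- nrow(reads)
  if (n) {
    starts <- vapply(reads$bases, find_adapter_start, integer(1),
                     adapter = params$adapter,
                     min_ov = params$min_adapter_overlap,
                     max_rate = params$max_adapter_mismatch_rate,
                     USE.NAMES = FALSE)
    cut <- !is.na(starts)
    if (any(cut)) {
      reads$bases[cut] <- substr(reads$bases[cut], 1L, starts[cut])
      reads$quals[cut] <- Map(function(q, s) q[seq_len(s)],
                              reads$quals[cut], starts[cut])
    }
  }
  keep <- nchar(reads$bases) >= params$min_length &
    !grepl("N", reads$bases, fixed = TRUE)
  list(reads = reads[keep, , drop = FALSE],
       discarded = sum(reads$multiplicity[!keep]))
}

#' Trim low-quality 3' tails and filter short reads
#'
#' Removes trailing bases while the terminal base's phred score is strictly
#' below `qual_threshold`, then discards reads shorter than `min_length`.
#' Idempotent: the surviving tail always ends on a base at or above the
#' threshold.
#'
#' @inheritParams trim_adapter
#' @return list with elements `reads` and `discarded` as in [trim_adapter()].
#' @export
quality_trim <- function(reads, params = preprocess_params()) {
  n <- nrow(reads)
  if (n) {
    keep_len <- vapply(reads$quals, function(q) {
      len <- length(q)
      while (len > 0L && q[len] < params$qual_threshold) len <- len - 1L
      len
    }, integer(1))
    cut <- keep_len < nchar(reads$bases)
    if (any(cut)) {
      reads$bases[cut] <- substr(reads$bases[cut], 1L, keep_len[cut])
      reads$quals[cut] <- Map(function(q, s) q[seq_len(s)],
                              reads$quals[cut], keep_len[cut])
    }
  }
  keep <- nchar(reads$bases) >= params$min_length
  list(reads = reads[keep, , drop = FALSE],
       discarded = sum(reads$multiplicity[!keep]))
}

#' Collapse reads with identical sequences
#'
#' Reads sharing the same base string are merged into one record whose
#' multiplicity is the sum of the merged multiplicities; the representative
#' keeps the first-seen id and quality string. The multiplicity total is
#' conserved.
#'
#' @param reads reads table.
#' @return collapsed reads table, one row per distinct sequence, in
#'   first-seen order.
#' @export
collapse_reads <- function(reads) {
  if (nrow(reads) == 0L) return(reads)
  first <- !duplicated(reads$bases)
  grp <- match(reads$bases, reads$bases[first])
  out <- reads[first, , drop = FALSE]
  out$multiplicity <- as.integer(rowsum(reads$multiplicity, grp)[, 1])
  rownames(out) <- NULL
  out
}

#' Run the full preprocessing stage
#'
#' Adapter trimming, quality trimming and collapsing in order, with
#' per-stage discard accounting in raw-read units.
#'
#' @inheritParams trim_adapter
#' @return list with `reads` (collapsed surviving reads), and counts
#'   `reads_in`, `discarded_adapter`, `discarded_quality`,
#'   `reads_surviving`, `unique_sequences`.
#' @export
preprocess_reads <- function(reads, params = preprocess_params()) {
  reads_in <- sum(reads$multiplicity)
  a <- trim_adapter(reads, params)
  q <- quality_trim(a$reads, params)
  collapsed <- collapse_reads(q$reads)
  list(reads = collapsed,
       reads_in = reads_in,
       discarded_adapter = a$discarded,
       discarded_quality = q$discarded,
       reads_surviving = sum(q$reads$multiplicity),
       unique_sequences = nrow(collapsed))
}
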