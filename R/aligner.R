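#' Build a k-mer index over 3'UTR references
#'
#' Exhaustive forward-strand k-mer table: every length-`k` substring of
#' every UTR maps to its (UTR, offset) postings. UTRs shorter than `k` are
#' skipped with a warning.
#'
#' @param utrs UTR table (see [read_utr_fasta()]); at least one row.
#' @param k seed length, >= 8 (default 10).
#' @return a `utr_index` object.
#' @export
build_utr_index <- function(utrs, k = 10L) {
  k <- as.integer(k)
  if (is.null(utrs) || nrow(utrs) == 0L) stop("empty reference set")
  if (k < 8L) stop("seed length k must be >= 8")
  tab <- new.env(hash = TRUE, parent = emptyenv())
  n_pos <- 0L
  for (i in seq_len(nrow(utrs))) {
    s <- utrs$sequence[i]
    L <- nchar(s)
    if (L < k) {
      warning("UTR '", utrs$utr_id[i], "' shorter than k = ", k,
              "; not indexed")
      next
    }
    starts <- seq_len(L - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    sp <- split(starts - 1L, kmers)   # 0-based offsets
    for (km in names(sp)) {
      entry <- cbind(i, sp[[km]])
      cur <- tab[[km]]
      tab[[km]] <- if (is.null(cur)) entry else rbind(cur, entry)
    }
    n_pos <- n_pos + length(starts)
  }
  if (n_pos == 0L) stop("empty index: no UTR is at least k = ", k, " nt long")
  structure(list(k = k, utrs = utrs,
                 raws = lapply(utrs$sequence, charToRaw),
                 lens = nchar(utrs$sequence),
                 n_positions = n_pos, table = tab),
            class = "utr_index")
}

#' @export
print.utr_index <- function(x, ...) {
  cat("UTR k-mer index: ", nrow(x$utrs), " UTR(s), k = ", x$k, ", ",
      x$n_positions, " indexed positions\n", sep = "")
  invisible(x)
}

# empty alignment result
empty_alignments <- function() {
  df <- data.frame(utr_idx = integer(), utr_id = character(),
                   start = integer(), end = integer(),
                   n_mismatch = integer(), stringsAsFactors = FALSE)
  df$mismatch_pos <- list()
  df
}

#' Align one sequence against the UTR index
#'
#' Ungapped, substitution-only, forward-strand alignment reporting every
#' placement with at most `max_mismatch` mismatches. For reads of length
#' >= 2k a pigeonhole split (under one mismatch, one read half is exact,
#' hence its leading k-mer is indexed) generates candidates which are then
#' verified; shorter reads fall back to an exhaustive scan over all
#' offsets. Both routes are exact.
#'
#' @param seq DNA string to align.
#' @param index a [build_utr_index()] object.
#' @param max_mismatch maximum substitutions (default 1). Values > 1 force
#'   the exhaustive route.
#' @return `data.frame` with one row per placement: `utr_idx`, `utr_id`,
#'   `start`, `end` (0-based half-open), `n_mismatch`, and list column
#'   `mismatch_pos` (0-based offsets within the placement), sorted by
#'   (`utr_id`, `start`).
#' @export
align_seq <- function(seq, index, max_mismatch = 1L) {
  n <- nchar(seq)
  rr <- charToRaw(seq)
  hits_u <- integer(0); hits_s <- integer(0)
  if (n >= 2L * index$k && max_mismatch <= 1L) {
    half <- n %/% 2L
    for (off in c(0L, half)) {
      cand <- index$table[[substr(seq, off + 1L, off + index$k)]]
      if (!is.null(cand)) {
        hits_u <- c(hits_u, cand[, 1])
        hits_s <- c(hits_s, cand[, 2] - off)
      }
    }
    keep <- hits_s >= 0L & hits_s + n <= index$lens[hits_u]
    hits_u <- hits_u[keep]; hits_s <- hits_s[keep]
    if (length(hits_u)) {
      dup <- duplicated(cbind(hits_u, hits_s))
      hits_u <- hits_u[!dup]; hits_s <- hits_s[!dup]
    }
  } else {
    for (i in seq_along(index$raws)) {
      sr <- index$raws[[i]]
      L <- length(sr)
      if (L < n) next
      m <- integer(L - n + 1L)
      for (p in seq_len(n)) m <- m + (sr[p:(p + L - n)] != rr[p])
      ok <- which(m <= max_mismatch)
      hits_u <- c(hits_u, rep.int(i, length(ok)))
      hits_s <- c(hits_s, ok - 1L)
    }
  }
  if (!length(hits_u)) return(empty_alignments())
  mmpos <- vector("list", length(hits_u))
  nmm <- integer(length(hits_u))
  keep <- logical(length(hits_u))
  for (j in seq_along(hits_u)) {
    sr <- index$raws[[hits_u[j]]]
    d <- which(sr[(hits_s[j] + 1L):(hits_s[j] + n)] != rr) - 1L
    nmm[j] <- length(d)
    keep[j] <- length(d) <= max_mismatch
    mmpos[[j]] <- d
  }
  hits_u <- hits_u[keep]; hits_s <- hits_s[keep]
  nmm <- nmm[keep]; mmpos <- mmpos[keep]
  if (!length(hits_u)) return(empty_alignments())
  out <- data.frame(utr_idx = hits_u,
                    utr_id = index$utrs$utr_id[hits_u],
                    start = hits_s, end = hits_s + n,
                    n_mismatch = nmm, stringsAsFactors = FALSE)
  out$mismatch_pos <- mmpos
  ord <- order(out$utr_id, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
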