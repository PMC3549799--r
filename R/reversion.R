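#' Expand a read into its single-C-to-T reverted variants
#'
#' PAR-CLIP crosslinking leaves T-to-C substitutions in reads, which break
#' alignment under a small mismatch budget. For each cytidine in the read,
#' one variant is generated with exactly that C reverted to T; the
#' unmodified read comes first. All variants are then aligned, so a read
#' carrying one conversion regains an exact (or one-mismatch) placement.
#' A read with c cytidines yields 1 + c sequences.
#'
#' @param bases a single DNA string.
#' @return `data.frame` with columns `bases` (variant sequence) and
#'   `reverted_position` (0-based index of the reverted C; `NA` for the
#'   original read), original first, then variants in left-to-right C order.
#' @export
#' @examples
#' expand_c_to_t("AATGCTCAATGGCGA")$bases
expand_c_to_t <- function(bases) {
  stopifnot(length(bases) == 1L)
  cpos <- which(strsplit(bases, "", fixed = TRUE)[[1]] == "C")
  variants <- vapply(cpos, function(p) {
    v <- bases
    substr(v, p, p) <- "T"
    v
  }, character(1))
  data.frame(bases = c(bases, variants),
             reverted_position = c(NA_integer_, cpos - 1L),
             stringsAsFactors = FALSE)
}

# evaluate the ORIGINAL read bases against the reference at a placement:
# conversions = read C over reference T; mismatches = remaining diffs.
evaluate_placement <- function(read_raw, ref_raw, start) {
  n <- length(read_raw)
  ref <- ref_raw[(start + 1L):(start + n)]
  d <- which(ref != read_raw)
  conv <- d[read_raw[d] == as.raw(67L) & ref[d] == as.raw(84L)]  # C over T
  list(mismatch_pos = setdiff(d, conv) - 1L, conversion_pos = conv - 1L)
}

# empty mapped-reads table
empty_mapped <- function() {
  df <- data.frame(read_id = character(), multiplicity = integer(),
                   utr_id = character(), start = integer(), end = integer(),
                   n_mismatch = integer(), n_conversion = integer(),
                   stringsAsFactors = FALSE)
  df$mismatch_pos <- list()
  df$conversion_pos <- list()
  df
}

# choose one placement for a read from candidate (utr_idx, start) pairs:
# fewest true mismatches, then most conversions, then smallest
# (utr_id, start). Returns a one-row mapped table or NULL.
reconcile_placements <- function(read, index, cand_u, cand_s, max_mismatch) {
  if (!length(cand_u)) return(NULL)
  rr <- charToRaw(read$bases)
  evals <- vector("list", length(cand_u))
  nmm <- integer(length(cand_u))
  ncv <- integer(length(cand_u))
  for (j in seq_along(cand_u)) {
    ev <- evaluate_placement(rr, index$raws[[cand_u[j]]], cand_s[j])
    evals[[j]] <- ev
    nmm[j] <- length(ev$mismatch_pos)
    ncv[j] <- length(ev$conversion_pos)
  }
  ok <- which(nmm <= max_mismatch)
  if (!length(ok)) return(NULL)
  ord <- ok[order(nmm[ok], -ncv[ok], index$utrs$utr_id[cand_u[ok]], cand_s[ok])]
  best <- ord[1]
  out <- data.frame(read_id = read$read_id,
                    multiplicity = read$multiplicity,
                    utr_id = index$utrs$utr_id[cand_u[best]],
                    start = cand_s[best],
                    end = cand_s[best] + nchar(read$bases),
                    n_mismatch = nmm[best], n_conversion = ncv[best],
                    stringsAsFactors = FALSE)
  out$mismatch_pos <- list(evals[[best]]$mismatch_pos)
  out$conversion_pos <- list(evals[[best]]$conversion_pos)
  out
}

# map one read in PAR-CLIP mode: align the original and every single-C
# revert, pool candidate placements, re-evaluate the original read there.
map_read_parclip <- function(read, index, max_mismatch = 1L) {
  variants <- expand_c_to_t(read$bases)
  cand_u <- integer(0); cand_s <- integer(0)
  for (v in variants$bases) {
    hits <- align_seq(v, index, max_mismatch)
    cand_u <- c(cand_u, hits$utr_idx)
    cand_s <- c(cand_s, hits$start)
  }
  if (length(cand_u)) {
    dup <- duplicated(cbind(cand_u, cand_s))
    cand_u <- cand_u[!dup]; cand_s <- cand_s[!dup]
  }
  reconcile_placements(read, index, cand_u, cand_s, max_mismatch)
}

# map one read in CLIP mode: conversions are not called (no 4SU signature).
map_read_clip <- function(read, index, max_mismatch = 1L) {
  hits <- align_seq(read$bases, index, max_mismatch)
  if (nrow(hits) == 0L) return(NULL)
  ord <- order(hits$n_mismatch, hits$utr_id, hits$start)
  best <- hits[ord[1], ]
  out <- data.frame(read_id = read$read_id,
                    multiplicity = read$multiplicity,
                    utr_id = best$utr_id, start = best$start, end = best$end,
                    n_mismatch = best$n_mismatch, n_conversion = 0L,
                    stringsAsFactors = FALSE)
  out$mismatch_pos <- best$mismatch_pos
  out$conversion_pos <- list(integer(0))
  out
}

#' Map preprocessed reads to the 3'UTR references
#'
#' In PAR-CLIP mode each read is expanded by [expand_c_to_t()], all
#' variants are aligned with at most `max_mismatch` substitutions, and the
#' candidate placements are reconciled back to the original read: at the
#' chosen locus, every read-C-over-reference-T difference is recorded as a
#' T-to-C conversion (even one absorbed by the mismatch allowance) and only
#' the remaining differences count as mismatches. Placement choice is
#' deterministic: fewest true mismatches, then most conversions, then
#' smallest (utr_id, offset). In CLIP mode the original read is aligned
#' directly and no conversions are called.
#'
#' @param reads collapsed reads table.
#' @param index a [build_utr_index()] object.
#' @param mode `"parclip"` or `"clip"`.
#' @param max_mismatch maximum true mismatches per placement (default 1).
#' @param workers number of deterministic mapping chunks; results are
#'   identical for any value (fixed merge order).
#' @return list with `mapped` (one row per mapped read: placement,
#'   `mismatch_pos` / `conversion_pos` as 0-based offsets within the
#'   placement) and `unmapped` (multiplicity-weighted count).
#' @export
map_reads <- function(reads, index, mode = c("parclip", "clip"),
                      max_mismatch = 1L, workers = 1L) {
  mode <- match.arg(mode)
  n <- nrow(reads)
  if (n == 0L) return(list(mapped = empty_mapped(), unmapped = 0L))
  workers <- max(1L, as.integer(workers))
  chunks <- split(seq_len(n), ceiling(seq_len(n) / ceiling(n / workers)))
  map_one <- if (mode == "parclip") map_read_parclip else map_read_clip
  parts <- lapply(chunks, function(idx) {
    rows <- lapply(idx, function(i) map_one(reads[i, , drop = FALSE],
                                            index, max_mismatch))
    rows[!vapply(rows, is.null, logical(1))]
  })
  rows <- do.call(c, parts)
  mapped <- if (length(rows)) do.call(rbind, rows) else empty_mapped()
  rownames(mapped) <- NULL
  list(mapped = mapped,
       unmapped = sum(reads$multiplicity) - sum(mapped$multiplicity))
}
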