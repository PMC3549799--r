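# quick read constructor: uniform phred 40 unless given
make_reads <- function(bases, quals = NULL, ids = NULL, multiplicity = 1L) {
  if (is.null(ids)) ids <- sprintf("r%d", seq_along(bases))
  if (is.null(quals)) quals <- lapply(nchar(bases), function(n) rep(40L, n))
  sequenced_reads(ids, bases, quals, multiplicity)
}

# random DNA string, independent of the package's generator
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# independent alignment oracle: exhaustive substitution-only matching via
# Biostrings, per UTR; returns data.frame(utr_id, start) 0-based
oracle_align <- function(seq, utrs, max_mismatch = 1L) {
  out <- list()
  for (i in seq_len(nrow(utrs))) {
    if (nchar(utrs$sequence[i]) < nchar(seq)) next
    m <- Biostrings::matchPattern(seq, Biostrings::DNAString(utrs$sequence[i]),
                                  max.mismatch = max_mismatch,
                                  with.indels = FALSE)
    if (length(m))
      out[[length(out) + 1L]] <- data.frame(utr_id = utrs$utr_id[i],
                                            start = Biostrings::start(m) - 1L,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(utr_id = character(), start = integer(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$utr_id, res$start), , drop = FALSE]
}

# build a mapped-reads table directly (bypassing the aligner) for cluster
# and site tests; conversion_pos are read-relative 0-based offsets
make_mapped <- function(utr_id, start, end, conversion_pos = NULL,
                        multiplicity = 1L, ids = NULL) {
  n <- length(start)
  if (is.null(ids)) ids <- sprintf("m%d", seq_len(n))
  if (is.null(conversion_pos)) conversion_pos <- rep(list(integer(0)), n)
  df <- data.frame(read_id = ids,
                   multiplicity = as.integer(rep_len(multiplicity, n)),
                   utr_id = rep_len(utr_id, n),
                   start = as.integer(start), end = as.integer(end),
                   n_mismatch = 0L,
                   n_conversion = lengths(conversion_pos),
                   stringsAsFactors = FALSE)
  df$mismatch_pos <- rep(list(integer(0)), n)
  df$conversion_pos <- lapply(conversion_pos, as.integer)
  df
}

# small, fast simulation configs for unit tests; later arguments override
sim_config_with <- function(base, ...) {
  do.call(sim_config, utils::modifyList(base, list(...)))
}

small_sim_config <- function(seed = 11L, ...) {
  sim_config_with(list(seed = seed, n_utrs = 6L, n_sites_per_utr = 1L,
                       background_read_count = 40L), ...)
}

noiseless_sim_config <- function(seed = 5L, ...) {
  sim_config_with(list(seed = seed, n_utrs = 6L, n_sites_per_utr = 1L,
                       background_read_count = 40L,
                       conv_prob_seed_region = 0,
                       conv_prob_effector_region = 0,
                       conv_prob_background = 0, seq_error_rate = 0,
                       adapter_readthrough_fraction = 0,
                       qual_decay = list(q_start = 38, q_end = 30, sd = 0,
                                         bad_tail_prob = 0,
                                         bad_tail_len = 1L)), ...)
}

# a miRNA whose seed gives the classic site motifs:
# seed 2-8 = AAGGCAC, reverse complement GTGCCTT; 8mer site = GTGCCTTA
mirna_fix <- data.frame(mirna_id = "mir-x", sequence = "TAAGGCACGCGGTGAATGCC",
                        expression = NA_real_, stringsAsFactors = FALSE)

# wrap a UTR with one passing cluster spanning the whole sequence
cluster_over <- function(useq, utr_id = "u1") {
  utr <- data.frame(utr_id = utr_id, sequence = useq, conserved = NA,
                    stringsAsFactors = FALSE)
  m <- make_mapped(utr_id, rep(0L, 5), rep(nchar(useq), 5),
                   conversion_pos = rep(list(0L), 5))
  list(utr = utr, clustering = filter_clusters(build_clusters(m)))
}
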