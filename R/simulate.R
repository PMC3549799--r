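#' Configuration for the synthetic PAR-CLIP generator
#'
#' Defaults describe a small but realistic PAR-CLIP experiment on random
#' 3'UTRs: seed-complementary sites implanted at known coordinates, reads
#' piled over each site with position-dependent T-to-C conversion
#' (concentrated at site positions 8-14, the crosslink-enriched effector
#' region), uniform sequencing error, 3' adapter read-through, decaying
#' quality strings, and background reads sampled uniformly from the UTRs.
#'
#' @param seed RNG seed; identical configurations produce byte-identical
#'   outputs.
#' @param n_utrs number of random UTRs.
#' @param utr_length_range min/max UTR length (nt).
#' @param gc_fraction GC content of random sequence.
#' @param n_mirnas number of random miRNAs (unique positions 2-8).
#' @param mirna_length mature miRNA length (nt).
#' @param n_sites_per_utr implanted sites per UTR.
#' @param site_type_mix named probabilities over `8mer`, `7mer-m8`,
#'   `7mer-A1`.
#' @param conserved_fraction fraction of UTRs flagged conserved.
#' @param validated_fraction fraction of implanted (miRNA, UTR) pairs
#'   emitted as experimentally validated interactions.
#' @param reads_per_site_range min/max reads per implanted site.
#' @param background_read_count reads sampled uniformly from the UTRs.
#' @param read_length_range min/max read length (nt, >= 15).
#' @param conv_prob_seed_region per-T conversion probability at site
#'   positions 1-7 (default 0.05).
#' @param conv_prob_effector_region per-T conversion probability at site
#'   positions 8-14 (default 0.40).
#' @param conv_prob_background per-T conversion probability elsewhere
#'   (default 0.02).
#' @param seq_error_rate uniform per-base sequencing error (default 0.001).
#' @param adapter 3' adapter sequence appended on read-through.
#' @param adapter_readthrough_fraction fraction of reads running into the
#'   adapter.
#' @param qual_decay list: `q_start`/`q_end` mean phred at the 5'/3' read
#'   end, `sd` phred noise, `bad_tail_prob` probability of a low-quality
#'   tail, `bad_tail_len` its maximum length.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_utrs = 30L,
                       utr_length_range = c(400L, 800L),
                       gc_fraction = 0.5,
                       n_mirnas = 10L,
                       mirna_length = 22L,
                       n_sites_per_utr = 2L,
                       site_type_mix = c("8mer" = 0.4, "7mer-m8" = 0.3,
                                         "7mer-A1" = 0.3),
                       conserved_fraction = 0.5,
                       validated_fraction = 0.2,
                       reads_per_site_range = c(10L, 30L),
                       background_read_count = 200L,
                       read_length_range = c(20L, 32L),
                       conv_prob_seed_region = 0.05,
                       conv_prob_effector_region = 0.40,
                       conv_prob_background = 0.02,
                       seq_error_rate = 0.001,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       adapter_readthrough_fraction = 0.3,
                       qual_decay = list(q_start = 38, q_end = 30, sd = 3,
                                         bad_tail_prob = 0.1,
                                         bad_tail_len = 3L)) {
  probs <- c(site_type_mix, conserved_fraction, validated_fraction,
             conv_prob_seed_region, conv_prob_effector_region,
             conv_prob_background, seq_error_rate,
             adapter_readthrough_fraction)
  stopifnot(all(probs >= 0 & probs <= 1),
            abs(sum(site_type_mix) - 1) < 1e-8,
            utr_length_range[1] <= utr_length_range[2],
            reads_per_site_range[1] <= reads_per_site_range[2],
            read_length_range[1] >= 15L,
            read_length_range[1] <= read_length_range[2],
            mirna_length >= 8L)
  structure(list(seed = as.integer(seed), n_utrs = as.integer(n_utrs),
                 utr_length_range = as.integer(utr_length_range),
                 gc_fraction = gc_fraction, n_mirnas = as.integer(n_mirnas),
                 mirna_length = as.integer(mirna_length),
                 n_sites_per_utr = as.integer(n_sites_per_utr),
                 site_type_mix = site_type_mix,
                 conserved_fraction = conserved_fraction,
                 validated_fraction = validated_fraction,
                 reads_per_site_range = as.integer(reads_per_site_range),
                 background_read_count = as.integer(background_read_count),
                 read_length_range = as.integer(read_length_range),
                 conv_prob_seed_region = conv_prob_seed_region,
                 conv_prob_effector_region = conv_prob_effector_region,
                 conv_prob_background = conv_prob_background,
                 seq_error_rate = seq_error_rate,
                 adapter = toupper(adapter),
                 adapter_readthrough_fraction = adapter_readthrough_fraction,
                 qual_decay = qual_decay),
            class = "sim_config")
}

# uniform integer draw on [lo, hi], safe for lo == hi
sample_range <- function(lo, hi) {
  if (hi <= lo) return(as.integer(lo))
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

random_dna <- function(n, gc) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# the 8-nt block written into the UTR for one site; controls the type
# exactly: position-1 base and the m8-pairing base are fixed so a random
# neighbour cannot upgrade or downgrade the match type.
site_block <- function(mirna_seq, type) {
  core6 <- revcomp(substr(mirna_seq, 2L, 7L))
  m8c <- comp_base(substr(mirna_seq, 8L, 8L))
  not_m8c <- sample(setdiff(c("A", "C", "G", "T"), m8c), 1L)
  switch(type,
         "8mer" = paste0(m8c, core6, "A"),
         "7mer-m8" = paste0(m8c, core6, sample(c("C", "G", "T"), 1L)),
         "7mer-A1" = paste0(not_m8c, core6, "A"),
         stop("unknown site type: ", type))
}

#' Generate synthetic 3'UTR and miRNA references with implanted sites
#'
#' Random UTRs at the configured GC content; random miRNAs with unique
#' seed regions; seed-complementary site motifs written at non-overlapping
#' positions (each site's 0-based position-1 coordinate is at least 14 so
#' the full 1-14 profile lies on the UTR); per-UTR conservation flags; a
#' log-normal miRNA expression table; and a validated-MTI table drawn from
#' the implanted pairs.
#'
#' @param config a [sim_config()].
#' @return list with `utrs`, `mirnas`, `expression`, `validated`, and the
#'   ground-truth `sites` table (`utr_id`, `mirna_id`, `type`,
#'   `block_start`, `site_start`, `site_end` 0-based half-open, `p1`
#'   0-based coordinate of the position-1 nucleotide, `conserved`).
#' @export
simulate_references <- function(config = sim_config()) {
  set.seed(config$seed)
  # miRNAs with unique positions 2-8 so site attribution is unambiguous
  mir_seqs <- character(0)
  while (length(mir_seqs) < config$n_mirnas) {
    s <- random_dna(config$mirna_length, 0.5)
    if (!substr(s, 2L, 8L) %in% substr(mir_seqs, 2L, 8L))
      mir_seqs <- c(mir_seqs, s)
  }
  mirnas <- data.frame(mirna_id = sprintf("mir-%03d", seq_len(config$n_mirnas)),
                       sequence = mir_seqs,
                       expression = round(stats::rlnorm(config$n_mirnas,
                                                        meanlog = 3, sdlog = 1.2), 3),
                       stringsAsFactors = FALSE)
  lens <- sample(seq(config$utr_length_range[1], config$utr_length_range[2]),
                 config$n_utrs, replace = TRUE)
  utrs <- data.frame(utr_id = sprintf("utr%03d", seq_len(config$n_utrs)),
                     sequence = vapply(lens, random_dna, character(1),
                                       gc = config$gc_fraction),
                     conserved = stats::runif(config$n_utrs) < config$conserved_fraction,
                     stringsAsFactors = FALSE)
  sites <- list()
  for (u in seq_len(config$n_utrs)) {
    L <- lens[u]
    taken <- integer(0)   # block starts already used
    for (s in seq_len(config$n_sites_per_utr)) {
      mi <- sample.int(config$n_mirnas, 1L)
      type <- sample(names(config$site_type_mix), 1L,
                     prob = config$site_type_mix)
      lo <- 14L
      hi <- L - 8L
      placed <- FALSE
      for (try in seq_len(200L)) {
        q <- sample_range(lo, hi)
        if (all(abs(q - taken) >= 30L)) { placed <- TRUE; break }
      }
      if (!placed)
        stop("infeasible site packing: UTR '", utrs$utr_id[u],
             "' too short for ", config$n_sites_per_utr, " sites")
      block <- site_block(mirnas$sequence[mi], type)
      substr(utrs$sequence[u], q + 1L, q + 8L) <- block
      taken <- c(taken, q)
      site_start <- switch(type, "8mer" = q, "7mer-m8" = q, "7mer-A1" = q + 1L)
      site_end <- switch(type, "8mer" = q + 8L, "7mer-m8" = q + 7L,
                         "7mer-A1" = q + 8L)
      sites[[length(sites) + 1L]] <- data.frame(
        utr_id = utrs$utr_id[u], mirna_id = mirnas$mirna_id[mi],
        type = type, block_start = q,
        site_start = site_start, site_end = site_end, p1 = q + 7L,
        conserved = utrs$conserved[u], stringsAsFactors = FALSE)
    }
  }
  truth_sites <- if (length(sites)) do.call(rbind, sites) else
    data.frame(utr_id = character(), mirna_id = character(),
               type = character(), block_start = integer(),
               site_start = integer(), site_end = integer(), p1 = integer(),
               conserved = logical(), stringsAsFactors = FALSE)
  validated <- truth_sites[stats::runif(nrow(truth_sites)) <
                             config$validated_fraction,
                           c("mirna_id", "utr_id"), drop = FALSE]
  validated <- validated[!duplicated(validated), , drop = FALSE]
  rownames(validated) <- NULL
  list(utrs = utrs, mirnas = mirnas,
       expression = mirnas[, c("mirna_id", "expression")],
       validated = validated, sites = truth_sites)
}

#' Simulate PAR-CLIP reads over the synthetic references
#'
#' For each implanted site, reads are drawn whose spans cover the site
#' interval with jittered starts. Each covered reference T is
#' converted to C independently with the position-dependent probability
#' (effector positions 8-14, seed positions 1-7, background elsewhere);
#' injected conversions are recorded in the read truth table before
#' sequencing error is applied. A fraction of reads runs through into the
#' 3' adapter; phred strings decay toward the 3' end with occasional
#' low-quality tails. Background reads are sampled uniformly from the
#' UTRs.
#'
#' @param config a [sim_config()].
#' @param refs result of [simulate_references()] for the same config.
#' @return list with `reads` (FASTQ-ready reads table) and `read_truth`
#'   (`read_id`, `utr_id`, `insert_start`, `insert_end`, `origin`
#'   (site row index or 0 for background), `conversions` list column of
#'   0-based UTR coordinates).
#' @export
simulate_reads <- function(config = sim_config(), refs = simulate_references(config)) {
  set.seed(config$seed + 1L)
  utrs <- refs$utrs
  lens <- nchar(utrs$sequence)
  # per-UTR, per-position conversion rate vectors
  rate <- lapply(lens, function(L) rep(config$conv_prob_background, L))
  if (nrow(refs$sites)) {
    for (si in seq_len(nrow(refs$sites))) {
      u <- match(refs$sites$utr_id[si], utrs$utr_id)
      p1 <- refs$sites$p1[si]
      rate[[u]][(p1 - 6L):p1 + 1L] <- config$conv_prob_seed_region
      rate[[u]][(p1 - 13L):(p1 - 7L) + 1L] <- config$conv_prob_effector_region
    }
  }
  ids <- character(0); bases <- character(0); quals <- list()
  t_utr <- character(0); t_start <- integer(0); t_end <- integer(0)
  t_origin <- integer(0); t_conv <- list()
  counter <- 0L
  emit_read <- function(u, start, rl, origin) {
    counter <<- counter + 1L
    L <- lens[u]
    ref <- substr(utrs$sequence[u], start + 1L, start + rl)
    chars <- strsplit(ref, "", fixed = TRUE)[[1]]
    # T-to-C conversion at the positional rate
    tpos <- which(chars == "T")
    conv <- tpos[stats::runif(length(tpos)) <
                   rate[[u]][start + tpos]]
    chars[conv] <- "C"
    # uniform sequencing error
    err <- which(stats::runif(rl) < config$seq_error_rate)
    for (e in err)
      chars[e] <- sample(setdiff(c("A", "C", "G", "T"), chars[e]), 1L)
    out <- paste(chars, collapse = "")
    # 3' adapter read-through
    if (stats::runif(1) < config$adapter_readthrough_fraction)
      out <- paste0(out, config$adapter)
    n_out <- nchar(out)
    qd <- config$qual_decay
    q <- round(seq(qd$q_start, qd$q_end, length.out = n_out) +
                 stats::rnorm(n_out, 0, qd$sd))
    if (stats::runif(1) < qd$bad_tail_prob) {
      nb <- sample.int(qd$bad_tail_len, 1L)
      q[(n_out - nb + 1L):n_out] <- sample(2:19, nb, replace = TRUE)
    }
    q <- pmin(pmax(q, 2L), 41L)
    ids[counter] <<- sprintf("sim_%06d", counter)
    bases[counter] <<- out
    quals[[counter]] <<- as.integer(q)
    t_utr[counter] <<- utrs$utr_id[u]
    t_start[counter] <<- start
    t_end[counter] <<- start + rl
    t_origin[counter] <<- origin
    t_conv[[counter]] <<- as.integer(start + conv - 1L)   # 0-based UTR coords
  }
  if (nrow(refs$sites)) {
    for (si in seq_len(nrow(refs$sites))) {
      u <- match(refs$sites$utr_id[si], utrs$utr_id)
      p1 <- refs$sites$p1[si]
      n_r <- sample_range(config$reads_per_site_range[1],
                          config$reads_per_site_range[2])
      for (r in seq_len(n_r)) {
        rl <- sample_range(config$read_length_range[1],
                           config$read_length_range[2])
        # read span covers the site interval, start jittered
        lo <- max(0L, refs$sites$site_end[si] - rl)
        hi <- min(refs$sites$site_start[si], lens[u] - rl)
        start <- sample_range(lo, hi)
        emit_read(u, start, rl, si)
      }
    }
  }
  for (b in seq_len(config$background_read_count)) {
    rl <- sample_range(config$read_length_range[1],
                       config$read_length_range[2])
    u <- sample.int(nrow(utrs), 1L, prob = lens)
    start <- sample.int(lens[u] - rl + 1L, 1L) - 1L
    emit_read(u, start, rl, 0L)
  }
  reads <- sequenced_reads(ids, bases, quals)
  truth <- data.frame(read_id = ids, utr_id = t_utr,
                      insert_start = t_start, insert_end = t_end,
                      origin = t_origin, stringsAsFactors = FALSE)
  truth$conversions <- t_conv
  list(reads = reads, read_truth = truth)
}

#' Generate a complete synthetic PAR-CLIP dataset
#'
#' Runs [simulate_references()] and [simulate_reads()] and, when `out_dir`
#' is given, writes `reads.fastq`, `utrs.fa`, `mirnas.fa`,
#' `conservation.tsv`, `expression.tsv`, `validated.tsv`,
#' `truth_sites.tsv` and `truth_reads.tsv`. Outputs are byte-identical for
#' identical configurations.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory.
#' @return list with `config`, `utrs`, `mirnas`, `expression`,
#'   `validated`, `sites` (truth), `reads`, `read_truth`.
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  refs <- simulate_references(config)
  rd <- simulate_reads(config, refs)
  out <- c(list(config = config), refs, rd)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fastq(rd$reads, file.path(out_dir, "reads.fastq"))
    write_fasta(refs$utrs$utr_id, refs$utrs$sequence,
                file.path(out_dir, "utrs.fa"))
    write_fasta(refs$mirnas$mirna_id, refs$mirnas$sequence,
                file.path(out_dir, "mirnas.fa"))
    tsv <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = TRUE)
    tsv(data.frame(utr_id = refs$utrs$utr_id,
                   conserved = as.integer(refs$utrs$conserved)),
        "conservation.tsv")
    tsv(refs$expression, "expression.tsv")
    tsv(refs$validated, "validated.tsv")
    tsv(refs$sites, "truth_sites.tsv")
    rt <- rd$read_truth
    rt$conversions <- vapply(rt$conversions, paste, character(1), collapse = ";")
    tsv(rt, "truth_reads.tsv")
  }
  invisible(out)
}

#' Simulate a pooled conversion profile at the site level
#'
#' Draws the per-position pooled counts of a conversion profile directly
#' from the generative model (each site has a T at a given position with
#' probability `t_prob`; covering reads per site are uniform on
#' `reads_per_site_range`; converted reads are binomial at the regional
#' rate). Used for t-test calibration and power experiments where
#' replicating the full read-level pipeline would be needlessly slow.
#'
#' @param n_sites number of pooled sites.
#' @param reads_per_site_range min/max covering reads per site.
#' @param t_prob probability a site position is a reference T (0.25 at
#'   GC 0.5).
#' @param rate_seed conversion rate at positions 1-7.
#' @param rate_effector conversion rate at positions 8-14; equal rates
#'   give the null.
#' @param P number of positions.
#' @return a [conversion_profile()].
#' @export
simulate_region_profile <- function(n_sites = 60L,
                                    reads_per_site_range = c(10L, 30L),
                                    t_prob = 0.25,
                                    rate_seed = 0.05,
                                    rate_effector = 0.40,
                                    P = 14L) {
  rates <- c(rep(rate_seed, 7L), rep(rate_effector, P - 7L))
  covering <- integer(P)
  converted <- integer(P)
  for (k in seq_len(P)) {
    has_t <- stats::runif(n_sites) < t_prob
    rps <- reads_per_site_range[1] +
      sample.int(reads_per_site_range[2] - reads_per_site_range[1] + 1L,
                 n_sites, replace = TRUE) - 1L
    depth <- sum(rps[has_t])
    covering[k] <- depth
    converted[k] <- stats::rbinom(1L, depth, rates[k])
  }
  conversion_profile(converted, covering)
}
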