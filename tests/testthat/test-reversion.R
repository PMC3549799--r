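test_that("single-C reversion expands a read into 1 + #C variants", {
  v <- expand_c_to_t("AATGCTCAATGGCGA")
  expect_equal(v$bases, c("AATGCTCAATGGCGA",
                          "AATGTTCAATGGCGA",
                          "AATGCTTAATGGCGA",
                          "AATGCTCAATGGTGA"))
  expect_equal(v$reverted_position, c(NA, 4L, 6L, 12L))
  expect_equal(nrow(expand_c_to_t("AAAA")), 1L)      # no C: original only
  v <- expand_c_to_t("CCCC")
  expect_equal(nrow(v), 5L)
  for (i in 2:5) {
    d <- which(strsplit(v$bases[i], "")[[1]] != strsplit("CCCC", "")[[1]])
    expect_equal(d, i - 1L)                          # exactly one position
    expect_equal(substr(v$bases[i], d, d), "T")      # and it is C -> T
  }
})

test_that("variant count identity holds on random reads", {
  set.seed(21)
  for (i in 1:50) {
    b <- rand_dna(sample(15:36, 1))
    v <- expand_c_to_t(b)
    n_c <- lengths(regmatches(b, gregexpr("C", b, fixed = TRUE)))
    expect_equal(nrow(v), 1L + n_c)
    expect_equal(v$bases[1], b)
    # every variant differs from the parent at exactly its reverted C
    if (nrow(v) > 1) {
      pb <- strsplit(b, "")[[1]]
      for (j in 2:nrow(v)) {
        vb <- strsplit(v$bases[j], "")[[1]]
        d <- which(vb != pb)
        expect_equal(d - 1L, v$reverted_position[j])
        expect_equal(pb[d], "C")
        expect_equal(vb[d], "T")
      }
    }
  }
})

test_that("reversion recovers reads whose only differences are conversions", {
  set.seed(31)
  utr <- data.frame(utr_id = "u1", sequence = rand_dna(300), conserved = NA,
                    stringsAsFactors = FALSE)
  idx <- build_utr_index(utr)
  start <- 100L
  frag <- substr(utr$sequence, start + 1L, start + 24L)
  tpos <- which(strsplit(frag, "")[[1]] == "T")
  expect_gte(length(tpos), 3L)  # fixture sanity
  put_c <- function(s, at) { for (p in at) substr(s, p, p) <- "C"; s }

  # k conversions, k <= 2: mappable; conversions called at the right spots
  for (k in 1:2) {
    read <- make_reads(put_c(frag, tpos[seq_len(k)]))
    mp <- map_reads(read, idx, "parclip")
    expect_equal(nrow(mp$mapped), 1L)
    expect_equal(mp$mapped$start, start)
    expect_equal(mp$mapped$conversion_pos[[1]], tpos[seq_len(k)] - 1L)
    expect_equal(mp$mapped$mismatch_pos[[1]], integer(0))
    expect_equal(mp$mapped$n_mismatch, 0L)
  }
  # three conversions exceed the one-revert + one-mismatch budget
  mp <- map_reads(make_reads(put_c(frag, tpos[1:3])), idx, "parclip")
  expect_equal(nrow(mp$mapped), 0L)
  expect_equal(mp$unmapped, 1L)
  # one conversion plus one ordinary mismatch: mapped, kept separate
  read1 <- put_c(frag, tpos[1])
  apos <- setdiff(which(strsplit(frag, "")[[1]] == "A"), tpos)[1]
  substr(read1, apos, apos) <- "G"
  mp <- map_reads(make_reads(read1), idx, "parclip")
  expect_equal(mp$mapped$conversion_pos[[1]], tpos[1] - 1L)
  expect_equal(mp$mapped$mismatch_pos[[1]], apos - 1L)
  # conversion and mismatch position sets never intersect
  expect_length(intersect(mp$mapped$conversion_pos[[1]],
                          mp$mapped$mismatch_pos[[1]]), 0L)
})

test_that("a conversion absorbed by the mismatch allowance is still counted", {
  set.seed(8)
  utr <- data.frame(utr_id = "u1", sequence = rand_dna(200), conserved = NA,
                    stringsAsFactors = FALSE)
  idx <- build_utr_index(utr)
  frag <- substr(utr$sequence, 51, 74)
  tp <- which(strsplit(frag, "")[[1]] == "T")[1]
  substr(frag, tp, tp) <- "C"
  # the original aligns within one mismatch, so no reversion is needed --
  # the C-over-T difference must still be reported as a conversion
  mp <- map_reads(make_reads(frag), idx, "parclip")
  expect_equal(mp$mapped$n_conversion, 1L)
  expect_equal(mp$mapped$n_mismatch, 0L)
})

test_that("equally good placements tie-break on smallest (utr_id, offset)", {
  seqA <- rand_dna(60)
  frag <- substr(seqA, 11, 34)
  utrs <- data.frame(utr_id = c("b_utr", "a_utr"),
                     sequence = c(seqA, paste0(rand_dna(40), frag)),
                     conserved = NA, stringsAsFactors = FALSE)
  idx <- build_utr_index(utrs)
  mp <- map_reads(make_reads(frag), idx, "parclip")
  expect_equal(mp$mapped$utr_id, "a_utr")   # lexicographic, not input order
  # two loci on one UTR: smaller offset wins
  utr2 <- data.frame(utr_id = "u", sequence = paste0(frag, rand_dna(30), frag),
                     conserved = NA, stringsAsFactors = FALSE)
  mp <- map_reads(make_reads(frag), build_utr_index(utr2), "parclip")
  expect_equal(mp$mapped$start, 0L)
})

test_that("placement selection prefers fewer mismatches, then more conversions", {
  # reference with two candidate loci: at locus 1 the read has one true
  # mismatch; at locus 2 the read's difference is C over T (a conversion)
  base <- "ACGGATCGGAGCAATGCAGGTCAG"  # 24 nt, no T at position 5, T at 17
  loc1 <- base
  substr(loc1, 5, 5) <- "G"   # read A over ref G -> true mismatch
  loc2 <- base
  substr(loc2, 17, 17) <- "T" # read C over ref T -> conversion
  read <- base
  substr(read, 17, 17) <- "C"
  # place loc variants far apart in one UTR
  utr <- data.frame(utr_id = "u",
                    sequence = paste0(loc1, "GGGGGGGGGG", loc2),
                    conserved = NA, stringsAsFactors = FALSE)
  mp <- map_reads(make_reads(read), build_utr_index(utr), "parclip")
  expect_equal(mp$mapped$start, 34L)         # the conversion locus
  expect_equal(mp$mapped$n_mismatch, 0L)
  expect_equal(mp$mapped$n_conversion, 1L)
})
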