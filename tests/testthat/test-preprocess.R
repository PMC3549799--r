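test_that("adapter trimming truncates at the leftmost match and filters", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  p <- preprocess_params(adapter = adapter)
  insert <- "ACGTACGTACGTACGTACGT"        # 20 nt
  r <- make_reads(paste0(insert, adapter))
  out <- trim_adapter(r, p)
  expect_equal(out$reads$bases, insert)
  expect_equal(lengths(out$reads$quals), 20L)
  # empty adapter: no-op, 15-nt read kept
  out <- trim_adapter(make_reads("ACGTACGTACGTACG"), preprocess_params())
  expect_equal(out$reads$bases, "ACGTACGTACGTACG")
  expect_equal(out$discarded, 0L)
  # 30-nt read whose last 16 nt are adapter -> 14-nt remainder -> discarded
  r <- make_reads(paste0(substr(insert, 1, 14), substr(adapter, 1, 16)))
  out <- trim_adapter(r, p)
  expect_equal(nrow(out$reads), 0L)
  expect_equal(out$discarded, 1L)
  # leftmost rule: adapter occurs twice, cut at the first occurrence
  r <- make_reads(paste0("AAAAAAAAAAAAAAAA", adapter, "CCCC", adapter))
  out <- trim_adapter(r, p)
  expect_equal(out$reads$bases, "AAAAAAAAAAAAAAAA")
})

test_that("adapter matching honours overlap and mismatch-rate settings", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  p <- preprocess_params(adapter = adapter)
  insert <- "ACGTACGTACGTACGTACGT"
  # terminal 5-nt exact adapter prefix is trimmed (min overlap)
  out <- trim_adapter(make_reads(paste0(insert, substr(adapter, 1, 5))), p)
  expect_equal(out$reads$bases, insert)
  # 4-nt overlap is below the minimum and left alone
  out <- trim_adapter(make_reads(paste0(insert, substr(adapter, 1, 4))), p)
  expect_equal(nchar(out$reads$bases), 24L)
  # one mismatch in a 12-nt overlap is within the 10% rate
  frag <- substr(adapter, 1, 12)
  substr(frag, 6, 6) <- "A"  # adapter base there is T
  out <- trim_adapter(make_reads(paste0(insert, frag)), p)
  expect_equal(out$reads$bases, insert)
})

test_that("reads with ambiguous bases after trimming are discarded", {
  adapter <- "TGGAATTCTCGGGTGCCAAGG"
  p <- preprocess_params(adapter = adapter)
  # N inside the kept part -> discard
  out <- trim_adapter(make_reads("ACGTACGTNACGTACGTACG"), p)
  expect_equal(nrow(out$reads), 0L)
  # N only inside the trimmed adapter -> kept
  withN <- paste0("ACGTACGTACGTACGTACGT", adapter)
  substr(withN, 25, 25) <- "N"
  out <- trim_adapter(make_reads(withN), p)
  expect_equal(out$reads$bases, "ACGTACGTACGTACGTACGT")
})

test_that("quality trimming strips 3' tails strictly below the threshold", {
  p <- preprocess_params()
  q <- c(rep(30L, 14), 40L, 40L, 19L, 5L)
  r <- make_reads(rand_dna(18), quals = list(q))
  out <- quality_trim(r, p)
  expect_equal(nchar(out$reads$bases), 16L)   # exactly the two sub-20 bases go
  expect_equal(out$reads$quals[[1]], q[1:16])
  # boundary: terminal phred exactly 20 is retained
  r <- make_reads(rand_dna(16), quals = list(c(rep(30L, 15), 20L)))
  expect_equal(nchar(quality_trim(r, p)$reads$bases), 16L)
  # 16-nt read with last three bases below 20 -> 13 nt -> discarded
  r <- make_reads(rand_dna(16), quals = list(c(rep(30L, 13), 10L, 10L, 10L)))
  out <- quality_trim(r, p)
  expect_equal(nrow(out$reads), 0L)
  expect_equal(out$discarded, 1L)
})

test_that("quality trimming is idempotent", {
  set.seed(7)
  reads <- make_reads(replicate(30, rand_dna(25)),
                      quals = replicate(30, sample(2:41, 25, replace = TRUE),
                                        simplify = FALSE))
  once <- quality_trim(reads, preprocess_params())
  twice <- quality_trim(once$reads, preprocess_params())
  expect_equal(twice$reads, once$reads)
  expect_equal(twice$discarded, 0L)
})

test_that("collapsing conserves multiplicity and keeps first-seen records", {
  r <- make_reads(c("ACGTACGTACGTACG", "ACGTACGTACGTACG", "TTTTTTTTTTTTTTT"),
                  quals = list(rep(40L, 15), rep(20L, 15), rep(30L, 15)))
  out <- collapse_reads(r)
  expect_equal(nrow(out), 2L)
  expect_equal(out$multiplicity, c(2L, 1L))
  expect_equal(out$read_id, c("r1", "r3"))        # first-seen id
  expect_equal(out$quals[[1]], rep(40L, 15))      # first-seen quals
  expect_equal(nrow(collapse_reads(r[0, ])), 0L)  # empty in, empty out
})

test_that("collapsing a large duplicate set conserves the read count", {
  set.seed(13)
  pool <- replicate(8, rand_dna(20))
  picks <- sample(pool, 1000, replace = TRUE)
  out <- collapse_reads(make_reads(picks))
  expect_equal(sum(out$multiplicity), 1000L)
  expect_equal(nrow(out), length(unique(picks)))
  # brute-force counts agree
  expect_equal(out$multiplicity,
               as.integer(table(factor(picks, levels = out$bases))))
})

test_that("preprocessing accounts for every input read", {
  set.seed(99)
  cfg <- small_sim_config()
  d <- simulate_dataset(cfg)
  pp <- preprocess_reads(d$reads, preprocess_params(adapter = cfg$adapter))
  expect_equal(pp$reads_in,
               pp$discarded_adapter + pp$discarded_quality + pp$reads_surviving)
  expect_equal(sum(pp$reads$multiplicity), pp$reads_surviving)
  # every surviving read respects the length/ambiguity/tail rules
  expect_true(all(nchar(pp$reads$bases) >= 15L))
  expect_false(any(grepl("N", pp$reads$bases, fixed = TRUE)))
  expect_true(all(vapply(pp$reads$quals, function(q) q[length(q)] >= 20L,
                         logical(1))))
})
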