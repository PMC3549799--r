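test_that("profile ratios pool converted over covering reads at T positions", {
  # UTR with a known T layout around an implanted 8mer site
  useq <- paste0(strrep("G", 20), "T", strrep("G", 6),   # T at position 9
                 "GTGCCTTA",                              # site, 0-based 27..34
                 strrep("G", 10))
  utr <- data.frame(utr_id = "u1", sequence = useq, conserved = NA,
                    stringsAsFactors = FALSE)
  # 10 reads covering everything; 6 converted at the position-9 T (0-based 20)
  conv <- c(rep(list(20L), 6), rep(list(integer(0)), 4))
  m <- make_mapped("u1", rep(0L, 10), rep(nchar(useq), 10),
                   conversion_pos = conv)
  clustering <- filter_clusters(build_clusters(m))
  sites <- find_seed_matches(clustering, utr, mirna_fix)
  expect_equal(sites$seed_match_type, "8mer")
  # position 1 is the A at 0-based 34; position k sits at coordinate 35 - k,
  # so the lone upstream T (0-based 20) is position 15
  prof15 <- site_conversion_profile(sites, clustering$members, utr, P = 15L)
  expect_equal(prof15$ratio[15], 0.6)
  expect_equal(prof15$covering[15], 10)
  expect_equal(prof15$converted[15], 6)
  # Ts inside the site motif are covered but unconverted; non-T positions NaN
  expect_equal(prof15$ratio[c(2, 3, 7)], c(0, 0, 0))
  expect_true(all(is.nan(prof15$ratio[c(1, 4, 5, 6, 8:14)])))
})

test_that("regional t test matches a closed-form hand computation", {
  b <- c(0.4, 0.45, 0.5, 0.42, 0.47, 0.44, 0.41)
  a <- c(0.05, 0.04, 0.06, 0.05, 0.03, 0.06, 0.04)
  prof <- conversion_profile(round(c(a, b) * 100), rep(100, 14))
  tt <- region_ttest(prof)
  # independent route: stats::t.test on the same ratios
  ref <- t.test(b, a, var.equal = TRUE, alternative = "greater")
  expect_equal(tt$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(tt$p_value, ref$p.value, tolerance = 1e-12)
  expect_equal(tt$df, 12)
  expect_lt(tt$p_value, 0.001)
  # swapped regions: the one-tailed complement
  swap <- region_ttest(prof, region_a = 8:14, region_b = 1:7)
  expect_gt(swap$p_value, 0.999)
  expect_equal(swap$t, -tt$t, tolerance = 1e-12)
})

test_that("identical constant regions give t = 0 and p = 0.5", {
  prof <- conversion_profile(rep(5, 14), rep(10, 14))
  tt <- region_ttest(prof)
  expect_equal(tt$t, 0)
  expect_equal(tt$p_value, 0.5)
})

test_that("regions with fewer than two defined ratios are flagged", {
  conv <- c(1, rep(0, 13))
  cov <- c(10, 0, 0, 0, 0, 0, 0, rep(10, 7))   # one defined ratio in 1-7
  expect_warning(tt <- region_ttest(conversion_profile(conv, cov)),
                 "undefined")
  expect_false(tt$defined)
  expect_true(is.na(tt$p_value))
})

test_that("simulated regional rates are recovered and strongly separated", {
  set.seed(19)
  prof <- simulate_region_profile(n_sites = 200L, rate_seed = 0.05,
                                  rate_effector = 0.5)
  expect_true(all(abs(prof$ratio[8:14] - 0.5) < 0.1))
  expect_true(all(abs(prof$ratio[1:7] - 0.05) < 0.05))
  tt <- region_ttest(prof)
  expect_lt(tt$p_value, 1e-6)
  expect_gt(tt$t, 0)
})

test_that("the all-inclusive stratum reproduces the unstratified test", {
  d <- simulate_dataset(small_sim_config(seed = 29))
  res <- run_pipeline(d$reads, d$utrs, d$mirnas, mode = "parclip",
                      preprocess = preprocess_params(adapter = d$config$adapter),
                      expression = d$expression)
  full <- res$ttest
  strat <- stratified_tests(res$sites, res$clusters$members, d$utrs,
                            strata = "CN78")
  expect_equal(strat$p_value, full$p_value)
  expect_equal(strat$n_sites, nrow(res$sites))
  # restricting to all miRNAs via top_k changes nothing
  strat_all <- stratified_tests(res$sites, res$clusters$members, d$utrs,
                                strata = "CN78", expression = d$expression,
                                top_k = nrow(d$mirnas))
  expect_equal(strat_all$p_value, full$p_value)
})

test_that("stratification restricts sites and denominators monotonically", {
  d <- simulate_dataset(small_sim_config(seed = 37))
  res <- run_pipeline(d$reads, d$utrs, d$mirnas, mode = "parclip",
                      preprocess = preprocess_params(adapter = d$config$adapter))
  strat <- stratified_tests(res$sites, res$clusters$members, d$utrs)
  expect_equal(strat$stratum, default_strata())
  expect_equal(strat$n_sites[strat$stratum == "CN78"],
               sum(strat$n_sites[strat$stratum %in% c("C78", "N78")]))
  expect_equal(strat$n_sites[strat$stratum == "CN78"],
               sum(strat$n_sites[strat$stratum %in% c("CN7", "CN8")]))
  # stratified profile denominators never exceed the full profile's
  full <- site_conversion_profile(res$sites, res$clusters$members, d$utrs)
  c8 <- res$sites[res$sites$seed_match_type == "8mer", ]
  sub <- site_conversion_profile(c8, res$clusters$members, d$utrs)
  expect_true(all(sub$covering <= full$covering))
  # empty strata are reported as NA rows, not dropped
  none <- stratified_tests(res$sites[0, ], res$clusters$members, d$utrs)
  expect_equal(nrow(none), 9L)
  expect_true(all(is.na(none$p_value)))
})
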