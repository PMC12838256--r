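test_that("variance components match the worked genotype example and oracle", {
  case_gt <- c(0L, 1L, 2L, 1L)
  control_gt <- c(0L, 0L, 1L, 0L)
  vs <- make_vs(matrix(c(case_gt, control_gt), 1),
                samples = c(paste0("ca", 1:4), paste0("co", 1:4)))
  comp <- site_components(vs, paste0("ca", 1:4), paste0("co", 1:4))
  o <- wc_oracle(case_gt, control_gt)
  expect_equal(comp$a, o$a, tolerance = 1e-12)
  expect_equal(comp$b, o$b, tolerance = 1e-12)
  expect_equal(comp$c, o$c, tolerance = 1e-12)
  expect_equal(comp$theta, o$theta, tolerance = 1e-12)
})

test_that("complete fixed difference with no heterozygotes gives theta = 1", {
  gt <- matrix(c(rep(2L, 10), rep(0L, 10)), 1)
  vs <- make_vs(gt, samples = c(paste0("ca", 1:10), paste0("co", 1:10)))
  comp <- site_components(vs, paste0("ca", 1:10), paste0("co", 1:10))
  expect_identical(comp$theta, 1)
})

test_that("undifferentiated populations give near-zero mean theta", {
  set.seed(4)
  n <- 60
  p <- runif(400, 0.1, 0.9)
  gt <- matrix(rbinom(400 * 2 * n, 2, rep(p, 2 * n)), nrow = 400)
  vs <- make_vs(gt, samples = c(paste0("ca", 1:n), paste0("co", 1:n)))
  comp <- site_components(vs, paste0("ca", 1:n), paste0("co", 1:n))
  expect_lt(abs(mean(comp$theta, na.rm = TRUE)), 0.02)
})

test_that("components and pi match scalar oracles on random configurations", {
  set.seed(11)
  n_rep <- 300
  gt <- random_gt(n_rep, 12, miss = 0.25)
  ca <- paste0("S", 1:6); co <- paste0("S", 7:12)
  vs <- make_vs(gt)
  comp <- site_components(vs, ca, co)
  for (i in seq_len(n_rep)) {
    o <- wc_oracle(gt[i, 1:6], gt[i, 7:12])
    expect_equal(comp$a[i], o$a, tolerance = 1e-12)
    expect_equal(comp$b[i], o$b, tolerance = 1e-12)
    expect_equal(comp$c[i], o$c, tolerance = 1e-12)
    expect_equal(comp$theta[i], o$theta, tolerance = 1e-12)
    bp <- pi_bruteforce(gt[i, 1:6])
    if (sum(!is.na(gt[i, 1:6])) >= 1)
      expect_equal(comp$pi_case[i], bp, tolerance = 1e-12)
  }
})

test_that("per-site pi equals mean pairwise haplotype difference", {
  # two diploids 0/0 and 1/1: haplotypes A,A,T,T -> 4/6 over C(4,2) pairs
  vs <- make_vs(matrix(c(0L, 2L, 0L, 0L), 1))
  comp <- site_components(vs, c("S1", "S2"), c("S3", "S4"))
  expect_equal(comp$pi_case, 4 / 6, tolerance = 1e-12)
  expect_equal(comp$pi_case, (4 / 3) * 2 * 0.5 * 0.5, tolerance = 1e-12)
})

test_that("window grid follows the stride rule with partial-window flagging", {
  w <- make_windows(c(c1 = 250000L))
  expect_equal(nrow(w), 4)
  expect_equal(w$start, c(0L, 50000L, 100000L, 150000L))
  expect_equal(w$end, c(100000L, 150000L, 200000L, 250000L))
  expect_false(any(w$partial))
  # chromosome of exactly one window
  w1 <- make_windows(c(c1 = 100000L))
  expect_equal(nrow(w1), 1)
  # trailing remainder emits one flagged partial window
  w2 <- make_windows(c(c1 = 230000L))
  expect_equal(nrow(w2), 4)
  expect_equal(w2$start[4], 150000L)
  expect_equal(w2$end[4], 230000L)
  expect_true(w2$partial[4])
  # step = window gives a disjoint tiling
  w3 <- make_windows(c(c1 = 400000L), step_bp = 100000)
  expect_true(all(w3$start[-1] == w3$end[-nrow(w3)]))
  expect_error(make_windows(c(c1 = 1e6), window_bp = 0), "positive")
  expect_error(make_windows(c(c1 = 50000L)), "shorter")
})

test_that("SNPs contribute to every overlapping window", {
  comp <- data.frame(chrom = "c1", pos = 60000L, a = 0.1, b = 0.05, c = 0.02,
                     pi_case = 0.3, pi_control = 0.4)
  w <- make_windows(c(c1 = 250000L))
  agg <- aggregate_windows(comp, w)
  expect_equal(agg$n_snps, c(1L, 1L, 0L, 0L))
  expect_equal(agg$fst[1], 0.1 / 0.17, tolerance = 1e-12)
  expect_equal(agg$fst[2], 0.1 / 0.17, tolerance = 1e-12)
  expect_true(all(is.na(agg$fst[3:4])))
  expect_equal(agg$pi_case[1], 0.3 / 100000, tolerance = 1e-12)
  expect_equal(agg$pi_ratio[1], 0.4 / 0.3, tolerance = 1e-12)
})

test_that("window FST is the ratio of sums over hand-computed components", {
  comp <- data.frame(
    chrom = "c1", pos = c(10000L, 20000L, 60000L),
    a = c(0.1, 0.2, -0.05), b = c(0.05, 0.1, 0.02), c = c(0.02, 0.03, 0.01),
    pi_case = c(0.2, 0.3, 0.1), pi_control = c(0.25, 0.2, 0.15))
  w <- make_windows(c(c1 = 100000L))
  agg <- aggregate_windows(comp, w)
  expect_equal(agg$fst, 0.25 / 0.48, tolerance = 1e-12)  # spreadsheet sum
  expect_equal(agg$pi_case, 0.6 / 100000, tolerance = 1e-12)
  # windows whose sites are all uninformative get NA and no SNP count
  comp$a <- NA_real_
  agg2 <- aggregate_windows(comp, w)
  expect_true(is.na(agg2$fst))
  expect_equal(agg2$n_snps, 0L)
  expect_error(aggregate_windows(comp[c(2, 1, 3), ], w), "sorted")
})

test_that("swapping population labels preserves FST and inverts pi-ratio", {
  cfg <- sweep_test_config(seed = 31)
  co <- simulate_cohort(cfg)
  cl <- test_chrom_lengths(cfg)
  w1 <- window_scan(co$variants, co$case_ids, co$control_ids, cl)
  w2 <- window_scan(co$variants, co$control_ids, co$case_ids, cl)
  expect_equal(w1$fst, w2$fst, tolerance = 1e-9)
  ok <- !is.na(w1$pi_ratio) & !is.na(w2$pi_ratio)
  expect_equal(w1$pi_ratio[ok], 1 / w2$pi_ratio[ok], tolerance = 1e-9)
  # explicit inversion flag matches the label swap
  w3 <- window_scan(co$variants, co$case_ids, co$control_ids, cl,
                    invert_pi_ratio = TRUE)
  expect_equal(w3$pi_ratio[ok], w2$pi_ratio[ok], tolerance = 1e-9)
})

test_that("monomorphic sites contribute nothing to window pi", {
  gt <- rbind(c(0L, 1L, 1L, 2L), c(0L, 0L, 0L, 0L))
  vs <- make_vs(gt, pos = c(10L, 20L))
  comp <- site_components(vs, c("S1", "S2"), c("S3", "S4"))
  w <- make_windows(c(chr1 = 100000L))
  agg_all <- aggregate_windows(comp, w)
  agg_poly <- aggregate_windows(comp[1, ], w)
  expect_equal(agg_all$pi_case, agg_poly$pi_case, tolerance = 1e-12)
})
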