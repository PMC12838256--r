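# Passing / failing annotation values for each SNP hard-filter rule.
pass_vals <- c(QD = 10, FS = 5, SOR = 2, MQ = 50, MQRankSum = 0, QUAL = 200,
               ReadPosRankSum = 0)
fail_vals <- c(QD = 1, FS = 50, SOR = 5, MQ = 10, MQRankSum = -12, QUAL = 10,
               ReadPosRankSum = -6)

test_that("site filter applies strict OR semantics with recorded reasons", {
  info <- as.data.frame(rbind(
    pass_vals,
    replace(pass_vals, "QD", 2.5),
    replace(pass_vals, "QD", 3.0),      # boundary: strict '<' passes
    replace(replace(pass_vals, "FS", 100), "SOR", 5),
    replace(pass_vals, "FS", 30.0),     # boundary passes
    replace(pass_vals, "SOR", 4.0),     # boundary passes
    replace(pass_vals, "MQRankSum", NA)))  # missing value: rule skipped
  vs <- make_vs(matrix(1L, nrow(info), 4), info = info)
  st <- filter_sites(vs)
  expect_equal(st$pass, c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(st$reasons[2], "QD < 3")
  expect_true(grepl("FS > 30", st$reasons[4]) &&
                grepl("SOR > 4", st$reasons[4]))
})

test_that("every combination of rule violations matches a truth-table oracle", {
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), 7))
  names(combos) <- names(pass_vals)
  info <- as.data.frame(t(apply(combos, 1, function(v)
    ifelse(v, fail_vals, pass_vals))))
  vs <- make_vs(matrix(1L, nrow(info), 2), info = info)
  st <- filter_sites(vs)
  oracle_pass <- rowSums(combos) == 0
  expect_equal(st$pass, unname(oracle_pass))
  expect_equal(sum(st$pass), 1)  # only the all-passing row survives
  # reason count equals the number of violated rules
  expect_equal(lengths(strsplit(st$reasons, ";"))[!st$pass],
               unname(rowSums(combos))[!oracle_pass])
})

test_that("missing annotation columns skip the rule with a message", {
  vs <- make_vs(matrix(1L, 2, 2), info = data.frame(QD = c(10, 1)))
  expect_message(st <- filter_sites(vs), "FS")
  expect_equal(st$pass, c(TRUE, FALSE))
})

test_that("indel rule set uses its own thresholds", {
  info <- data.frame(QD = c(10, 10), FS = c(50, 150),
                     ReadPosRankSum = c(-6, -6))
  vs <- make_vs(matrix(1L, 2, 2), info = info)
  st <- suppressMessages(filter_sites(vs, variant_type = "indel"))
  # FS=50 passes the indel cutoff (100) and RPRS=-6 passes (-10)
  expect_equal(st$pass, c(TRUE, FALSE))
})

test_that("genotype masking honours GQ, DP and AD-ratio boundaries", {
  gt <- matrix(c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L), 1)
  vs <- make_vs(gt)
  vs$gq <- matrix(c(19L, 20L, 99L, 99L, 99L, 99L, 99L, 99L), 1)
  vs$dp <- matrix(c(10L, 10L, 3L, 4L, 30L, 31L, 10L, 10L), 1)
  vs$ad_alt <- matrix(c(5L, 5L, 1L, 2L, 15L, 15L, 9L, 8L), 1)
  vs$ad_ref <- vs$dp - vs$ad_alt
  # sample 7: AD=(1,9) ratio 0.1 -> masked; sample 8: AD=(2,8) ratio 0.2 kept
  md <- stats::setNames(rep(10, 8), vs$samples)
  out <- filter_genotypes(vs, mean_depth = md)
  expect_equal(unname(is.na(out$gt[1, ])),
               c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(attr(out, "mask_counts")[["gq"]], 1)
  expect_equal(attr(out, "mask_counts")[["dp"]], 2)
  # hom genotypes are exempt from the AD-ratio rule
  vs2 <- make_vs(matrix(c(0L, 2L), 1))
  vs2$ad_ref <- matrix(c(9L, 1L), 1); vs2$ad_alt <- matrix(c(1L, 9L), 1)
  out2 <- filter_genotypes(vs2, mean_depth = stats::setNames(rep(10, 2),
                                                             vs2$samples))
  expect_false(anyNA(out2$gt))
})

test_that("biallelic rule drops monomorphic, fixed and all-missing sites", {
  gt <- rbind(c(0L, 0L, 0L, 0L),       # AC=0
              c(2L, 2L, 2L, 2L),       # AF=1
              c(0L, 1L, 0L, 0L),       # keep
              c(NA, NA, NA, NA),       # all-missing
              c(NA, 2L, 2L, NA))       # AF=1 over called
  vs <- make_vs(gt)
  bi <- apply_biallelic_rule(vs)
  expect_equal(bi$keep, c(FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(bi$reason, c("AC=0", "AF=1", "", "all-missing", "AF=1"))
})

test_that("pipeline output is invariant under sample reordering", {
  cfg <- simulation_config(n_case = 6, n_control = 4, n_chromosomes = 1,
                           chrom_length_bp = 200000L, snp_density = 1e-3,
                           seed = 8)
  vs <- simulate_cohort(cfg)$variants
  perm <- rev(vs$samples)
  a <- filter_variants(vs)
  b <- filter_variants(subset_variants(vs, samples = perm))
  expect_equal(n_sites(a$variants), n_sites(b$variants))
  expect_equal(a$summary$n_removed, b$summary$n_removed)
  expect_identical(a$variants$pos, b$variants$pos)
})
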