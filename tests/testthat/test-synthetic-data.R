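test_that("configuration invariants are enforced with named errors", {
  expect_error(simulation_config(n_case = 1), "n_case")
  expect_error(simulation_config(n_control = 1), "n_control")
  expect_error(simulation_config(background_fst = 1), "background_fst")
  expect_error(simulation_config(background_fst = -0.1), "background_fst")
  expect_error(
    simulation_config(sweep_regions = sweep_region("chr9", 1, 10, 0.5, 0.5)),
    "chromosome")
  expect_error(
    simulation_config(sweep_regions = sweep_region("chr1", 1, 3e6, 0.5, 0.5)),
    "bounds")
  expect_error(
    simulation_config(background_fst = 0.3,
                      sweep_regions = sweep_region("chr1", 1, 10, 0.2, 0.5)),
    "exceed")
  expect_error(
    simulation_config(sweep_regions = rbind(
      sweep_region("chr1", 1000, 2000, 0.5, 0.5),
      sweep_region("chr1", 1500, 2500, 0.5, 0.5))),
    "overlap")
  expect_error(
    simulation_config(sweep_regions = sweep_region("chr1", 1, 10, 0.5, 1.5)),
    "case_diversity_factor")
  expect_error(phenotype_config(data.frame(
    trait = "x", case_mean = 1, case_sd = 0, control_mean = 1,
    control_sd = 1)), "SD")
})

test_that("cohort generation is a pure function of the config", {
  cfg <- simulation_config(n_case = 8, n_control = 6, n_chromosomes = 1,
                           snp_density = 2e-4, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$variants, b$variants)
  expect_identical(a$manifest, b$manifest)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_vcf(a$variants, f1); write_vcf(b$variants, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_false(identical(
    a$variants, simulate_cohort(simulation_config(
      n_case = 8, n_control = 6, n_chromosomes = 1, snp_density = 2e-4,
      seed = 43))$variants))
})

test_that("zero background differentiation gives near-zero FST", {
  cfg <- simulation_config(background_fst = 0, seed = 5)
  co <- simulate_cohort(cfg)
  comp <- site_components(co$variants, co$case_ids, co$control_ids)
  expect_lt(abs(genomewide_summary(comp)$fst), 0.01)
  expect_lt(abs(mean(comp$theta, na.rm = TRUE)), 0.02)
})

test_that("background FST parameter is recovered by the estimator", {
  cfg <- simulation_config(n_chromosomes = 1, chrom_length_bp = 4000000L,
                           snp_density = 4e-3, background_fst = 0.05,
                           seed = 3)
  co <- simulate_cohort(cfg)
  comp <- site_components(co$variants, co$case_ids, co$control_ids)
  expect_equal(genomewide_summary(comp)$fst, 0.05, tolerance = 0.2)
  expect_lt(abs(genomewide_summary(comp)$fst - 0.05), 0.012)
})

test_that("sweep regions lose case diversity by the configured factor", {
  d <- 0.5
  cfg <- simulation_config(n_chromosomes = 1, chrom_length_bp = 2000000L,
                           snp_density = 2e-3, background_fst = 0.05,
                           sweep_regions = sweep_region("chr1", 500001,
                                                        1500000, 0.3, d),
                           seed = 21)
  co <- simulate_cohort(cfg)
  comp <- site_components(co$variants, co$case_ids, co$control_ids)
  inside <- co$truth$in_sweep
  ratio <- mean(comp$pi_case[inside], na.rm = TRUE) /
    mean(comp$pi_case[!inside], na.rm = TRUE)
  expect_lt(abs(ratio - d), 0.05)
  # the control population sees only the sweep differentiation, not the
  # case-specific shrink: expected ratio (1 - sweep_fst) / (1 - background)
  ratio_co <- mean(comp$pi_control[inside], na.rm = TRUE) /
    mean(comp$pi_control[!inside], na.rm = TRUE)
  expect_lt(abs(ratio_co - 0.7 / 0.95), 0.05)
})

test_that("phenotype draws follow the configured group distributions", {
  pc <- phenotype_config()
  big <- simulate_phenotypes(pc, n_case = 10000, n_control = 100, seed = 1)
  expect_lt(abs(mean(big$maxillary_length_mm[big$group == "case"]) - 149.12),
            1)
  tiny <- phenotype_config(data.frame(
    trait = "x", case_mean = 5, case_sd = 1e-9, control_mean = 7,
    control_sd = 1e-9))
  t2 <- simulate_phenotypes(tiny, 5, 5, seed = 2)
  expect_equal(t2$x[t2$group == "case"], rep(5, 5), tolerance = 1e-6)
  expect_identical(simulate_phenotypes(pc, 10, 10, seed = 9),
                   simulate_phenotypes(pc, 10, 10, seed = 9))
})

test_that("fixture bundle writes a coherent, round-trippable file set", {
  cfg <- simulation_config(n_case = 10, n_control = 5, n_chromosomes = 2,
                           chrom_length_bp = 1500000L, snp_density = 3e-4,
                           background_fst = 0.05,
                           sweep_regions = sweep_region("chr1", 600001,
                                                        700000, 0.4, 0.4),
                           seed = 13)
  outdir <- tempfile()
  b <- write_fixture_bundle(cfg, outdir = outdir)
  expect_true(all(file.exists(unlist(b[c("vcf", "gff", "cases", "controls",
                                         "phenotypes", "term_map")]))))
  vs <- read_vcf(b$vcf)
  expect_equal(n_samples(vs), 15)
  expect_identical(vs$gt, b$cohort$variants$gt)
  expect_identical(vs$pos, b$cohort$variants$pos)
  for (k in names(b$cohort$variants$info))
    expect_equal(vs$info[[k]], b$cohort$variants$info[[k]])
  expect_identical(read_sample_list(b$cases), b$cohort$case_ids)
  genes <- read_gff_genes(b$gff)
  expect_setequal(genes$gene_id, b$genes$gene_id)
  # planted gene roles: inside / near (<= 50 kb) / far (> 250 kb) per sweep
  roles <- b$genes[match(c("SW1_IN", "SW1_NEAR", "SW1_FAR"),
                         b$genes$gene_id), ]
  expect_true(roles$start[1] >= 600001 && roles$end[1] <= 700000)
  expect_lte(roles$start[2] - 700000, 50000)
  expect_gt(roles$start[3] - 700000, 250000)
  tm <- read_term_map(b$term_map)
  expect_setequal(tm$gene_id[tm$term_id == "TERM_SWEEP"],
                  c("SW1_IN", "SW1_NEAR"))
  ph <- read_phenotypes(b$phenotypes)
  expect_equal(nrow(ph), 15)
  expect_true(all(c("maxillary_length_mm", "mandible_length_mm",
                    "incisor_angle_deg") %in% names(ph)))
})
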