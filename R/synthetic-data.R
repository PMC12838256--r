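#' Configuration for the synthetic two-population cohort generator
#'
#' The generator emulates a case/control whole-genome resequencing cohort
#' (default 145 cases vs 30 controls, the study design this package targets)
#' under the Balding-Nichols model: each SNP draws an ancestral allele
#' frequency `p ~ Uniform(0.05, 0.95)`, then population frequencies
#' `p_i ~ Beta(p(1-F)/F, (1-p)(1-F)/F)` independently per population, where
#' `F` is `background_fst` outside sweep regions and `sweep_fst` inside them.
#' The Beta parameterisation gives `E[p_i] = p` and `Var(p_i) = F p(1-p)`, so
#' `F` is the expected Weir-Cockerham FST -- an analytically known truth for
#' parameter-recovery tests.
#'
#' Inside a sweep region the case-population frequency is additionally shrunk
#' toward the nearest fixation boundary so that the expected case
#' heterozygosity equals `case_diversity_factor` times the *neutral-region*
#' expected case heterozygosity (joint frequency-shift + diversity-loss, so
#' both the FST and the pi-ratio scan statistics fire on the same region).
#'
#' @param n_case,n_control numbers of diploid individuals (defaults 145 / 30).
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp length of each chromosome in bp.
#' @param snp_density expected SNPs per bp (sites are Poisson-distributed).
#' @param background_fst genome-background differentiation, in `[0, 1)`.
#' @param sweep_regions data.frame with columns `chrom`, `start_bp`, `end_bp`
#'   (1-based inclusive), `sweep_fst`, `case_diversity_factor`; see
#'   [sweep_region()]. May be empty (no sweeps).
#' @param mean_depth expected per-genotype read depth (Poisson mean).
#' @param corrupt_genotype_frac fraction of genotypes given a failing GQ (< 20).
#' @param corrupt_site_frac fraction of sites given one failing hard-filter
#'   annotation.
#' @param seed integer RNG seed; all output is a pure function of the config.
#'
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_case = 145, n_control = 30,
                              n_chromosomes = 3, chrom_length_bp = 2e6,
                              snp_density = 1e-3, background_fst = 0.02,
                              sweep_regions = NULL, mean_depth = 10,
                              corrupt_genotype_frac = 0.02,
                              corrupt_site_frac = 0.02, seed = 1L) {
  if (is.null(sweep_regions))
    sweep_regions <- data.frame(chrom = character(), start_bp = integer(),
                                end_bp = integer(), sweep_fst = numeric(),
                                case_diversity_factor = numeric())
  cfg <- list(n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_chromosomes = as.integer(n_chromosomes),
              chrom_length_bp = as.integer(chrom_length_bp),
              snp_density = snp_density, background_fst = background_fst,
              sweep_regions = as.data.frame(sweep_regions),
              mean_depth = mean_depth,
              corrupt_genotype_frac = corrupt_genotype_frac,
              corrupt_site_frac = corrupt_site_frac, seed = as.integer(seed))
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' Describe one planted sweep region
#'
#' @param chrom chromosome name (e.g. `"chr1"`).
#' @param start_bp,end_bp 1-based inclusive bounds of the region.
#' @param sweep_fst differentiation level inside the region; must exceed the
#'   cohort's `background_fst`.
#' @param case_diversity_factor multiplier in `(0, 1]` applied to the expected
#'   case-population heterozygosity inside the region.
#' @return one-row data.frame suitable for `simulation_config(sweep_regions=)`.
#' @export
sweep_region <- function(chrom, start_bp, end_bp, sweep_fst,
                         case_diversity_factor) {
  data.frame(chrom = chrom, start_bp = as.integer(start_bp),
             end_bp = as.integer(end_bp), sweep_fst = sweep_fst,
             case_diversity_factor = case_diversity_factor)
}

validate_simulation_config <- function(cfg) {
  fail <- function(...) stop("invalid simulation_config: ", ..., call. = FALSE)
  if (cfg$n_case < 2) fail("n_case must be >= 2")
  if (cfg$n_control < 2) fail("n_control must be >= 2")
  if (cfg$background_fst < 0 || cfg$background_fst >= 1)
    fail("background_fst must be in [0, 1)")
  if (cfg$n_chromosomes < 1) fail("n_chromosomes must be >= 1")
  if (cfg$chrom_length_bp < 1) fail("chrom_length_bp must be >= 1")
  if (cfg$snp_density <= 0) fail("snp_density must be > 0")
  if (cfg$mean_depth <= 0) fail("mean_depth must be > 0")
  sr <- cfg$sweep_regions
  if (nrow(sr) > 0) {
    valid_chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
    if (!all(sr$chrom %in% valid_chroms))
      fail("sweep region chromosome outside simulated chromosomes")
    if (any(sr$start_bp < 1 | sr$end_bp > cfg$chrom_length_bp |
            sr$start_bp > sr$end_bp))
      fail("sweep region outside chromosome bounds")
    if (any(sr$sweep_fst <= cfg$background_fst))
      fail("sweep_fst must exceed background_fst")
    if (any(sr$sweep_fst >= 1)) fail("sweep_fst must be < 1")
    if (any(sr$case_diversity_factor <= 0 | sr$case_diversity_factor > 1))
      fail("case_diversity_factor must be in (0, 1]")
    for (ch in unique(sr$chrom)) {
      r <- sr[sr$chrom == ch, , drop = FALSE]
      r <- r[order(r$start_bp), , drop = FALSE]
      if (nrow(r) > 1 && any(r$start_bp[-1] <= r$end_bp[-nrow(r)]))
        fail("sweep regions overlap on ", ch)
    }
  }
  invisible(cfg)
}

# Shrink an allele frequency toward the nearest fixation boundary so its
# heterozygosity 2p(1-p) is multiplied by d. Closed form: for p <= 1/2 solve
# s^2 p - s + d(1-p) = 0 for the shrink factor s = p'/p (smaller root);
# symmetric in 1-p for p > 1/2. d = 1 gives s = 1 exactly.
shrink_het <- function(p, d) {
  flip <- p > 0.5
  q <- ifelse(flip, 1 - p, p)
  out <- q
  ok <- q > 0 & q < 1 & d < 1
  if (any(ok)) {
    qq <- q[ok]; dd <- if (length(d) == 1) d else d[ok]
    s <- (1 - sqrt(pmax(0, 1 - 4 * dd * qq * (1 - qq)))) / (2 * qq)
    out[ok] <- s * qq
  }
  ifelse(flip, 1 - out, out)
}

#' Simulate a two-population SNP cohort
#'
#' Draws sites, population allele frequencies, diploid genotypes
#' (Hardy-Weinberg binomial draws from the population frequency), per-genotype
#' DP ~ Poisson(`mean_depth`), AD split binomially for heterozygotes, high GQ
#' except for a corrupted fraction, and passing site annotations except for a
#' corrupted fraction. Monomorphic draws are retained (downstream biallelic
#' filtering removes them). Deterministic given `config$seed`.
#'
#' @param config a [simulation_config()].
#' @return list with elements `variants` (a [variant_set()]), `manifest`
#'   (data.frame `sample_id`, `group`), `case_ids`, `control_ids`, and
#'   `truth` (per-site data.frame of the generating `p`, `F`, population
#'   frequencies and sweep membership, for validation studies).
#' @export
simulate_cohort <- function(config) {
  validate_simulation_config(config)
  withr::with_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))
  chrom <- character(0); pos <- integer(0)
  for (ch in chroms) {
    n_snp <- stats::rpois(1, cfg$chrom_length_bp * cfg$snp_density)
    n_snp <- min(n_snp, cfg$chrom_length_bp)
    p_ch <- sort(sample.int(cfg$chrom_length_bp, n_snp))
    chrom <- c(chrom, rep(ch, n_snp)); pos <- c(pos, p_ch)
  }
  s <- length(pos)
  if (s == 0) stop("no SNPs simulated; increase snp_density or lengths")

  # per-site differentiation F and case diversity shrink target
  f <- rep(cfg$background_fst, s)
  d_eff <- rep(1, s)
  in_sweep <- rep(FALSE, s)
  sr <- cfg$sweep_regions
  if (nrow(sr) > 0) {
    for (i in seq_len(nrow(sr))) {
      hit <- chrom == sr$chrom[i] & pos >= sr$start_bp[i] & pos <= sr$end_bp[i]
      f[hit] <- sr$sweep_fst[i]
      in_sweep[hit] <- TRUE
      # effective shrink so E[case het] = d * (1 - background_fst) * 2p(1-p),
      # i.e. d x the neutral-region expectation; capped at 1 when sweep_fst
      # alone already depresses case diversity below that target.
      d_eff[hit] <- min(1, sr$case_diversity_factor[i] *
                          (1 - cfg$background_fst) / (1 - sr$sweep_fst[i]))
    }
  }

  p <- stats::runif(s, 0.05, 0.95)
  draw_pop <- function() {
    out <- p
    v <- f > 0
    if (any(v)) {
      ratio <- (1 - f[v]) / f[v]
      out[v] <- stats::rbeta(sum(v), p[v] * ratio, (1 - p[v]) * ratio)
    }
    out
  }
  p_case <- draw_pop()
  p_control <- draw_pop()
  p_case <- ifelse(d_eff < 1, shrink_het(p_case, d_eff), p_case)

  n_ca <- cfg$n_case; n_co <- cfg$n_control; n <- n_ca + n_co
  gt_case <- matrix(stats::rbinom(s * n_ca, 2, p_case), nrow = s)
  gt_control <- matrix(stats::rbinom(s * n_co, 2, p_control), nrow = s)
  gt <- cbind(gt_case, gt_control)

  dp <- matrix(stats::rpois(s * n, cfg$mean_depth), nrow = s)
  ad_alt <- matrix(0L, s, n)
  ad_alt[gt == 2L] <- dp[gt == 2L]
  het <- which(gt == 1L)
  ad_alt[het] <- stats::rbinom(length(het), dp[het], 0.5)
  ad_ref <- dp - ad_alt

  gq <- matrix(sample(60:99, s * n, replace = TRUE), nrow = s)
  bad_gt <- stats::runif(s * n) < cfg$corrupt_genotype_frac
  gq[bad_gt] <- sample(0:19, sum(bad_gt), replace = TRUE)

  r2 <- function(x) as.numeric(sprintf("%.2f", x))
  info <- data.frame(
    QD = r2(stats::runif(s, 20, 35)), FS = r2(stats::runif(s, 0, 10)),
    SOR = r2(stats::runif(s, 0.5, 2.5)), MQ = r2(stats::runif(s, 55, 60)),
    MQRankSum = r2(stats::runif(s, -2, 2)),
    QUAL = r2(stats::runif(s, 100, 1000)),
    ReadPosRankSum = r2(stats::runif(s, -2, 2)))
  bad_site <- which(stats::runif(s) < cfg$corrupt_site_frac)
  if (length(bad_site) > 0) {
    failing <- c(QD = 1, FS = 50, SOR = 5, MQ = 20, MQRankSum = -12,
                 QUAL = 30, ReadPosRankSum = -6)
    rule <- sample(names(failing), length(bad_site), replace = TRUE)
    for (k in seq_along(bad_site))
      info[bad_site[k], rule[k]] <- failing[[rule[k]]]
  }

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, s, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), character(1))

  samples <- c(sprintf("case_%03d", seq_len(n_ca)),
               sprintf("control_%03d", seq_len(n_co)))
  vs <- variant_set(chrom, pos, ref, alt, gt, gq = gq, dp = dp,
                    ad_ref = ad_ref, ad_alt = ad_alt, info = info,
                    samples = samples)
  manifest <- data.frame(
    sample_id = samples,
    group = rep(c("case", "control"), c(n_ca, n_co)))
  list(variants = vs, manifest = manifest,
       case_ids = samples[seq_len(n_ca)],
       control_ids = samples[n_ca + seq_len(n_co)],
       truth = data.frame(chrom = chrom, pos = pos, p_ancestral = p,
                          fst_true = f, p_case = p_case,
                          p_control = p_control, in_sweep = in_sweep))
}

#' Phenotype group distributions
#'
#' Defaults are the published craniofacial summary statistics for the
#' mandibular-prognathism case group versus phenotypically normal controls:
#' maxillary length 149.12 +/- 22.89 vs 156.92 +/- 23.04 mm, mandible length
#' 197.43 +/- 32.41 vs 211.46 +/- 23.19 mm, incisor protrusion angle
#' 104.43 +/- 7.04 vs 104.66 +/- 8.31 degrees.
#'
#' @param traits data.frame with columns `trait`, `case_mean`, `case_sd`,
#'   `control_mean`, `control_sd`; defaults as above.
#' @return validated list of class `phenotype_config`.
#' @export
phenotype_config <- function(traits = NULL) {
  if (is.null(traits)) {
    traits <- data.frame(
      trait = c("maxillary_length_mm", "mandible_length_mm",
                "incisor_angle_deg"),
      case_mean = c(149.12, 197.43, 104.43),
      case_sd = c(22.89, 32.41, 7.04),
      control_mean = c(156.92, 211.46, 104.66),
      control_sd = c(23.04, 23.19, 8.31))
  }
  traits <- as.data.frame(traits)
  need <- c("trait", "case_mean", "case_sd", "control_mean", "control_sd")
  if (!all(need %in% names(traits)))
    stop("phenotype_config traits need columns: ", paste(need, collapse = ", "))
  if (any(traits$case_sd <= 0) || any(traits$control_sd <= 0))
    stop("invalid phenotype_config: all SDs must be > 0")
  structure(list(traits = traits), class = "phenotype_config")
}

#' Simulate per-individual phenotype measurements
#'
#' Draws each trait from `Normal(group mean, group SD)` per the configured
#' group distributions.
#'
#' @param pconfig a [phenotype_config()].
#' @param n_case,n_control group sizes.
#' @param seed integer RNG seed.
#' @return data.frame: `individual_id`, `group`, one column per trait.
#' @export
simulate_phenotypes <- function(pconfig, n_case = 145, n_control = 30,
                                seed = 1L) {
  stopifnot(inherits(pconfig, "phenotype_config"))
  withr::with_seed(seed, {
    tab <- data.frame(
      individual_id = c(sprintf("case_%03d", seq_len(n_case)),
                        sprintf("control_%03d", seq_len(n_control))),
      group = rep(c("case", "control"), c(n_case, n_control)))
    for (i in seq_len(nrow(pconfig$traits))) {
      tr <- pconfig$traits[i, ]
      tab[[tr$trait]] <- c(stats::rnorm(n_case, tr$case_mean, tr$case_sd),
                           stats::rnorm(n_control, tr$control_mean,
                                        tr$control_sd))
    }
    tab
  })
}

# Toy gene annotation tiled across the simulated chromosomes. For each sweep
# region, genes are planted inside it ("<id>_IN"), just outside but within
# 50 kb of its SNPs ("<id>_NEAR"), and far beyond the reach of any
# sweep-overlapping scan window ("<id>_FAR"); background genes within 250 kb
# of a sweep are dropped so that the far/near distinction is unambiguous.
simulate_gene_annotation <- function(config) {
  chroms <- paste0("chr", seq_len(config$n_chromosomes))
  len <- config$chrom_length_bp
  genes <- do.call(rbind, lapply(chroms, function(ch) {
    starts <- seq(10000L, by = 100000L,
                  length.out = max(0L, (len - 40000L) %/% 100000L))
    if (length(starts) == 0) return(NULL)
    data.frame(gene_id = sprintf("G_%s_%02d", ch, seq_along(starts)),
               chrom = ch, start = starts, end = starts + 19999L,
               role = "background")
  }))
  sr <- config$sweep_regions
  if (nrow(sr) > 0) {
    for (i in seq_len(nrow(sr))) {
      ch <- sr$chrom[i]; s0 <- sr$start_bp[i]; e0 <- sr$end_bp[i]
      keep <- !(genes$chrom == ch & genes$start <= e0 + 250000L &
                  genes$end >= s0 - 250000L)
      genes <- genes[keep, , drop = FALSE]
      mid <- as.integer((s0 + e0) %/% 2)
      far_start <- if (e0 + 320000L <= len) e0 + 300001L else s0 - 320000L
      planted <- data.frame(
        gene_id = sprintf("SW%d_%s", i, c("IN", "NEAR", "FAR")),
        chrom = ch,
        start = c(mid - 10000L, e0 + 20001L, far_start),
        end = c(mid + 9999L, e0 + 40000L, far_start + 19999L),
        role = c("sweep_inside", "sweep_near", "sweep_far"))
      genes <- rbind(genes, planted)
    }
  }
  genes <- genes[order(match(genes$chrom, chroms), genes$start), ]
  rownames(genes) <- NULL
  genes
}

# Gene-to-term map with one term ("TERM_SWEEP") planted on the sweep-adjacent
# genes (inside/near) and uniform background terms elsewhere.
simulate_term_map <- function(genes, n_background_terms = 8, seed = 1L) {
  withr::with_seed(seed, {
    bg_terms <- sprintf("TERM_BG%02d", seq_len(n_background_terms))
    per_gene <- lapply(genes$gene_id, function(g)
      sample(bg_terms, sample(1:3, 1)))
    map <- data.frame(gene_id = rep(genes$gene_id, lengths(per_gene)),
                      term_id = unlist(per_gene))
    sweepy <- genes$gene_id[genes$role %in% c("sweep_inside", "sweep_near")]
    if (length(sweepy) > 0)
      map <- rbind(map, data.frame(gene_id = sweepy, term_id = "TERM_SWEEP"))
    rownames(map) <- NULL
    map
  })
}

#' Write a complete synthetic fixture bundle to disk
#'
#' Writes the cohort VCF, a toy GFF3 gene annotation (with genes planted
#' inside, within 50 kb of, and far from each sweep region), case/control
#' sample lists, a phenotype TSV, and a gene-to-term map in which the term
#' `TERM_SWEEP` is enriched among sweep-adjacent genes.
#'
#' @param config a [simulation_config()].
#' @param pconfig a [phenotype_config()]; default [phenotype_config()].
#' @param outdir output directory (created if missing).
#' @return (invisibly) named list of the written file paths plus the in-memory
#'   cohort and gene table.
#' @export
write_fixture_bundle <- function(config, pconfig = phenotype_config(),
                                 outdir) {
  if (!dir.exists(outdir))
    dir.create(outdir, recursive = TRUE)
  cohort <- simulate_cohort(config)
  genes <- simulate_gene_annotation(config)
  term_map <- simulate_term_map(genes, seed = config$seed + 2L)
  pheno <- simulate_phenotypes(pconfig, config$n_case, config$n_control,
                               seed = config$seed + 1L)
  paths <- list(
    vcf = file.path(outdir, "cohort.vcf"),
    gff = file.path(outdir, "genes.gff3"),
    cases = file.path(outdir, "cases.txt"),
    controls = file.path(outdir, "controls.txt"),
    phenotypes = file.path(outdir, "phenotypes.tsv"),
    term_map = file.path(outdir, "gene2term.tsv"))
  write_vcf(cohort$variants, paths$vcf,
            contig_lengths = stats::setNames(
              rep(config$chrom_length_bp, config$n_chromosomes),
              paste0("chr", seq_len(config$n_chromosomes))))
  write_gff_genes(genes, paths$gff)
  writeLines(cohort$case_ids, paths$cases)
  writeLines(cohort$control_ids, paths$controls)
  utils::write.table(pheno, paths$phenotypes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(term_map, paths$term_map, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, list(cohort = cohort, genes = genes,
                          term_map = term_map, phenotypes = pheno)))
}
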