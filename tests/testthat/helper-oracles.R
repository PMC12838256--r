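# Independent oracles used across the suite. These are deliberately written
# step-by-step on scalars (not shared with the vectorised implementation).

# Weir-Cockerham variance components for two populations, transcribed
# formula-by-formula from the r = 2 estimator definition.
wc_oracle <- function(case_gt, control_gt) {
  pops <- list(case_gt[!is.na(case_gt)], control_gt[!is.na(control_gt)])
  n <- vapply(pops, length, 0L)
  if (any(n < 2)) return(list(a = NA_real_, b = NA_real_, c = NA_real_,
                              theta = NA_real_))
  r <- 2
  p <- vapply(pops, function(g) sum(g) / (2 * length(g)), 0)
  h <- vapply(pops, function(g) mean(g == 1L), 0)
  nbar <- sum(n) / r
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  denom <- a + b + cc
  list(a = a, b = b, c = cc,
       theta = if (denom > 0) a / denom else NA_real_)
}

# Brute-force per-site nucleotide diversity: expand diploid dosages to the
# haplotype multiset and average the pairwise difference over all C(m,2)
# haplotype pairs.
pi_bruteforce <- function(gt) {
  gt <- gt[!is.na(gt)]
  hap <- unlist(lapply(gt, function(d) c(rep(1L, d), rep(0L, 2L - d))))
  m <- length(hap)
  if (m < 2) return(NA_real_)
  pairs <- utils::combn(m, 2)
  mean(hap[pairs[1, ]] != hap[pairs[2, ]])
}

# Exhaustive over-representation p-value: fraction of all n-subsets of the
# universe whose overlap with the term's genes is >= the observed overlap.
hyper_bruteforce <- function(k_obs, term_genes, candidates_n, universe) {
  subsets <- utils::combn(length(universe), candidates_n)
  hits <- apply(subsets, 2, function(idx)
    sum(universe[idx] %in% term_genes) >= k_obs)
  mean(hits)
}

# Small variant_set builder with clean (passing) quality annotations derived
# from the dosage matrix.
make_vs <- function(gt, chrom = NULL, pos = NULL, info = NULL,
                    samples = NULL) {
  gt <- as.matrix(gt)
  s <- nrow(gt)
  if (is.null(chrom)) chrom <- rep("chr1", s)
  if (is.null(pos)) pos <- seq_len(s)
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  dp <- matrix(10L, s, ncol(gt))
  ad_alt <- matrix(0L, s, ncol(gt))
  ad_alt[gt == 1L] <- 5L
  ad_alt[gt == 2L] <- 10L
  if (is.null(info))
    info <- data.frame(QD = rep(10, s), FS = 5, SOR = 2, MQ = 50,
                       MQRankSum = 0, QUAL = 200, ReadPosRankSum = 0)
  variant_set(chrom, pos, rep("A", s), rep("T", s), gt,
              gq = matrix(99L, s, ncol(gt)), dp = dp,
              ad_ref = dp - ad_alt, ad_alt = ad_alt, info = info,
              samples = samples)
}

# Random dosage matrix with missingness, for property-style comparisons.
random_gt <- function(n_sites, n_samples, miss = 0.15) {
  g <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
              n_sites, n_samples)
  g[matrix(stats::runif(length(g)) < miss, n_sites, n_samples)] <- NA_integer_
  g
}

# Shared small test cohort with one planted sweep (memoised per session).
sweep_test_config <- function(seed = 7) {
  simulation_config(background_fst = 0.02,
                    sweep_regions = sweep_region("chr1", 1000001, 1100000,
                                                 sweep_fst = 0.5,
                                                 case_diversity_factor = 0.3),
                    seed = seed)
}

test_chrom_lengths <- function(cfg) {
  stats::setNames(rep(cfg$chrom_length_bp, cfg$n_chromosomes),
                  paste0("chr", seq_len(cfg$n_chromosomes)))
}
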