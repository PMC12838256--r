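#' Hard-filter thresholds
#'
#' Defaults are the GATK-style hard filters used for cohort SNP filtering:
#' a SNP site fails if `QD < 3.0 || FS > 30.0 || SOR > 4.0 || MQ < 30.0 ||
#' MQRankSum < -10.0 || QUAL < 50.0 || ReadPosRankSum < -5.0` (InDels:
#' `QD < 3.0 || FS > 100.0 || ReadPosRankSum < -10.0`); a genotype is set to
#' missing if `GQ < 20`, if its depth is below 1/3x or above 3x the
#' individual's mean depth, or (heterozygotes only) if the allele-depth
#' ratio `min(AD)/sum(AD)` is below 0.2. All inequalities are strict, so
#' boundary values (QD = 3.0, GQ = 20, DP = 3x mean, ratio = 0.2) pass.
#'
#' @param snp,indel named lists of site rules (names as below).
#' @param gq_min genotype-quality cutoff (fail when GQ < `gq_min`).
#' @param dp_low_factor,dp_high_factor depth bounds as multiples of the
#'   individual's mean depth (fail when DP < mean*low or DP > mean*high).
#' @param ad_ratio_min minimum heterozygote allele-depth balance.
#' @return list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(
    snp = list(QD_min = 3.0, FS_max = 30.0, SOR_max = 4.0, MQ_min = 30.0,
               MQRankSum_min = -10.0, QUAL_min = 50.0,
               ReadPosRankSum_min = -5.0),
    indel = list(QD_min = 3.0, FS_max = 100.0, ReadPosRankSum_min = -10.0),
    gq_min = 20, dp_low_factor = 1 / 3, dp_high_factor = 3,
    ad_ratio_min = 0.2) {
  structure(list(snp = snp, indel = indel, gq_min = gq_min,
                 dp_low_factor = dp_low_factor,
                 dp_high_factor = dp_high_factor,
                 ad_ratio_min = ad_ratio_min),
            class = "filter_thresholds")
}

# One site rule: key in the info table, direction, cutoff, printable label.
site_rule_table <- function(rules) {
  keys <- sub("_(min|max)$", "", names(rules))
  dir <- sub(".*_", "", names(rules))
  data.frame(key = keys, dir = dir, cutoff = unlist(rules, use.names = FALSE),
             label = ifelse(dir == "min",
                            sprintf("%s < %s", keys, unlist(rules)),
                            sprintf("%s > %s", keys, unlist(rules))))
}

#' Apply site-level hard filters
#'
#' A site fails if ANY rule's inequality holds (OR semantics). A rule whose
#' annotation column is absent, or is `NA` at a given site, is skipped for
#' that site (GATK emits some annotations conditionally); skipped columns are
#' reported once via `message()`.
#'
#' @param x a [variant_set()].
#' @param thresholds a [filter_thresholds()].
#' @param variant_type `"snp"` or `"indel"` (selects the rule set).
#' @return data.frame with one row per site: `pass` (logical) and `reasons`
#'   (`;`-separated labels of the violated rules, `""` when passing).
#' @export
filter_sites <- function(x, thresholds = filter_thresholds(),
                         variant_type = c("snp", "indel")) {
  variant_type <- match.arg(variant_type)
  rules <- site_rule_table(thresholds[[variant_type]])
  n <- n_sites(x)
  fail_mat <- matrix(FALSE, n, nrow(rules))
  missing_keys <- character(0)
  for (i in seq_len(nrow(rules))) {
    key <- rules$key[i]
    if (!key %in% names(x$info)) {
      missing_keys <- c(missing_keys, key)
      next
    }
    val <- x$info[[key]]
    hit <- if (rules$dir[i] == "min") val < rules$cutoff[i]
           else val > rules$cutoff[i]
    fail_mat[, i] <- !is.na(hit) & hit
  }
  if (length(missing_keys) > 0)
    message("site annotation(s) absent, rule(s) skipped: ",
            paste(missing_keys, collapse = ", "))
  reasons <- apply(fail_mat, 1, function(r)
    paste(rules$label[r], collapse = ";"))
  data.frame(pass = !apply(fail_mat, 1, any), reasons = reasons,
             stringsAsFactors = FALSE)
}

#' Mask low-quality genotypes
#'
#' Sets to missing every genotype with `GQ < gq_min`, depth outside
#' `(mean_depth * dp_low_factor, mean_depth * dp_high_factor)` using each
#' individual's own mean depth, or (heterozygotes) allele-depth ratio
#' `min(AD)/sum(AD) < ad_ratio_min`. A genotype whose GQ/DP/AD value is
#' missing is left untouched by the corresponding rule; a heterozygote with
#' `sum(AD) = 0` is likewise left to the other rules (no read evidence to
#' judge balance on).
#'
#' @param x a [variant_set()].
#' @param mean_depth named numeric vector of per-sample mean depths; if
#'   `NULL`, computed from the DP matrix of `x` (first-pass estimate).
#' @param thresholds a [filter_thresholds()].
#' @return the `variant_set` with offending genotypes set to `NA`, carrying a
#'   `mask_counts` attribute (genotypes masked per rule).
#' @export
filter_genotypes <- function(x, mean_depth = NULL,
                             thresholds = filter_thresholds()) {
  if (is.null(mean_depth)) {
    mean_depth <- colMeans(x$dp, na.rm = TRUE)
    names(mean_depth) <- x$samples
  }
  md <- mean_depth[x$samples]
  if (anyNA(md) || any(md <= 0))
    stop("mean depth missing or non-positive for some sample(s)")
  gq_bad <- !is.na(x$gq) & x$gq < thresholds$gq_min
  lo <- matrix(md * thresholds$dp_low_factor, nrow = n_sites(x),
               ncol = n_samples(x), byrow = TRUE)
  hi <- matrix(md * thresholds$dp_high_factor, nrow = n_sites(x),
               ncol = n_samples(x), byrow = TRUE)
  dp_bad <- !is.na(x$dp) & (x$dp < lo | x$dp > hi)
  ad_sum <- x$ad_ref + x$ad_alt
  ratio <- pmin(x$ad_ref, x$ad_alt) / ad_sum
  ad_bad <- !is.na(x$gt) & x$gt == 1L & !is.na(ratio) & ad_sum > 0 &
    ratio < thresholds$ad_ratio_min
  counts <- c(gq = sum(gq_bad & !is.na(x$gt)),
              dp = sum(dp_bad & !is.na(x$gt)),
              ad_ratio = sum(ad_bad))
  x$gt[gq_bad | dp_bad | ad_bad] <- NA_integer_
  attr(x, "mask_counts") <- counts
  x
}

#' Biallelic retention rule
#'
#' After genotype masking, recomputes the alternate allele count and
#' frequency over non-missing genotypes and keeps a site iff
#' `allele count > 0 and allele frequency < 1` (excluding monomorphic and
#' fixed sites). A site with zero non-missing genotypes is dropped with
#' reason `all-missing`.
#'
#' @param x a [variant_set()] (genotype masking already applied).
#' @return data.frame per site: `keep` (logical), `reason`
#'   (`""`, `"AC=0"`, `"AF=1"`, or `"all-missing"`), `ac`, `af`.
#' @export
apply_biallelic_rule <- function(x) {
  called <- rowSums(!is.na(x$gt))
  ac <- rowSums(x$gt, na.rm = TRUE)
  af <- ifelse(called > 0, ac / (2 * called), NA_real_)
  reason <- rep("", n_sites(x))
  reason[called == 0] <- "all-missing"
  reason[called > 0 & ac == 0] <- "AC=0"
  reason[called > 0 & af == 1] <- "AF=1"
  data.frame(keep = reason == "", reason = reason, ac = ac, af = af,
             stringsAsFactors = FALSE)
}

#' Full filtering pipeline
#'
#' Fixed order: site hard filters, then genotype masking, then the biallelic
#' rule on the masked genotypes.
#'
#' @inheritParams filter_genotypes
#' @param variant_type `"snp"` or `"indel"`.
#' @return list: `variants` (surviving sites with masked genotypes),
#'   `summary` (data.frame `rule`, `n_removed` — sites for site/biallelic
#'   rules, genotypes for masking rules), `site_status`, `biallelic_status`.
#' @export
filter_variants <- function(x, thresholds = filter_thresholds(),
                            mean_depth = NULL,
                            variant_type = c("snp", "indel")) {
  variant_type <- match.arg(variant_type)
  site_status <- filter_sites(x, thresholds, variant_type)
  kept <- subset_variants(x, sites = which(site_status$pass))
  kept <- filter_genotypes(kept, mean_depth, thresholds)
  masks <- attr(kept, "mask_counts")
  bi <- apply_biallelic_rule(kept)
  out <- subset_variants(kept, sites = which(bi$keep))
  summary <- data.frame(
    rule = c("site_hard_filter", "genotype_GQ", "genotype_DP",
             "genotype_AD_ratio", "biallelic_AC_AF"),
    n_removed = c(sum(!site_status$pass), masks[["gq"]], masks[["dp"]],
                  masks[["ad_ratio"]], sum(!bi$keep)))
  list(variants = out, summary = summary, site_status = site_status,
       biallelic_status = bi)
}
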