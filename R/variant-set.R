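#' In-memory set of biallelic SNP sites
#'
#' A `variant_set` holds a cohort of biallelic SNPs in column-per-sample
#' matrix form: diploid genotypes as alternate-allele dosages (0, 1, 2, or
#' `NA` for missing), per-genotype quality (GQ), depth (DP) and allele depths
#' (AD ref/alt), plus the site-level annotations used by hard filtering
#' (QD, FS, SOR, MQ, MQRankSum, QUAL, ReadPosRankSum).
#'
#' Coordinates are 1-based inclusive, as in VCF. Window intervals elsewhere in
#' the package are half-open 0-based `[start, end)`; the conversion happens
#' only at the window-assignment boundary.
#'
#' @param chrom character vector of chromosome names, one per site.
#' @param pos integer vector of 1-based positions.
#' @param ref,alt single-character reference / alternate alleles per site.
#' @param gt integer matrix (sites x samples) of alt-allele dosages in
#'   `{0, 1, 2, NA}`.
#' @param gq,dp integer matrices (sites x samples); `NA` allowed.
#' @param ad_ref,ad_alt integer matrices (sites x samples) of per-genotype
#'   ref/alt read depths; `NA` allowed.
#' @param info data.frame of site annotations with (some of the) columns
#'   `QD`, `FS`, `SOR`, `MQ`, `MQRankSum`, `QUAL`, `ReadPosRankSum`.
#' @param samples character vector of sample identifiers (column order of the
#'   matrices).
#'
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(chrom, pos, ref, alt, gt, gq = NULL, dp = NULL,
                        ad_ref = NULL, ad_alt = NULL, info = NULL,
                        samples = colnames(gt)) {
  n_sites <- length(pos)
  if (length(chrom) != n_sites || length(ref) != n_sites || length(alt) != n_sites)
    stop("chrom, pos, ref, alt must have equal length")
  if (any(pos < 1L, na.rm = TRUE)) stop("positions must be >= 1")
  gt <- as.matrix(gt)
  if (nrow(gt) != n_sites) stop("gt must have one row per site")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(gt)))
  if (length(samples) != ncol(gt)) stop("samples length must equal ncol(gt)")
  bad <- !(gt %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("gt dosages must be 0, 1, 2 or NA")
  blank <- function(m) {
    if (is.null(m)) matrix(NA_integer_, n_sites, length(samples)) else as.matrix(m)
  }
  gq <- blank(gq); dp <- blank(dp); ad_ref <- blank(ad_ref); ad_alt <- blank(ad_alt)
  for (m in list(gq, dp, ad_ref, ad_alt))
    if (!all(dim(m) == dim(gt))) stop("gq/dp/ad matrices must match gt dimensions")
  if (any(ad_ref < 0, na.rm = TRUE) || any(ad_alt < 0, na.rm = TRUE))
    stop("allele depths must be non-negative")
  if (is.null(info)) {
    info <- data.frame(row.names = seq_len(n_sites))
  } else {
    info <- as.data.frame(info)
    if (nrow(info) != n_sites) stop("info must have one row per site")
  }
  dimnames(gt) <- dimnames(gq) <- dimnames(dp) <- dimnames(ad_ref) <-
    dimnames(ad_alt) <- list(NULL, samples)
  structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         gt = gt, gq = gq, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
         info = info, samples = as.character(samples)),
    class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d sites x %d samples on %d chromosome(s)\n",
              n_sites(x), n_samples(x), length(unique(x$chrom))))
  invisible(x)
}

#' Number of sites / samples in a variant_set
#' @param x a `variant_set`.
#' @return integer count.
#' @export
n_sites <- function(x) length(x$pos)

#' @rdname n_sites
#' @export
n_samples <- function(x) length(x$samples)

#' Subset a variant_set by site index and/or sample identifiers
#'
#' @param x a `variant_set`.
#' @param sites integer or logical index over sites (default: all).
#' @param samples character vector of sample ids to keep (default: all).
#' @return a `variant_set`.
#' @export
subset_variants <- function(x, sites = NULL, samples = NULL) {
  if (is.null(sites)) sites <- seq_len(n_sites(x))
  if (is.null(samples)) {
    cols <- seq_len(n_samples(x))
  } else {
    cols <- match(samples, x$samples)
    if (anyNA(cols)) stop("unknown sample(s): ",
                          paste(samples[is.na(cols)], collapse = ", "))
  }
  variant_set(
    chrom = x$chrom[sites], pos = x$pos[sites],
    ref = x$ref[sites], alt = x$alt[sites],
    gt = x$gt[sites, cols, drop = FALSE],
    gq = x$gq[sites, cols, drop = FALSE],
    dp = x$dp[sites, cols, drop = FALSE],
    ad_ref = x$ad_ref[sites, cols, drop = FALSE],
    ad_alt = x$ad_alt[sites, cols, drop = FALSE],
    info = x$info[sites, , drop = FALSE],
    samples = x$samples[cols])
}
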