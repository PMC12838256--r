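#' Call top-quantile outlier windows for both scan statistics
#'
#' Windows in the upper `1 - quantile` tail of the FST and pi-ratio
#' distributions are flagged separately per statistic. The threshold is the
#' empirical quantile (linear interpolation of the empirical CDF,
#' `stats::quantile` type 7) over non-`NA` windows, and a window is an
#' outlier when its statistic is `>= threshold`, so ties at the cutoff are
#' all kept. `NA` windows are never selected. Putative selection signals are
#' the windows outlying in BOTH statistics.
#'
#' @param windows a window-statistic data.frame from [aggregate_windows()].
#' @param snp_positions optional data.frame `chrom`, `pos` of the scanned
#'   SNPs; when given, SNPs falling in outlier windows are reported.
#' @param quantile upper-tail quantile (default 0.99, i.e. top 1%).
#' @return list of class `sweep_region`: `fst_outliers`, `pi_outliers`,
#'   `both_outliers` (window data.frames), `thresholds` (named numeric),
#'   `selected_snps` (list with `fst`, `pi`, `both` position data.frames, if
#'   `snp_positions` given), `quantile`.
#' @export
call_outliers <- function(windows, snp_positions = NULL, quantile = 0.99) {
  if (quantile <= 0 || quantile >= 1) stop("quantile must be in (0, 1)")
  pick <- function(stat) {
    v <- windows[[stat]]
    ok <- !is.na(v)
    if (!any(ok)) stop("no rankable windows for ", stat)
    if (sum(ok) < 100)
      warning("only ", sum(ok), " non-NA windows for ", stat,
              "; quantile threshold is unstable")
    thr <- stats::quantile(v[ok], probs = quantile, names = FALSE, type = 7)
    sel <- ok & v >= thr
    if (all(sel[ok]))
      warning("all ", stat, " windows tie at the threshold; every window selected")
    list(thr = thr, sel = sel)
  }
  f <- pick("fst"); p <- pick("pi_ratio")
  both <- f$sel & p$sel
  snp_in <- function(sel) {
    if (is.null(snp_positions)) return(NULL)
    w <- windows[sel, , drop = FALSE]
    hit <- rep(FALSE, nrow(snp_positions))
    for (i in seq_len(nrow(w)))
      hit <- hit | (snp_positions$chrom == w$chrom[i] &
                      snp_positions$pos - 1L >= w$start[i] &
                      snp_positions$pos - 1L < w$end[i])
    snp_positions[hit, c("chrom", "pos"), drop = FALSE]
  }
  structure(list(
    fst_outliers = windows[f$sel, , drop = FALSE],
    pi_outliers = windows[p$sel, , drop = FALSE],
    both_outliers = windows[both, , drop = FALSE],
    thresholds = c(fst = f$thr, pi_ratio = p$thr),
    selected_snps = if (is.null(snp_positions)) NULL else
      list(fst = snp_in(f$sel), pi = snp_in(p$sel), both = snp_in(both)),
    quantile = quantile), class = "sweep_region")
}

#' @export
print.sweep_region <- function(x, ...) {
  cat(sprintf(
    "sweep_region: %d FST-outlier, %d pi-ratio-outlier, %d shared window(s)\n",
    nrow(x$fst_outliers), nrow(x$pi_outliers), nrow(x$both_outliers)))
  cat(sprintf("thresholds: FST >= %.4g, pi-ratio >= %.4g (top %.3g%%)\n",
              x$thresholds[["fst"]], x$thresholds[["pi_ratio"]],
              100 * (1 - x$quantile)))
  invisible(x)
}

#' Intersect the per-statistic candidate gene sets
#'
#' @param fst_genes,pi_genes character vectors of gene ids flagged by the
#'   FST and pi-ratio scans (from [genes_near_snps()]).
#' @return list: `shared` (intersection, sorted), `fst_only`, `pi_only`, and
#'   `counts` (named integer vector `fst`, `pi`, `shared`, `fst_only`,
#'   `pi_only` — the three-part Venn breakdown).
#' @export
intersect_candidates <- function(fst_genes, pi_genes) {
  fst_genes <- unique(fst_genes); pi_genes <- unique(pi_genes)
  shared <- sort(intersect(fst_genes, pi_genes))
  if (length(shared) == 0 && (length(fst_genes) > 0 || length(pi_genes) > 0))
    warning("candidate gene sets are disjoint")
  list(shared = shared,
       fst_only = sort(setdiff(fst_genes, pi_genes)),
       pi_only = sort(setdiff(pi_genes, fst_genes)),
       counts = c(fst = length(fst_genes), pi = length(pi_genes),
                  shared = length(shared),
                  fst_only = length(setdiff(fst_genes, pi_genes)),
                  pi_only = length(setdiff(pi_genes, fst_genes))))
}
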