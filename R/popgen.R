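#' Per-site Weir-Cockerham variance components and nucleotide diversity
#'
#' For two populations (r = 2) with n_i called diploids, alternate-allele
#' frequency p_i and observed heterozygote proportion h_i in population i,
#' computes the Weir-Cockerham variance components
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}\left(\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{\bar h}{4}\right)\right]}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) - \frac{r-1}{r}s^2 - \frac{2\bar n - 1}{4\bar n}\bar h\right], \quad c = \bar h / 2}
#' with \eqn{\bar n = \sum n_i / r},
#' \eqn{n_c = (r\bar n - \sum n_i^2/(r\bar n)) / (r-1)},
#' \eqn{\bar p = \sum n_i p_i / (r \bar n)},
#' \eqn{s^2 = \sum n_i (p_i - \bar p)^2 / ((r-1)\bar n)} and
#' \eqn{\bar h = \sum n_i h_i / (r \bar n)}. The per-site estimate is
#' \eqn{\theta = a/(a+b+c)}; windowed scans use the ratio of sums instead.
#'
#' Per-site nucleotide diversity per population is the unbiased
#' \eqn{\pi = \frac{m}{m-1} 2 p (1-p)} with `m = 2 * n_called` allele copies
#' (equal to the mean pairwise difference over all C(m,2) haplotype pairs).
#'
#' Sites with fewer than 2 called diploids in either population get `NA`
#' components (and are skipped in window aggregation); \eqn{\pi} for a
#' population needs `m >= 2`.
#'
#' @param x a [variant_set()] of biallelic SNPs (typically after filtering).
#' @param case_ids,control_ids sample identifiers of the two populations.
#' @return data.frame of class `site_components`: `chrom`, `pos`, `a`, `b`,
#'   `c`, `theta` (per-site a/(a+b+c), `NA` when the denominator is <= 0),
#'   `pi_case`, `pi_control`, `n_case_called`, `n_control_called`.
#' @export
site_components <- function(x, case_ids, control_ids) {
  stopifnot(inherits(x, "variant_set"))
  if (length(intersect(case_ids, control_ids)) > 0)
    stop("case and control sample sets overlap")
  pop_stats <- function(ids) {
    cols <- match(ids, x$samples)
    if (anyNA(cols)) stop("unknown sample(s): ",
                          paste(ids[is.na(cols)], collapse = ", "))
    g <- x$gt[, cols, drop = FALSE]
    n <- rowSums(!is.na(g))
    ac <- rowSums(g, na.rm = TRUE)
    list(n = n, p = ifelse(n > 0, ac / (2 * n), NA_real_),
         h = ifelse(n > 0, rowSums(g == 1L, na.rm = TRUE) / n, NA_real_))
  }
  ca <- pop_stats(case_ids); co <- pop_stats(control_ids)
  ok <- ca$n >= 2 & co$n >= 2
  r <- 2
  nbar <- (ca$n + co$n) / r
  nc <- (r * nbar - (ca$n^2 + co$n^2) / (r * nbar)) / (r - 1)
  pbar <- (ca$n * ca$p + co$n * co$p) / (r * nbar)
  s2 <- (ca$n * (ca$p - pbar)^2 + co$n * (co$p - pbar)^2) / ((r - 1) * nbar)
  hbar <- (ca$n * ca$h + co$n * co$h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
                                hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) *
       hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_; b[!ok] <- NA_real_; cc[!ok] <- NA_real_
  denom <- a + b + cc
  theta <- ifelse(!is.na(denom) & denom > 0, a / denom, NA_real_)
  pi_pop <- function(st) {
    m <- 2 * st$n
    ifelse(m >= 2, (m / (m - 1)) * 2 * st$p * (1 - st$p), NA_real_)
  }
  structure(
    data.frame(chrom = x$chrom, pos = x$pos, a = a, b = b, c = cc,
               theta = theta, pi_case = pi_pop(ca), pi_control = pi_pop(co),
               n_case_called = ca$n, n_control_called = co$n,
               stringsAsFactors = FALSE),
    class = c("site_components", "data.frame"))
}

#' Build a sliding-window grid
#'
#' Windows are half-open `[start, end)` intervals in bp, tiling each
#' chromosome from 0 with the given stride. A final partial window (stride
#' past the last full window, truncated at the chromosome end) is emitted iff
#' it covers at least 1 bp beyond the last full window, and is flagged
#' `partial`.
#'
#' @param chrom_lengths named integer vector of chromosome lengths in bp.
#' @param window_bp window size (default 100000).
#' @param step_bp stride (default 50000).
#' @return data.frame: `chrom`, `start`, `end`, `partial`.
#' @export
make_windows <- function(chrom_lengths, window_bp = 100000,
                         step_bp = 50000) {
  if (window_bp <= 0 || step_bp <= 0)
    stop("window_bp and step_bp must be positive")
  if (is.null(names(chrom_lengths)))
    stop("chrom_lengths must be named by chromosome")
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    if (len < window_bp)
      stop("chromosome ", ch, " shorter than one window")
    full_starts <- seq(0, len - window_bp, by = step_bp)
    w <- data.frame(chrom = ch, start = full_starts,
                    end = full_starts + window_bp, partial = FALSE)
    last_full_end <- max(w$end)
    if (last_full_end < len) {
      ps <- max(full_starts) + step_bp
      w <- rbind(w, data.frame(chrom = ch, start = ps, end = len,
                               partial = TRUE))
    }
    w
  })
  out <- do.call(rbind, out)
  out$start <- as.integer(out$start); out$end <- as.integer(out$end)
  rownames(out) <- NULL
  out
}

#' Aggregate per-site components into window statistics
#'
#' Each SNP contributes to every window overlapping it (two for the default
#' 100 kb / 50 kb grid). Window FST is the ratio of sums
#' `sum(a) / sum(a + b + c)` over the window's informative SNPs (`NA` when
#' the denominator is <= 0 or no SNPs); window \eqn{\pi} per population is
#' the sum of per-site \eqn{\pi} divided by the window span in bp; the
#' default `pi_ratio` is `pi_control / pi_case` so that large values flag
#' diversity loss in cases (set `invert_pi_ratio = TRUE` for the opposite
#' convention). Negative per-site components are retained in the sums.
#'
#' @param comp a `site_components` data.frame, sorted by chrom then pos.
#' @param windows a window grid from [make_windows()] (regular `step_bp`
#'   stride assumed).
#' @param step_bp the stride the grid was built with.
#' @param invert_pi_ratio if `TRUE`, report `pi_case / pi_control`.
#' @return data.frame: `chrom`, `start`, `end`, `partial`, `n_snps`, `fst`,
#'   `pi_case`, `pi_control`, `pi_ratio`.
#' @export
aggregate_windows <- function(comp, windows, step_bp = 50000,
                              invert_pi_ratio = FALSE) {
  ord <- order(comp$chrom, comp$pos)
  if (any(ord != seq_len(nrow(comp))) &&
      any(comp$chrom != comp$chrom[ord] | comp$pos != comp$pos[ord]))
    stop("site components must be sorted by chrom, pos")
  step_bp <- as.integer(step_bp)
  window_bp <- max(windows$end - windows$start)
  n_over <- ceiling(window_bp / step_bp)
  wkey <- paste(windows$chrom, as.integer(windows$start))
  x0 <- comp$pos - 1L  # 0-based coordinate for half-open window arithmetic
  k_hi <- (x0 %/% step_bp) * step_bp
  acc <- list()
  for (j in seq_len(n_over) - 1L) {
    s <- k_hi - j * step_bp  # integer arithmetic: keys must not go scientific
    idx <- match(paste(comp$chrom, s), wkey)
    keep <- !is.na(idx) & s >= 0 & x0 >= s & x0 < windows$end[idx] &
      (x0 - s) < window_bp
    acc[[j + 1L]] <- data.frame(site = which(keep), win = idx[keep])
  }
  pairs <- do.call(rbind, acc)
  zero <- numeric(nrow(windows))
  agg <- function(v, sites, wins) {
    ok <- !is.na(v[sites])
    out <- zero
    if (any(ok)) {
      t <- rowsum(v[sites][ok], wins[ok])
      out[as.integer(rownames(t))] <- t[, 1]
    }
    out
  }
  informative <- !is.na(comp$a)
  n_snps <- agg(as.numeric(informative), pairs$site, pairs$win)
  sum_a <- agg(ifelse(informative, comp$a, NA), pairs$site, pairs$win)
  sum_abc <- agg(ifelse(informative, comp$a + comp$b + comp$c, NA),
                 pairs$site, pairs$win)
  sum_pi_ca <- agg(comp$pi_case, pairs$site, pairs$win)
  sum_pi_co <- agg(comp$pi_control, pairs$site, pairs$win)
  span <- windows$end - windows$start
  fst <- ifelse(n_snps > 0 & sum_abc > 0, sum_a / sum_abc, NA_real_)
  pi_case <- sum_pi_ca / span
  pi_control <- sum_pi_co / span
  num <- if (invert_pi_ratio) pi_case else pi_control
  den <- if (invert_pi_ratio) pi_control else pi_case
  pi_ratio <- ifelse(den > 0, num / den, NA_real_)
  data.frame(chrom = windows$chrom, start = windows$start,
             end = windows$end, partial = windows$partial,
             n_snps = as.integer(n_snps), fst = fst, pi_case = pi_case,
             pi_control = pi_control, pi_ratio = pi_ratio,
             stringsAsFactors = FALSE)
}

#' One-call windowed scan
#'
#' Convenience wrapper: per-site components, window grid, aggregation.
#'
#' @inheritParams site_components
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @inheritParams aggregate_windows
#' @param window_bp,step_bp window size and stride in bp.
#' @return a window-statistic data.frame (see [aggregate_windows()]).
#' @export
window_scan <- function(x, case_ids, control_ids, chrom_lengths,
                        window_bp = 100000, step_bp = 50000,
                        invert_pi_ratio = FALSE) {
  comp <- site_components(x, case_ids, control_ids)
  w <- make_windows(chrom_lengths, window_bp, step_bp)
  aggregate_windows(comp, w, step_bp = step_bp,
                    invert_pi_ratio = invert_pi_ratio)
}

#' Genome-wide ratio-of-sums summaries
#'
#' @param comp a `site_components` data.frame.
#' @return named list: `fst` (sum(a)/sum(a+b+c) over informative sites) and
#'   `pi_ratio` (sum(pi_control)/sum(pi_case)).
#' @export
genomewide_summary <- function(comp) {
  ok <- !is.na(comp$a)
  list(fst = sum(comp$a[ok]) / sum(comp$a[ok] + comp$b[ok] + comp$c[ok]),
       pi_ratio = sum(comp$pi_control, na.rm = TRUE) /
         sum(comp$pi_case, na.rm = TRUE))
}
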