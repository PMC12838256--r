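#' Case down-sampling concordance
#'
#' Addresses case/control imbalance: each iteration draws `n_target` cases
#' uniformly without replacement, recomputes the windowed scan on the same
#' window grid, and measures concordance with the full-data scan as (i)
#' Spearman rank correlation per statistic over windows non-`NA` in both
#' runs, and (ii) top-quantile outlier-window overlap per statistic, as both
#' Jaccard index and recall of the full-data outlier set. Deterministic
#' given `seed`.
#'
#' @inheritParams window_scan
#' @param n_target cases drawn per iteration (default 30, matching the
#'   control count the procedure was designed around).
#' @param iterations number of resampling iterations (default 100).
#' @param seed integer RNG seed.
#' @param quantile outlier quantile (default 0.99).
#' @return list of class `downsample_report`: `iterations` (data.frame with
#'   per-iteration `rho_fst`, `rho_pi`, `jaccard_fst`, `recall_fst`,
#'   `jaccard_pi`, `recall_pi`), `summary` (mean and 2.5%/97.5% percentiles
#'   per metric), `full` (the full-data window table), `n_target`, `seed`.
#' @export
downsample_concordance <- function(x, case_ids, control_ids, chrom_lengths,
                                   n_target = 30, iterations = 100,
                                   seed = 1L, window_bp = 100000,
                                   step_bp = 50000, quantile = 0.99) {
  if (n_target > length(case_ids))
    stop("n_target exceeds the number of cases")
  full <- window_scan(x, case_ids, control_ids, chrom_lengths,
                      window_bp, step_bp)
  full_out <- call_outliers(full, quantile = quantile)
  wid <- function(w) paste(w$chrom, w$start)
  full_sets <- list(fst = wid(full_out$fst_outliers),
                    pi = wid(full_out$pi_outliers))
  spearman <- function(u, v) {
    ok <- !is.na(u) & !is.na(v)
    if (sum(ok) < 3 || stats::sd(u[ok]) == 0 || stats::sd(v[ok]) == 0) {
      warning("constant or insufficient window statistics; Spearman rho undefined")
      return(NA_real_)
    }
    stats::cor(u[ok], v[ok], method = "spearman")
  }
  overlap <- function(sub_set, full_set) {
    c(jaccard = length(intersect(sub_set, full_set)) /
        max(1L, length(union(sub_set, full_set))),
      recall = if (length(full_set) == 0) NA_real_ else
        length(intersect(sub_set, full_set)) / length(full_set))
  }
  iters <- withr::with_seed(seed, {
    do.call(rbind, lapply(seq_len(iterations), function(i) {
      sub_cases <- sample(case_ids, n_target)
      sub <- window_scan(x, sub_cases, control_ids, chrom_lengths,
                         window_bp, step_bp)
      sub_out <- suppressWarnings(call_outliers(sub, quantile = quantile))
      o_f <- overlap(wid(sub_out$fst_outliers), full_sets$fst)
      o_p <- overlap(wid(sub_out$pi_outliers), full_sets$pi)
      data.frame(iteration = i,
                 rho_fst = spearman(full$fst, sub$fst),
                 rho_pi = spearman(full$pi_ratio, sub$pi_ratio),
                 jaccard_fst = o_f[["jaccard"]], recall_fst = o_f[["recall"]],
                 jaccard_pi = o_p[["jaccard"]], recall_pi = o_p[["recall"]])
    }))
  })
  metrics <- setdiff(names(iters), "iteration")
  summary <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(iters[[m]], na.rm = TRUE), 0),
    q025 = vapply(metrics, function(m)
      unname(stats::quantile(iters[[m]], 0.025, na.rm = TRUE)), 0),
    q975 = vapply(metrics, function(m)
      unname(stats::quantile(iters[[m]], 0.975, na.rm = TRUE)), 0),
    row.names = NULL)
  structure(list(iterations = iters, summary = summary, full = full,
                 n_target = n_target, seed = seed),
            class = "downsample_report")
}

#' @export
print.downsample_report <- function(x, ...) {
  cat(sprintf("downsample_report: %d iterations at n_target = %d\n",
              nrow(x$iterations), x$n_target))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Chromosome-wise block-jackknife for genome-wide summaries
#'
#' Partitions each chromosome into contiguous blocks of `block_bp`
#' (default 200 kb), computes delete-one-block estimates of a genome-wide
#' statistic, and returns the jackknife standard error
#' \deqn{SE^2 = \frac{B-1}{B} \sum_j (\hat\theta_{(-j)} - \hat\theta_{(.)})^2}
#' with the normal-approximation 95% CI `estimate +/- 1.96 * SE`. Because a
#' 200 kb block spans more than one 100 kb window, the jackknife targets
#' genome-wide summaries (ratio-of-sums FST, genome-wide pi-ratio, or any
#' user statistic of the site components), not individual windows.
#'
#' @param comp a `site_components` data.frame from [site_components()].
#' @param statistic `"fst"` (genome-wide `sum(a)/sum(a+b+c)`), `"pi_ratio"`
#'   (genome-wide `sum(pi_control)/sum(pi_case)`), or a function taking a
#'   `site_components` subset and returning a single number.
#' @param block_bp block length in bp (default 200000).
#' @param conf_level confidence level (default 0.95; multiplier 1.96).
#' @return list of class `jackknife_report`: `statistic`, `estimate`, `se`,
#'   `ci_lower`, `ci_upper`, `n_blocks`.
#' @export
block_jackknife <- function(comp, statistic = c("fst", "pi_ratio"),
                            block_bp = 200000, conf_level = 0.95) {
  if (is.function(statistic)) {
    stat_fun <- statistic
    stat_name <- "custom"
  } else {
    stat_name <- match.arg(statistic)
    stat_fun <- function(d) genomewide_summary(d)[[stat_name]]
  }
  block <- paste(comp$chrom, (comp$pos - 1L) %/% as.integer(block_bp))
  blocks <- unique(block)
  b <- length(blocks)
  if (b < 2) stop("need >= 2 non-empty blocks")
  estimate <- stat_fun(comp)
  loo <- vapply(blocks, function(bl)
    stat_fun(comp[block != bl, , drop = FALSE]), numeric(1))
  se <- sqrt(((b - 1) / b) * sum((loo - mean(loo))^2))
  z <- round(stats::qnorm(1 - (1 - conf_level) / 2), 2)
  structure(list(statistic = stat_name, estimate = estimate, se = se,
                 ci_lower = estimate - z * se, ci_upper = estimate + z * se,
                 n_blocks = b),
            class = "jackknife_report")
}

#' @export
print.jackknife_report <- function(x, ...) {
  cat(sprintf("block-jackknife (%d blocks): %s = %.5g, SE = %.3g, 95%% CI [%.5g, %.5g]\n",
              x$n_blocks, x$statistic, x$estimate, x$se, x$ci_lower,
              x$ci_upper))
  invisible(x)
}
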