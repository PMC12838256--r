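#' Candidate genes within a flank of selected SNPs
#'
#' A gene is a candidate iff some selected SNP on the same chromosome lies
#' within `flank_bp` of the gene interval, distance being 0 inside
#' `[start, end]` and `min(|pos - start|, |pos - end|)` outside — i.e. the
#' "within +/- 50 kb of SNPs under selection" rule, inclusive at exactly
#' `flank_bp` and measured from the gene boundaries (not the midpoint).
#' Strand is ignored. Overlap queries run on \pkg{IRanges} interval trees.
#'
#' @param selected_snps data.frame `chrom`, `pos` (1-based) of SNPs under
#'   selection.
#' @param genes gene table from [read_gff_genes()] (`gene_id`, `chrom`,
#'   `start`, `end`, 1-based inclusive).
#' @param flank_bp flank distance in bp (default 50000).
#' @param chrom_allow optional chromosome allow-list (e.g. autosomes only);
#'   SNPs and genes elsewhere are dropped before matching.
#' @return data.frame of candidate genes: `gene_id`, `chrom`, `start`,
#'   `end`, `n_support_snps` (selected SNPs within the flank).
#' @export
genes_near_snps <- function(selected_snps, genes, flank_bp = 50000,
                            chrom_allow = NULL) {
  if (flank_bp < 0) stop("flank_bp must be >= 0")
  if (!is.null(chrom_allow)) {
    selected_snps <- selected_snps[selected_snps$chrom %in% chrom_allow, ,
                                   drop = FALSE]
    genes <- genes[genes$chrom %in% chrom_allow, , drop = FALSE]
  }
  if (nrow(selected_snps) == 0 || nrow(genes) == 0)
    return(data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      n_support_snps = integer()))
  unmatched <- setdiff(unique(selected_snps$chrom), unique(genes$chrom))
  if (length(unmatched) == length(unique(selected_snps$chrom)))
    stop("no gene chromosome matches any SNP chromosome; unmatched: ",
         paste(unmatched, collapse = ", "))
  hits <- integer(nrow(genes))
  for (ch in intersect(unique(genes$chrom), unique(selected_snps$chrom))) {
    gi <- which(genes$chrom == ch)
    sp <- selected_snps$pos[selected_snps$chrom == ch]
    q <- IRanges::IRanges(start = genes$start[gi] - flank_bp,
                          end = genes$end[gi] + flank_bp)
    s <- IRanges::IRanges(start = sp, width = 1L)
    ov <- IRanges::countOverlaps(q, s)
    hits[gi] <- hits[gi] + ov
  }
  out <- genes[hits > 0, c("gene_id", "chrom", "start", "end"), drop = FALSE]
  out$n_support_snps <- hits[hits > 0]
  rownames(out) <- NULL
  out
}
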