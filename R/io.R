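#' Write a variant_set as a VCF v4.2 file
#'
#' Emits plain-text VCF with `FORMAT GT:AD:DP:GQ` and the site annotations as
#' INFO keys `QD,FS,SOR,MQ,MQRankSum,RPRS` (ReadPosRankSum is written under
#' the key `RPRS`); the `QUAL` annotation fills the QUAL column. Output is a
#' pure function of the input, so identical variant sets give byte-identical
#' files.
#'
#' @param x a [variant_set()].
#' @param path output file path.
#' @param contig_lengths optional named integer vector of chromosome lengths
#'   for `##contig` header lines.
#' @return (invisibly) `path`.
#' @export
write_vcf <- function(x, path, contig_lengths = NULL) {
  stopifnot(inherits(x, "variant_set"))
  num <- function(v) ifelse(is.na(v), ".", sprintf("%.2f", v))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=sweepscan")
  if (!is.null(contig_lengths))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  info_keys <- c(QD = "QD", FS = "FS", SOR = "SOR", MQ = "MQ",
                 MQRankSum = "MQRankSum", ReadPosRankSum = "RPRS")
  present <- intersect(names(info_keys), names(x$info))
  hdr <- c(hdr,
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   info_keys[present], present),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allele depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", x$samples), collapse = "\t"))
  info_str <- if (length(present) == 0) rep(".", n_sites(x)) else {
    parts <- lapply(present, function(k)
      ifelse(is.na(x$info[[k]]), NA_character_,
             paste0(info_keys[[k]], "=", num(x$info[[k]]))))
    apply(do.call(cbind, parts), 1, function(r)
      if (all(is.na(r))) "." else paste(r[!is.na(r)], collapse = ";"))
  }
  qual <- if ("QUAL" %in% names(x$info)) num(x$info$QUAL) else
    rep(".", n_sites(x))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[x$gt + 1L], nrow = n_sites(x))
  gt_str[is.na(x$gt)] <- "./."
  ad_str <- matrix(paste0(x$ad_ref, ",", x$ad_alt), nrow = n_sites(x))
  ad_str[is.na(x$ad_ref) | is.na(x$ad_alt)] <- "."
  dp_str <- matrix(as.character(x$dp), nrow = n_sites(x))
  dp_str[is.na(x$dp)] <- "."
  gq_str <- matrix(as.character(x$gq), nrow = n_sites(x))
  gq_str[is.na(x$gq)] <- "."
  field <- matrix(paste(gt_str, ad_str, dp_str, gq_str, sep = ":"),
                  nrow = n_sites(x))
  cols <- c(list(x$chrom, x$pos, ".", x$ref, x$alt, qual, "PASS", info_str,
                 "GT:AD:DP:GQ"),
            lapply(seq_len(n_samples(x)), function(j) field[, j]),
            list(sep = "\t"))
  body <- do.call(paste, cols)
  con <- file(path, "wb")  # binary mode: LF line endings on any platform
  on.exit(close(con))
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Read a VCF into a variant_set
#'
#' Parses a (plain or gzipped) VCF via \pkg{vcfR}, keeping the FORMAT keys
#' GT/AD/DP/GQ and the INFO keys QD, FS, SOR, MQ, MQRankSum and
#' RPRS/ReadPosRankSum. Missing FORMAT or INFO keys yield `NA` values, not
#' errors; genotypes `./.` (or containing any allele other than 0/1) become
#' missing dosages.
#'
#' @param path VCF file path.
#' @param sample_subset optional character vector of sample ids to keep; an
#'   unknown id is an error.
#' @return a [variant_set()].
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n <- nrow(fix)
  grab <- function(element, as_num = TRUE) {
    out <- tryCatch(
      vcfR::extract.gt(v, element = element, as.numeric = as_num),
      error = function(e) NULL)
    if (is.null(out)) matrix(NA_integer_, n, length(colnames(v@gt)) - 1L)
    else out
  }
  gt_raw <- grab("GT", as_num = FALSE)
  lut <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
           "1|0" = 1L, "1/1" = 2L, "1|1" = 2L)
  gt <- matrix(unname(lut[gt_raw]), nrow = n)
  dp <- grab("DP"); gq <- grab("GQ")
  ad_raw <- grab("AD", as_num = FALSE)
  ad_ref <- suppressWarnings(
    matrix(as.integer(sub(",.*", "", ad_raw)), nrow = n))
  ad_alt <- suppressWarnings(
    matrix(as.integer(sub("^[^,]*,", "", ad_raw)), nrow = n))
  info_spec <- c(QD = "QD", FS = "FS", SOR = "SOR", MQ = "MQ",
                 MQRankSum = "MQRankSum", ReadPosRankSum = "RPRS")
  info <- data.frame(row.names = seq_len(n))
  for (k in names(info_spec)) {
    val <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = info_spec[[k]])))
    if (length(val) == n && !all(is.na(val))) info[[k]] <- val
  }
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  if (!all(is.na(qual))) info$QUAL <- qual
  samples <- colnames(v@gt)[-1]
  vs <- variant_set(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    gt = gt, gq = gq, dp = dp, ad_ref = ad_ref, ad_alt = ad_alt,
    info = info, samples = samples)
  if (!is.null(sample_subset)) vs <- subset_variants(vs, samples = sample_subset)
  vs
}

#' Read gene records from a GFF3 file
#'
#' Returns only features of type `gene`, with 1-based inclusive coordinates
#' as in the file. Features lacking an `ID` attribute are skipped with a
#' warning.
#'
#' @param path GFF3 file path.
#' @return data.frame: `gene_id`, `chrom`, `start`, `end`.
#' @export
read_gff_genes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  empty <- data.frame(gene_id = character(), chrom = character(),
                      start = integer(), end = integer())
  raw <- readLines(path)
  if (!any(!grepl("^#", raw) & nzchar(raw))) return(empty)
  g <- ape::read.gff(path)
  g <- g[g$type == "gene", , drop = FALSE]
  if (nrow(g) == 0) return(empty)
  has_id <- grepl("(^|;)\\s*ID=", g$attributes)
  if (any(!has_id)) {
    warning(sum(!has_id), " gene feature(s) without ID attribute skipped")
    g <- g[has_id, , drop = FALSE]
  }
  ids <- sub(".*?(^|;)\\s*ID=([^;]+).*", "\\2", g$attributes)
  out <- data.frame(gene_id = ids, chrom = as.character(g$seqid),
                    start = as.integer(g$start), end = as.integer(g$end))
  if (any(out$start > out$end)) stop("gene with start > end in ", path)
  rownames(out) <- NULL
  out
}

# GFF3 writer for the synthetic annotation (gene + one mRNA child per gene,
# so type filtering is exercised on read).
write_gff_genes <- function(genes, path) {
  gene_lines <- sprintf("%s\tsweepscan\tgene\t%d\t%d\t.\t+\t.\tID=%s;role=%s",
                        genes$chrom, genes$start, genes$end, genes$gene_id,
                        genes$role)
  mrna_lines <- sprintf("%s\tsweepscan\tmRNA\t%d\t%d\t.\t+\t.\tID=%s.t1;Parent=%s",
                        genes$chrom, genes$start, genes$end, genes$gene_id,
                        genes$gene_id)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("##gff-version 3", as.vector(rbind(gene_lines, mrna_lines))),
             con, sep = "\n")
  invisible(path)
}

#' Read / write a window-statistic table
#'
#' TSV with columns `chrom`, `start`, `end`, `n_snps`, `fst`, `pi_case`,
#' `pi_control`, `pi_ratio` (windows half-open `[start, end)` in bp).
#' Numeric values round-trip to 10 significant digits; undefined statistics
#' are serialized as `NA`.
#'
#' @param stats window table as returned by [aggregate_windows()].
#' @param path file path.
#' @return `read_window_table` returns the data.frame; `write_window_table`
#'   returns `path` invisibly.
#' @export
write_window_table <- function(stats, path) {
  cols <- c("chrom", "start", "end", "n_snps", "fst", "pi_case",
            "pi_control", "pi_ratio")
  stopifnot(all(cols %in% names(stats)))
  out <- stats[, cols]
  for (k in c("fst", "pi_case", "pi_control", "pi_ratio"))
    out[[k]] <- ifelse(is.na(out[[k]]), "NA", sprintf("%.10g", out[[k]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_table
#' @export
read_window_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(chrom = "character"))
  for (k in c("start", "end", "n_snps"))
    if (k %in% names(tab)) tab[[k]] <- as.integer(tab[[k]])
  for (k in c("fst", "pi_case", "pi_control", "pi_ratio"))
    if (k %in% names(tab)) tab[[k]] <- suppressWarnings(as.numeric(tab[[k]]))
  tab
}

#' Read a sample list (one id per line)
#' @param path text file path.
#' @return character vector of ids (blank lines dropped).
#' @export
read_sample_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' Read a phenotype table (TSV)
#' @param path TSV with columns `individual_id`, `group`, then traits.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("individual_id", "group") %in% names(tab)))
    stop("phenotype table needs columns individual_id and group")
  tab
}

#' Read a gene-to-term map (two-column TSV: gene_id, term_id)
#' @param path TSV file path.
#' @return data.frame with columns `gene_id`, `term_id`.
#' @export
read_term_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(tab)))
    stop("term map needs columns gene_id and term_id")
  tab[, c("gene_id", "term_id")]
}

#' Load a simulation configuration from YAML
#'
#' Keys mirror the arguments of [simulation_config()]; `sweep_regions` is a
#' sequence of maps with keys `chrom`, `start_bp`, `end_bp`, `sweep_fst`,
#' `case_diversity_factor`.
#'
#' @param path YAML file path.
#' @return a validated [simulation_config()].
#' @export
read_simulation_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  if (!is.null(y$sweep_regions))
    y$sweep_regions <- do.call(rbind, lapply(y$sweep_regions, as.data.frame))
  do.call(simulation_config, y)
}
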