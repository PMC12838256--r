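#' Hypergeometric over-representation analysis
#'
#' For each annotation term, tests whether the candidate gene set contains
#' more genes carrying the term than expected under random sampling from the
#' universe: upper-tail hypergeometric `p = P(X >= k)` with `k` candidate
#' genes carrying the term, `K` universe genes carrying it, `n` candidates
#' and `N` universe genes, followed by Benjamini-Hochberg adjustment across
#' all tested terms, with `adjusted p < alpha` flagged significant. Terms
#' with zero candidate overlap are excluded from the tested family (the
#' usual over-representation-tool convention; this affects the adjusted
#' p-values and is deliberate).
#'
#' @param candidates character vector of candidate gene ids; must be a
#'   subset of `universe`.
#' @param term_map data.frame `gene_id`, `term_id`.
#' @param universe background gene set; defaults to all genes in `term_map`.
#' @param alpha significance level on the adjusted p (default 0.05).
#' @return data.frame sorted by p-value: `term_id`, `k`, `K`, `n`, `N`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
overrepresentation <- function(candidates, term_map, universe = NULL,
                               alpha = 0.05) {
  candidates <- unique(candidates)
  if (is.null(universe)) universe <- unique(term_map$gene_id)
  universe <- unique(universe)
  missing <- setdiff(candidates, universe)
  if (length(missing) > 0)
    stop("candidate gene(s) absent from universe: ",
         paste(missing, collapse = ", "))
  term_map <- term_map[term_map$gene_id %in% universe, , drop = FALSE]
  term_map <- unique(term_map[, c("gene_id", "term_id")])
  n <- length(candidates); N <- length(universe)
  by_term <- split(term_map$gene_id, term_map$term_id)
  res <- do.call(rbind, lapply(names(by_term), function(term) {
    tg <- by_term[[term]]
    k <- length(intersect(candidates, tg))
    if (k == 0) return(NULL)
    K <- length(tg)
    data.frame(term_id = term, k = k, K = K, n = n, N = N,
               p_value = stats::phyper(k - 1, K, N - K, n,
                                       lower.tail = FALSE))
  }))
  if (is.null(res))
    return(data.frame(term_id = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p_value = numeric(),
                      p_adjusted = numeric(), significant = logical()))
  res$p_adjusted <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$p_adjusted < alpha
  res <- res[order(res$p_value, res$term_id), ]
  rownames(res) <- NULL
  res
}
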