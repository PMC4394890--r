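#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric upper-tail test per term set: the probability of
#' observing at least the seen overlap between the query and the term, given
#' the universe. Query symbols outside the universe are dropped with a
#' warning; term sets are intersected with the universe. No multiple-testing
#' correction is applied by default (a raw alpha cutoff); set `bh = TRUE`
#' to add Benjamini-Hochberg adjusted p-values, in which case significance
#' is called on the adjusted values.
#'
#' @param query character vector of query symbols (e.g. network genes).
#' @param term_sets named list of character vectors (see [read_gene_sets()]).
#' @param universe background symbol set; must be non-empty.
#' @param alpha significance cutoff on the p-value (default 0.01).
#' @param bh apply Benjamini-Hochberg adjustment (default FALSE).
#' @return data.frame with columns term, overlap, term_size, query_size,
#'   p_value, significant (and p_adjust when `bh`), sorted by ascending
#'   p-value with ties broken by term name.
#' @export
hypergeometric_enrichment <- function(query, term_sets, universe,
                                      alpha = 0.01, bh = FALSE) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("configuration error: empty universe")
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0L) {
    warning(length(outside), " query symbol(s) outside the universe dropped: ",
            paste(utils::head(outside, 5L), collapse = ", "))
    query <- intersect(query, universe)
  }
  N <- length(universe)
  k <- length(query)
  terms <- lapply(term_sets, function(s) intersect(unique(s), universe))
  m <- lengths(terms)
  ov <- vapply(terms, function(s) length(intersect(s, query)), integer(1))
  # P(X >= ov) for X ~ Hypergeometric(m, N - m, k)
  p <- stats::phyper(ov - 1L, m, N - m, k, lower.tail = FALSE)
  out <- data.frame(term = names(term_sets) %||% character(),
                    overlap = ov, term_size = m, query_size = k,
                    p_value = p, stringsAsFactors = FALSE, row.names = NULL)
  if (bh) {
    out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
    out$significant <- out$p_adjust < alpha
  } else {
    out$significant <- out$p_value < alpha
  }
  out <- out[radix_order(out$p_value, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}
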