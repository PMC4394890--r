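# Disease-recurrence stage: re-filter a differential-expression table at a
# stricter cutoff, form FFLs from the DE genes and DE TFs together with the
# disease miRNAs, and annotate the resulting network with expression
# direction.

#' Filter a differential-expression table
#'
#' Keeps genes with `p_value` strictly below the cutoff (the stricter
#' re-filter applied to move from a 0.05 screen to a 0.01 gene list),
#' preserving the up/down direction.
#'
#' @param de data.frame with columns gene, p_value, direction
#'   (see [read_de_table()]).
#' @param p_cutoff strict upper bound on p, in (0, 1]; default 0.01.
#' @return data.frame of the retained rows; the direction map is available
#'   as `setNames(out$direction, out$gene)`.
#' @export
filter_de <- function(de, p_cutoff = 0.01) {
  stopifnot(is.data.frame(de),
            all(c("gene", "p_value", "direction") %in% names(de)))
  if (!(p_cutoff > 0 && p_cutoff <= 1)) stop("p_cutoff must be in (0, 1]")
  bad <- is.na(de$p_value) | de$p_value < 0 | de$p_value > 1
  if (any(bad)) {
    stop("format error: p_value outside [0, 1] at row ", which(bad)[1])
  }
  out <- de[de$p_value < p_cutoff, , drop = FALSE]
  rownames(out) <- NULL
  ffl_log("filter_de: %d genes in, %d below p < %g", nrow(de), nrow(out),
          p_cutoff)
  out
}

#' Build the recurrence co-regulatory network
#'
#' Enumerates FFLs among the differentially expressed genes, the
#' differentially expressed TFs and the disease miRNAs, assembles the FFL
#' network (feedback loops are excluded at this stage) and annotates every
#' gene node with its expression direction. The DE TFs are taken verbatim as
#' a separate list rather than re-derived from the DE table, since they are
#' typically called at a looser screening cutoff than the gene list.
#'
#' @param de_genes data.frame from [filter_de()] (gene, p_value, direction)
#'   or a character vector of gene symbols (then no direction is annotated
#'   unless `direction` is given).
#' @param de_tfs character vector of differentially expressed TF symbols.
#' @param mirnas character vector of disease miRNA symbols.
#' @param reg a `regulatory_set` whose target maps cover the inputs.
#' @param direction optional named character vector gene -> "up"/"down",
#'   overriding or supplementing the table's direction column.
#' @return list with elements `network` (a [coreg_network()] whose node
#'   table has a `direction` column) and `ffls` (the `ffl_table`).
#' @export
build_recurrence_network <- function(de_genes, de_tfs, mirnas, reg,
                                     direction = NULL) {
  stopifnot(inherits(reg, "regulatory_set"))
  if (is.data.frame(de_genes)) {
    dir_map <- stats::setNames(de_genes$direction, de_genes$gene)
    gene_syms <- unique(de_genes$gene)
  } else {
    dir_map <- character(0)
    gene_syms <- unique(as.character(de_genes))
  }
  if (!is.null(direction)) dir_map[names(direction)] <- direction
  cat <- catalog(disease_genes = gene_syms, disease_mirnas = mirnas,
                 tf_universe = de_tfs, gene_universe = gene_syms)
  ffls <- enumerate_ffls(reg, cat)
  net <- assemble_network(ffls)
  dir_col <- rep(NA_character_, nrow(net$nodes))
  hit <- net$nodes$name %in% names(dir_map)
  dir_col[hit] <- unname(dir_map[net$nodes$name[hit]])
  net$nodes$direction <- dir_col
  ffl_log("build_recurrence_network: %d FFLs, %d nodes, %d edges",
          nrow(ffls), nrow(net$nodes), nrow(net$edges))
  list(network = net, ffls = ffls)
}
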