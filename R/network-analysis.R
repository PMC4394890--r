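# Assembly of co-regulatory networks from motif instances and the standard
# descriptive analyses: degrees, top-5% hubs, pathway-seeded and induced
# subnetworks, degree-distribution skewness.

#' Assemble a network from motif instances
#'
#' The node set is the union of all motif participants (tagged TF, miRNA or
#' gene); the edge set is the union of all constituent edges, deduplicated.
#' A symbol occupying both the TF and gene roles across motifs is assigned
#' category TF (the regulator role dominates) and the conflict is logged.
#'
#' @param ffls an `ffl_table` (may have zero rows).
#' @param fbls an optional `fbl_table`.
#' @return A [coreg_network()].
#' @export
assemble_network <- function(ffls, fbls = NULL) {
  edge_blocks <- list()
  if (nrow(ffls) > 0L) {
    edge_blocks <- c(edge_blocks, list(
      data.frame(from = ffls$tf, to = ffls$gene, sign = "activates",
                 evidence = ffls$ev_tg, stringsAsFactors = FALSE),
      data.frame(from = ffls$mirna, to = ffls$gene, sign = "represses",
                 evidence = ffls$ev_mg, stringsAsFactors = FALSE)))
    has_tm <- !is.na(ffls$ev_tm)
    has_mt <- !is.na(ffls$ev_mt)
    if (any(has_tm)) edge_blocks <- c(edge_blocks, list(
      data.frame(from = ffls$tf[has_tm], to = ffls$mirna[has_tm],
                 sign = "activates", evidence = ffls$ev_tm[has_tm],
                 stringsAsFactors = FALSE)))
    if (any(has_mt)) edge_blocks <- c(edge_blocks, list(
      data.frame(from = ffls$mirna[has_mt], to = ffls$tf[has_mt],
                 sign = "represses", evidence = ffls$ev_mt[has_mt],
                 stringsAsFactors = FALSE)))
  }
  if (!is.null(fbls) && nrow(fbls) > 0L) {
    edge_blocks <- c(edge_blocks, list(
      data.frame(from = fbls$tf, to = fbls$mirna, sign = "activates",
                 evidence = fbls$ev_tm, stringsAsFactors = FALSE),
      data.frame(from = fbls$mirna, to = fbls$tf, sign = "represses",
                 evidence = fbls$ev_mt, stringsAsFactors = FALSE)))
  }
  if (length(edge_blocks) == 0L) return(coreg_network())
  edges <- do.call(rbind, edge_blocks)

  tf_syms <- unique(c(ffls$tf, if (!is.null(fbls)) fbls$tf))
  mir_syms <- unique(c(ffls$mirna, if (!is.null(fbls)) fbls$mirna))
  gene_syms <- unique(ffls$gene)
  dual <- intersect(gene_syms, tf_syms)
  if (length(dual) > 0L) {
    ffl_log("assemble_network: %d symbol(s) in both TF and gene roles, tagged TF: %s",
            length(dual), paste(utils::head(dual, 5L), collapse = ", "))
    gene_syms <- setdiff(gene_syms, dual)
  }
  nodes <- data.frame(
    name = c(tf_syms, mir_syms, gene_syms),
    category = rep(c("TF", "miRNA", "gene"),
                   c(length(tf_syms), length(mir_syms), length(gene_syms))),
    stringsAsFactors = FALSE
  )
  net <- coreg_network(nodes, edges)
  ffl_log("assemble_network: %d motifs -> %d nodes, %d edges",
          nrow(ffls) + if (is.null(fbls)) 0L else nrow(fbls),
          nrow(net$nodes), nrow(net$edges))
  net
}

#' Per-node total degree
#'
#' Total degree is in-degree plus out-degree with each distinct edge counted
#' once regardless of its evidence mix; the degree sum equals twice the edge
#' count.
#'
#' @param net a `coreg_network`.
#' @return data.frame with columns name, category, degree.
#' @export
degree_table <- function(net) {
  stopifnot(inherits(net, "coreg_network"))
  ends <- c(net$edges$from, net$edges$to)
  deg <- table(factor(ends, levels = net$nodes$name))
  data.frame(name = net$nodes$name, category = net$nodes$category,
             degree = as.integer(deg), stringsAsFactors = FALSE)
}

#' Detect hub nodes per category
#'
#' Within each category (TF, miRNA, gene) the nodes are sorted by descending
#' degree and the top `ceiling(fraction * category size)` selected; any node
#' tied with the last selected degree is also included. The applied counts
#' are attached as the "applied_counts" attribute and logged.
#'
#' @param net a `coreg_network`.
#' @param fraction hub fraction in (0, 1]; default 0.05 (top 5 percent).
#' @return data.frame of hubs (name, category, degree), sorted by category
#'   then descending degree.
#' @export
detect_hubs <- function(net, fraction = 0.05) {
  stopifnot(inherits(net, "coreg_network"))
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  deg <- degree_table(net)
  out <- list()
  applied <- list()
  for (cat in c("TF", "miRNA", "gene")) {
    sub <- deg[deg$category == cat, , drop = FALSE]
    if (nrow(sub) == 0L) {
      warning("category ", sQuote(cat), " is empty; no hubs selected")
      applied[[cat]] <- data.frame(category = cat, size = 0L, k = 0L,
                                   selected = 0L, stringsAsFactors = FALSE)
      next
    }
    sub <- sub[order(-sub$degree, sub$name, method = "radix"), , drop = FALSE]
    k <- ceiling(fraction * nrow(sub))
    thr <- sub$degree[k]
    sel <- sub[sub$degree >= thr, , drop = FALSE]
    if (nrow(sel) > k) {
      warning("category ", sQuote(cat), ": degree ties expand hub selection ",
              "from ", k, " to ", nrow(sel), " node(s)")
    }
    applied[[cat]] <- data.frame(category = cat, size = nrow(sub), k = k,
                                 selected = nrow(sel), stringsAsFactors = FALSE)
    out[[cat]] <- sel
  }
  hubs <- if (length(out)) do.call(rbind, out) else
    deg[0, , drop = FALSE]
  rownames(hubs) <- NULL
  counts <- do.call(rbind, applied)
  rownames(counts) <- NULL
  ffl_log("detect_hubs: %s",
          paste(sprintf("%s %d/%d", counts$category, counts$selected,
                        counts$size), collapse = ", "))
  attr(hubs, "applied_counts") <- counts
  hubs
}

#' Pathway-seeded subnetwork
#'
#' Merges the FFLs whose gene belongs to the seed set (e.g. the members of a
#' canonical pathway) into a network.
#'
#' @param ffls an `ffl_table`.
#' @param seed_genes character vector of pathway member symbols.
#' @return A [coreg_network()] assembled from the matching FFLs.
#' @export
pathway_subnetwork <- function(ffls, seed_genes) {
  sub <- ffls[ffls$gene %in% seed_genes, , drop = FALSE]
  class(sub) <- class(ffls)
  assemble_network(sub)
}

#' Induced subnetwork on a node set
#'
#' Keeps the edges with both endpoints in `nodes` (the strict induced
#' subgraph); symbols absent from the network are ignored with a warning.
#'
#' @param net a `coreg_network`.
#' @param nodes character vector of node names.
#' @return A [coreg_network()].
#' @export
induced_subnetwork <- function(net, nodes) {
  stopifnot(inherits(net, "coreg_network"))
  nodes <- unique(as.character(nodes))
  extra <- setdiff(nodes, net$nodes$name)
  if (length(extra) > 0L) {
    warning(length(extra), " requested node(s) absent from the network, ",
            "ignored: ", paste(utils::head(extra, 5L), collapse = ", "))
    nodes <- setdiff(nodes, extra)
  }
  keep_n <- net$nodes[net$nodes$name %in% nodes, , drop = FALSE]
  keep_e <- net$edges[net$edges$from %in% nodes & net$edges$to %in% nodes, ,
                      drop = FALSE]
  coreg_network(keep_n, keep_e)
}

#' Sample skewness of the degree distribution
#'
#' The moment-based sample skewness g1 = m3 / m2^(3/2) of the node degree
#' sequence, used to quantify the right-skew typical of regulatory networks
#' (a few high-degree hubs, many low-degree nodes).
#'
#' @param net a `coreg_network` with at least 3 nodes and non-constant
#'   degrees.
#' @return The skewness as a single numeric value.
#' @export
degree_skewness <- function(net) {
  d <- degree_table(net)$degree
  if (length(d) < 3L) stop("degree skewness needs at least 3 nodes")
  m2 <- mean((d - mean(d))^2)
  if (m2 == 0) stop("undefined statistic: degree sequence has zero variance")
  m3 <- mean((d - mean(d))^3)
  m3 / m2^1.5
}
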