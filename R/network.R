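#' Construct a co-regulatory network
#'
#' A network is a node-typed, edge-signed directed graph. Each node carries
#' exactly one category (TF, miRNA or gene); each edge a sign ("activates"
#' for TF sources, "represses" for miRNA sources) and an evidence label.
#'
#' @param nodes data.frame with columns `name`, `category`; optional extra
#'   annotation columns (e.g. `direction`) are preserved.
#' @param edges data.frame with columns `from`, `to`, `sign`, `evidence`.
#' @return An object of class `coreg_network`.
#' @export
coreg_network <- function(nodes = data.frame(name = character(),
                                             category = character(),
                                             stringsAsFactors = FALSE),
                          edges = data.frame(from = character(),
                                             to = character(),
                                             sign = character(),
                                             evidence = character(),
                                             stringsAsFactors = FALSE)) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  if (!all(c("name", "category") %in% names(nodes))) {
    stop("nodes must have columns 'name' and 'category'")
  }
  for (col in c("from", "to", "sign", "evidence")) {
    if (!col %in% names(edges)) stop("edges must have column ", sQuote(col))
  }
  if (anyDuplicated(nodes$name)) {
    stop("duplicate node name: ", nodes$name[duplicated(nodes$name)][1],
         " (a symbol has exactly one category per network)")
  }
  bad_cat <- !nodes$category %in% c("TF", "miRNA", "gene")
  if (any(bad_cat)) stop("unknown node category: ", nodes$category[bad_cat][1])
  orphan <- !(edges$from %in% nodes$name & edges$to %in% nodes$name)
  if (any(orphan)) {
    stop("edge endpoint missing from node set: ",
         edges$from[orphan][1], " -> ", edges$to[orphan][1])
  }
  edges <- edges[!duplicated(paste(edges$from, edges$to, sep = "\r")), ,
                 drop = FALSE]
  nodes <- nodes[radix_order(nodes$name), , drop = FALSE]
  edges <- edges[radix_order(edges$from, edges$to), , drop = FALSE]
  rownames(nodes) <- rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "coreg_network")
}

#' @export
print.coreg_network <- function(x, ...) {
  tab <- table(factor(x$nodes$category, levels = c("TF", "miRNA", "gene")))
  cat(sprintf("<coreg_network> %d nodes (%d TFs, %d miRNAs, %d genes), %d edges\n",
              nrow(x$nodes), tab[["TF"]], tab[["miRNA"]], tab[["gene"]],
              nrow(x$edges)))
  invisible(x)
}

as_igraph <- function(net) {
  stopifnot(inherits(net, "coreg_network"))
  igraph::graph_from_data_frame(net$edges, directed = TRUE,
                                vertices = net$nodes)
}

#' Export a network for Cytoscape-style tools
#'
#' Writes the network as SIF (relation labels "activates"/"represses"),
#' GraphML (via igraph, with category/sign/evidence attributes) or a long
#' TSV (`record` column distinguishes node and edge rows). GraphML and TSV
#' round-trip through [read_network()].
#'
#' @param net a `coreg_network`.
#' @param format "SIF", "GraphML" or "TSV".
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, format = c("SIF", "GraphML", "TSV"), path) {
  stopifnot(inherits(net, "coreg_network"))
  if (length(format) == 1L && !format %in% c("SIF", "GraphML", "TSV")) {
    stop("usage error: unknown network format ", sQuote(format))
  }
  format <- match.arg(format)
  if (format == "SIF") {
    e <- net$edges
    lines <- sprintf("%s\t%s\t%s", e$from, e$sign, e$to)
    isolated <- setdiff(net$nodes$name, c(e$from, e$to))
    writeLines(c(lines, isolated), path)
  } else if (format == "GraphML") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    n <- net$nodes
    e <- net$edges
    node_rows <- data.frame(record = rep("node", nrow(n)), name = n$name,
                            category = n$category,
                            from = rep(NA_character_, nrow(n)),
                            to = rep(NA_character_, nrow(n)),
                            sign = rep(NA_character_, nrow(n)),
                            evidence = rep(NA_character_, nrow(n)),
                            stringsAsFactors = FALSE)
    edge_rows <- data.frame(record = rep("edge", nrow(e)),
                            name = rep(NA_character_, nrow(e)),
                            category = rep(NA_character_, nrow(e)),
                            from = e$from, to = e$to, sign = e$sign,
                            evidence = e$evidence, stringsAsFactors = FALSE)
    utils::write.table(rbind(node_rows, edge_rows), path, sep = "\t",
                       quote = FALSE, row.names = FALSE, na = "")
  }
  invisible(path)
}

#' Read a network written by [write_network()]
#'
#' @param path path to a GraphML or long-TSV network file.
#' @param format "GraphML" or "TSV".
#' @return A `coreg_network`.
#' @export
read_network <- function(path, format = c("GraphML", "TSV")) {
  format <- match.arg(format)
  if (format == "GraphML") {
    g <- igraph::read_graph(path, format = "graphml")
    nv <- igraph::vcount(g)
    nodes <- data.frame(
      name = if (nv > 0L) igraph::vertex_attr(g, "name") else character(),
      category = if (nv > 0L && "category" %in% igraph::vertex_attr_names(g))
        igraph::vertex_attr(g, "category") else character(nv),
      stringsAsFactors = FALSE
    )
    el <- igraph::as_edgelist(g, names = TRUE)
    ne <- nrow(el)
    get_eattr <- function(a) {
      if (ne > 0L && a %in% igraph::edge_attr_names(g))
        igraph::edge_attr(g, a) else character(ne)
    }
    edges <- data.frame(from = el[, 1], to = el[, 2],
                        sign = get_eattr("sign"),
                        evidence = get_eattr("evidence"),
                        stringsAsFactors = FALSE)
  } else {
    df <- utils::read.delim(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "")
    nodes <- df[df$record == "node", c("name", "category"), drop = FALSE]
    edges <- df[df$record == "edge",
                c("from", "to", "sign", "evidence"), drop = FALSE]
  }
  coreg_network(nodes, edges)
}

#' Node-attribute table of a network
#'
#' One row per node with category, total degree and hub flag; suitable as a
#' Cytoscape node-attribute import.
#'
#' @param net a `coreg_network`.
#' @param hub_fraction per-category hub fraction passed to [detect_hubs()].
#' @return data.frame with columns name, category, degree, is_hub.
#' @export
node_attribute_table <- function(net, hub_fraction = 0.05) {
  deg <- degree_table(net)
  hubs <- suppressWarnings(detect_hubs(net, hub_fraction))
  deg$is_hub <- deg$name %in% hubs$name
  deg
}
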