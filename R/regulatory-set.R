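#' Construct a regulatory edge set
#'
#' A regulatory set is the package's central container: a deduplicated table
#' of directed, typed, evidence-labelled regulation edges. TF regulators
#' activate their targets (genes or miRNAs); miRNA regulators repress theirs
#' (genes or TFs). Edges are keyed by (regulator, target, regulator_type);
#' duplicate keys collapse, and a key seen with both "predicted" and
#' "validated" evidence becomes "both".
#'
#' @param regulator character vector of regulator symbols.
#' @param target character vector of target symbols.
#' @param regulator_type character vector, each "TF" or "miRNA".
#' @param target_type optional character vector ("TF", "miRNA", "gene" or NA);
#'   when NA the consuming stage infers the role from its catalog.
#' @param evidence character vector, each "predicted", "validated" or "both".
#' @return An object of class `regulatory_set` (a data.frame with columns
#'   regulator, target, regulator_type, target_type, evidence).
#' @examples
#' regulatory_set(c("TF1", "miR-1"), c("G1", "G1"),
#'                c("TF", "miRNA"), evidence = "predicted")
#' @export
regulatory_set <- function(regulator = character(), target = character(),
                           regulator_type = character(),
                           target_type = NA_character_,
                           evidence = "predicted") {
  n <- max(length(regulator), length(target), length(regulator_type))
  if (n == 0L) {
    df <- data.frame(regulator = character(), target = character(),
                     regulator_type = character(), target_type = character(),
                     evidence = character(), stringsAsFactors = FALSE)
    return(new_regulatory_set(df))
  }
  df <- data.frame(
    regulator      = as.character(regulator),
    target         = as.character(target),
    regulator_type = as.character(regulator_type),
    target_type    = rep_len(as.character(target_type), n),
    evidence       = rep_len(as.character(evidence), n),
    stringsAsFactors = FALSE
  )
  new_regulatory_set(df)
}

# validate + dedup; the only constructor path
new_regulatory_set <- function(df) {
  stopifnot(is.data.frame(df))
  needed <- c("regulator", "target", "regulator_type")
  miss <- setdiff(needed, names(df))
  if (length(miss) > 0L) {
    stop("regulatory set is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (!"target_type" %in% names(df)) df$target_type <- NA_character_
  if (!"evidence" %in% names(df)) df$evidence <- "predicted"
  df <- df[, c("regulator", "target", "regulator_type", "target_type", "evidence")]
  rownames(df) <- NULL

  bad_rt <- !df$regulator_type %in% c("TF", "miRNA")
  if (any(bad_rt)) {
    stop("invalid regulator_type ", sQuote(df$regulator_type[which(bad_rt)[1]]),
         " at row ", which(bad_rt)[1], " (must be TF or miRNA)")
  }
  bad_ev <- !df$evidence %in% c("predicted", "validated", "both")
  if (any(bad_ev)) {
    stop("invalid evidence ", sQuote(df$evidence[which(bad_ev)[1]]),
         " at row ", which(bad_ev)[1])
  }
  self <- df$regulator == df$target
  if (any(self)) {
    stop("self-loop edge not allowed: ", df$regulator[which(self)[1]],
         " -> itself (row ", which(self)[1], ")")
  }
  mm <- df$regulator_type == "miRNA" & !is.na(df$target_type) &
    df$target_type == "miRNA"
  if (any(mm)) {
    stop("miRNA -> miRNA edges are not allowed (row ", which(mm)[1], ")")
  }

  df <- collapse_edges(df)
  class(df) <- c("regulatory_set", "data.frame")
  df
}

# collapse duplicate (regulator, target, regulator_type) keys; mixed or
# repeated evidence classes merge to "both" only when both classes are seen
collapse_edges <- function(df) {
  if (nrow(df) < 2L) return(df)
  key <- edge_key(df$regulator, df$target, df$regulator_type)
  if (!anyDuplicated(key)) return(df)
  ev_rank <- c(predicted = 1L, validated = 2L, both = 3L)
  grp <- split(seq_len(nrow(df)), key)
  keep <- vapply(grp, `[`, integer(1), 1L)
  ev <- vapply(grp, function(idx) {
    e <- unique(df$evidence[idx])
    if ("both" %in% e || all(c("predicted", "validated") %in% e)) "both" else e[1]
  }, character(1))
  tt <- vapply(grp, function(idx) {
    t <- unique(df$target_type[idx])
    t <- t[!is.na(t)]
    if (length(t) > 0L) t[1] else NA_character_
  }, character(1))
  out <- df[keep, , drop = FALSE]
  out$evidence <- ev
  out$target_type <- tt
  out <- out[radix_order(out$regulator, out$target, out$regulator_type), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.regulatory_set <- function(x, ...) {
  cat(sprintf("<regulatory_set> %d edge(s)\n", nrow(x)))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Restrict a regulatory set to an evidence class
#'
#' The "validated" view keeps edges with evidence `validated` or `both` and is
#' the basis of the verified network; the "predicted" view is symmetric.
#'
#' @param reg a `regulatory_set`.
#' @param evidence "validated" or "predicted".
#' @return A `regulatory_set` with the retained edges.
#' @export
restrict_evidence <- function(reg, evidence = c("validated", "predicted")) {
  stopifnot(inherits(reg, "regulatory_set"))
  evidence <- match.arg(evidence)
  keep <- reg$evidence %in% c(evidence, "both")
  out <- as.data.frame(reg)[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_regulatory_set(out)
}

#' Build a catalog of symbol sets
#'
#' A catalog names the analysis scope: curated disease genes, curated disease
#' miRNAs, the TF universe and the gene universe the disease genes were drawn
#' from. Disease genes must lie inside the gene universe.
#'
#' @param disease_genes,disease_mirnas,tf_universe,gene_universe character
#'   vectors of symbols (deduplicated on construction).
#' @return An object of class `catalog`.
#' @export
catalog <- function(disease_genes, disease_mirnas, tf_universe, gene_universe) {
  cat <- list(
    disease_genes  = unique(as.character(disease_genes)),
    disease_mirnas = unique(as.character(disease_mirnas)),
    tf_universe    = unique(as.character(tf_universe)),
    gene_universe  = unique(as.character(gene_universe))
  )
  extra <- setdiff(cat$disease_genes, cat$gene_universe)
  if (length(extra) > 0L) {
    stop("disease genes outside the gene universe: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  }
  structure(cat, class = "catalog")
}

#' @export
print.catalog <- function(x, ...) {
  cat(sprintf(
    "<catalog> %d disease genes, %d disease miRNAs, %d TFs, %d universe genes\n",
    length(x$disease_genes), length(x$disease_mirnas),
    length(x$tf_universe), length(x$gene_universe)))
  invisible(x)
}

check_catalog_nonempty <- function(cat, fields) {
  stopifnot(inherits(cat, "catalog"))
  for (f in fields) {
    if (length(cat[[f]]) == 0L) {
      stop("configuration error: catalog field ", sQuote(f), " is empty")
    }
  }
  invisible(TRUE)
}

#' Normalize miRNA symbols
#'
#' Optional, off-by-default normalizer: strips a species prefix such as
#' "hsa-" and lower-cases a leading "MiR"/"MIR" to "miR". No arm or family
#' collapsing is attempted; symbols are otherwise matched exactly as given.
#'
#' @param x character vector of miRNA symbols.
#' @return Normalized character vector.
#' @examples
#' normalize_mirna("hsa-miR-29a-3p")  # "miR-29a-3p"
#' @export
normalize_mirna <- function(x) {
  x <- sub("^[a-z]{3}-", "", as.character(x))
  sub("^[Mm][Ii][Rr]", "miR", x)
}
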