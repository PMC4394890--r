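# Enumeration and classification of miRNA-TF-gene feed-forward loops (FFLs)
# and miRNA-TF feedback loops (FBLs) on a scope-restricted regulatory set.
#
# An FFL is a (TF, miRNA, gene) triple with TF -> gene, miRNA -| gene and at
# least one cross-regulation edge between the TF and the miRNA:
#   TF-FFL        TF -> miRNA only         (TF is the main regulator)
#   miRNA-FFL     miRNA -| TF only         (miRNA is the main regulator)
#   composite-FFL both cross edges present (mutual regulation)
# An FBL is an unordered (TF, miRNA) pair with both cross edges.
#
# Strategy: iterate the cross-regulating (TF, miRNA) pairs and intersect
# their target sets; the contract is equality with the exhaustive triple scan.

# split cross-regulation structure out of a regulatory set, given a catalog
cross_pairs <- function(reg, cat) {
  is_tf <- reg$regulator_type == "TF" & reg$regulator %in% cat$tf_universe
  is_mir <- reg$regulator_type == "miRNA" & reg$regulator %in% cat$disease_mirnas
  tm <- reg[is_tf & reg$target %in% cat$disease_mirnas, , drop = FALSE]
  mt <- reg[is_mir & reg$target %in% cat$tf_universe, , drop = FALSE]
  key_tm <- paste(tm$regulator, tm$target, sep = "\r")
  key_mt <- paste(mt$target, mt$regulator, sep = "\r")   # (tf, mirna) order
  all_keys <- union(key_tm, key_mt)
  parts <- strsplit(all_keys, "\r", fixed = TRUE)
  data.frame(
    tf = vapply(parts, `[`, character(1), 1L),
    mirna = vapply(parts, `[`, character(1), 2L),
    has_tm = all_keys %in% key_tm,
    has_mt = all_keys %in% key_mt,
    stringsAsFactors = FALSE
  )
}

# evidence lookup keyed on (regulator, target, regulator_type)
evidence_map <- function(reg) {
  stats::setNames(reg$evidence, edge_key(reg$regulator, reg$target,
                                         reg$regulator_type))
}

#' Enumerate feed-forward loops
#'
#' Finds every (TF, miRNA, gene) triple — TF in the TF universe, miRNA in the
#' disease-miRNA catalog, gene in the disease-gene catalog — wired as an FFL,
#' and classifies it as TF-FFL, miRNA-FFL or composite-FFL by which
#' cross-regulation edges are present. Each triple is emitted exactly once,
#' in (tf, mirna, gene) lexicographic order. A loop is `verified` when all
#' of its constituent edges carry validated (or merged) evidence.
#'
#' @param reg a scope-restricted `regulatory_set` (see [restrict_to_scope()]).
#' @param cat a [catalog()].
#' @return A data.frame of class `ffl_table` with columns tf, mirna, gene,
#'   loop_type, verified and the per-edge evidence columns ev_tg, ev_mg,
#'   ev_tm, ev_mt (NA for an absent cross edge).
#' @export
enumerate_ffls <- function(reg, cat) {
  stopifnot(inherits(reg, "regulatory_set"))
  check_catalog_nonempty(cat, c("disease_genes", "disease_mirnas", "tf_universe"))
  pairs <- cross_pairs(reg, cat)
  empty <- data.frame(tf = character(), mirna = character(), gene = character(),
                      loop_type = character(), verified = logical(),
                      ev_tg = character(), ev_mg = character(),
                      ev_tm = character(), ev_mt = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("ffl_table", "data.frame")
  if (nrow(pairs) == 0L) return(empty)

  is_tf <- reg$regulator_type == "TF" & reg$regulator %in% cat$tf_universe
  is_mir <- reg$regulator_type == "miRNA" & reg$regulator %in% cat$disease_mirnas
  tg <- reg[is_tf & reg$target %in% cat$disease_genes, , drop = FALSE]
  mg <- reg[is_mir & reg$target %in% cat$disease_genes, , drop = FALSE]
  tg_by_tf <- split(tg$target, tg$regulator)
  mg_by_mir <- split(mg$target, mg$regulator)

  blocks <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    t <- pairs$tf[i]; m <- pairs$mirna[i]
    shared <- intersect(tg_by_tf[[t]] %||% character(),
                        mg_by_mir[[m]] %||% character())
    # a disease gene that is itself a TF may take the gene role, but never
    # the same symbol as this triple's TF (self-loops are already excluded
    # at the edge level, so this is belt and braces)
    shared <- shared[shared != t & shared != m]
    if (length(shared) == 0L) next
    loop_type <- if (pairs$has_tm[i] && pairs$has_mt[i]) "composite-FFL"
                 else if (pairs$has_tm[i]) "TF-FFL" else "miRNA-FFL"
    blocks[[i]] <- data.frame(tf = t, mirna = m, gene = shared,
                              loop_type = loop_type, stringsAsFactors = FALSE)
  }
  blocks <- blocks[!vapply(blocks, is.null, logical(1))]
  if (length(blocks) == 0L) return(empty)
  out <- do.call(rbind, blocks)

  ev <- evidence_map(reg)
  out$ev_tg <- unname(ev[edge_key(out$tf, out$gene, "TF")])
  out$ev_mg <- unname(ev[edge_key(out$mirna, out$gene, "miRNA")])
  out$ev_tm <- unname(ev[edge_key(out$tf, out$mirna, "TF")])
  out$ev_mt <- unname(ev[edge_key(out$mirna, out$tf, "miRNA")])
  validated <- function(e) !is.na(e) & e %in% c("validated", "both")
  present_ok <- function(e) is.na(e) | validated(e)
  out$verified <- validated(out$ev_tg) & validated(out$ev_mg) &
    present_ok(out$ev_tm) & present_ok(out$ev_mt) &
    (validated(out$ev_tm) | validated(out$ev_mt))
  out <- out[, c("tf", "mirna", "gene", "loop_type", "verified",
                 "ev_tg", "ev_mg", "ev_tm", "ev_mt")]
  out <- out[radix_order(out$tf, out$mirna, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  ffl_log("enumerate_ffls: %d edges in, %d FFLs out", nrow(reg), nrow(out))
  class(out) <- c("ffl_table", "data.frame")
  out
}

#' Enumerate feedback loops
#'
#' Finds every (TF, miRNA) pair with mutual regulation (TF -> miRNA and
#' miRNA -| TF), each reported once, in (tf, mirna) lexicographic order.
#'
#' @inheritParams enumerate_ffls
#' @return A data.frame of class `fbl_table` with columns tf, mirna,
#'   verified, ev_tm, ev_mt.
#' @export
enumerate_fbls <- function(reg, cat) {
  stopifnot(inherits(reg, "regulatory_set"))
  check_catalog_nonempty(cat, c("disease_mirnas", "tf_universe"))
  pairs <- cross_pairs(reg, cat)
  out <- pairs[pairs$has_tm & pairs$has_mt, c("tf", "mirna"), drop = FALSE]
  ev <- evidence_map(reg)
  out$ev_tm <- unname(ev[edge_key(out$tf, out$mirna, "TF")])
  out$ev_mt <- unname(ev[edge_key(out$mirna, out$tf, "miRNA")])
  out$verified <- out$ev_tm %in% c("validated", "both") &
    out$ev_mt %in% c("validated", "both")
  out <- out[, c("tf", "mirna", "verified", "ev_tm", "ev_mt")]
  out <- out[radix_order(out$tf, out$mirna), , drop = FALSE]
  rownames(out) <- NULL
  ffl_log("enumerate_fbls: %d FBLs", nrow(out))
  class(out) <- c("fbl_table", "data.frame")
  out
}

#' Summarize motif counts by loop type
#'
#' One row per loop type (TF-FFL, miRNA-FFL, composite-FFL, FBL) with the
#' module count and the numbers of distinct genes, miRNAs and TFs involved,
#' for the full (merged-evidence) enumeration and for the verified subset.
#'
#' @param ffls an `ffl_table` from [enumerate_ffls()].
#' @param fbls an `fbl_table` from [enumerate_fbls()] (optional).
#' @return data.frame with columns module_type, modules, genes, mirnas, tfs,
#'   verified_modules, verified_genes, verified_mirnas, verified_tfs. FBL
#'   gene counts are NA (the motif has no gene slot).
#' @export
summarize_motifs <- function(ffls, fbls = NULL) {
  count_block <- function(df, has_gene) {
    c(modules = nrow(df),
      genes = if (has_gene) length(unique(df$gene)) else NA_integer_,
      mirnas = length(unique(df$mirna)),
      tfs = length(unique(df$tf)))
  }
  types <- c("TF-FFL", "miRNA-FFL", "composite-FFL")
  rows <- lapply(types, function(ty) {
    sub <- ffls[ffls$loop_type == ty, , drop = FALSE]
    c(count_block(sub, TRUE), count_block(sub[sub$verified, , drop = FALSE], TRUE))
  })
  if (!is.null(fbls)) {
    rows <- c(rows, list(c(count_block(fbls, FALSE),
                           count_block(fbls[fbls$verified, , drop = FALSE], FALSE))))
    types <- c(types, "FBL")
  }
  m <- do.call(rbind, rows)
  data.frame(module_type = types,
             modules = m[, 1], genes = m[, 2], mirnas = m[, 3], tfs = m[, 4],
             verified_modules = m[, 5], verified_genes = m[, 6],
             verified_mirnas = m[, 7], verified_tfs = m[, 8],
             stringsAsFactors = FALSE, row.names = NULL)
}
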