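# Integration of raw predicted/validated target sources into the
# analysis-ready regulatory set: prediction intersection for miRNA targets,
# Z-score filtering for TFBS-derived TF targets, evidence merging, and
# restriction to the disease scope.

#' Intersect two miRNA target-prediction sets
#'
#' Keeps the edges whose (regulator, target) key appears in both inputs —
#' the overlap of two prediction tools. Output evidence is "predicted".
#'
#' @param a,b `regulatory_set`s containing only miRNA-regulator edges.
#' @return A `regulatory_set` of the shared predictions.
#' @export
intersect_predictions <- function(a, b) {
  stopifnot(inherits(a, "regulatory_set"), inherits(b, "regulatory_set"))
  if (any(a$regulator_type != "miRNA") || any(b$regulator_type != "miRNA")) {
    stop("contract violation: intersect_predictions expects miRNA edges only")
  }
  ka <- paste(a$regulator, a$target, sep = "\r")
  kb <- paste(b$regulator, b$target, sep = "\r")
  out <- as.data.frame(a)[ka %in% kb, , drop = FALSE]
  out$evidence <- rep("predicted", nrow(out))
  ffl_log("intersect_predictions: %d x %d edges in, %d shared",
          nrow(a), nrow(b), nrow(out))
  new_regulatory_set(out)
}

#' Filter TFBS records into predicted TF edges
#'
#' Retains binding-site records at or above the conservation Z-score cutoff
#' (default 2.33, the one-sided 1\% normal quantile) and emits one predicted
#' TF edge per retained record, deduplicated.
#'
#' @param records data.frame with columns tf, target, zscore
#'   (see [read_tfbs_table()]).
#' @param cutoff finite Z-score threshold; records with `zscore >= cutoff`
#'   are kept.
#' @return A `regulatory_set` of predicted TF edges.
#' @export
filter_tfbs <- function(records, cutoff = 2.33) {
  stopifnot(is.data.frame(records),
            all(c("tf", "target", "zscore") %in% names(records)))
  if (is.na(cutoff)) stop("cutoff must not be NA")
  keep <- records[records$zscore >= cutoff, , drop = FALSE]
  ffl_log("filter_tfbs: %d records in, %d at Z >= %.3g",
          nrow(records), nrow(keep), cutoff)
  regulatory_set(regulator = keep$tf, target = keep$target,
                 regulator_type = if (nrow(keep)) "TF" else character(),
                 evidence = if (nrow(keep)) "predicted" else character())
}

#' Merge predicted and validated evidence
#'
#' Key-union of the two sets; an edge present in both carries
#' evidence "both". Use [restrict_evidence()] on the result for the
#' validated-only view behind the verified network.
#'
#' @param predicted,validated `regulatory_set`s.
#' @return The merged `regulatory_set`.
#' @export
merge_evidence <- function(predicted, validated) {
  stopifnot(inherits(predicted, "regulatory_set"),
            inherits(validated, "regulatory_set"))
  p <- as.data.frame(predicted)
  v <- as.data.frame(validated)
  if (nrow(p)) p$evidence <- ifelse(p$evidence == "both", "both", "predicted")
  if (nrow(v)) v$evidence <- ifelse(v$evidence == "both", "both", "validated")
  out <- new_regulatory_set(rbind(p, v))
  ffl_log("merge_evidence: %d predicted + %d validated -> %d merged",
          nrow(p), nrow(v), nrow(out))
  out
}

#' Restrict a regulatory set to the disease scope
#'
#' Implements the asymmetric scope rule: miRNA regulation is trusted only
#' from curated disease miRNAs (onto disease genes or TFs), while TF
#' regulation is kept from any TF in the universe (onto disease genes,
#' disease miRNAs or TFs) so that no TF-mediated regulation is lost.
#'
#' @param reg a `regulatory_set`.
#' @param cat a [catalog()] with non-empty disease_genes, disease_mirnas and
#'   tf_universe.
#' @return The scope-restricted `regulatory_set`.
#' @export
restrict_to_scope <- function(reg, cat) {
  stopifnot(inherits(reg, "regulatory_set"))
  check_catalog_nonempty(cat, c("disease_genes", "disease_mirnas", "tf_universe"))
  is_mir <- reg$regulator_type == "miRNA"
  keep_mir <- is_mir &
    reg$regulator %in% cat$disease_mirnas &
    reg$target %in% c(cat$disease_genes, cat$tf_universe)
  keep_tf <- !is_mir &
    reg$regulator %in% cat$tf_universe &
    reg$target %in% c(cat$disease_genes, cat$disease_mirnas, cat$tf_universe)
  out <- as.data.frame(reg)[keep_mir | keep_tf, , drop = FALSE]
  ffl_log("restrict_to_scope: %d edges in, %d in scope", nrow(reg), nrow(out))
  new_regulatory_set(out)
}
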