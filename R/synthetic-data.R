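# Synthetic tripartite regulatory graphs with closed-form motif
# expectations. TFs regulate genes and miRNAs; miRNAs repress genes and TFs.
# Every potential edge is drawn independently with a per-edge-type
# probability (an Erdos-Renyi-style model), which gives exact analytic
# expectations for each motif class and makes the generator a calibration
# oracle for the enumerator. TF->gene and miRNA-|gene edges are wired across
# the full gene universe; the disease-gene catalog is a uniform sample of
# that universe, so the same synthetic world also feeds the permutation
# test.

#' Parameters for the synthetic regulatory-graph generator
#'
#' @param n_tf,n_mirna number of TFs and miRNAs (all treated as the TF
#'   universe and the disease-miRNA catalog respectively).
#' @param n_gene number of disease genes (drawn from the universe).
#' @param universe_size total number of genes in the universe;
#'   `n_gene <= universe_size`.
#' @param p_tg,p_tm,p_mg,p_mt independent edge probabilities in [0, 1] for
#'   TF->gene, TF->miRNA, miRNA-|gene and miRNA-|TF edges.
#' @param validated_fraction probability that a drawn edge is labelled
#'   "validated" rather than "predicted".
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(n_tf = 10L, n_mirna = 10L, n_gene = 30L,
                         universe_size = n_gene,
                         p_tg = 0.1, p_tm = 0.1, p_mg = 0.1, p_mt = 0.1,
                         validated_fraction = 0.2, seed = 1L) {
  p <- list(n_tf = as.integer(n_tf), n_mirna = as.integer(n_mirna),
            n_gene = as.integer(n_gene),
            universe_size = as.integer(universe_size),
            p_tg = p_tg, p_tm = p_tm, p_mg = p_mg, p_mt = p_mt,
            validated_fraction = validated_fraction, seed = as.integer(seed))
  probs <- c(p$p_tg, p$p_tm, p$p_mg, p$p_mt, p$validated_fraction)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]")
  }
  if (p$n_gene > p$universe_size) {
    stop("configuration error: n_gene exceeds universe_size")
  }
  if (any(c(p$n_tf, p$n_mirna, p$n_gene, p$universe_size) < 0L)) {
    stop("configuration error: counts must be non-negative")
  }
  structure(p, class = "synth_params")
}

#' Preset generator parameters
#'
#' "paper-scale" mimics a disease co-regulatory analysis with 169 TFs,
#' 83 miRNAs and 153 disease genes in a 1000-gene universe, with edge
#' probabilities placed (via [expected_motif_counts()]) in the 2-3k FFL
#' regime typical of such studies. "tiny" is a fast small-graph preset for
#' demos and tests.
#'
#' @param name "paper-scale" or "tiny".
#' @param seed RNG seed.
#' @return A [synth_params()] object.
#' @export
synth_preset <- function(name = c("paper-scale", "tiny"), seed = 1L) {
  name <- match.arg(name)
  switch(name,
    "paper-scale" = synth_params(n_tf = 169L, n_mirna = 83L, n_gene = 153L,
                                 universe_size = 1000L,
                                 p_tg = 0.15, p_tm = 0.025,
                                 p_mg = 0.15, p_mt = 0.025,
                                 validated_fraction = 0.15, seed = seed),
    "tiny" = synth_params(n_tf = 8L, n_mirna = 8L, n_gene = 20L,
                          universe_size = 30L,
                          p_tg = 0.15, p_tm = 0.1, p_mg = 0.15, p_mt = 0.1,
                          validated_fraction = 0.2, seed = seed))
}

# vectorized independent edge draws between two symbol vectors
draw_edges <- function(from, to, p, no_self = TRUE) {
  if (length(from) == 0L || length(to) == 0L || p == 0) {
    return(data.frame(regulator = character(), target = character(),
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(regulator = from, to = to, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  names(grid) <- c("regulator", "target")
  if (no_self) grid <- grid[grid$regulator != grid$target, , drop = FALSE]
  keep <- stats::runif(nrow(grid)) < p
  grid[keep, , drop = FALSE]
}

#' Generate a synthetic regulatory set and catalog
#'
#' Draws the four edge types independently with their per-type
#' probabilities, labels each edge validated with probability
#' `validated_fraction` (else predicted), and samples the disease genes
#' uniformly from the gene universe. Deterministic under `params$seed`.
#'
#' @param params a [synth_params()] object.
#' @return list with elements `reg` (a `regulatory_set`) and `cat`
#'   (a [catalog()]).
#' @export
synth_generate <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  tfs <- sprintf("TF%03d", seq_len(params$n_tf))
  mirs <- sprintf("miR-%03d", seq_len(params$n_mirna))
  genes <- sprintf("G%05d", seq_len(params$universe_size))

  set.seed(params$seed)
  tg <- draw_edges(tfs, genes, params$p_tg)
  tm <- draw_edges(tfs, mirs, params$p_tm)
  mg <- draw_edges(mirs, genes, params$p_mg)
  mt <- draw_edges(mirs, tfs, params$p_mt)
  df <- rbind(
    cbind(tg, regulator_type = rep("TF", nrow(tg)),
          target_type = rep("gene", nrow(tg))),
    cbind(tm, regulator_type = rep("TF", nrow(tm)),
          target_type = rep("miRNA", nrow(tm))),
    cbind(mg, regulator_type = rep("miRNA", nrow(mg)),
          target_type = rep("gene", nrow(mg))),
    cbind(mt, regulator_type = rep("miRNA", nrow(mt)),
          target_type = rep("TF", nrow(mt)))
  )
  df$evidence <- ifelse(stats::runif(nrow(df)) < params$validated_fraction,
                        "validated", "predicted")
  disease_genes <- sort(sample(genes, params$n_gene))
  list(
    reg = new_regulatory_set(df),
    cat = catalog(disease_genes = disease_genes, disease_mirnas = mirs,
                  tf_universe = tfs, gene_universe = genes)
  )
}

#' Closed-form expected motif counts under the independence model
#'
#' For independent edges, the expected number of each motif class over the
#' (TF, disease miRNA, disease gene) triples is the product of the required
#' edge probabilities (and the complements of the excluded cross edges):
#' \deqn{E[TF\text{-}FFL] = n_{tf} n_{mir} n_{gene}\, p_{tg} p_{mg} p_{tm} (1-p_{mt})}
#' and symmetrically for miRNA-FFLs; composite-FFLs require both cross
#' edges; FBLs are over (TF, miRNA) pairs only.
#'
#' @param params a [synth_params()] object.
#' @return Named numeric vector with elements tf_ffl, mirna_ffl,
#'   composite_ffl, fbl.
#' @export
expected_motif_counts <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  triples <- params$n_tf * params$n_mirna * params$n_gene
  base <- triples * params$p_tg * params$p_mg
  c(tf_ffl = base * params$p_tm * (1 - params$p_mt),
    mirna_ffl = base * params$p_mt * (1 - params$p_tm),
    composite_ffl = base * params$p_tm * params$p_mt,
    fbl = params$n_tf * params$n_mirna * params$p_tm * params$p_mt)
}

#' Generate a synthetic differential-expression table
#'
#' Null genes receive p ~ Uniform(0, 1); a `signal_fraction` of genes
#' receive p ~ Uniform(0, effect_p_scale). Directions are Bernoulli(1/2).
#' Deterministic under `seed`.
#'
#' @param n_genes number of genes (symbols G00001... unless `genes` given).
#' @param signal_fraction fraction of genes carrying signal, in [0, 1].
#' @param effect_p_scale upper bound of the signal p-value distribution.
#' @param seed RNG seed.
#' @param genes optional character vector of gene symbols to use.
#' @return data.frame with columns gene, p_value, direction.
#' @export
synth_de_table <- function(n_genes, signal_fraction = 0.1,
                           effect_p_scale = 0.005, seed = 1L, genes = NULL) {
  if (!(signal_fraction >= 0 && signal_fraction <= 1)) {
    stop("signal_fraction must be in [0, 1]")
  }
  if (is.null(genes)) genes <- sprintf("G%05d", seq_len(n_genes))
  n_genes <- length(genes)
  if (n_genes == 0L) {
    return(data.frame(gene = character(), p_value = numeric(),
                      direction = character(), stringsAsFactors = FALSE))
  }
  set.seed(as.integer(seed))
  n_signal <- round(signal_fraction * n_genes)
  signal <- rep(FALSE, n_genes)
  signal[sample.int(n_genes, n_signal)] <- TRUE
  p <- stats::runif(n_genes)
  p[signal] <- p[signal] * effect_p_scale
  data.frame(gene = genes, p_value = p,
             direction = ifelse(stats::runif(n_genes) < 0.5, "up", "down"),
             stringsAsFactors = FALSE)
}
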