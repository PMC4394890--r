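# Independent oracles and small fixture builders shared across the suite.
# The motif oracles are deliberately naive exhaustive scans over all
# candidate triples/pairs; they never share code with the package's
# pair-index enumeration.

# exhaustive O(n^3) FFL scan
brute_force_ffls <- function(reg, cat) {
  keys <- paste(reg$regulator, reg$target, reg$regulator_type, sep = "|")
  has <- function(r, t, ty) paste(r, t, ty, sep = "|") %in% keys
  rows <- list()
  for (tf in cat$tf_universe) {
    for (m in cat$disease_mirnas) {
      for (g in cat$disease_genes) {
        if (tf == g || tf == m || m == g) next
        if (!has(tf, g, "TF") || !has(m, g, "miRNA")) next
        tm <- has(tf, m, "TF")
        mt <- has(m, tf, "miRNA")
        if (!tm && !mt) next
        type <- if (tm && mt) "composite-FFL" else if (tm) "TF-FFL" else "miRNA-FFL"
        rows[[length(rows) + 1L]] <- data.frame(
          tf = tf, mirna = m, gene = g, loop_type = type,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(tf = character(), mirna = character(),
                      gene = character(), loop_type = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$tf, out$mirna, out$gene, method = "radix"), , drop = FALSE]
}

# exhaustive O(n^2) FBL scan
brute_force_fbls <- function(reg, cat) {
  keys <- paste(reg$regulator, reg$target, reg$regulator_type, sep = "|")
  has <- function(r, t, ty) paste(r, t, ty, sep = "|") %in% keys
  rows <- list()
  for (tf in cat$tf_universe) {
    for (m in cat$disease_mirnas) {
      if (has(tf, m, "TF") && has(m, tf, "miRNA")) {
        rows[[length(rows) + 1L]] <- data.frame(tf = tf, mirna = m,
                                                stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(tf = character(), mirna = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$tf, out$mirna, method = "radix"), , drop = FALSE]
}

ffl_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  paste(df$tf, df$mirna, df$gene, df$loop_type, sep = "|")
}

# a small hand-wired regulatory world used by several tests:
#   TF1 -> G1, G2; TF2 -> G1; miR-1 -| G1, G2; miR-2 -| G1
#   TF1 -> miR-1 (TF-FFL wiring); miR-2 -| TF2 (miRNA-FFL wiring)
toy_world <- function() {
  reg <- regulatory_set(
    regulator = c("TF1", "TF1", "TF2", "miR-1", "miR-1", "miR-2",
                  "TF1", "miR-2"),
    target    = c("G1", "G2", "G1", "G1", "G2", "G1", "miR-1", "TF2"),
    regulator_type = c("TF", "TF", "TF", "miRNA", "miRNA", "miRNA",
                       "TF", "miRNA"),
    evidence = "predicted"
  )
  cat <- catalog(disease_genes = c("G1", "G2"),
                 disease_mirnas = c("miR-1", "miR-2"),
                 tf_universe = c("TF1", "TF2"),
                 gene_universe = c("G1", "G2", "G3"))
  list(reg = reg, cat = cat)
}

# random small synthetic world with at most `max_nodes` regulator/target nodes
random_world <- function(seed, max_nodes = 50L) {
  set.seed(seed)
  n_tf <- sample(2:8, 1)
  n_mir <- sample(2:8, 1)
  n_gene <- sample(3:(max_nodes - n_tf - n_mir), 1)
  extra <- sample(0:10, 1)
  params <- synth_params(
    n_tf = n_tf, n_mirna = n_mir, n_gene = n_gene,
    universe_size = n_gene + extra,
    p_tg = runif(1, 0.05, 0.4), p_tm = runif(1, 0.05, 0.4),
    p_mg = runif(1, 0.05, 0.4), p_mt = runif(1, 0.05, 0.4),
    validated_fraction = runif(1), seed = seed + 1L)
  synth_generate(params)
}
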