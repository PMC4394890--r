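# Random-gene permutation test for FFL-count significance: how many FFLs do
# the observed disease genes form with a fixed TF and miRNA set, compared
# with equally sized gene sets drawn uniformly from a gene universe?
#
# Counting uses a pair index: for every cross-regulating (TF, miRNA) pair
# the shared targets are precomputed once, so each replicate only counts
# membership of the drawn genes in those target pools.

build_ffl_index <- function(tfs, mirnas, reg) {
  cat <- list(tf_universe = unique(tfs), disease_mirnas = unique(mirnas))
  pairs <- cross_pairs(reg, cat)
  is_tf <- reg$regulator_type == "TF" & reg$regulator %in% cat$tf_universe
  is_mir <- reg$regulator_type == "miRNA" & reg$regulator %in% cat$disease_mirnas
  tg_by_tf <- split(reg$target[is_tf], reg$regulator[is_tf])
  mg_by_mir <- split(reg$target[is_mir], reg$regulator[is_mir])
  pool <- character(0)
  if (nrow(pairs) > 0L) {
    shared <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      s <- intersect(tg_by_tf[[pairs$tf[i]]] %||% character(),
                     mg_by_mir[[pairs$mirna[i]]] %||% character())
      shared[[i]] <- s[s != pairs$tf[i] & s != pairs$mirna[i]]
    }
    pool <- unlist(shared, use.names = FALSE)
  }
  list(pool = pool)
}

count_ffls_index <- function(index, genes) {
  sum(index$pool %in% genes)
}

#' Count FFLs for a given gene set
#'
#' Total number of feed-forward loops formed by the given TFs, miRNAs and
#' genes on an unrestricted regulatory set (full target maps). Equals
#' `nrow(enumerate_ffls(...))` with the corresponding catalog.
#'
#' @param genes,tfs,mirnas character vectors of symbols.
#' @param reg a `regulatory_set` covering the full target maps.
#' @return Integer FFL count.
#' @export
observed_ffl_count <- function(genes, tfs, mirnas, reg) {
  stopifnot(inherits(reg, "regulatory_set"))
  count_ffls_index(build_ffl_index(tfs, mirnas, reg), unique(genes))
}

#' Permutation test for the observed FFL count
#'
#' Draws `replicates` gene sets of the observed size uniformly without
#' replacement from the universe, counts the FFLs each forms with the fixed
#' TF and miRNA sets, and reports the empirical p-value: the proportion of
#' replicates whose count is at least the observed count (no pseudo-count by
#' default; set `conservative = TRUE` for (b+1)/(R+1)). Each replicate uses a
#' deterministic RNG substream derived from the root seed, so results are
#' identical for identical seeds regardless of evaluation order.
#'
#' @param observed_genes character vector; the disease gene set under test.
#' @param tfs,mirnas fixed regulator sets.
#' @param reg unrestricted `regulatory_set`.
#' @param universe gene universe to resample from; must contain at least
#'   `length(observed_genes)` symbols.
#' @param replicates number of random draws (default 10000).
#' @param seed integer root seed.
#' @param conservative add-one correction, FALSE by default.
#' @return An object of class `permutation_result` with fields observed,
#'   null_counts, p_value, replicates, seed.
#' @export
permutation_test <- function(observed_genes, tfs, mirnas, reg, universe,
                             replicates = 10000L, seed = 1L,
                             conservative = FALSE) {
  stopifnot(inherits(reg, "regulatory_set"), replicates >= 1L)
  observed_genes <- unique(as.character(observed_genes))
  universe <- unique(as.character(universe))
  k <- length(observed_genes)
  if (k > length(universe)) {
    stop("configuration error: observed gene set (", k,
         ") larger than universe (", length(universe), ")")
  }
  index <- build_ffl_index(tfs, mirnas, reg)
  observed <- count_ffls_index(index, observed_genes)

  # fast membership counting: map the pair-index pool onto universe indices
  pool_idx <- match(index$pool, universe)
  in_univ <- !is.na(pool_idx)
  pool_idx <- pool_idx[in_univ]
  # pool entries outside the universe can never be drawn, but still count
  # toward the observed genes; null draws only see the in-universe part
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  n_univ <- length(universe)
  null_counts <- integer(replicates)
  memb <- logical(n_univ)
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    draw <- sample.int(n_univ, k)
    memb[draw] <- TRUE
    null_counts[r] <- sum(memb[pool_idx])
    memb[draw] <- FALSE
  }
  b <- sum(null_counts >= observed)
  p <- if (conservative) (b + 1) / (replicates + 1) else b / replicates
  structure(list(observed = observed, null_counts = null_counts,
                 p_value = p, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> observed = %d, replicates = %d, p = %g\n",
              x$observed, x$replicates, x$p_value))
  cat(sprintf("null counts: min %d, median %g, max %d\n",
              min(x$null_counts), stats::median(x$null_counts),
              max(x$null_counts)))
  invisible(x)
}

#' Exact resampling null by subset enumeration
#'
#' Enumerates every k-subset of the universe and computes the exact tail
#' probability P(count >= observed). Intended as the small-universe oracle
#' for [permutation_test()]; refuses when choose(n, k) exceeds `max_subsets`.
#'
#' @inheritParams permutation_test
#' @param max_subsets combinatorial safety bound (default 1e5).
#' @return list with fields p_value, observed, n_subsets.
#' @export
exact_null <- function(observed_genes, tfs, mirnas, reg, universe,
                       max_subsets = 1e5) {
  stopifnot(inherits(reg, "regulatory_set"))
  observed_genes <- unique(as.character(observed_genes))
  universe <- unique(as.character(universe))
  k <- length(observed_genes)
  n <- length(universe)
  if (k > n) stop("configuration error: observed gene set larger than universe")
  n_sub <- choose(n, k)
  if (n_sub > max_subsets) {
    stop("exact_null refused: choose(", n, ", ", k, ") = ",
         format(n_sub, big.mark = ","), " subsets exceeds the bound of ",
         format(max_subsets, big.mark = ","))
  }
  index <- build_ffl_index(tfs, mirnas, reg)
  observed <- count_ffls_index(index, observed_genes)
  subsets <- utils::combn(universe, k, simplify = FALSE)
  counts <- vapply(subsets, function(s) count_ffls_index(index, s), integer(1))
  list(p_value = mean(counts >= observed), observed = observed,
       n_subsets = length(subsets))
}
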