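test_that("loop types follow the cross-regulation definition", {
  cat <- catalog("G1", "M1", "T1", "G1")
  base <- data.frame(regulator = c("T1", "M1"), target = c("G1", "G1"),
                     regulator_type = c("TF", "miRNA"),
                     stringsAsFactors = FALSE)
  # no cross edge: no FFL
  expect_equal(nrow(enumerate_ffls(new_regulatory_set(base), cat)), 0L)
  # T -> M: TF-FFL
  tm <- rbind(base, data.frame(regulator = "T1", target = "M1",
                               regulator_type = "TF"))
  f1 <- enumerate_ffls(new_regulatory_set(tm), cat)
  expect_equal(f1$loop_type, "TF-FFL")
  # adding M -| T converts it to a composite-FFL
  both <- rbind(tm, data.frame(regulator = "M1", target = "T1",
                               regulator_type = "miRNA"))
  f2 <- enumerate_ffls(new_regulatory_set(both), cat)
  expect_equal(f2$loop_type, "composite-FFL")
  # M -| T alone: miRNA-FFL
  mt <- rbind(base, data.frame(regulator = "M1", target = "T1",
                               regulator_type = "miRNA"))
  f3 <- enumerate_ffls(new_regulatory_set(mt), cat)
  expect_equal(f3$loop_type, "miRNA-FFL")
  # FBLs need both cross edges
  expect_equal(nrow(enumerate_fbls(new_regulatory_set(tm), cat)), 0L)
  expect_equal(nrow(enumerate_fbls(new_regulatory_set(both), cat)), 1L)
})

test_that("enumeration equals the exhaustive scan on random graphs", {
  for (seed in 1:25) {
    w <- random_world(seed)
    reg <- restrict_to_scope(w$reg, w$cat)
    fast <- enumerate_ffls(reg, w$cat)
    slow <- brute_force_ffls(reg, w$cat)
    expect_setequal(ffl_key(fast), ffl_key(slow))
    fast_fbl <- enumerate_fbls(reg, w$cat)
    slow_fbl <- brute_force_fbls(reg, w$cat)
    expect_setequal(paste(fast_fbl$tf, fast_fbl$mirna),
                    paste(slow_fbl$tf, slow_fbl$mirna))
  }
})

test_that("scope restriction does not change the enumerated motifs", {
  for (seed in c(31, 32)) {
    w <- random_world(seed)
    expect_equal(ffl_key(enumerate_ffls(restrict_to_scope(w$reg, w$cat), w$cat)),
                 ffl_key(enumerate_ffls(w$reg, w$cat)))
  }
})

test_that("FFL output order is deterministic and each triple appears once", {
  w <- random_world(77)
  ffls <- enumerate_ffls(w$reg, w$cat)
  key <- paste(ffls$tf, ffls$mirna, ffls$gene)
  expect_false(anyDuplicated(key) > 0)
  expect_equal(ffls, ffls[order(ffls$tf, ffls$mirna, ffls$gene,
                                method = "radix"), ],
               ignore_attr = "row.names")
})

test_that("loop types partition the FFL set and composites imply FBLs", {
  for (seed in c(41, 42, 43)) {
    w <- random_world(seed)
    ffls <- enumerate_ffls(w$reg, w$cat)
    fbls <- enumerate_fbls(w$reg, w$cat)
    expect_true(all(ffls$loop_type %in%
                      c("TF-FFL", "miRNA-FFL", "composite-FFL")))
    expect_equal(sum(table(ffls$loop_type)), nrow(ffls))
    comp <- unique(paste(ffls$tf[ffls$loop_type == "composite-FFL"],
                         ffls$mirna[ffls$loop_type == "composite-FFL"]))
    expect_true(all(comp %in% paste(fbls$tf, fbls$mirna)))
    expect_lte(length(comp), nrow(fbls))
  }
})

test_that("adding edges never removes a motif instance", {
  w <- random_world(60)
  reg_full <- w$reg
  half <- as.data.frame(reg_full)[seq_len(floor(nrow(reg_full) / 2)), ]
  reg_half <- new_regulatory_set(half)
  k_half <- ffl_key(enumerate_ffls(reg_half, w$cat))
  k_full <- ffl_key(enumerate_ffls(reg_full, w$cat))
  # a motif may change type when a cross edge arrives, so compare triples
  triple <- function(k) sub("\\|[^|]*$", "", k)
  expect_true(all(triple(k_half) %in% triple(k_full)))
})

test_that("a motif is verified only when all constituent edges are validated", {
  cat <- catalog("G1", "M1", "T1", "G1")
  mk <- function(ev_tg, ev_mg, ev_tm) {
    new_regulatory_set(data.frame(
      regulator = c("T1", "M1", "T1"), target = c("G1", "G1", "M1"),
      regulator_type = c("TF", "miRNA", "TF"),
      evidence = c(ev_tg, ev_mg, ev_tm), stringsAsFactors = FALSE))
  }
  expect_true(enumerate_ffls(mk("validated", "both", "validated"), cat)$verified)
  expect_false(enumerate_ffls(mk("predicted", "validated", "validated"),
                              cat)$verified)
  expect_false(enumerate_ffls(mk("validated", "validated", "predicted"),
                              cat)$verified)
})

test_that("summarize_motifs reports counts per loop type and evidence class", {
  w <- toy_world()
  ffls <- enumerate_ffls(w$reg, w$cat)
  fbls <- enumerate_fbls(w$reg, w$cat)
  s <- summarize_motifs(ffls, fbls)
  expect_equal(s$module_type,
               c("TF-FFL", "miRNA-FFL", "composite-FFL", "FBL"))
  expect_equal(sum(s$modules[1:3]), nrow(ffls))
  expect_true(is.na(s$genes[s$module_type == "FBL"]))
  # all toy edges are predicted, so the verified columns are zero
  expect_true(all(s$verified_modules == 0))

  single <- enumerate_ffls(
    new_regulatory_set(data.frame(
      regulator = c("T1", "M1", "T1"), target = c("G1", "G1", "M1"),
      regulator_type = c("TF", "miRNA", "TF"), stringsAsFactors = FALSE)),
    catalog("G1", "M1", "T1", "G1"))
  s1 <- summarize_motifs(single)
  expect_equal(unlist(s1[s1$module_type == "TF-FFL",
                         c("modules", "genes", "mirnas", "tfs")],
                      use.names = FALSE), c(1L, 1L, 1L, 1L))
})

test_that("a TF-coding disease gene can take either role, never both in one triple", {
  # TFX is both a universe TF and a disease gene
  cat <- catalog(disease_genes = c("G1", "TFX"), disease_mirnas = "M1",
                 tf_universe = c("T1", "TFX"), gene_universe = c("G1", "TFX"))
  reg <- new_regulatory_set(data.frame(
    regulator = c("T1", "M1", "T1", "TFX", "M1"),
    target    = c("TFX", "TFX", "M1", "G1", "G1"),
    regulator_type = c("TF", "miRNA", "TF", "TF", "miRNA"),
    stringsAsFactors = FALSE))
  ffls <- enumerate_ffls(reg, cat)
  # TFX takes the gene role in (T1, M1, TFX) and the TF role in
  # (TFX, M1, G1) — two separate instances, never both roles in one triple
  expect_setequal(ffl_key(ffls),
                  c("T1|M1|TFX|TF-FFL", "TFX|M1|G1|miRNA-FFL"))
  expect_false(any(ffls$tf == ffls$gene))
  expect_true(all(ffl_key(ffls) %in% ffl_key(brute_force_ffls(reg, cat))))
})
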