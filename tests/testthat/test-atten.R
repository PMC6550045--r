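# Transcriptome arm: filtering, normalization, the paired NB test, set
# algebra, attenuation and delta-delta-Ct.

# Small paired count container with prescribed group means (noiseless).
make_counts <- function(mat, treatments, replicates) {
  meta <- data.frame(sample = paste(treatments, replicates, sep = "_r"),
                     treatment = treatments, replicate = replicates)
  colnames(mat) <- meta$sample
  wound_counts(mat, meta)
}

two_group_cm <- function(ctrl, amp) {
  mat <- cbind(matrix(rep(ctrl, 3), ncol = 3),
               matrix(rep(amp, 3), ncol = 3))
  make_counts(mat, rep(c("control", "amp"), each = 3), rep(1:3, 2))
}

test_that("the low-count filter applies the total-30 boundary rule", {
  cm <- two_group_cm(c(5, 5, 100), c(4, 5, 100))
  # gene 1: 3*5 + 3*4 = 27 < 30 -> removed; gene 2: 30 -> retained
  kept <- filter_low_counts(cm, "amp")
  expect_false(rownames(cm$counts)[1] %in% kept)
  expect_true(rownames(cm$counts)[2] %in% kept)
  expect_true(rownames(cm$counts)[3] %in% kept)
  expect_error(filter_low_counts(cm, "beclo"), "not in metadata")
})

test_that("the low-count filter equals the row-sum oracle on random input", {
  set.seed(14)
  mat <- matrix(rpois(100 * 6, 6), 100, 6)
  cm <- make_counts(mat, rep(c("control", "amp"), each = 3), rep(1:3, 2))
  kept <- filter_low_counts(cm, "amp")
  oracle <- rownames(cm$counts)[rowSums(mat) >= 30]
  expect_identical(kept, oracle)
})

test_that("size factors follow the median-of-ratios definition", {
  mat <- matrix(rep(c(10, 20, 50, 100), 4), ncol = 4)
  expect_equal(unname(size_factors(mat)), rep(1, 4))
  # doubling one sample doubles its factor relative to the others
  mat2 <- mat; mat2[, 2] <- mat2[, 2] * 2
  sf2 <- unname(size_factors(mat2))
  expect_equal(sf2[2] / sf2[1], 2, tolerance = 1e-12)
  expect_equal(sf2[c(1, 3, 4)], rep(sf2[1], 3), tolerance = 1e-12)
  set.seed(3)
  m <- matrix(rnbinom(200 * 5, mu = 50, size = 5) + 1L, 200, 5)
  sf <- size_factors(m)
  geo <- exp(rowMeans(log(m)))
  oracle <- apply(m, 2, function(s) median(s / geo))
  expect_equal(unname(sf), unname(oracle), tolerance = 1e-12)
  expect_error(size_factors(matrix(c(0, 1, 1, 0), 2, 2)), "nonzero")
})

test_that("a gene with identical counts in both groups is a clean null", {
  base <- c(100, 40, 60, 200, 30, 500, 80, 120, 90, 150)
  cm <- two_group_cm(base, base)
  res <- paired_nb_test(cm, "amp")
  expect_equal(res$log2fc, rep(0, nrow(res)), tolerance = 1e-10)
  expect_true(all(res$p > 0.9))
})

test_that("the paired NB test picks up a strong planted fold change", {
  sim <- simulate_counts(count_sim_config(n_genes = 400, seed = 19))
  res <- paired_nb_test(sim$counts, "amp")
  truth <- sim$truth[match(res$gene, sim$truth$gene), ]
  up_true <- truth$lfc_amp > 1
  reg <- classify_regulation(list(amp = res))
  # most strongly upregulated genes land in the up-set, none in the down-set
  expect_gt(mean(res$gene[up_true] %in% reg$up$amp), 0.8)
  expect_equal(sum(res$gene[up_true] %in% reg$down$amp), 0)
  # log2FC estimates track the truth
  expect_lt(mean(abs(res$log2fc - truth$lfc_amp)[truth$class != "null"]), 0.5)
})

test_that("regulation cutoffs are applied exactly", {
  res <- data.frame(gene = c("A", "B", "C", "D"),
                    log2fc = c(log2(2.5), log2(1.8), -2, -0.5),
                    fold_change = c(2.5, 1.8, 0.25, 2^-0.5),
                    p = c(0.001, 0.001, 0.001, 0.001),
                    p_adj = c(0.04, 0.04, 0.04, 0.06))
  reg <- classify_regulation(list(x = res))
  expect_identical(reg$up$x, "A")       # FC 1.8 excluded, p_adj 0.06 excluded
  expect_identical(reg$down$x, "C")
  expect_equal(length(intersect(reg$up$x, reg$down$x)), 0)
})

test_that("Venn intersection counts equal set algebra on toy sets", {
  mk <- function(up_genes, down_genes) {
    genes <- c("A", "B", "C", "D", "E")
    data.frame(gene = genes,
               log2fc = ifelse(genes %in% up_genes, 2,
                               ifelse(genes %in% down_genes, -2, 0)),
               fold_change = ifelse(genes %in% up_genes, 4,
                                    ifelse(genes %in% down_genes, 0.25, 1)),
               p = 0.001,
               p_adj = ifelse(genes %in% c(up_genes, down_genes), 0.01, 0.9))
  }
  res <- list(amp = mk(c("A", "B", "C"), "E"),
              beclo = mk("B", character(0)),
              amp_beclo = mk(c("B", "C"), "E"))
  reg <- classify_regulation(res)
  v <- reg$venn
  expect_equal(v$n_up[v$contrasts == "amp"], 3)
  expect_equal(v$n_up[v$contrasts == "amp&amp_beclo"], 2)   # {B, C}
  expect_equal(v$n_up[v$contrasts == "amp&beclo&amp_beclo"], 1)  # {B}
  expect_equal(v$n_down[v$contrasts == "amp&amp_beclo"], 1)  # {E}
  expect_equal(v$n_down[v$contrasts == "beclo"], 0)
})

test_that("attenuation classes follow the definitions and partition the set", {
  amp <- data.frame(gene = c("A", "B", "C", "D"),
                    log2fc = c(2, -1.5, 1, 3))
  combo <- data.frame(gene = c("A", "B", "C", "D"),
                      log2fc = c(1, -2, 1, -0.5))
  af <- attenuation_fraction(amp, combo, c("A", "B", "C", "D"))
  cls <- setNames(af$table$class, af$table$gene)
  expect_equal(unname(cls["A"]), "attenuated")    # 2 -> 1
  expect_equal(unname(cls["B"]), "enhanced")      # -1.5 -> -2
  expect_equal(unname(cls["C"]), "unchanged")     # equal magnitudes
  expect_equal(unname(cls["D"]), "sign_flipped")  # 3 -> -0.5
  expect_equal(sum(af$counts), 4)
  expect_equal(af$fraction_attenuated, 0.25)
  # the flipped gene has |combo| < |amp|, so the identity-line tally adds it
  expect_equal(af$fraction_attenuated_incl_flipped, 0.5)
  expect_error(attenuation_fraction(amp, combo, character(0)), "empty")
})

test_that("three of four attenuated genes give fraction 0.75", {
  amp <- data.frame(gene = letters[1:4], log2fc = c(2, 2, -3, 1.5))
  combo <- data.frame(gene = letters[1:4], log2fc = c(1, 0.5, -1, 1.5))
  af <- attenuation_fraction(amp, combo, letters[1:4])
  expect_equal(af$fraction_attenuated, 0.75)
  expect_equal(sum(af$counts), af$n)
})

test_that("genes missing from the combined contrast count as unchanged", {
  amp <- data.frame(gene = c("A", "B"), log2fc = c(2, 2))
  combo <- data.frame(gene = "A", log2fc = 1)
  af <- attenuation_fraction(amp, combo, c("A", "B"))
  expect_equal(unname(setNames(af$table$class, af$table$gene)["B"]),
               "unchanged")
  expect_true(af$table$combo_missing[af$table$gene == "B"])
})

test_that("the immune-gene table joins fold changes across contrasts", {
  res <- list(
    amp = data.frame(gene = c("il1b", "tnfa"), log2fc = c(3, 2),
                     fold_change = c(8, 4), p = 0.01, p_adj = 0.02),
    beclo = data.frame(gene = c("il1b", "tnfa"), log2fc = c(0.1, -0.2),
                       fold_change = 2^c(0.1, -0.2), p = 0.5, p_adj = 0.7),
    amp_beclo = data.frame(gene = c("il1b", "tnfa"), log2fc = c(1, 1),
                           fold_change = c(2, 2), p = 0.05, p_adj = 0.1))
  expect_equal(nrow(immune_gene_table(res, character(0))), 0)
  tab <- immune_gene_table(res, "il1b")
  expect_equal(nrow(tab), 3)
  expect_equal(tab$fold_change[tab$contrast == "amp"], 8)
  w <- capture_warnings(immune_gene_table(res, c("il1b", "nosuchgene")))
  expect_length(w, 3)             # one per contrast
  expect_true(all(grepl("absent", w)))
  # join oracle: every row matches its source contrast result
  tab2 <- suppressWarnings(immune_gene_table(res, c("il1b", "tnfa")))
  for (r in seq_len(nrow(tab2))) {
    src <- res[[tab2$contrast[r]]]
    expect_equal(tab2$log2fc[r], src$log2fc[src$gene == tab2$gene[r]])
  }
})

test_that("delta-delta-Ct fold changes match hand computation", {
  ct <- data.frame(sample = c("c1", "c2", "t1"),
                   gene = "il1b",
                   ct = c(22, 22, 20),
                   ref_ct = c(15, 15, 15))
  out <- ddct_fold_change(ct, control_samples = c("c1", "c2"))
  expect_equal(out$fold_change[out$sample == "t1"], 4)   # 2 cycles earlier
  expect_equal(out$fold_change[out$sample == "c1"], 1)
  # reference-gene shifts cancel
  ct2 <- transform(ct, ct = ct + 3, ref_ct = ref_ct + 3)
  out2 <- ddct_fold_change(ct2, c("c1", "c2"))
  expect_equal(out2$fold_change, out$fold_change)
  expect_error(ddct_fold_change(transform(ct, ref_ct = NA), c("c1", "c2")),
               "reference")
})

test_that("delta-delta-Ct matches a spreadsheet-style recomputation", {
  set.seed(22)
  samples <- c("c1", "c2", "c3", "t1", "t2", "t3")
  genes <- c("il6", "mmp9")
  ct <- expand.grid(sample = samples, gene = genes,
                    stringsAsFactors = FALSE)
  ct$ct <- runif(nrow(ct), 18, 30)
  ct$ref_ct <- runif(nrow(ct), 14, 16)
  out <- ddct_fold_change(ct, control_samples = c("c1", "c2", "c3"))
  for (r in seq_len(nrow(out))) {
    dct <- ct$ct[r] - ct$ref_ct[r]
    ctl <- ct$sample %in% c("c1", "c2", "c3") & ct$gene == ct$gene[r]
    expected <- 2^(-(dct - mean(ct$ct[ctl] - ct$ref_ct[ctl])))
    expect_equal(out$fold_change[r], expected, tolerance = 1e-12)
  }
})

test_that("scaling all counts by an integer leaves log2FCs unchanged", {
  base_c <- c(100, 40, 60, 200, 500)
  base_t <- c(400, 40, 30, 200, 1000)
  cm1 <- two_group_cm(base_c, base_t)
  cm4 <- two_group_cm(base_c * 4L, base_t * 4L)
  r1 <- paired_nb_test(cm1, "amp", genes = rownames(cm1$counts))
  r4 <- paired_nb_test(cm4, "amp", genes = rownames(cm4$counts))
  # relative normalization is invariant to a common multiplier ...
  expect_equal(unname(size_factors(cm4$counts)),
               unname(size_factors(cm1$counts)), tolerance = 1e-10)
  # ... and log2FCs agree up to the pseudocount's vanishing influence
  expect_equal(r1$log2fc, r4$log2fc, tolerance = 0.02)
})

test_that("the test pipeline is deterministic", {
  sim <- simulate_counts(count_sim_config(n_genes = 150, seed = 33))
  a <- paired_nb_test(sim$counts, "amp")
  b <- paired_nb_test(sim$counts, "amp")
  expect_identical(a, b)
})

test_that("the counts container validates its inputs", {
  mat <- matrix(1:12, 3, 4)
  meta <- data.frame(sample = paste0("s", 1:4),
                     treatment = c("control", "control", "amp", "amp"),
                     replicate = c(1, 2, 1, 2))
  expect_s3_class(wound_counts(mat, meta), "wound_counts")
  expect_error(wound_counts(mat - 5, meta), "non-negative")
  expect_error(wound_counts(mat, meta[1:3, ]), "one meta row")
  bad <- meta; bad$treatment[1] <- "sham"
  expect_error(wound_counts(mat, bad), "treatments must be")
})
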