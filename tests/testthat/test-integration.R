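test_that("expression_stats applies the expressed-gene rule and CPM math", {
  m <- rbind(
    allzero_ctrl = c(0, 0, 0, 0, 5, 5, 5, 5),
    flat = rep(8, 8),
    shifted = c(10, 10, 10, 10, 20, 20, 20, 20))
  colnames(m) <- paste0("s", 1:8)
  # equal library sizes by adding a balancing gene
  m <- rbind(m, filler = max(colSums(m)) + 10 - colSums(m))
  cm <- count_matrix(m, groups = rep(c("ctrl", "trt"), each = 4))
  st <- expression_stats(cm, control = "ctrl", treatment = "trt")
  expect_false("allzero_ctrl" %in% st$gene_id)
  expect_equal(attr(st, "n_dropped"), 1)
  flat <- st[st$gene_id == "flat", ]
  expect_equal(flat$d_mean, 0)
  expect_equal(flat$d_cv, 0)
  sh <- st[st$gene_id == "shifted", ]
  lib <- unname(colSums(m)[1])
  expect_equal(sh$d_mean, 10 / lib * 1e6)
  expect_equal(sh$d_cv, 0)
  expect_error(expression_stats(cm[, c(1, 2, 5, 6)]), "3 replicates")
})

test_that("bias_index matches hand computations and tie conventions", {
  expect_equal(bias_index(c(5, 2, 1)), 1)
  expect_equal(bias_index(c(5, -2, 1)), 1 / 3)
  expect_equal(bias_index(c(3, -3)), 0)
  # zero differences keep their zero-signed average rank by default
  expect_equal(bias_index(c(0, 1)), 2 / 3)  # signed ranks (0, +2) over 3
  expect_equal(bias_index(c(0, 1), drop_zeros = TRUE), 1)
  expect_error(bias_index(numeric(0)), "empty")
  expect_error(bias_index(0, drop_zeros = TRUE), "empty")
})

test_that("bias_index is the rescaled Wilcoxon signed-rank statistic", {
  set.seed(42)
  for (i in 1:500) {
    n <- sample(3:40, 1)
    x <- round(rnorm(n), 6)
    v <- suppressWarnings(wilcox.test(x)$statistic)  # sum of positive ranks
    expect_equal(bias_index(x),
                 (2 * unname(v) - n * (n + 1) / 2) / (n * (n + 1) / 2),
                 tolerance = 1e-12)
  }
})

mk_stats <- function(d_mean, chrom = rep("c1", length(d_mean))) {
  structure(data.frame(gene_id = paste0("g", seq_along(d_mean)),
                       chrom = chrom, d_mean = d_mean, d_cv = -d_mean,
                       stringsAsFactors = FALSE),
            class = c("expr_stats", "data.frame"))
}

test_that("mcw_test is exact on a degenerate subset and matches
           exhaustive enumeration on a toy", {
  st <- mk_stats(c(3, -1, 2, -4, 5))
  # subset = all expressed genes: every permutation identical
  all_test <- mcw_test(st, st$gene_id, "mean", n_perm = 50, seed = 1)
  expect_equal(all_test$p_upper, 1)
  expect_equal(all_test$p_lower, 1)

  # exhaustive oracle over all C(5,2) = 10 subsets of size 2
  combos <- combn(5, 2)
  b_all <- apply(combos, 2, function(ix) bias_index(st$d_mean[ix]))
  b_obs <- bias_index(st$d_mean[c(1, 3)])
  p_up_exact <- mean(b_all >= b_obs)
  p_lo_exact <- mean(b_all <= b_obs)
  mc <- mcw_test(st, c("g1", "g3"), "mean", n_perm = 4000, seed = 7)
  expect_equal(mc$b_observed, b_obs)
  se <- sqrt(p_up_exact * (1 - p_up_exact) / 4000)
  expect_lt(abs(mc$p_upper - p_up_exact), 3 * se + 1e-9)
  se2 <- sqrt(p_lo_exact * (1 - p_lo_exact) / 4000)
  expect_lt(abs(mc$p_lower - p_lo_exact), 3 * se2 + 1e-9)

  st2 <- mk_stats(c(1, 2, 3), chrom = c("c1", "c1", "c2"))
  expect_error(mcw_test(st2, "g9", "mean"), "not an expressed gene")
})

test_that("mcw_test is deterministic under a fixed seed", {
  st <- mk_stats(rnorm(40), chrom = rep(c("c1", "c2"), 20))
  a <- mcw_test(st, paste0("g", 1:10), "mean", n_perm = 200, seed = 5)
  b <- mcw_test(st, paste0("g", 1:10), "mean", n_perm = 200, seed = 5)
  expect_identical(a[c("b_observed", "p_upper", "p_lower")],
                   b[c("b_observed", "p_upper", "p_lower")])
})

test_that("subset assignment distinguishes TSS window, body/flank and
           blocks", {
  lay <- toy_layout(c(chr1 = 5e4))
  genes <- data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = "chr1",
    start = c(5000, 20000, 40000),
    end = c(15000, 30000, 45000),
    strand = c("+", "+", "+"), stringsAsFactors = FALSE)
  grid <- build_window_grid(lay, 100)
  mk_dmr <- function(start, dir) {
    d <- data.frame(chrom = "chr1", start = start, end = start + 100,
                    window = start / 100 + 1, direction = dir,
                    pvalue = 1e-5, stringsAsFactors = FALSE)
    class(d) <- c("dmr_set", "data.frame")
    d
  }
  blocks <- data.frame(chrom = "chr1", start = 38000, end = 46000,
                       direction = "hypo", n_dmrs = 2,
                       stringsAsFactors = FALSE)
  class(blocks) <- c("isodmb_set", "data.frame")

  # DMR ending exactly where the TSS window starts: half-open, no overlap
  d1 <- mk_dmr(3400, "hyper")  # gA TSS window is [3500, 5500)
  s1 <- assign_subsets(genes, d1, blocks, lay)
  expect_false(s1$I_hyper[1])
  # a DMR 4 kb into the gene body: Subset II yes, Subset I no
  d2 <- mk_dmr(9000, "hyper")
  s2 <- assign_subsets(genes, d2, blocks, lay)
  expect_false(s2$I_hyper[1])
  expect_true(s2$II_hyper[1])
  # DMR overlapping the TSS window
  d3 <- mk_dmr(3600, "hyper")
  expect_true(assign_subsets(genes, d3, blocks, lay)$I_hyper[1])
  # intergenic DMR flags its two flanking genes (Subset II)
  d4 <- mk_dmr(17000, "hypo")
  s4 <- assign_subsets(genes, d4, blocks, lay)
  expect_equal(s4$II_hypo, c(TRUE, TRUE, FALSE))
  # gene fully inside a hypo block -> Subset III hypo
  s5 <- assign_subsets(genes, d1, blocks, lay)
  expect_equal(s5$III_hypo, c(FALSE, FALSE, TRUE))
})

test_that("call_degs thresholds and coherence matches exhaustive
           enumeration on a toy", {
  dge <- data.frame(feature_id = c("g1", "g2"), mean_ctrl = 1, mean_trt = 2,
                    log2fc = 1, pvalue = c(0.01, 0.2),
                    direction = c("up", "up"), stringsAsFactors = FALSE)
  expect_equal(nrow(call_degs(dge, alpha = 1e-9)), 0)
  expect_equal(nrow(call_degs(dge, alpha = 1)), 2)
  expect_equal(call_degs(dge, 0.05)$gene_id, "g1")

  # toy: 2 blocks x 3 genes, both up-DEGs in the hypo block
  genes <- data.frame(
    gene_id = paste0("g", 1:6), chrom = "chr1",
    start = c(100, 1100, 2100, 5100, 6100, 7100),
    end = c(900, 1900, 2900, 5900, 6900, 7900),
    strand = "+", stringsAsFactors = FALSE)
  blocks <- data.frame(chrom = "chr1", start = c(0, 5000),
                       end = c(3000, 8000),
                       direction = c("hypo", "hyper"), n_dmrs = 3,
                       stringsAsFactors = FALSE)
  class(blocks) <- c("isodmb_set", "data.frame")
  degs <- data.frame(gene_id = c("g1", "g2"), direction = "up",
                     pvalue = 0.01, stringsAsFactors = FALSE)
  res <- coherence_test(blocks, degs, genes, genes$gene_id,
                        n_perm = 4000, seed = 9)
  hypo <- res$table[res$table$direction == "hypo", ]
  expect_equal(hypo$frac_ge2, 1)
  expect_equal(hypo$frac_all_up, 1)
  # exhaustive: both tags land in the hypo block for C(3,2)/C(6,2) = 0.2
  p_exact <- choose(3, 2) / choose(6, 2)
  se <- sqrt(p_exact * (1 - p_exact) / 4000)
  expect_lt(abs(hypo$p_upper_ge2 - p_exact), 3 * se)
  expect_lt(abs(hypo$p_upper_all_up - p_exact), 3 * se)

  # no block holds >= 2 DEGs -> all fractions 0
  degs1 <- degs[1, ]
  res0 <- coherence_test(blocks, degs1, genes, genes$gene_id,
                         n_perm = 100, seed = 1)
  expect_true(all(res0$table$frac_ge2 == 0))
  expect_error(coherence_test(blocks, data.frame(gene_id = "zz",
                                                 direction = "up"),
                              genes, genes$gene_id),
               "subset of expressed")
})

test_that("hypergeometric enrichment matches closed forms and BH", {
  # query == set of size 2 in a universe of 5: p = 1/C(5,2) = 0.1
  universe <- paste0("g", 1:5)
  res <- enrichment_test(c("g1", "g2"), universe,
                         list(s = c("g1", "g2")))
  expect_equal(res$pvalue, 0.1)
  # empty overlap with a large set -> p near 1
  res2 <- enrichment_test("g1", universe, list(s = paste0("g", 2:5)))
  expect_gt(res2$pvalue, 0.75)
  # BH arithmetic
  sets <- list(a = c("g1"), b = c("g1", "g2"), c = c("g1", "g2", "g3"))
  res3 <- enrichment_test(paste0("g", 1:3), universe, sets)
  expect_equal(res3$qvalue,
               p.adjust(res3$pvalue, "BH"))
  expect_error(enrichment_test("zz", universe, sets), "outside")
})

test_that("GMT reader parses sets and rejects short lines", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2", "setB\tdesc\tg3"), path)
  sets <- read_gmt(path)
  expect_equal(sets, list(setA = c("g1", "g2"), setB = "g3"))
  writeLines("bad\tonlydesc", path)
  expect_error(read_gmt(path), "GMT line 1")
})
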