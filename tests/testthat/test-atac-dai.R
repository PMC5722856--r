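test_that("region_counts partitions signal exactly", {
  lay <- toy_layout(c(c1 = 300))
  grid <- build_window_grid(lay, 100)
  m <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
              dimnames = list(paste0("w", 1:3), c("s1", "s2")))
  wins <- count_matrix(m, groups = c("a", "b"))

  whole <- data.frame(chrom = "c1", start = 0, end = 300)
  rc <- region_counts(wins, grid, whole)
  expect_equal(unname(rc$counts[1, ]), unname(colSums(m)))

  halves <- data.frame(chrom = "c1", start = c(0, 150), end = c(150, 300))
  rc2 <- region_counts(wins, grid, halves)
  expect_equal(unname(colSums(rc2$counts)), unname(colSums(m)))
  # window midpoints at 50, 150, 250: first region gets w1, second w2+w3
  expect_equal(unname(rc2$counts[, 1]), c(1, 2 + 3))

  toy <- data.frame(chrom = "c1", start = c(0, 100), end = c(100, 300))
  rc3 <- region_counts(wins, grid, toy)
  expect_equal(unname(rc3$counts[, 2]), c(4, 5 + 6))
  expect_error(region_counts(wins, grid,
                             data.frame(chrom = "c1", start = 0, end = 999),
                             layout = lay),
               "exceeds")
})

test_that("QC boundaries are strict below the cutoffs", {
  m <- matrix(c(1500, 1499, 3000), nrow = 1,
              dimnames = list("r1", c("s1", "s2", "s3")))
  cm <- count_matrix(m, groups = c("a", "a", "b"))
  qc <- qc_filter(cm, total_reads = c(10000, 2000, 20001),
                  region_bp = 2e6)
  # s1: depth 1500 (pass boundary), eff 0.15 exactly (pass boundary)
  # s2: depth 1499 -> fail;  s3: eff 0.1499... -> fail
  expect_equal(qc$qc$pass, c(TRUE, FALSE, FALSE))
  expect_equal(colnames(qc$passed$counts), "s1")
  expect_equal(qc$qc$efficiency[1], 0.15)
  expect_equal(qc$qc$efficiency_per_mb[1], 0.15 / 2)
})

test_that("call_dais maps direction to accessibility", {
  set.seed(14)
  iso <- classify_isochores(data.frame(
    chrom = "c1", start = seq(0, 900, 100), end = seq(100, 1000, 100),
    gc = rep(c(35, 50), 5)))
  n <- 6
  base <- rep(500, 10)
  eff <- ifelse(iso$class == "H2", 0.5, 2)   # strong planted effects
  m <- cbind(matrix(rnbinom(10 * n, size = 100, mu = base), 10),
             matrix(rnbinom(10 * n, size = 100, mu = base * eff), 10))
  dimnames(m) <- list(paste0("r", 1:10), paste0("s", 1:(2 * n)))
  cm <- count_matrix(m, groups = rep(c("DMSO", "TBT"), each = n))
  # quantile normalization is meaningless on 10 features shifted in bulk;
  # test the direction mapping on raw counts
  dais <- call_dais(cm, iso, alpha = 0.05, control = "DMSO",
                    treatment = "TBT", normalization = "none")
  expect_true(all(dais$direction[dais$class == "H2"] == "inaccessible"))
  expect_true(all(dais$direction[dais$class == "L1"] == "accessible"))
  # alpha -> 0 calls nothing
  dais0 <- call_dais(cm, iso, alpha = 1e-300, control = "DMSO",
                     treatment = "TBT")
  expect_true(all(dais0$direction == "none"))
})

test_that("class-fraction permutation p matches the hypergeometric
           enumeration on a 20-isochore toy", {
  dai <- data.frame(
    chrom = "c1", start = seq(0, 1900, 100) * 100,
    end = (seq(0, 1900, 100) + 50) * 100,
    class = rep(c("H2", "L1"), each = 10),
    pvalue = 0.01,
    direction = c(rep("inaccessible", 9), "accessible",
                  rep("accessible", 9), "inaccessible"),
    stringsAsFactors = FALSE)
  class(dai) <- c("dai_table", "data.frame")
  res <- dai_class_fractions(dai, n_perm = 10000, seed = 21)
  row <- res[res$class == "H2" & res$direction == "inaccessible", ]
  expect_equal(row$k, 9)
  expect_equal(row$fraction, 0.9)
  # exact: K ~ Hypergeom(10 H2 slots among 20, 10 inaccessible tags)
  p_exact <- sum(dhyper(9:10, 10, 10, 10))
  se <- sqrt(p_exact * (1 - p_exact) / 10000)
  expect_lt(abs(row$p_upper - p_exact), 3 * se + 1e-4)

  # all tags one direction: permutation invariant, p = 1
  dai1 <- dai
  dai1$direction <- "accessible"
  res1 <- dai_class_fractions(dai1, n_perm = 200, seed = 1)
  expect_true(all(res1$p_upper[res1$direction == "accessible"] == 1))
  expect_error(dai_class_fractions(dai[dai$direction == "none", ]),
               "no significant DAIs")
})

test_that("shared DAIs count direction-consistent repeats and flag empty
           overlap", {
  mk <- function(direction) {
    d <- data.frame(chrom = "c1", start = seq(0, 400, 100),
                    end = seq(100, 500, 100), class = "H2",
                    pvalue = 0.01, direction = direction,
                    stringsAsFactors = FALSE)
    class(d) <- c("dai_table", "data.frame")
    d
  }
  a <- mk(c("accessible", "accessible", "inaccessible", "none", "none"))
  res <- shared_dais(a, a, n_perm = 200, seed = 2)
  expect_equal(res$fraction, 1)
  expect_equal(res$n_shared, 3)

  b <- mk(c("none", "none", "none", "accessible", "inaccessible"))
  res2 <- shared_dais(a, b, n_perm = 200, seed = 2)
  expect_equal(res2$n_shared, 0L)
  expect_true(is.na(res2$fraction))

  expect_error(shared_dais(a, mk("none")[1:3, ]), "same isochores")
})

test_that("clustering separates an engineered perfect split and keeps
           duplicates together", {
  set.seed(77)
  n_feat <- 40
  base <- 1000
  shift <- rep(c(1, 1.6), each = 6)
  m <- sapply(shift, function(s)
    rnbinom(n_feat, size = 400, mu = base * rep(c(1, s), length.out = n_feat)))
  dimnames(m) <- list(paste0("f", 1:n_feat), paste0("s", 1:12))
  cm <- count_matrix(m, groups = rep(c("DMSO", "TBT"), each = 6))
  res <- cluster_samples(cm, corr_prune = 0.99)
  expect_equal(sort(unname(as.vector(res$table))), c(0, 0, 6, 6))
  expect_equal(res$chisq, 12, tolerance = 1e-9)
  expect_equal(res$p_chisq, pchisq(12, 1, lower.tail = FALSE))

  # duplicated samples are perfectly correlated and co-cluster
  m2 <- cbind(m, dup1 = m[, 1], dup2 = m[, 1])
  cm2 <- count_matrix(m2, groups = c(rep(c("DMSO", "TBT"), each = 6),
                                     "DMSO", "DMSO"))
  res2 <- cluster_samples(cm2)
  expect_equal(res2$cluster[["s1"]], res2$cluster[["dup1"]])
  expect_equal(res2$cluster[["dup1"]], res2$cluster[["dup2"]])
  expect_error(cluster_samples(cm[, 1:3]), "4 samples")
})
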