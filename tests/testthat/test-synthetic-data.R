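small_cfg <- function(..., n_genes = 100) {
  sim_config(seed = 3, chrom_length = 1e6, n_genes = n_genes,
             n_blocks_per_chrom = 1, block_length_range = c(1e5, 2e5), ...)
}

test_that("the generator is deterministic under a fixed seed", {
  a <- simulate_genome(small_cfg())
  b <- simulate_genome(small_cfg())
  expect_identical(a$isochores, b$isochores)
  expect_identical(a$genes, b$genes)
  expect_identical(a$truth_blocks, b$truth_blocks)
  expect_identical(simulate_methylome(a)$counts, simulate_methylome(b)$counts)
  expect_identical(simulate_expression(a)$counts,
                   simulate_expression(b)$counts)
  expect_identical(simulate_atac(a)$counts$F3$counts,
                   simulate_atac(b)$counts$F3$counts)
})

test_that("gene placement follows the density weights", {
  # degenerate weights: all genes in H3 segments
  # few, short genes: they must all fit inside the H3 footprint
  cfg <- small_cfg(gene_density_weights = c(L1 = 0, L2 = 0, H1 = 0,
                                            H2 = 0, H3 = 1),
                   n_genes = 12, gene_length_meanlog = log(3000))
  sim <- simulate_genome(cfg)
  h3 <- sim$isochores[sim$isochores$class == "H3", ]
  gr_g <- GenomicRanges::GRanges(sim$genes$chrom,
                                 IRanges::IRanges(sim$genes$start + 1,
                                                  sim$genes$end))
  gr_h3 <- GenomicRanges::GRanges(h3$chrom,
                                  IRanges::IRanges(h3$start + 1, h3$end))
  expect_true(all(GenomicRanges::countOverlaps(gr_g, gr_h3) > 0))

  # flat weights: per-class gene counts proportional to class footprint
  cfg2 <- sim_config(seed = 5, gene_density_weights = rep(1, 5),
                     n_genes = 400)
  sim2 <- simulate_genome(cfg2)
  iso <- sim2$isochores
  mid <- (sim2$genes$start + sim2$genes$end) / 2
  cls <- iso$class[vapply(seq_along(mid), function(i) {
    which(iso$chrom == sim2$genes$chrom[i] & iso$start <= mid[i] &
            iso$end > mid[i])[1]
  }, 0L)]
  footprint <- tapply(iso$end - iso$start, iso$class, sum)
  footprint <- footprint / sum(footprint)
  for (cl in names(footprint)) {
    p <- footprint[[cl]]
    tol <- 3 * sqrt(p * (1 - p) / 400)
    expect_lt(abs(mean(cls == cl) - p), tol + 0.02)
  }

  # genes never overlap each other
  for (ch in unique(sim2$genes$chrom)) {
    g <- sim2$genes[sim2$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    expect_true(all(g$start[-1] >= g$end[-nrow(g)]))
  }
})

test_that("planted methylome effects have the stated magnitude and a true
           null is flat", {
  sim <- simulate_genome(small_cfg())
  meth <- simulate_methylome(sim)
  grid <- attr(meth, "grid")
  tb <- sim$truth_blocks
  gr_w <- GenomicRanges::GRanges(grid$chrom,
                                 IRanges::IRanges(grid$start + 1, grid$end))
  hyper <- tb[tb$direction == "hyper", ]
  inside <- GenomicRanges::countOverlaps(
    gr_w, GenomicRanges::GRanges(hyper$chrom,
                                 IRanges::IRanges(hyper$start + 1,
                                                  hyper$end))) > 0
  trt <- meth$counts[, meth$samples$group == "TBT"]
  ctrl <- meth$counts[, meth$samples$group == "DMSO"]
  ratio <- mean(trt[inside, ]) / mean(ctrl[inside, ])
  expect_equal(ratio, 2, tolerance = 0.1)

  null_cfg <- small_cfg(effect_size = 1)
  nm <- simulate_methylome(simulate_genome(null_cfg), null_cfg)
  r0 <- mean(nm$counts[, nm$samples$group == "TBT"]) /
    mean(nm$counts[, nm$samples$group == "DMSO"])
  expect_equal(r0, 1, tolerance = 0.02)
})

test_that("planted expression effects appear only inside blocks", {
  cfg <- small_cfg(expr_pi = 1, phi_expr = 0.01)
  sim <- simulate_genome(cfg)
  expr <- simulate_expression(sim, cfg)
  truth <- attr(expr, "truth")
  expect_true(all(truth$lfc[truth$block_direction == "none"] == 0))
  expect_true(all(truth$lfc[truth$block_direction == "hypo"] ==
                    cfg$expr_delta))
  hypo <- truth$block_direction == "hypo"
  if (any(hypo)) {
    fc <- rowMeans(expr$counts[hypo, expr$samples$group == "TBT",
                               drop = FALSE]) /
      rowMeans(expr$counts[hypo, expr$samples$group == "DMSO",
                           drop = FALSE])
    expect_equal(mean(fc), 2, tolerance = 0.25)
  }
  # pi = 0 plants nothing
  cfg0 <- small_cfg(expr_pi = 0)
  truth0 <- attr(simulate_expression(simulate_genome(cfg0), cfg0), "truth")
  expect_true(all(truth0$lfc == 0))
})

test_that("ATAC affected sets respect the shared fraction limits", {
  cfg1 <- small_cfg(shared_fraction = 1)
  atac1 <- simulate_atac(simulate_genome(cfg1), cfg1)
  expect_setequal(atac1$truth$F3, atac1$truth$F4)

  cfg0 <- small_cfg(shared_fraction = 0)
  atac0 <- simulate_atac(simulate_genome(cfg0), cfg0)
  expect_length(intersect(atac0$truth$F3, atac0$truth$F4), 0)

  # default sharing is near 0.5 within binomial tolerance (default genome)
  run <- default_run()
  atac <- default_atac()$atac
  n <- length(atac$truth$F3)
  ov <- length(intersect(atac$truth$F3, atac$truth$F4)) / n
  expect_lt(abs(ov - 0.5), 3 * sqrt(0.25 / n) + 2 / n)

  expect_error(sim_config(shared_fraction = 1.5), "shared_fraction")
})
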