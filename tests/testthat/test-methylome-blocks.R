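diff_from_windows <- function(grid, p, direction) {
  data.frame(feature_id = paste0("w", grid$window),
             mean_ctrl = 10, mean_trt = ifelse(direction == "up", 20, 5),
             log2fc = ifelse(direction == "up", 1, -1),
             pvalue = p, direction = direction, stringsAsFactors = FALSE)
}

test_that("call_dmrs thresholds raw p and keeps directions", {
  grid <- build_window_grid(toy_layout(c(chr1 = 2000)), 100)
  p <- rep(0.5, 20)
  dir <- rep("up", 20)
  p[c(3, 7, 8)] <- 1e-5
  dir[7] <- "down"
  diff <- diff_from_windows(grid, p, dir)
  expect_equal(nrow(call_dmrs(diff, grid, alpha = 1e-9)), 0)
  expect_equal(nrow(call_dmrs(diff, grid, alpha = 1)), 20)
  d <- call_dmrs(diff, grid, alpha = 0.001)
  expect_equal(d$window, c(3, 7, 8))
  expect_equal(d$direction, c("hyper", "hypo", "hyper"))
  # significant window with no direction is inconsistent input
  diff$direction[3] <- "none"
  expect_error(call_dmrs(diff, grid, 0.001), "zero fold change")
})

test_that("mDMR merging collapses only grid-adjacent same-direction runs", {
  grid <- build_window_grid(toy_layout(c(chr1 = 5000)), 100)
  mk <- function(windows, dirs) {
    d <- grid[match(windows, grid$window),
              c("chrom", "start", "end", "window")]
    d$direction <- dirs
    d$pvalue <- 1e-5
    class(d) <- c("dmr_set", "data.frame")
    d
  }
  expect_equal(nrow(merge_mdmrs(mk(c(10, 11), c("hyper", "hyper")))), 1)
  expect_equal(nrow(merge_mdmrs(mk(c(10, 12), c("hyper", "hyper")))), 2)
  expect_equal(nrow(merge_mdmrs(mk(c(10, 11), c("hyper", "hypo")))), 2)
  m <- merge_mdmrs(mk(c(10, 11, 12), rep("hypo", 3)))
  expect_equal(m$start, 900)
  expect_equal(m$end, 1200)
  expect_equal(m$n_windows, 3)
})

test_that("chromosome boundaries break merged runs", {
  grid <- build_window_grid(toy_layout(c(a = 300, b = 300)), 100)
  d <- grid
  d$direction <- "hyper"
  d$pvalue <- 1e-5
  class(d) <- c("dmr_set", "data.frame")
  m <- merge_mdmrs(d)
  expect_equal(nrow(m), 2)
  b <- build_isodmbs(d)
  expect_equal(nrow(b), 2)
})

test_that("ratio curve matches hand counts and the analytic bound", {
  lay <- toy_layout(c(chr1 = 10000))
  grid <- build_window_grid(lay, 100)
  # 4 DMRs forming 2 adjacent same-direction pairs -> R = 0.5
  p <- rep(0.5, 100)
  dir <- rep("up", 100)
  p[c(10, 11, 50, 51)] <- 1e-5
  diff <- diff_from_windows(grid, p, dir)
  rc <- ratio_curve(diff, grid, lay)
  expect_equal(rc$ratio[rc$p == 0.001], 0.5)
  # all isolated -> R = 1
  p2 <- rep(0.5, 100)
  p2[c(10, 50, 90)] <- 1e-5
  rc2 <- ratio_curve(diff_from_windows(grid, p2, dir), grid, lay)
  expect_equal(rc2$ratio[rc2$p == 0.001], 1)
  # one unbroken same-direction run per chromosome -> R equals the bound
  rc3 <- ratio_curve(diff_from_windows(grid, rep(1e-5, 100), dir),
                     grid, lay)
  expect_equal(rc3$ratio[rc3$p == 0.001], min_ratio_bound(lay))
  # zero-DMR grid points are flagged NA
  p3 <- rep(0.5, 100)
  p3[c(10, 50)] <- 0.002   # significant at 0.005 but not at 0.001
  rc4 <- ratio_curve(diff_from_windows(grid, p3, dir), grid, lay)
  expect_true(is.na(rc4$ratio[rc4$p == 0.001]))
  expect_equal(rc4$n_dmr[rc4$p == 0.001], 0)
  expect_error(ratio_curve(diff, grid, lay, p_grid = c(0.001, 0.1)),
               "descending")
})

test_that("min_ratio_bound follows ceil tiling", {
  expect_equal(min_ratio_bound(toy_layout(c(chr1 = 1000))), 0.1)
  expect_equal(min_ratio_bound(toy_layout(c(a = 250, b = 149))), 2 / 5)
})

test_that("select_threshold finds where the ratio decreases consistently", {
  mk_curve <- function(p, r) {
    structure(data.frame(p = p, n_dmr = 100, n_mdmr = round(100 * r),
                         ratio = r),
              class = c("ratio_curve", "data.frame"), bound = 1e-4)
  }
  p <- c(0.1, 0.05, 0.01, 0.005, 0.001)
  expect_equal(as.numeric(select_threshold(
    mk_curve(p, c(0.9, 0.8, 0.7, 0.6, 0.95)))), 0.005)
  expect_equal(as.numeric(select_threshold(
    mk_curve(p, c(0.9, 0.8, 0.7, 0.6, 0.5)))), 0.001)
  expect_warning(
    p_flat <- select_threshold(mk_curve(p, rep(0.7, 5))),
    "falling back")
  expect_equal(as.numeric(p_flat), 0.001)
  expect_error(select_threshold(mk_curve(p[1:2], c(0.9, 0.8))),
               "3 usable")
})

test_that("isoDMB segmentation equals a run-length-encoding oracle", {
  grid <- build_window_grid(toy_layout(c(chr1 = 1e5)), 100)
  # worked example: directions (hyper, hyper, hypo, hyper) -> 3 blocks
  d <- grid[c(5, 9, 20, 40), c("chrom", "start", "end", "window")]
  d$direction <- c("hyper", "hyper", "hypo", "hyper")
  d$pvalue <- 1e-5
  class(d) <- c("dmr_set", "data.frame")
  b <- build_isodmbs(d)
  expect_equal(b$n_dmrs, c(2, 1, 1))
  expect_equal(b$start[1], grid$start[5])
  expect_equal(b$end[1], grid$end[9])

  # single DMR -> single one-window block
  b1 <- build_isodmbs(d[2, ])
  expect_equal(nrow(b1), 1)
  expect_equal(b1$end - b1$start, 100)

  # oracle: member counts equal rle() on the direction sequence
  set.seed(8)
  for (i in 1:1000) {
    n <- sample(1:30, 1)
    wins <- sort(sample(1:1000, n))
    dirs <- sample(c("hyper", "hypo"), n, replace = TRUE)
    dd <- grid[wins, c("chrom", "start", "end", "window")]
    dd$direction <- dirs
    dd$pvalue <- 1e-5
    class(dd) <- c("dmr_set", "data.frame")
    bb <- build_isodmbs(dd)
    expect_equal(bb$n_dmrs, rle(dirs)$lengths)
    expect_equal(bb$direction, rle(dirs)$values)
    # blocks alternate in direction on a chromosome
    expect_true(all(bb$direction[-1] != bb$direction[-nrow(bb)]))
  }
})

test_that("block counts are nested for any threshold on real-shaped data", {
  run <- default_run()
  for (alpha in c(0.05, 0.01, 0.001)) {
    dmrs <- call_dmrs(run$diff, run$grid, alpha)
    expect_lte(nrow(build_isodmbs(dmrs)), nrow(merge_mdmrs(dmrs)))
    expect_lte(nrow(merge_mdmrs(dmrs)), nrow(dmrs))
  }
})
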