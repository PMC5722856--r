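# Shared fixtures, built in code.

toy_layout <- function(lengths = c(chr1 = 1000)) {
  genome_layout(names(lengths), unname(lengths))
}

# Null NB count matrix (no group difference), two groups of n samples.
nb_null_matrix <- function(n_feat, seed, mu = 10, phi = 0.1, n = 4) {
  set.seed(seed)
  m <- matrix(stats::rnbinom(n_feat * 2 * n, size = 1 / phi, mu = mu),
              nrow = n_feat,
              dimnames = list(paste0("f", seq_len(n_feat)),
                              paste0("s", seq_len(2 * n))))
  count_matrix(m, groups = rep(c("ctrl", "trt"), each = n))
}

# Direction-matched Jaccard pooled over hyper and hypo comparisons.
pooled_matched_jaccard <- function(blocks, truth) {
  inter <- 0
  uni <- 0
  for (d in c("hyper", "hypo")) {
    a <- blocks[blocks$direction == d, , drop = FALSE]
    b <- truth[truth$direction == d, , drop = FALSE]
    for (ch in unique(c(a$chrom, b$chrom))) {
      ia <- IRanges::reduce(IRanges::IRanges(
        a$start[a$chrom == ch] + 1, a$end[a$chrom == ch]))
      ib <- IRanges::reduce(IRanges::IRanges(
        b$start[b$chrom == ch] + 1, b$end[b$chrom == ch]))
      inter <- inter + sum(IRanges::width(IRanges::intersect(ia, ib)))
      uni <- uni + sum(IRanges::width(IRanges::union(ia, ib)))
    }
  }
  inter / uni
}

# Fraction of DMRs falling inside planted blocks (any direction-matched
# block counts as a true positive).
dmr_precision <- function(dmrs, truth) {
  gr_d <- GenomicRanges::GRanges(dmrs$chrom,
                                 IRanges::IRanges(dmrs$start + 1, dmrs$end))
  hits <- logical(nrow(dmrs))
  for (d in c("hyper", "hypo")) {
    sel <- dmrs$direction == d
    tb <- truth[truth$direction == d, , drop = FALSE]
    gr_t <- GenomicRanges::GRanges(tb$chrom,
                                   IRanges::IRanges(tb$start + 1, tb$end))
    hits[sel] <- GenomicRanges::countOverlaps(gr_d[sel], gr_t) > 0
  }
  mean(hits)
}

# The default seeded synthetic dataset and its methylome analysis chain,
# computed once and shared across test files.
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- sim_config(seed = 1)
      sim <- simulate_genome(cfg)
      meth <- simulate_methylome(sim)
      grid <- attr(meth, "grid")
      diff <- diff_test(meth, control = "DMSO", treatment = "TBT")
      dmrs <- call_dmrs(diff, grid, alpha = 0.001)
      cache <<- list(cfg = cfg, sim = sim, meth = meth, grid = grid,
                     diff = diff, dmrs = dmrs,
                     mdmrs = merge_mdmrs(dmrs),
                     isodmbs = build_isodmbs(dmrs))
    }
    cache
  }
})

# Expression analysis on the default dataset (cached).
default_expression <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      run <- default_run()
      expr <- simulate_expression(run$sim)
      stats <- expression_stats(expr, genes = run$sim$genes,
                                control = "DMSO", treatment = "TBT")
      subsets <- assign_subsets(run$sim$genes, run$dmrs, run$isodmbs,
                                run$sim$layout)
      dge <- diff_test(expr, control = "DMSO", treatment = "TBT")
      cache <<- list(expr = expr, stats = stats, subsets = subsets,
                     dge = dge, degs = call_degs(dge, alpha = 0.05))
    }
    cache
  }
})

# ATAC analysis on the default dataset (cached).
default_atac <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      run <- default_run()
      atac <- simulate_atac(run$sim)
      dais <- lapply(atac$counts, function(cm)
        call_dais(cm, run$sim$isochores, alpha = 0.05,
                  control = "DMSO", treatment = "TBT"))
      cache <<- list(atac = atac, dais = dais, iso = run$sim$isochores)
    }
    cache
  }
})
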