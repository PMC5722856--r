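#' Per-gene expression summary statistics
#'
#' Library-size-normalizes counts to CPM, keeps genes expressed (> 0) in at
#' least `min_nonzero` replicates of EACH group, and reports per-group mean
#' and coefficient of variation plus their treatment - control differences.
#'
#' @param expr A [count_matrix()] of genes x samples.
#' @param genes Optional gene table; when given, a `chrom` column is attached
#'   (needed by the chromosome-stratified permutation tests).
#' @param control,treatment Group labels (defaults as in [diff_test()]).
#' @param min_nonzero Minimum non-zero replicates per group (default 3).
#' @return Data frame of class `expr_stats`: `gene_id`, `chrom` (if known),
#'   `mean_ctrl`, `mean_trt`, `cv_ctrl`, `cv_trt`, `d_mean`, `d_cv`.
#'   Attribute `n_dropped` counts genes failing the expression rule.
#' @export
expression_stats <- function(expr, genes = NULL, control = NULL,
                             treatment = NULL, min_nonzero = 3) {
  stopifnot(inherits(expr, "count_matrix"))
  gi <- group_indices(expr, control, treatment)
  if (length(gi$control) < min_nonzero || length(gi$treatment) < min_nonzero) {
    stop("need at least ", min_nonzero, " replicates per group")
  }
  m <- expr$counts
  cpm <- t(t(m) / colSums(m)) * 1e6
  nz_c <- rowSums(m[, gi$control, drop = FALSE] > 0)
  nz_t <- rowSums(m[, gi$treatment, drop = FALSE] > 0)
  keep <- nz_c >= min_nonzero & nz_t >= min_nonzero
  cpm <- cpm[keep, , drop = FALSE]
  cv <- function(v) stats::sd(v) / mean(v)
  ctrl <- cpm[, gi$control, drop = FALSE]
  trt <- cpm[, gi$treatment, drop = FALSE]
  out <- data.frame(
    gene_id = rownames(cpm),
    mean_ctrl = rowMeans(ctrl), mean_trt = rowMeans(trt),
    cv_ctrl = apply(ctrl, 1, cv), cv_trt = apply(trt, 1, cv),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$d_mean <- out$mean_trt - out$mean_ctrl
  out$d_cv <- out$cv_trt - out$cv_ctrl
  if (!is.null(genes)) {
    out$chrom <- genes$chrom[match(out$gene_id, genes$gene_id)]
    if (anyNA(out$chrom)) stop("expressed gene missing from the gene table")
    out <- out[, c("gene_id", "chrom", setdiff(names(out),
                                               c("gene_id", "chrom")))]
  }
  attr(out, "n_dropped") <- sum(!keep)
  class(out) <- c("expr_stats", "data.frame")
  out
}

genes_to_gr <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start + 1, genes$end))
}

intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start + 1, x$end))
}

#' Assign genes to DMR-association subsets I, II and III
#'
#' Per direction of methylation change (hyper/hypo):
#' * Subset I — genes with a DMR overlapping the close TSS vicinity
#'   (`upstream` bp upstream to `downstream` bp downstream of the TSS).
#' * Subset II — genes whose body overlaps a DMR, plus, for DMRs lying in
#'   intergenic DNA, the two nearest genes bounding that intergenic region
#'   ("flanking" genes).
#' * Subset III — genes whose body overlaps an isoDMB.
#'
#' Subsets I and II are computed independently (one uses the TSS window, the
#' other the body/flank), so neither contains the other by construction.
#'
#' @param genes Gene table.
#' @param dmrs A `dmr_set`.
#' @param isodmbs An `isodmb_set`.
#' @param layout A `genome_layout`.
#' @param upstream,downstream TSS window extent (defaults 1500/500).
#' @return Data frame: `gene_id` plus logical columns
#'   `I_hyper`, `I_hypo`, `II_hyper`, `II_hypo`, `III_hyper`, `III_hypo`.
#' @export
assign_subsets <- function(genes, dmrs, isodmbs, layout,
                           upstream = 1500, downstream = 500) {
  genes <- validate_genes(genes, layout)
  tssw <- tss_window(genes, layout, upstream, downstream)
  gr_body <- genes_to_gr(genes)
  gr_tss <- intervals_to_gr(tssw)
  out <- data.frame(gene_id = genes$gene_id, stringsAsFactors = FALSE)
  for (dir in c("hyper", "hypo")) {
    dsub <- dmrs[dmrs$direction == dir, , drop = FALSE]
    bsub <- isodmbs[isodmbs$direction == dir, , drop = FALSE]
    sI <- sII <- sIII <- logical(nrow(genes))
    if (nrow(dsub)) {
      gr_d <- intervals_to_gr(dsub)
      sI[unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr_tss, gr_d)))] <- TRUE
      hit_body <- GenomicRanges::findOverlaps(gr_body, gr_d)
      sII[unique(S4Vectors::queryHits(hit_body))] <- TRUE
      # flanking genes of intergenic DMRs (nearest gene on each side)
      gr_all_genes <- genes_to_gr(genes)
      intergenic <- which(GenomicRanges::countOverlaps(gr_d,
                                                       gr_all_genes) == 0)
      if (length(intergenic)) {
        gi <- gr_d[intergenic]
        up <- GenomicRanges::follow(gi, gr_all_genes, ignore.strand = TRUE)
        dn <- GenomicRanges::precede(gi, gr_all_genes, ignore.strand = TRUE)
        sII[stats::na.omit(c(up, dn))] <- TRUE
      }
    }
    if (nrow(bsub)) {
      gr_b <- intervals_to_gr(bsub)
      sIII[unique(S4Vectors::queryHits(
        GenomicRanges::findOverlaps(gr_body, gr_b)))] <- TRUE
    }
    out[[paste0("I_", dir)]] <- sI
    out[[paste0("II_", dir)]] <- sII
    out[[paste0("III_", dir)]] <- sIII
  }
  out
}

#' Signed-rank expression bias index
#'
#' Genes are ranked in ascending order of |difference|, ranks are signed by
#' the sign of the difference, and the sum of signed ranks is normalized by
#' its maximum absolute value n(n+1)/2 — the value it would take if every
#' difference pointed the same way. Ties in |difference| receive average
#' ranks; zero differences contribute zero-signed ranks but keep their place
#' in the ranking and in the normalizer (set `drop_zeros = TRUE` for the
#' classic Wilcoxon convention of discarding them).
#'
#' @param d Numeric vector of differences (treatment - control) for a gene
#'   set.
#' @param drop_zeros Drop zero differences before ranking (default FALSE).
#' @return B in [-1, 1].
#' @examples
#' bias_index(c(5, 2, 1))    # 1
#' bias_index(c(5, -2, 1))   # 1/3
#' @export
bias_index <- function(d, drop_zeros = FALSE) {
  if (length(d) == 0L) stop("empty gene set")
  if (drop_zeros) {
    d <- d[d != 0]
    if (length(d) == 0L) stop("empty gene set after dropping zeros")
  }
  n <- length(d)
  r <- rank(abs(d), ties.method = "average")
  sum(sign(d) * r) / (n * (n + 1) / 2)
}

#' Monte Carlo-Wilcoxon (MCW) bias test
#'
#' Tests whether a gene subset's expression statistic (per-gene difference in
#' group mean or CV) is directionally biased relative to chance, using the
#' signed-rank [bias_index()] and a chromosome-stratified permutation null:
#' each permutation redraws, independently within every chromosome, the same
#' number of subset genes uniformly (without replacement) from that
#' chromosome's expressed genes, and recomputes the index.
#'
#' @param stats An `expr_stats` with a `chrom` column.
#' @param subset Character vector of gene ids (must be expressed genes).
#' @param statistic `"mean"` or `"cv"`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param drop_zeros Passed to [bias_index()].
#' @return List of class `mcw_test`: `statistic`, `n_genes`, `b_observed`,
#'   `n_perm`, `p_upper` (fraction of permutations with index >= observed),
#'   `p_lower` (<= observed), `seed`.
#' @export
mcw_test <- function(stats, subset, statistic = c("mean", "cv"),
                     n_perm = 10000, seed = NULL, drop_zeros = FALSE) {
  statistic <- match.arg(statistic)
  if (is.null(stats$chrom)) {
    stop("expr_stats needs a 'chrom' column (pass the gene table to ",
         "expression_stats)")
  }
  if (length(subset) == 0L) stop("empty gene set")
  idx <- match(subset, stats$gene_id)
  if (anyNA(idx)) {
    stop("subset gene ", subset[which(is.na(idx))[1]],
         " is not an expressed gene")
  }
  d_all <- if (statistic == "mean") stats$d_mean else stats$d_cv
  chrom <- stats$chrom
  per_chrom <- split(seq_along(chrom), chrom)
  need <- table(chrom[idx])
  for (ch in names(need)) {
    if (need[[ch]] > length(per_chrom[[ch]])) {
      stop("chromosome ", ch, " has more subset genes than expressed genes")
    }
  }
  b_obs <- bias_index(d_all[idx], drop_zeros = drop_zeros)
  if (!is.null(seed)) set.seed(seed)
  counts <- lapply(names(need), function(ch)
    list(pool = per_chrom[[ch]], k = need[[ch]]))
  b_perm <- vapply(seq_len(n_perm), function(i) {
    draw <- unlist(lapply(counts, function(cc)
      cc$pool[sample.int(length(cc$pool), cc$k)]), use.names = FALSE)
    stopifnot(length(draw) == length(idx))  # chromosome counts preserved
    bias_index(d_all[draw], drop_zeros = drop_zeros)
  }, 0)
  structure(list(statistic = statistic, n_genes = length(idx),
                 b_observed = b_obs, n_perm = n_perm,
                 p_upper = mean(b_perm >= b_obs),
                 p_lower = mean(b_perm <= b_obs), seed = seed),
            class = "mcw_test")
}

#' @export
print.mcw_test <- function(x, ...) {
  cat(sprintf("MCW bias test (%s, %d genes): B = %.4f\n",
              x$statistic, x$n_genes, x$b_observed))
  cat(sprintf("  %d permutations: p_upper = %.4g, p_lower = %.4g\n",
              x$n_perm, x$p_upper, x$p_lower))
  invisible(x)
}

#' Call differentially expressed genes (DEGs)
#'
#' @param diff A `diff_result` over genes (from [diff_test()]).
#' @param alpha Raw p-value threshold (default 0.05).
#' @return Data frame `gene_id`, `direction` (`up`/`down`), `pvalue`.
#' @export
call_degs <- function(diff, alpha = 0.05) {
  sig <- diff$pvalue < alpha & diff$direction != "none"
  out <- data.frame(gene_id = diff$feature_id[sig],
                    direction = diff$direction[sig],
                    pvalue = diff$pvalue[sig],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "alpha") <- alpha
  out
}

#' isoDMB-DEG coherence test
#'
#' For each isoDMB direction, measures (i) the fraction of blocks containing
#' at least two DEGs and (ii) among those blocks, the fractions whose DEG
#' sets are all-up and all-down. Significance comes from permuting DEG tags
#' (up/down labels kept attached) across expressed genes within each
#' chromosome.
#'
#' @param isodmbs An `isodmb_set`.
#' @param degs DEG table from [call_degs()] (must be expressed genes).
#' @param genes Gene table (coordinates for block membership).
#' @param expressed Character vector of expressed gene ids (the permutation
#'   universe).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return List of class `coherence_test`; per direction a row with observed
#'   `frac_ge2`, `frac_all_up`, `frac_all_down` and p_upper/p_lower for each.
#' @export
coherence_test <- function(isodmbs, degs, genes, expressed,
                           n_perm = 10000, seed = NULL) {
  if (!all(degs$gene_id %in% expressed)) {
    stop("DEGs must be a subset of expressed genes")
  }
  eg <- genes[match(expressed, genes$gene_id), , drop = FALSE]
  if (anyNA(eg$start)) stop("expressed gene missing from the gene table")
  gr_genes <- genes_to_gr(eg)
  # block membership of expressed genes, per direction
  membership <- lapply(c(hyper = "hyper", hypo = "hypo"), function(dir) {
    bl <- isodmbs[isodmbs$direction == dir, , drop = FALSE]
    if (nrow(bl) == 0L) return(list(n_blocks = 0L, members = list()))
    hits <- GenomicRanges::findOverlaps(gr_genes, intervals_to_gr(bl))
    members <- split(S4Vectors::queryHits(hits),
                     factor(S4Vectors::subjectHits(hits),
                            levels = seq_len(nrow(bl))))
    list(n_blocks = nrow(bl), members = members)
  })
  tag <- rep(NA_character_, length(expressed))
  tag[match(degs$gene_id, expressed)] <- degs$direction
  per_chrom <- split(seq_along(expressed), eg$chrom)

  block_stats <- function(tag) {
    res <- list()
    for (dir in c("hyper", "hypo")) {
      mb <- membership[[dir]]
      if (mb$n_blocks == 0L) {
        res[[dir]] <- c(frac_ge2 = 0, frac_all_up = 0, frac_all_down = 0)
        next
      }
      per_block <- vapply(mb$members, function(ix) {
        tg <- tag[ix]
        tg <- tg[!is.na(tg)]
        if (length(tg) < 2L) return(c(0, 0, 0))
        c(1, as.numeric(all(tg == "up")), as.numeric(all(tg == "down")))
      }, numeric(3))
      n_ge2 <- sum(per_block[1, ])
      res[[dir]] <- c(
        frac_ge2 = n_ge2 / mb$n_blocks,
        frac_all_up = if (n_ge2 > 0) sum(per_block[2, ]) / n_ge2 else 0,
        frac_all_down = if (n_ge2 > 0) sum(per_block[3, ]) / n_ge2 else 0
      )
    }
    res
  }

  obs <- block_stats(tag)
  if (!is.null(seed)) set.seed(seed)
  perm <- replicate(n_perm, {
    ptag <- rep(NA_character_, length(tag))
    for (ix in per_chrom) {
      has <- ix[!is.na(tag[ix])]
      if (length(has)) {
        ptag[ix[sample.int(length(ix), length(has))]] <- tag[has]
      }
    }
    block_stats(ptag)
  }, simplify = FALSE)

  rows <- lapply(c("hyper", "hypo"), function(dir) {
    pm <- vapply(perm, function(p) p[[dir]], numeric(3))
    o <- obs[[dir]]
    data.frame(direction = dir,
               frac_ge2 = o["frac_ge2"],
               p_upper_ge2 = mean(pm["frac_ge2", ] >= o["frac_ge2"]),
               p_lower_ge2 = mean(pm["frac_ge2", ] <= o["frac_ge2"]),
               frac_all_up = o["frac_all_up"],
               p_upper_all_up = mean(pm["frac_all_up", ] >= o["frac_all_up"]),
               frac_all_down = o["frac_all_down"],
               p_upper_all_down =
                 mean(pm["frac_all_down", ] >= o["frac_all_down"]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  structure(list(table = do.call(rbind, rows), n_perm = n_perm, seed = seed),
            class = "coherence_test")
}

#' @export
print.coherence_test <- function(x, ...) {
  cat("isoDMB-DEG coherence test (", x$n_perm, "permutations )\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Hypergeometric gene-set enrichment with BH correction
#'
#' Upper-tail hypergeometric (one-sided overrepresentation) p-value per gene
#' set, Benjamini-Hochberg adjusted across sets.
#'
#' @param query Character vector of query gene ids (subset of `universe`).
#' @param universe Character vector: the background population.
#' @param gene_sets Named list of character vectors (e.g. from [read_gmt()]);
#'   members outside the universe are ignored.
#' @return Data frame: `set`, `set_size`, `overlap`, `pvalue`, `qvalue`,
#'   ordered by p-value.
#' @export
enrichment_test <- function(query, universe, gene_sets) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe)) {
    stop("query gene ", setdiff(query, universe)[1], " outside the universe")
  }
  n_u <- length(universe)
  n_q <- length(query)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    k <- length(intersect(set, query))
    p <- stats::phyper(k - 1, length(set), n_u - length(set), n_q,
                       lower.tail = FALSE)
    data.frame(set = nm, set_size = length(set), overlap = k, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qvalue <- stats::p.adjust(out$pvalue, method = "BH")
  out[order(out$pvalue), , drop = FALSE]
}
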