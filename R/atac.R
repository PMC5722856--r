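#' Aggregate windowed counts into region counts
#'
#' Sums per-window signal into per-region counts; a window contributes to
#' the region containing its midpoint, so regions that partition the genome
#' partition the signal exactly.
#'
#' @param windows A [count_matrix()] of grid windows x samples.
#' @param grid The window grid matching `windows` (see [build_window_grid()]).
#' @param regions Data frame of regions (`chrom`, `start`, `end`), e.g. an
#'   `isochore_set`.
#' @param layout Optional `genome_layout` for bounds checking of `regions`.
#' @return A [count_matrix()] of regions x samples; rownames are
#'   `chrom:start-end`, and the region table is attached as attribute
#'   `regions`.
#' @export
region_counts <- function(windows, grid, regions, layout = NULL) {
  stopifnot(inherits(windows, "count_matrix"))
  if (!is.null(layout)) validate_intervals(regions, layout, what = "region")
  idx <- match_windows(rownames(windows$counts), grid)
  mid <- floor((grid$start[idx] + grid$end[idx]) / 2)
  gr_mid <- GenomicRanges::GRanges(grid$chrom[idx],
                                   IRanges::IRanges(mid + 1, mid + 1))
  gr_reg <- intervals_to_gr(regions)
  hits <- GenomicRanges::findOverlaps(gr_mid, gr_reg)
  region_of <- rep(NA_integer_, length(idx))
  region_of[S4Vectors::queryHits(hits)] <- S4Vectors::subjectHits(hits)
  keep <- !is.na(region_of)
  agg <- rowsum(windows$counts[keep, , drop = FALSE], region_of[keep])
  m <- matrix(0, nrow = nrow(regions), ncol = ncol(windows$counts),
              dimnames = list(
                paste0(regions$chrom, ":", regions$start, "-", regions$end),
                colnames(windows$counts)))
  m[as.integer(rownames(agg)), ] <- agg
  out <- count_matrix(m, samples = windows$samples)
  attr(out, "regions") <- regions
  out
}

#' ATAC sample quality control by depth and efficiency
#'
#' A sample passes when its in-region depth is at least `min_depth` reads
#' AND its efficiency (in-region reads / total reads) is at least `min_eff`;
#' both boundaries are inclusive (samples strictly below either cutoff
#' fail). A length-normalized efficiency (efficiency per Mb of region) is
#' reported for comparing region sets of different footprint.
#'
#' @param x [count_matrix()] of regions x samples.
#' @param total_reads Numeric vector of total sequenced reads per sample; if
#'   missing, taken from a `total_reads` column of `x$samples`.
#' @param region_bp Total bp covered by the region set (for the normalized
#'   efficiency; optional).
#' @param min_depth Minimum in-region reads (default 1500).
#' @param min_eff Minimum efficiency (default 0.15).
#' @return List: `passed` (a filtered `count_matrix`), `qc` (data frame
#'   `sample`, `depth`, `efficiency`, `efficiency_per_mb`, `pass`).
#' @export
qc_filter <- function(x, total_reads = NULL, region_bp = NA,
                      min_depth = 1500, min_eff = 0.15) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.null(total_reads)) total_reads <- x$samples$total_reads
  if (is.null(total_reads)) stop("total reads per sample are required")
  depth <- colSums(x$counts)
  eff <- depth / total_reads
  pass <- depth >= min_depth & eff >= min_eff
  qc <- data.frame(sample = colnames(x$counts), depth = depth,
                   efficiency = eff,
                   efficiency_per_mb = eff / (region_bp / 1e6),
                   pass = pass, stringsAsFactors = FALSE, row.names = NULL)
  list(passed = x[, pass], qc = qc)
}

#' Call differentially accessible isochores (DAIs)
#'
#' Runs the two-group differential count test per isochore and maps the
#' direction of change to accessibility: treatment coverage above control at
#' p < `alpha` is an accessible DAI, below is inaccessible.
#'
#' @param x [count_matrix()] of isochores x samples (e.g. from
#'   [region_counts()] with an `isochore_set`).
#' @param isochores The `isochore_set` matching the rows of `x`.
#' @param alpha Raw p-value threshold (default 0.05).
#' @param generation Optional generation label stored on the result.
#' @param ... Passed to [diff_test()].
#' @return Data frame of class `dai_table`: per isochore `chrom`, `start`,
#'   `end`, `class`, `pvalue`, `direction`
#'   (`accessible`/`inaccessible`/`none`). Attributes `alpha`, `generation`.
#' @export
call_dais <- function(x, isochores, alpha = 0.05, generation = NULL, ...) {
  stopifnot(nrow(isochores) == nrow(x$counts))
  diff <- diff_test(x, min_row_sum = 0, ...)
  ord <- match(rownames(x$counts), diff$feature_id)
  out <- data.frame(chrom = isochores$chrom, start = isochores$start,
                    end = isochores$end, class = isochores$class,
                    pvalue = diff$pvalue[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  sig <- out$pvalue < alpha
  out$direction <- ifelse(!sig, "none",
                          ifelse(diff$direction[ord] == "up",
                                 "accessible", "inaccessible"))
  attr(out, "alpha") <- alpha
  attr(out, "generation") <- generation
  class(out) <- c("dai_table", "data.frame")
  out
}

#' Per-class DAI fractions with a direction-permutation null
#'
#' For every isochore class and direction, the observed fraction of that
#' class's significant DAIs carrying the direction, with significance from
#' randomly rearranging the direction tags among all significant DAIs
#' (class labels fixed).
#'
#' @param dais A `dai_table`.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @return Data frame: `class`, `direction`, `n_dais` (in class), `k`
#'   (in class with direction), `fraction`, `p_upper`, `p_lower`.
#' @export
dai_class_fractions <- function(dais, n_perm = 10000, seed = NULL) {
  sig <- dais[dais$direction != "none", , drop = FALSE]
  if (nrow(sig) == 0L) stop("no significant DAIs")
  classes <- sort(unique(sig$class))
  dirs <- c("accessible", "inaccessible")
  tab <- function(cl, dr, direction) {
    sum(sig$class == cl & direction == dr)
  }
  obs <- sapply(classes, function(cl)
    sapply(dirs, function(dr) tab(cl, dr, sig$direction)))
  if (!is.null(seed)) set.seed(seed)
  n_class <- table(factor(sig$class, levels = classes))
  perm_counts <- array(0, dim = c(length(dirs), length(classes), n_perm))
  for (i in seq_len(n_perm)) {
    ptag <- sample(sig$direction)
    perm_counts[, , i] <- sapply(classes, function(cl)
      sapply(dirs, function(dr) tab(cl, dr, ptag)))
  }
  rows <- list()
  for (ci in seq_along(classes)) {
    for (di in seq_along(dirs)) {
      k <- obs[di, ci]
      kp <- perm_counts[di, ci, ]
      rows[[length(rows) + 1L]] <- data.frame(
        class = classes[ci], direction = dirs[di],
        n_dais = as.integer(n_class[ci]), k = k,
        fraction = k / as.integer(n_class[ci]),
        p_upper = mean(kp >= k), p_lower = mean(kp <= k),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Shared DAIs between two generations
#'
#' Shared DAIs are isochores significant in BOTH generations with the same
#' direction of change; the shared fraction is their number over the number
#' of isochores significant in both (set `denominator = "union"` for
#' significant-in-either). The null rearranges direction tags within each
#' generation's significant set independently.
#'
#' @param dais_a,dais_b `dai_table`s over the same isochore universe (same
#'   row order).
#' @param n_perm Number of permutations (default 10000).
#' @param seed Optional integer seed.
#' @param denominator `"both"` (default) or `"union"`.
#' @return List of class `shared_dai_test`: `shared` (logical per isochore),
#'   `n_shared`, `n_denom`, `fraction`, `p_upper`, `p_lower`; `fraction` and
#'   the p-values are NA (flagged empty) when no isochore is significant in
#'   both generations.
#' @export
shared_dais <- function(dais_a, dais_b, n_perm = 10000, seed = NULL,
                        denominator = c("both", "union")) {
  denominator <- match.arg(denominator)
  if (nrow(dais_a) != nrow(dais_b) ||
      any(dais_a$start != dais_b$start | dais_a$chrom != dais_b$chrom)) {
    stop("the two DAI tables must cover the same isochores in order")
  }
  sig_a <- dais_a$direction != "none"
  sig_b <- dais_b$direction != "none"
  in_both <- sig_a & sig_b
  denom_set <- if (denominator == "both") in_both else (sig_a | sig_b)
  shared <- in_both & dais_a$direction == dais_b$direction
  n_denom <- sum(denom_set)
  if (sum(in_both) == 0L) {
    return(structure(list(shared = shared, n_shared = 0L, n_denom = n_denom,
                          fraction = NA_real_, p_upper = NA_real_,
                          p_lower = NA_real_, seed = seed),
                     class = "shared_dai_test"))
  }
  frac <- function(da, db) {
    both <- da != "none" & db != "none"
    den <- if (denominator == "both") both else (da != "none" | db != "none")
    if (sum(den) == 0L) return(0)
    sum(both & da == db) / sum(den)
  }
  obs <- frac(dais_a$direction, dais_b$direction)
  if (!is.null(seed)) set.seed(seed)
  ia <- which(sig_a); ib <- which(sig_b)
  fperm <- vapply(seq_len(n_perm), function(i) {
    da <- dais_a$direction; db <- dais_b$direction
    da[ia] <- sample(da[ia])
    db[ib] <- sample(db[ib])
    frac(da, db)
  }, 0)
  structure(list(shared = shared, n_shared = sum(shared), n_denom = n_denom,
                 fraction = obs, p_upper = mean(fperm >= obs),
                 p_lower = mean(fperm <= obs), seed = seed),
            class = "shared_dai_test")
}

#' @export
print.shared_dai_test <- function(x, ...) {
  cat(sprintf("shared DAIs: %d / %d (fraction %.3f), p_upper = %.4g\n",
              x$n_shared, x$n_denom, x$fraction, x$p_upper))
  invisible(x)
}

#' Correlation-based sample clustering with chi-square assortment tests
#'
#' Simplified deviation-and-clustering scheme for accessibility matrices:
#' counts are library-size normalized; each feature gets a variability score
#' (cross-sample standard deviation over the square root of the mean — about
#' 1 for Poisson noise) and features below `variability_threshold` are
#' dropped; of each remaining feature pair correlated above `corr_prune` in
#' absolute value, the higher-index feature is dropped; features are then
#' z-scored, the sample-sample Pearson correlation matrix is computed with
#' the diagonal set to 0, and average-linkage hierarchical clustering on
#' distance 1 - r is cut into two clusters (X, Y). A chi-square test without
#' continuity correction (with Fisher's exact p alongside) scores the
#' treatment x cluster assortment; when it is significant at 0.05 and a
#' `generation` column exists, each cluster's two subclusters are tested for
#' generation assortment the same way.
#'
#' @param x [count_matrix()] (typically restricted to one isochore class).
#' @param variability_threshold Minimum variability score (default 1.5).
#' @param corr_prune Absolute feature-feature correlation above which one of
#'   the pair is dropped (default 0.9).
#' @return List of class `cluster_result`: `hclust`, `newick`, `cluster`
#'   (named vector, values "X"/"Y"), `table`, `chisq`, `p_chisq`, `p_fisher`,
#'   `n_features`, and `subcluster_tests` (possibly NULL).
#' @export
cluster_samples <- function(x, variability_threshold = 1.5,
                            corr_prune = 0.9) {
  stopifnot(inherits(x, "count_matrix"))
  if (ncol(x$counts) < 4L) stop("need at least 4 samples")
  m <- x$counts
  libs <- colSums(m)
  y <- t(t(m) / libs) * mean(libs)
  mu <- rowMeans(y)
  sdv <- apply(y, 1L, stats::sd)
  score <- ifelse(mu > 0, sdv / sqrt(mu), 0)
  keep <- which(score >= variability_threshold)
  y <- y[keep, , drop = FALSE]
  if (nrow(y) >= 2L) {
    fc <- suppressWarnings(stats::cor(t(y)))
    fc[is.na(fc)] <- 0
    drop <- rep(FALSE, nrow(y))
    for (i in seq_len(nrow(y) - 1L)) {
      if (drop[i]) next
      j <- which(abs(fc[i, ]) > corr_prune)
      drop[j[j > i]] <- TRUE
    }
    y <- y[!drop, , drop = FALSE]
  }
  if (nrow(y) < 2L) stop("fewer than 2 features left after pruning")
  z <- t(scale(t(y)))
  r <- suppressWarnings(stats::cor(z))
  r[is.na(r)] <- 0
  diag(r) <- 0
  hc <- stats::hclust(stats::as.dist(1 - r), method = "average")
  cl <- stats::cutree(hc, k = 2)
  cluster <- c("X", "Y")[cl]
  names(cluster) <- colnames(x$counts)
  grp <- x$samples$group
  tab <- table(group = grp, cluster = cluster)
  cs <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  fi <- stats::fisher.test(tab)
  sub_tests <- NULL
  if (!is.na(cs$p.value) && cs$p.value < 0.05 &&
      !is.null(x$samples$generation)) {
    sub_tests <- lapply(c("X", "Y"), function(side) {
      members <- which(cluster == side)
      if (length(members) < 4L) return(NULL)
      rsub <- r[members, members]
      diag(rsub) <- 0
      hsub <- stats::hclust(stats::as.dist(1 - rsub), method = "average")
      scl <- stats::cutree(hsub, k = 2)
      stab <- table(generation = x$samples$generation[members],
                    subcluster = c("'", "''")[scl])
      if (any(dim(stab) < 2L)) return(NULL)
      scs <- suppressWarnings(stats::chisq.test(stab, correct = FALSE))
      list(cluster = side, table = stab, chisq = unname(scs$statistic),
           p_chisq = scs$p.value,
           p_fisher = stats::fisher.test(stab)$p.value)
    })
    sub_tests <- sub_tests[!vapply(sub_tests, is.null, TRUE)]
  }
  structure(list(hclust = hc, newick = ape::write.tree(ape::as.phylo(hc)),
                 cluster = cluster, table = tab,
                 chisq = unname(cs$statistic), p_chisq = cs$p.value,
                 p_fisher = fi$p.value, n_features = nrow(y),
                 subcluster_tests = sub_tests),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("sample clustering on", x$n_features, "features\n")
  print(x$table)
  cat(sprintf("chi-square = %.3f, p = %.4g (Fisher p = %.4g)\n",
              x$chisq, x$p_chisq, x$p_fisher))
  invisible(x)
}
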