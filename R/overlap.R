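to_irl <- function(x) {
  # per-chromosome IRanges list from a 0-based half-open interval frame
  split(IRanges::IRanges(start = x$start + 1, end = x$end),
        factor(x$chrom))
}

covered_bp <- function(x) {
  if (nrow(x) == 0L) return(0)
  sum(vapply(to_irl(x), function(ir) sum(IRanges::width(IRanges::reduce(ir))),
             0))
}

#' Jaccard index between two interval sets
#'
#' Base-pair intersection over union, after merging overlapping intervals
#' within each set; invariant to how either set fragments its intervals.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (0-based half-open).
#' @return J in [0, 1].
#' @examples
#' jaccard(data.frame(chrom = "c", start = 0, end = 100),
#'         data.frame(chrom = "c", start = 50, end = 150)) # 1/3
#' @export
jaccard <- function(a, b) {
  if (nrow(a) == 0L && nrow(b) == 0L) stop("both interval sets are empty")
  chroms <- union(unique(a$chrom), unique(b$chrom))
  inter <- 0; uni <- 0
  for (ch in chroms) {
    ra <- a[a$chrom == ch, , drop = FALSE]
    rb <- b[b$chrom == ch, , drop = FALSE]
    ia <- IRanges::reduce(IRanges::IRanges(ra$start + 1, ra$end))
    ib <- IRanges::reduce(IRanges::IRanges(rb$start + 1, rb$end))
    inter <- inter + sum(IRanges::width(IRanges::intersect(ia, ib)))
    uni <- uni + sum(IRanges::width(IRanges::union(ia, ib)))
  }
  inter / uni
}

#' Randomly relocate intervals within their chromosomes
#'
#' Each interval keeps its length and chromosome and receives an independent
#' uniform new start in `[0, L - length]`. Shuffled intervals may overlap one
#' another.
#'
#' @param x Intervals (`chrom`, `start`, `end`).
#' @param layout A `genome_layout`.
#' @param seed Optional integer seed.
#' @return Intervals of the same lengths/chromosomes at new positions.
#' @export
shuffle_intervals <- function(x, layout, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx <- match(x$chrom, layout$chrom)
  if (anyNA(idx)) stop("interval on unknown chromosome ",
                       x$chrom[which(is.na(idx))[1]])
  len <- x$end - x$start
  room <- layout$length[idx] - len
  if (any(room < 0)) {
    stop("interval longer than its chromosome: ",
         x$chrom[which(room < 0)[1]])
  }
  start <- floor(stats::runif(nrow(x)) * (room + 1))
  start <- pmin(start, room)   # guard the runif(1) == 1 edge
  data.frame(chrom = x$chrom, start = start, end = start + len,
             stringsAsFactors = FALSE)
}

#' Monte Carlo significance of an interval-overlap Jaccard index
#'
#' Shuffles the query set `a` (the comparison set `b` stays fixed),
#' recomputes the Jaccard index each time, and reports the fraction of
#' shuffles at least as extreme as the observed index in each direction:
#' `p_upper = #(J_null >= J_obs) / n`, `p_lower = #(J_null <= J_obs) / n`.
#'
#' @param a Query intervals (shuffled).
#' @param b Fixed intervals.
#' @param layout A `genome_layout`.
#' @param n Number of shuffles (default 10000).
#' @param seed Optional integer seed.
#' @param shuffle_both Also shuffle `b` each iteration (off by default,
#'   matching the query-randomization design).
#' @return List of class `overlap_test`: `j_observed`, `n_shuffles`,
#'   `p_upper`, `p_lower`, `null_mean`, `null_sd`, `seed`.
#' @export
overlap_mc_test <- function(a, b, layout, n = 10000, seed = NULL,
                            shuffle_both = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  j_obs <- jaccard(a, b)
  j_null <- vapply(seq_len(n), function(i) {
    bb <- if (shuffle_both) shuffle_intervals(b, layout) else b
    jaccard(shuffle_intervals(a, layout), bb)
  }, 0)
  structure(list(j_observed = j_obs, n_shuffles = n,
                 p_upper = mean(j_null >= j_obs),
                 p_lower = mean(j_null <= j_obs),
                 null_mean = mean(j_null), null_sd = stats::sd(j_null),
                 seed = seed),
            class = "overlap_test")
}

#' @export
print.overlap_test <- function(x, ...) {
  cat(sprintf(
    "Jaccard overlap test: J = %.4g (null %.4g +/- %.4g, %d shuffles)\n",
    x$j_observed, x$null_mean, x$null_sd, x$n_shuffles))
  cat(sprintf("  p_upper = %.4g, p_lower = %.4g\n", x$p_upper, x$p_lower))
  invisible(x)
}
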