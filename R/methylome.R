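#' Call differentially methylated regions (DMRs)
#'
#' DMRs are grid windows whose differential coverage p-value falls below
#' `alpha`, tagged hyper (treatment coverage above control) or hypo.
#'
#' @param diff A `diff_result` over the window grid (from [diff_test()]),
#'   whose `feature_id` matches `grid$window` ids as `"w<index>"` or equals
#'   the row order of `grid`.
#' @param grid Window grid from [build_window_grid()].
#' @param alpha Raw p-value threshold (default 0.001).
#' @return Data frame of class `dmr_set`: `chrom`, `start`, `end`, `window`,
#'   `direction` (`hyper`/`hypo`), `pvalue`; attribute `alpha`.
#' @export
call_dmrs <- function(diff, grid, alpha = 0.001) {
  idx <- match_windows(diff$feature_id, grid)
  sig <- which(diff$pvalue < alpha)
  if (length(sig)) {
    zero_fc <- diff$direction[sig] == "none"
    if (any(zero_fc)) {
      stop("window ", diff$feature_id[sig[zero_fc][1]],
           " significant at p < ", alpha,
           " with zero fold change: inconsistent input")
    }
  }
  out <- grid[idx[sig], c("chrom", "start", "end", "window")]
  out$direction <- ifelse(diff$direction[sig] == "up", "hyper", "hypo")
  out$pvalue <- diff$pvalue[sig]
  out <- out[order(out$window), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("dmr_set", "data.frame")
  out
}

match_windows <- function(feature_id, grid) {
  idx <- match(feature_id, paste0("w", grid$window))
  if (anyNA(idx)) idx <- match(feature_id, as.character(grid$window))
  if (anyNA(idx)) {
    stop("feature ids do not match the window grid (expect 'w<index>')")
  }
  idx
}

#' Merge grid-adjacent same-direction DMRs (mDMRs)
#'
#' Runs of DMRs occupying consecutive window indices on the same chromosome
#' with the same direction of change collapse into single merged regions.
#'
#' @param dmrs A `dmr_set`.
#' @return Data frame of class `mdmr_set`: `chrom`, `start`, `end`,
#'   `direction`, `n_windows`.
#' @export
merge_mdmrs <- function(dmrs) {
  if (nrow(dmrs) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      n_windows = integer(), stringsAsFactors = FALSE)
    class(out) <- c("mdmr_set", "data.frame")
    return(out)
  }
  d <- dmrs[order(dmrs$window), , drop = FALSE]
  new_run <- c(TRUE, diff(d$window) != 1L |
                 d$chrom[-1] != d$chrom[-nrow(d)] |
                 d$direction[-1] != d$direction[-nrow(d)])
  run <- cumsum(new_run)
  out <- data.frame(
    chrom = tapply(d$chrom, run, `[`, 1L),
    start = as.numeric(tapply(d$start, run, min)),
    end = as.numeric(tapply(d$end, run, max)),
    direction = tapply(d$direction, run, `[`, 1L),
    n_windows = as.integer(tapply(d$window, run, length)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("mdmr_set", "data.frame")
  out
}

#' Analytic lower bound of the mDMR/DMR ratio
#'
#' If every window of a chromosome were a same-direction DMR, all of them
#' would merge into one mDMR per chromosome, so the ratio can never fall
#' below (number of chromosomes) / (number of grid windows). On the
#' GRCm38/mm10 layout with 100-bp windows this bound is 8.07e-7.
#'
#' @param layout A `genome_layout`.
#' @param width Window width in bp (default 100).
#' @return The bound as a double.
#' @examples
#' min_ratio_bound(genome_layout("chr1", 1000)) # 0.1
#' @export
min_ratio_bound <- function(layout, width = 100) {
  nrow(layout) / sum(ceiling(layout$length / width))
}

#' mDMR/DMR ratio across a grid of significance thresholds
#'
#' For each threshold p in the grid (sorted descending), counts DMRs and
#' mDMRs and their ratio R(p). R near 1 means newly admitted DMRs are mostly
#' isolated; R falling toward the analytic bound means they mostly extend
#' regions already found.
#'
#' @param diff `diff_result` over the window grid.
#' @param grid Window grid.
#' @param layout `genome_layout` (for the analytic bound).
#' @param p_grid Thresholds, sorted descending
#'   (default `c(0.1, 0.05, 0.01, 0.005, 0.001)`).
#' @return Data frame of class `ratio_curve`: `p`, `n_dmr`, `n_mdmr`,
#'   `ratio` (NA where no DMRs); attribute `bound`.
#' @export
ratio_curve <- function(diff, grid, layout,
                        p_grid = c(0.1, 0.05, 0.01, 0.005, 0.001)) {
  if (is.unsorted(rev(p_grid), strictly = TRUE)) {
    stop("p_grid must be sorted in strictly descending order")
  }
  rows <- lapply(p_grid, function(a) {
    dmrs <- call_dmrs(diff, grid, alpha = a)
    n_dmr <- nrow(dmrs)
    n_mdmr <- nrow(merge_mdmrs(dmrs))
    data.frame(p = a, n_dmr = n_dmr, n_mdmr = n_mdmr,
               ratio = if (n_dmr > 0) n_mdmr / n_dmr else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "bound") <- min_ratio_bound(layout,
                                        width = grid$end[1] - grid$start[1])
  class(out) <- c("ratio_curve", "data.frame")
  out
}

#' Select the DMR significance threshold from a ratio curve
#'
#' Operationalizes "the ratio starts to decrease consistently": walking from
#' the largest grid p downward, p* is the end of the longest run over which
#' R(p) strictly decreases at every step. If the first step is not a decrease
#' (no run of length >= 2), the smallest grid p is returned with a warning.
#' The full curve should always accompany the choice for human review.
#'
#' @param curve A `ratio_curve` with at least 3 usable (non-NA) points.
#' @return The selected threshold p*, with attribute `curve`.
#' @export
select_threshold <- function(curve) {
  ok <- !is.na(curve$ratio)
  if (sum(ok) < 3L) stop("need at least 3 usable grid points")
  cv <- curve[ok, , drop = FALSE]
  r <- cv$ratio
  i <- 1L
  while (i < length(r) && r[i + 1L] < r[i]) i <- i + 1L
  if (i == 1L) {
    warning("ratio does not decrease from the largest grid p; ",
            "falling back to the smallest grid value")
    p_star <- cv$p[length(r)]
  } else {
    p_star <- cv$p[i]
  }
  attr(p_star, "curve") <- curve
  p_star
}

#' Segment same-direction DMRs into isoDMBs
#'
#' Iso-directional differentially methylated blocks: per chromosome, DMRs are
#' ordered by position and maximal runs of equal direction become blocks
#' regardless of the gaps between member DMRs. A block spans from the start
#' of its first DMR to the end of its last DMR (no extension beyond the
#' terminal DMRs); consecutive blocks on a chromosome therefore alternate in
#' direction.
#'
#' @param dmrs A `dmr_set`.
#' @return Data frame of class `isodmb_set`: `chrom`, `start`, `end`,
#'   `direction`, `n_dmrs`.
#' @export
build_isodmbs <- function(dmrs) {
  if (nrow(dmrs) == 0L) {
    out <- data.frame(chrom = character(), start = numeric(),
                      end = numeric(), direction = character(),
                      n_dmrs = integer(), stringsAsFactors = FALSE)
    class(out) <- c("isodmb_set", "data.frame")
    return(out)
  }
  d <- dmrs[order(dmrs$window), , drop = FALSE]
  new_run <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                 d$direction[-1] != d$direction[-nrow(d)])
  run <- cumsum(new_run)
  out <- data.frame(
    chrom = tapply(d$chrom, run, `[`, 1L),
    start = as.numeric(tapply(d$start, run, min)),
    end = as.numeric(tapply(d$end, run, max)),
    direction = tapply(d$direction, run, `[`, 1L),
    n_dmrs = as.integer(tapply(d$window, run, length)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("isodmb_set", "data.frame")
  out
}

#' Write DMR-like region sets as BED
#'
#' Direction goes in the BED name field; p-value (DMRs) or member count
#' (mDMRs/isoDMBs) in the score field.
#'
#' @param x A `dmr_set`, `mdmr_set` or `isodmb_set`.
#' @param path Output path.
#' @export
write_region_bed <- function(x, path) {
  score <- if (!is.null(x$pvalue)) x$pvalue else
    if (!is.null(x$n_dmrs)) x$n_dmrs else
      if (!is.null(x$n_windows)) x$n_windows else 0
  write_bed(data.frame(chrom = x$chrom, start = x$start, end = x$end,
                       name = x$direction, score = score,
                       stringsAsFactors = FALSE), path)
}
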