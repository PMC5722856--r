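#' GC track from a FASTA file
#'
#' Computes percent GC in consecutive non-overlapping bins. N (and other
#' ambiguity) bases are excluded from the denominator; all-N bins get NA.
#'
#' @param path FASTA file with one record per chromosome.
#' @param bin Bin width in bp (default 1000).
#' @return Data frame `chrom`, `start`, `end`, `gc` (percent).
#' @export
gc_track_from_fasta <- function(path, bin = 1000) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  per_chrom <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    len <- length(s)
    starts <- seq.int(1, len, by = bin)
    ends <- pmin(starts + bin - 1, len)
    v <- Biostrings::Views(s, start = starts, end = ends)
    freq <- Biostrings::letterFrequency(v, letters = c("G", "C", "A", "T"))
    denom <- rowSums(freq)
    gc <- ifelse(denom > 0, 100 * (freq[, "G"] + freq[, "C"]) / denom,
                 NA_real_)
    data.frame(chrom = names(seqs)[i], start = starts - 1, end = ends,
               gc = gc, stringsAsFactors = FALSE)
  })
  do.call(rbind, per_chrom)
}

#' Segment a GC track into isochores
#'
#' Recursive binary segmentation: within each segment, the cut maximizing
#' the pooled-variance two-sample t statistic between left and right bin GC
#' means is accepted when its two-sided p-value — Sidak-corrected for the
#' number of candidate cut positions scanned, since the cut is the maximizer
#' — is below `split_alpha` and both children are at least `min_length` bp;
#' the procedure then recurses into the children. Deterministic given the
#' track.
#'
#' @param gc_track Data frame `chrom`, `start`, `end`, `gc` of equal-size
#'   bins tiling each chromosome (e.g. from [gc_track_from_fasta()]).
#' @param min_length Minimum segment length in bp (default 1e4).
#' @param split_alpha Significance level for accepting a cut (default 0.05).
#' @return An isochore set: data frame of class `isochore_set` with `chrom`,
#'   `start`, `end`, `gc` (mean percent GC) and `class` (L1/L2/H1/H2/H3).
#' @export
segment_isochores <- function(gc_track, min_length = 1e4, split_alpha = 0.05) {
  stopifnot(all(c("chrom", "start", "end", "gc") %in% names(gc_track)))
  per_chrom <- lapply(split(gc_track, gc_track$chrom), function(tr) {
    tr <- tr[order(tr$start), , drop = FALSE]
    tr <- tr[!is.na(tr$gc), , drop = FALSE]
    if (nrow(tr) == 0L) return(NULL)
    cuts <- segment_bins(tr$gc, tr$start, tr$end, min_length, split_alpha)
    data.frame(chrom = tr$chrom[1],
               start = tr$start[cuts$from],
               end = tr$end[cuts$to],
               gc = cuts$gc, stringsAsFactors = FALSE)
  })
  segs <- do.call(rbind, per_chrom[!vapply(per_chrom, is.null, TRUE)])
  rownames(segs) <- NULL
  classify_isochores(segs)
}

# Recursive splitter on one chromosome's bin vector; returns segment bin
# spans [from, to] in order plus their mean GC.
segment_bins <- function(gc, start, end, min_length, split_alpha) {
  n <- length(gc)
  res_from <- integer(0); res_to <- integer(0); res_gc <- numeric(0)
  recurse <- function(i, j) {
    best <- best_cut(gc, i, j, start, end, min_length)
    if (!is.null(best) && best$p < split_alpha) {
      recurse(i, best$cut)
      recurse(best$cut + 1L, j)
    } else {
      res_from <<- c(res_from, i)
      res_to <<- c(res_to, j)
      res_gc <<- c(res_gc, mean(gc[i:j]))
    }
  }
  recurse(1L, n)
  list(from = res_from, to = res_to, gc = res_gc)
}

# Best (max |t|) admissible cut of bins i..j; NULL when no cut leaves both
# children >= min_length bp and >= 2 bins.
best_cut <- function(gc, i, j, start, end, min_length) {
  n <- j - i + 1L
  if (n < 4L) return(NULL)
  x <- gc[i:j]
  cs <- cumsum(x)
  css <- cumsum(x^2)
  k <- 2:(n - 2)                       # >= 2 bins each side for a variance
  nl <- k; nr <- n - k
  left_len <- end[i + k - 1L] - start[i]
  right_len <- end[j] - end[i + k - 1L]
  ok <- left_len >= min_length & right_len >= min_length
  if (!any(ok)) return(NULL)
  ml <- cs[k] / nl
  mr <- (cs[n] - cs[k]) / nr
  ssl <- css[k] - cs[k]^2 / nl
  ssr <- (css[n] - css[k]) - (cs[n] - cs[k])^2 / nr
  sp2 <- (ssl + ssr) / (n - 2)
  tstat <- abs(ml - mr) / sqrt(pmax(sp2, 1e-12) * (1 / nl + 1 / nr))
  tstat[!ok] <- -Inf
  b <- which.max(tstat)
  p_single <- 2 * stats::pt(tstat[b], df = n - 2, lower.tail = FALSE)
  # the cut maximizes |t| over all admissible positions, so the naive
  # p-value is corrected for that selection (Sidak over the candidate cuts;
  # conservative under their positive correlation)
  pval <- 1 - (1 - p_single)^sum(ok)
  list(cut = i + k[b] - 1L, p = pval, t = tstat[b])
}

#' Classify segments into the five isochore classes
#'
#' Classes from most AT-rich to most GC-rich with percent-GC thresholds
#' L1 < 37 <= L2 < 41 <= H1 < 46 <= H2 <= 53 < H3. The H2 range (46-53%) is
#' the anchor; the remaining cutoffs follow the standard Bernardi convention.
#'
#' @param segments Data frame with `chrom`, `start`, `end`, `gc`.
#' @return The same rows with a `class` column, classed `isochore_set`.
#' @examples
#' classify_isochores(data.frame(chrom = "c", start = 0, end = 10, gc = 50))
#' @export
classify_isochores <- function(segments) {
  gc <- segments$gc
  if (any(!is.finite(gc)) || any(gc < 0 | gc > 100)) {
    stop("GC percent must lie in [0, 100]")
  }
  segments$class <- ifelse(gc < 37, "L1",
                    ifelse(gc < 41, "L2",
                    ifelse(gc < 46, "H1",
                    ifelse(gc <= 53, "H2", "H3"))))
  class(segments) <- unique(c("isochore_set", class(segments)))
  segments
}

#' Read an isochore BED (class in the name field)
#'
#' Validates that the intervals tile each chromosome without gaps or
#' overlaps.
#'
#' @param path BED path; 4th column must be one of L1, L2, H1, H2, H3, or a
#'   `class:gc` pair (e.g. `"H2:49.5"`).
#' @param layout Optional `genome_layout`.
#' @return An `isochore_set` (the `gc` column is NA when not encoded).
#' @export
read_isochores_bed <- function(path, layout = NULL) {
  bed <- read_bed(path, layout)
  if (is.null(bed$name)) stop("isochore BED needs a class name field")
  parts <- strsplit(bed$name, ":", fixed = TRUE)
  bed$class <- vapply(parts, `[[`, "", 1L)
  bed$gc <- vapply(parts, function(p)
    if (length(p) > 1) suppressWarnings(as.numeric(p[2])) else NA_real_, 0)
  if (!all(bed$class %in% c("L1", "L2", "H1", "H2", "H3"))) {
    stop("unknown isochore class in ", path)
  }
  for (ch in unique(bed$chrom)) {
    sub <- bed[bed$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    bad <- which(sub$start[-1] != sub$end[-nrow(sub)])
    if (length(bad)) {
      stop("isochores do not tile ", ch, " at ",
           paste0(ch, ":", sub$end[bad[1]], "/", sub$start[bad[1] + 1]),
           " (gap or overlap)")
    }
  }
  out <- bed[, c("chrom", "start", "end", "gc", "class")]
  class(out) <- c("isochore_set", "data.frame")
  out
}

#' Write an isochore set as BED
#'
#' @param iso An `isochore_set`.
#' @param path Output path.
#' @export
write_isochores_bed <- function(iso, path) {
  nm <- ifelse(is.na(iso$gc), iso$class,
               paste0(iso$class, ":", round(iso$gc, 2)))
  write_bed(data.frame(chrom = iso$chrom, start = iso$start, end = iso$end,
                       name = nm, stringsAsFactors = FALSE), path)
}
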