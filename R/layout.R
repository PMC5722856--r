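#' Genome layout
#'
#' A genome layout is the single source of coordinate truth for every other
#' operation in the package: an ordered set of chromosomes with their lengths,
#' from which the 100-bp analysis window grid is derived deterministically.
#'
#' @param chrom Character vector of chromosome names (unique).
#' @param length Integer vector of chromosome lengths in base pairs (>= 1).
#' @return An object of class `genome_layout`: a data frame with columns
#'   `chrom` and `length`, one row per chromosome, in the given order.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1000, 500))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("no chromosomes")
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != length(length)) stop("chrom and length differ in size")
  if (any(!is.finite(length)) || any(length < 1)) {
    stop("chromosome lengths must be >= 1")
  }
  structure(
    data.frame(chrom = chrom, length = length, stringsAsFactors = FALSE),
    class = c("genome_layout", "data.frame")
  )
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", nrow(x), "chromosome(s),",
      format(sum(x$length), big.mark = ","), "bp total\n")
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  invisible(x)
}

#' Chromosome lengths of the GRCm38/mm10 mouse assembly
#'
#' Standard lengths (bp) of chr1-19, chrX, chrY and chrM in GRCm38/mm10,
#' as distributed in the UCSC mm10 chrom.sizes table.
#'
#' @return A `genome_layout` for the 22 mouse chromosomes.
#' @examples
#' sum(grcm38_layout()$length)
#' @export
grcm38_layout <- function() {
  genome_layout(
    chrom = c(paste0("chr", 1:19), "chrX", "chrY", "chrM"),
    length = c(195471971, 182113224, 160039680, 156508116, 151834684,
               149736546, 145441459, 129401213, 124595110, 130694993,
               122082543, 120129022, 120421639, 124902244, 104043685,
               98207768, 94987271, 90702639, 61431566, 171031299,
               91744698, 16299)
  )
}

#' Read a UCSC-style chrom.sizes table
#'
#' Two-column TSV: chromosome name, length in bp. No header.
#'
#' @param path Path to the file.
#' @return A `genome_layout`.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  genome_layout(tab$chrom, tab$length)
}

#' Write a chrom.sizes table
#'
#' @param layout A `genome_layout`.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(as.data.frame(layout)[, c("chrom", "length")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Tile a genome into consecutive non-overlapping windows
#'
#' Each chromosome is tiled left to right with windows of `width` bp; the
#' trailing window is shorter when the chromosome length is not a multiple of
#' `width` (ceiling tiling), so the windows of a chromosome partition
#' `[0, length)` exactly and the total count is `sum(ceiling(length / width))`.
#'
#' @param layout A `genome_layout`.
#' @param width Window width in bp (default 100).
#' @return A data frame of intervals with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `window` (1-based index over the whole grid).
#' @examples
#' build_window_grid(genome_layout("chr1", 250), width = 100)
#' @export
build_window_grid <- function(layout, width = 100) {
  stopifnot(inherits(layout, "genome_layout"))
  if (nrow(layout) == 0L) stop("no chromosomes")
  if (width < 1) stop("width must be >= 1")
  per_chrom <- lapply(seq_len(nrow(layout)), function(i) {
    len <- layout$length[i]
    starts <- seq.int(0, len - 1, by = width)
    data.frame(chrom = layout$chrom[i], start = starts,
               end = pmin(starts + width, len), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_chrom)
  out$window <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Regulatory window around a transcription start site
#'
#' Returns the interval covering `upstream` bp upstream through `downstream`
#' bp downstream of a gene's TSS, oriented by strand and clipped to the
#' chromosome bounds. On the '+' strand the TSS is the annotated start; on the
#' '-' strand it is the annotated `end - 1` (the last transcribed base in
#' 0-based half-open coordinates).
#'
#' @param genes Data frame of gene records with columns `gene_id`, `chrom`,
#'   `start`, `end`, `strand` (and optionally `tss`; recomputed if absent).
#' @param layout A `genome_layout` used for clipping.
#' @param upstream,downstream Window extent in bp (defaults 1500 and 500).
#' @return Data frame `gene_id`, `chrom`, `start`, `end` of TSS windows.
#' @examples
#' g <- data.frame(gene_id = "g1", chrom = "chr1", start = 5000, end = 9000,
#'                 strand = "+")
#' tss_window(g, genome_layout("chr1", 2e4))
#' @export
tss_window <- function(genes, layout, upstream = 1500, downstream = 500) {
  genes <- validate_genes(genes, layout)
  tss <- gene_tss(genes)
  plus <- genes$strand == "+"
  start <- ifelse(plus, tss - upstream, tss - downstream + 1)
  end <- ifelse(plus, tss + downstream, tss + upstream + 1)
  len <- layout$length[match(genes$chrom, layout$chrom)]
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = pmax(0, start), end = pmin(len, end),
             stringsAsFactors = FALSE)
}

#' TSS coordinates of gene records
#'
#' @param genes Gene table (see [tss_window()]).
#' @return Numeric vector of 0-based TSS positions.
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "+", genes$start, genes$end - 1)
}

validate_genes <- function(genes, layout = NULL) {
  need <- c("gene_id", "chrom", "start", "end", "strand")
  miss <- setdiff(need, names(genes))
  if (length(miss)) stop("gene table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(genes$strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  if (any(genes$start < 0) || any(genes$end <= genes$start)) {
    bad <- which(genes$start < 0 | genes$end <= genes$start)[1]
    stop("invalid interval for gene ", genes$gene_id[bad])
  }
  if (!is.null(layout)) {
    idx <- match(genes$chrom, layout$chrom)
    if (anyNA(idx)) {
      stop("gene ", genes$gene_id[which(is.na(idx))[1]],
           " on unknown chromosome")
    }
    over <- genes$end > layout$length[idx]
    if (any(over)) {
      stop("gene ", genes$gene_id[which(over)[1]], " exceeds chromosome length")
    }
  }
  genes
}

#' Validate a table of genomic intervals against a layout
#'
#' Checks 0-based half-open interval invariants (`0 <= start < end <= length`)
#' and known chromosomes. Used at every reader boundary.
#'
#' @param x Data frame with `chrom`, `start`, `end`.
#' @param layout Optional `genome_layout`.
#' @param what Label used in error messages.
#' @return `x` invisibly.
#' @export
validate_intervals <- function(x, layout = NULL, what = "interval") {
  if (any(x$start < 0) || any(x$end <= x$start)) {
    bad <- which(x$start < 0 | x$end <= x$start)[1]
    stop(what, " ", bad, " violates 0 <= start < end (",
         x$chrom[bad], ":", x$start[bad], "-", x$end[bad], ")")
  }
  if (!is.null(layout)) {
    idx <- match(x$chrom, layout$chrom)
    if (anyNA(idx)) {
      bad <- which(is.na(idx))[1]
      stop(what, " ", bad, " on unknown chromosome ", x$chrom[bad])
    }
    over <- x$end > layout$length[idx]
    if (any(over)) {
      bad <- which(over)[1]
      stop(what, " ", bad, " exceeds length of ", x$chrom[bad],
           " (end ", x$end[bad], " > ", layout$length[idx][bad], ")")
    }
  }
  invisible(x)
}
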