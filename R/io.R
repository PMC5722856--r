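#' Read a BED file of genomic intervals
#'
#' Accepts 3+ column BED (0-based half-open). Extra columns `name` and
#' `score` are kept when present.
#'
#' @param path Path to the BED file.
#' @param layout Optional `genome_layout`; when given, intervals are checked
#'   against chromosome bounds.
#' @return Data frame with columns `chrom`, `start`, `end` and, when present,
#'   `name` and `score`.
#' @export
read_bed <- function(path, layout = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("malformed BED line ", which(nf < 3L)[1], " in ", path,
         ": fewer than 3 fields")
  }
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (anyNA(start) || anyNA(end)) {
    stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
         " in ", path, ": non-numeric coordinates")
  }
  out <- data.frame(chrom = vapply(fields, `[[`, "", 1L),
                    start = start, end = end, stringsAsFactors = FALSE)
  if (all(nf >= 4L)) out$name <- vapply(fields, `[[`, "", 4L)
  if (all(nf >= 5L)) {
    out$score <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 5L)))
  }
  validate_intervals(out, layout, what = paste0("BED record (", path, ") "))
  out
}

#' Write intervals as BED
#'
#' @param x Data frame with `chrom`, `start`, `end` and optional `name`,
#'   `score` columns.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  if (!is.null(x$name)) {
    cols <- c(cols, "name")
    if (!is.null(x$score)) cols <- c(cols, "score")
  }
  df <- as.data.frame(x)[, cols, drop = FALSE]
  df$start <- format(df$start, scientific = FALSE, trim = TRUE)
  df$end <- format(df$end, scientific = FALSE, trim = TRUE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' TSV with header and columns `gene_id`, `chrom`, `start`, `end`, `strand`
#' (0-based half-open coordinates).
#'
#' @param path Path to the TSV.
#' @param layout Optional `genome_layout` for bounds checking.
#' @param one_based Set `TRUE` for tables with 1-based inclusive starts;
#'   converted to 0-based half-open at this boundary.
#' @return Data frame of gene records with a derived `tss` column.
#' @export
read_gene_table <- function(path, layout = NULL, one_based = FALSE) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (one_based) tab$start <- tab$start - 1
  tab <- validate_genes(tab, layout)
  tab$tss <- gene_tss(tab)
  tab
}

#' Write a gene annotation table
#'
#' @param genes Gene table.
#' @param path Output path.
#' @export
write_gene_table <- function(genes, path) {
  cols <- intersect(c("gene_id", "chrom", "start", "end", "strand"),
                    names(genes))
  utils::write.table(genes[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a count matrix with its sample design
#'
#' TSV with feature IDs in the first column and sample IDs as header.
#'
#' @param path Path to the TSV.
#' @param groups Optional character vector (or factor) of group labels, one
#'   per sample column, recycled onto the object.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path, groups = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("count matrix ", path, " has non-numeric entries")
  count_matrix(m, groups = groups)
}

#' Write a count matrix as TSV
#'
#' @param x A [count_matrix()] or plain matrix with dimnames.
#' @param path Output path.
#' @export
write_count_matrix <- function(x, path) {
  m <- if (inherits(x, "count_matrix")) x$counts else x
  df <- data.frame(feature = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Tab-separated lines: set name, description, then member gene IDs.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors of gene IDs.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short)) {
    stop("malformed GMT line ", short[1], " in ", path,
         ": need name, description and at least one gene")
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, "", 1L)
  sets
}
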