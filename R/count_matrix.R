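#' Count matrix with a two-group design
#'
#' Thin container for a features x samples matrix of non-negative counts plus
#' the sample grouping (control vs treatment) every differential test in the
#' package consumes. Extra per-sample metadata (e.g. generation labels for
#' ATAC samples, total sequenced reads for QC) travels in the `samples` data
#' frame.
#'
#' @param counts Numeric matrix, features in rows (rownames required),
#'   samples in columns (colnames required).
#' @param groups Character/factor of group labels per sample; defaults to the
#'   `"group"` column of `samples` if given there.
#' @param samples Optional data frame of per-sample metadata (one row per
#'   column of `counts`).
#' @return Object of class `count_matrix`: list with elements `counts`
#'   (matrix) and `samples` (data frame with at least `sample` and `group`).
#' @export
count_matrix <- function(counts, groups = NULL, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("f", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  }
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (is.null(samples)) {
    samples <- data.frame(sample = colnames(counts), stringsAsFactors = FALSE)
  }
  if (!is.null(groups)) samples$group <- as.character(groups)
  if (is.null(samples$group)) stop("a 'groups' design is required")
  if (nrow(samples) != ncol(counts)) {
    stop("samples metadata does not match number of columns")
  }
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "features x", ncol(x$counts),
      "samples\n")
  cat("groups:", paste(sprintf("%s (n=%d)", names(table(x$samples$group)),
                               table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by features and/or samples
#'
#' @param x A `count_matrix`.
#' @param i Feature index (row) selector.
#' @param j Sample index (column) selector.
#' @param ... Ignored.
#' @return A `count_matrix`.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE],
               samples = x$samples[j, , drop = FALSE])
}

group_indices <- function(cm, control, treatment) {
  g <- cm$samples$group
  lv <- unique(g)
  if (missing(control) || is.null(control)) control <- lv[1]
  if (missing(treatment) || is.null(treatment)) {
    treatment <- setdiff(lv, control)[1]
  }
  if (!control %in% g || !treatment %in% g) {
    stop("groups '", control, "' / '", treatment, "' not found in design")
  }
  list(control = which(g == control), treatment = which(g == treatment),
       control_label = control, treatment_label = treatment)
}
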