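#' Construct a count matrix container
#'
#' A `count_matrix` holds a non-negative integer expression matrix in the
#' canonical cells-by-genes orientation together with cell and gene
#' identifiers and cached library sizes \eqn{N_i = \sum_j Y_{ij}} (the
#' sequencing depth of cell \eqn{i}).
#'
#' @param counts Numeric matrix of non-negative integers, cells in rows and
#'   genes in columns. Dimnames, when present, seed the default identifiers.
#' @param cell_ids Character vector of unique cell identifiers (length `nrow`).
#' @param gene_ids Character vector of unique gene identifiers (length `ncol`).
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (base integer-valued matrix), `cell_ids`, `gene_ids` and `lib_sizes`.
#' @examples
#' y <- matrix(rpois(12, 5), nrow = 3)
#' cm <- count_matrix(y)
#' lib_sizes(cm)
#' @export
count_matrix <- function(counts, cell_ids = NULL, gene_ids = NULL) {
  counts <- as.matrix(counts)
  if (!is.numeric(counts)) {
    stop("'counts' must be a numeric matrix")
  }
  if (anyNA(counts)) stop("'counts' must not contain missing values")
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative count at row %d, column %d", bad[1], bad[2]))
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    bad <- which(abs(counts - round(counts)) > 1e-8, arr.ind = TRUE)[1, ]
    stop(sprintf("non-integral count at row %d, column %d", bad[1], bad[2]))
  }
  counts <- round(counts)
  if (is.null(cell_ids)) {
    cell_ids <- rownames(counts)
    if (is.null(cell_ids)) cell_ids <- sprintf("cell%d", seq_len(nrow(counts)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(counts)
    if (is.null(gene_ids)) gene_ids <- sprintf("gene%d", seq_len(ncol(counts)))
  }
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(counts)) stop("'cell_ids' length must match nrow(counts)")
  if (length(gene_ids) != ncol(counts)) stop("'gene_ids' length must match ncol(counts)")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  dimnames(counts) <- list(cell_ids, gene_ids)
  structure(
    list(
      counts = counts,
      cell_ids = cell_ids,
      gene_ids = gene_ids,
      lib_sizes = rowSums(counts)
    ),
    class = "count_matrix"
  )
}

#' Coerce to a count matrix
#'
#' @param x A matrix or `count_matrix`.
#' @param ... Passed to [count_matrix()].
#' @return A `count_matrix`.
#' @export
as_count_matrix <- function(x, ...) {
  if (inherits(x, "count_matrix")) return(x)
  count_matrix(x, ...)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf(
    "count_matrix: %d cells x %d genes; median depth %s; %.1f%% zeros\n",
    nrow(x$counts), ncol(x$counts),
    format(stats::median(x$lib_sizes), big.mark = ","),
    100 * mean(x$counts == 0)
  ))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Library sizes (sequencing depths)
#'
#' @param x A `count_matrix`.
#' @return Numeric vector of per-cell total counts \eqn{N_i}.
#' @export
lib_sizes <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  x$lib_sizes
}

#' Subset a count matrix
#'
#' @param x A `count_matrix`.
#' @param i,j Cell and gene indices (numeric, logical or character).
#' @param ... Ignored.
#' @return A `count_matrix` with library sizes recomputed for the retained genes.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  y <- x$counts
  if (missing(i)) i <- seq_len(nrow(y))
  if (missing(j)) j <- seq_len(ncol(y))
  count_matrix(y[i, j, drop = FALSE])
}

#' Filter genes by number of positive counts
#'
#' Keeps genes with at least `min_positive` cells in which the gene has a
#' positive count (an inclusive threshold: a gene with exactly `min_positive`
#' positives is retained). This mirrors the usual practice of discarding
#' near-all-zero genes before model fitting.
#'
#' @param counts A `count_matrix` (or coercible matrix).
#' @param min_positive Minimum number of positive counts required (>= 1).
#' @return A list with elements `counts` (the filtered `count_matrix`, gene
#'   order preserved), `kept` (logical vector over input genes) and `dropped`
#'   (character vector of removed gene ids).
#' @export
filter_genes <- function(counts, min_positive = 5L) {
  counts <- as_count_matrix(counts)
  if (min_positive < 1) stop("'min_positive' must be >= 1")
  npos <- colSums(counts$counts > 0)
  kept <- npos >= min_positive
  if (!any(kept)) stop("all genes dropped by filter; lower 'min_positive'")
  list(
    counts = counts[, which(kept)],
    kept = kept,
    dropped = counts$gene_ids[!kept]
  )
}
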