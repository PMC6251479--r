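# Readers and writers for the plain-text formats the package exchanges:
# MatrixMarket or delimited count matrices with row/column annotation files,
# weight matrices, DE result tables and serialized ZINB fits. The canonical
# in-memory orientation is cells x genes; files with genes in rows (the
# common convention in expression matrices) are transposed on read/write via
# the `orientation` flag.

#' Read a count matrix
#'
#' Supports MatrixMarket (`.mtx`, with optional `<stem>_genes.tsv` /
#' `<stem>_cells.tsv` annotation files or explicit paths) and dense
#' delimited text with a header row and first id column. Entries must be
#' non-negative integers (real-valued storage is accepted only if integral).
#'
#' @param path Path to the `.mtx` or delimited text file.
#' @param orientation `"genes_in_rows"` (default, the common file
#'   convention) or `"cells_in_rows"`.
#' @param gene_file,cell_file Optional paths to one-column-per-line id files
#'   (for `.mtx` input).
#' @param sep Field separator for dense text (default tab).
#' @return A `count_matrix` (cells x genes).
#' @export
read_counts <- function(path, orientation = c("genes_in_rows",
                                              "cells_in_rows"),
                        gene_file = NULL, cell_file = NULL, sep = "\t") {
  orientation <- match.arg(orientation)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    if (is.null(gene_file) && file.exists(paste0(stem, "_genes.tsv"))) {
      gene_file <- paste0(stem, "_genes.tsv")
    }
    if (is.null(cell_file) && file.exists(paste0(stem, "_cells.tsv"))) {
      cell_file <- paste0(stem, "_cells.tsv")
    }
    rown <- if (!is.null(gene_file) && orientation == "genes_in_rows" ||
                !is.null(cell_file) && orientation == "cells_in_rows") TRUE else FALSE
    if (orientation == "genes_in_rows") {
      if (!is.null(gene_file)) rownames(m) <- readLines(gene_file)
      if (!is.null(cell_file)) colnames(m) <- readLines(cell_file)
    } else {
      if (!is.null(cell_file)) rownames(m) <- readLines(cell_file)
      if (!is.null(gene_file)) colnames(m) <- readLines(gene_file)
    }
  } else {
    df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                            check.names = FALSE)
    m <- as.matrix(df)
  }
  if (any(m < 0)) {
    bad <- which(m < 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("negative entry at file row %d, column %d", bad[1L], bad[2L]))
  }
  if (any(abs(m - round(m)) > 1e-8)) {
    bad <- which(abs(m - round(m)) > 1e-8, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-integral entry at file row %d, column %d",
                 bad[1L], bad[2L]))
  }
  if (orientation == "genes_in_rows") m <- t(m)
  if (!is.null(gene_file)) {
    ids <- readLines(gene_file)
    if (length(ids) != ncol(m)) stop("gene annotation length does not match matrix")
  }
  if (!is.null(cell_file)) {
    ids <- readLines(cell_file)
    if (length(ids) != nrow(m)) stop("cell annotation length does not match matrix")
  }
  count_matrix(m)
}

#' Write a count matrix
#'
#' Writes either MatrixMarket (`.mtx` plus `<stem>_genes.tsv` and
#' `<stem>_cells.tsv`) or a dense TSV with genes in rows (the ecosystem's
#' usual file convention).
#'
#' @param counts A `count_matrix`.
#' @param path Output path; format chosen by extension (`.mtx` or text).
#' @param orientation Orientation of the written dense file.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path,
                         orientation = c("genes_in_rows", "cells_in_rows")) {
  orientation <- match.arg(orientation)
  cm <- as_count_matrix(counts)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    m <- if (orientation == "genes_in_rows") t(cm$counts) else cm$counts
    Matrix::writeMM(Matrix::Matrix(m, sparse = TRUE), path)
    stem <- sub("\\.mtx$", "", path, ignore.case = TRUE)
    writeLines(cm$gene_ids, paste0(stem, "_genes.tsv"))
    writeLines(cm$cell_ids, paste0(stem, "_cells.tsv"))
  } else {
    m <- if (orientation == "genes_in_rows") t(cm$counts) else cm$counts
    df <- data.frame(id = rownames(m), m, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Write / read an observation-weight matrix
#'
#' Dense TSV (cells in rows, header of gene ids, first column of cell ids)
#' or MatrixMarket real matrix. Entries equal to one are stored as 1.
#'
#' @param weights n-by-J weight matrix.
#' @param path Output path (`.mtx` or text).
#' @return `path` invisibly for the writer; a plain numeric matrix for the
#'   reader.
#' @export
write_weights <- function(weights, path) {
  w <- unclass(weights)
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    Matrix::writeMM(Matrix::Matrix(w, sparse = TRUE), path)
  } else {
    df <- data.frame(cell_id = if (is.null(rownames(w)))
      sprintf("cell%d", seq_len(nrow(w))) else rownames(w),
      w, check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  if (grepl("\\.mtx$", path, ignore.case = TRUE)) {
    w <- as.matrix(Matrix::readMM(path))
  } else {
    df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1L,
                            check.names = FALSE)
    w <- as.matrix(df)
  }
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  w
}

#' Write / read a DE result table
#'
#' Deterministic column order and 6-significant-digit floating formatting,
#' so identical analyses produce byte-identical files.
#'
#' @param result A `zinb_de` object or its `table` data.frame.
#' @param path Output TSV path.
#' @return `path` invisibly; the reader returns the table as a data.frame.
#' @export
write_de_results <- function(result, path) {
  tab <- if (inherits(result, "zinb_de")) result$table else result
  cols <- c("gene_id", "log2fc", "statistic", "df_test", "df_resid",
            "raw_p", "adjusted_p", "filtered", "fitted_mean", "low_df")
  tab <- tab[, intersect(cols, names(tab)), drop = FALSE]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(x) signif(x, 6))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_de_results
#' @export
read_de_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Serialize / restore a ZINB fit as plain text
#'
#' Writes the coefficient blocks as TSV matrices plus a JSON manifest
#' (dimensions, configuration, seed, log-likelihood trace) into a
#' directory; `read_zinb_fit()` reconstructs the fit, including the fitted
#' `mu` and `pi` surfaces recomputed from the coefficients.
#'
#' @param fit A `zinb_fit`.
#' @param dir Output directory (created if needed).
#' @return `dir` invisibly; the reader returns a `zinb_fit`.
#' @export
write_zinb_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "zinb_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wm <- function(m, f) utils::write.table(m, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE,
                                          col.names = FALSE)
  for (nm in c("beta_mu", "beta_pi", "gamma_mu", "gamma_pi", "W",
               "alpha_mu", "alpha_pi", "X", "V")) {
    if (!is.null(fit[[nm]]) && length(fit[[nm]])) wm(fit[[nm]], paste0(nm, ".tsv"))
  }
  manifest <- list(
    dims = as.list(fit$dims),
    zeta = fit$zeta,
    config = fit$config,
    loglik = fit$loglik,
    n_params = fit$n_params,
    converged = fit$converged,
    penalized_loglik_trace = fit$penalized_loglik_trace,
    cell_ids = fit$cell_ids,
    gene_ids = fit$gene_ids
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_zinb_fit
#' @export
read_zinb_fit <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"),
                             simplifyVector = TRUE)
  rm_ <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) as.matrix(utils::read.table(p, sep = "\t")) else NULL
  }
  d <- man$dims
  fit <- list(
    beta_mu = rm_("beta_mu.tsv"), beta_pi = rm_("beta_pi.tsv"),
    gamma_mu = rm_("gamma_mu.tsv"), gamma_pi = rm_("gamma_pi.tsv"),
    W = rm_("W.tsv"), alpha_mu = rm_("alpha_mu.tsv"),
    alpha_pi = rm_("alpha_pi.tsv"),
    X = rm_("X.tsv"), V = rm_("V.tsv"),
    zeta = man$zeta,
    loglik = man$loglik, n_params = man$n_params,
    converged = man$converged,
    penalized_loglik_trace = man$penalized_loglik_trace,
    dims = unlist(d), config = man$config,
    cell_ids = man$cell_ids, gene_ids = man$gene_ids,
    K = d$K
  )
  n <- d$n; J <- d$J
  fix0 <- function(m, nr, nc) if (is.null(m)) matrix(0, nr, nc) else unname(m)
  fit$beta_mu <- fix0(fit$beta_mu, d$M, J); fit$beta_pi <- fix0(fit$beta_pi, d$M, J)
  fit$gamma_mu <- fix0(fit$gamma_mu, d$L, n); fit$gamma_pi <- fix0(fit$gamma_pi, d$L, n)
  fit$W <- fix0(fit$W, n, d$K)
  fit$alpha_mu <- fix0(fit$alpha_mu, d$K, J); fit$alpha_pi <- fix0(fit$alpha_pi, d$K, J)
  em <- matrix(0, n, J); ep <- matrix(0, n, J)
  if (d$M > 0) { em <- em + fit$X %*% fit$beta_mu; ep <- ep + fit$X %*% fit$beta_pi }
  if (d$L > 0) { em <- em + t(fit$V %*% fit$gamma_mu); ep <- ep + t(fit$V %*% fit$gamma_pi) }
  if (d$K > 0) { em <- em + fit$W %*% fit$alpha_mu; ep <- ep + fit$W %*% fit$alpha_pi }
  fit$mu <- exp(.cap_eta(em))
  fit$pi <- .clip_pi(stats::plogis(.cap_eta(ep)))
  fit$theta <- if (man$config$dispersion == "genewise") exp(fit$zeta)
               else rep(exp(fit$zeta), J)
  class(fit) <- "zinb_fit"
  fit
}

#' Fit ZINB observation weights in one call
#'
#' Convenience wrapper: filters nothing, fits [zinb_fit()] with the given
#' design and returns [posterior_weights()]. This is the standard first step
#' before [zinb_de()].
#'
#' @inheritParams zinb_fit
#' @param ... Passed to [zinb_fit()].
#' @return A `zinb_weights` matrix; the fit is attached as attribute `fit`.
#' @export
zinb_weights <- function(counts, X = ~1, cell_data = NULL, ...) {
  cm <- as_count_matrix(counts)
  fit <- zinb_fit(cm, X = X, cell_data = cell_data, ...)
  w <- posterior_weights(cm, fit)
  attr(w, "fit") <- fit
  w
}
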