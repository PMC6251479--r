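#' Positive-count ("poscounts") size factors
#'
#' Median-of-ratios normalization adapted to sparse counts: the per-gene
#' reference is the geometric mean of the gene's *positive* counts only,
#' \eqn{r_j = \exp(\mathrm{mean}_{i: Y_{ij} > 0} \ln Y_{ij})}, so genes with
#' some zero counts still contribute. The size factor of cell \eqn{i} is the
#' median of \eqn{Y_{ij}/r_j} over the genes with \eqn{Y_{ij} > 0}, rescaled
#' so the geometric mean of the factors is one.
#'
#' @param counts A `count_matrix` or cells-by-genes matrix. Every cell must
#'   have at least one positive count.
#' @return An object of class `norm_factors`: a list with `size_factors`
#'   (length n, geometric mean 1) and `method`.
#' @examples
#' y <- matrix(c(4, 8, 0, 2, 2, 4, 1, 1, 6, 12, 0, 3), nrow = 3)
#' poscounts_size_factors(y)$size_factors
#' @export
poscounts_size_factors <- function(counts) {
  y <- if (inherits(counts, "count_matrix")) counts$counts else as.matrix(counts)
  zero_cells <- rowSums(y > 0) == 0
  if (any(zero_cells)) {
    nm <- rownames(y)[which(zero_cells)[1L]]
    if (is.null(nm)) nm <- as.character(which(zero_cells)[1L])
    stop(sprintf("cell '%s' has no positive counts; cannot normalize", nm))
  }
  logy <- suppressWarnings(log(y))
  logy[!is.finite(logy)] <- NA
  log_ref <- colMeans(logy, na.rm = TRUE)        # log geometric mean of positives
  ratios <- log(y) - rep(log_ref, each = nrow(y))
  ratios[y == 0] <- NA
  s <- exp(apply(ratios, 1L, stats::median, na.rm = TRUE))
  s <- s / exp(mean(log(s)))
  structure(list(size_factors = stats::setNames(s, rownames(y)),
                 method = "poscounts"),
            class = "norm_factors")
}

#' Library-size size factors
#'
#' Size factors proportional to total counts, rescaled to geometric mean one.
#'
#' @param counts A `count_matrix` or cells-by-genes matrix.
#' @return A `norm_factors` object.
#' @export
libsize_size_factors <- function(counts) {
  cm <- as_count_matrix(counts)
  s <- cm$lib_sizes / exp(mean(log(cm$lib_sizes)))
  structure(list(size_factors = stats::setNames(s, cm$cell_ids),
                 method = "libsize"),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("%s size factors for %d cells (range %.3g - %.3g)\n",
              x$method, length(x$size_factors),
              min(x$size_factors), max(x$size_factors)))
  invisible(x)
}

#' Average log counts per million
#'
#' Gene-level expression strength
#' \deqn{\hat A_j = \log_2\left[\frac{10^6}{n} \sum_i \frac{Y_{ij}}{N_i} + c\right],}
#' with a small stabilizer `c` equal to a prior count of 2 converted to CPM
#' at the mean library size, \eqn{c = 2 \times 10^6 / \bar N}. This is the
#' quantity the dispersion trend and the zero-abundance model are indexed by.
#'
#' @param counts A `count_matrix` or cells-by-genes matrix.
#' @param prior_count Prior count used for the stabilizer (default 2).
#' @return Named numeric vector of length J.
#' @export
ave_log_cpm <- function(counts, prior_count = 2) {
  cm <- as_count_matrix(counts)
  N <- cm$lib_sizes
  if (any(N <= 0)) stop("library sizes must be positive")
  cpm_mean <- 1e6 / nrow(cm$counts) * colSums(cm$counts / N)
  cstab <- prior_count * 1e6 / mean(N)
  stats::setNames(log2(cpm_mean + cstab), cm$gene_ids)
}
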