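# Performance-assessment machinery: confusion counts, FDP-TPR curves, ROC
# curves, per-comparison error rates, mock-null splits and p-value
# diagnostics, following the standard definitions
#   FDP = FP / max(1, FP + TP),  FPR = FP / (FP + TN),  TPR = TP / (TP + FN).

#' Confusion counts at a significance cutoff
#'
#' Tallies true/false positives/negatives when rejecting hypotheses whose
#' (adjusted) p-value is at or below `cutoff`. `NA` values are treated as
#' non-rejections.
#'
#' @param pvals Numeric vector of raw or adjusted p-values.
#' @param truth Logical vector: `TRUE` for genuinely non-null genes.
#' @param cutoff Rejection threshold.
#' @return A list with integer fields `TP`, `FP`, `TN`, `FN`.
#' @export
confusion_at <- function(pvals, truth, cutoff) {
  stopifnot(length(pvals) == length(truth))
  truth <- as.logical(truth)
  rej <- !is.na(pvals) & pvals <= cutoff
  list(TP = sum(rej & truth), FP = sum(rej & !truth),
       TN = sum(!rej & !truth), FN = sum(!rej & truth))
}

#' False discovery proportion vs true positive rate curve
#'
#' Sweeps all distinct p-value thresholds and reports, at each, the false
#' discovery proportion \eqn{FDP = FP/\max(1, FP+TP)} (the `max(1, .)` guard
#' makes FDP zero when nothing is rejected) and the true positive rate.
#' The working point at a nominal BH-adjusted FDR of `alpha` is included,
#' with a flag for whether the achieved FDP is at or below the nominal
#' level.
#'
#' @param pvals Raw p-values.
#' @param truth Logical vector of true DE status (must contain both classes).
#' @param alpha Nominal FDR for the working point (default 0.05).
#' @return An object of class `eval_curve`: a data.frame with columns
#'   `threshold`, `FDP`, `TPR`, plus attributes `working_point` (list with
#'   `FDP`, `TPR`, `achieved`) and `type = "fdptpr"`.
#' @export
fdp_tpr_curve <- function(pvals, truth, alpha = 0.05) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) {
    stop("'truth' must contain at least one TRUE and one FALSE")
  }
  th <- sort(unique(pvals[!is.na(pvals)]))
  cc <- lapply(th, function(t) confusion_at(pvals, truth, t))
  fdp <- vapply(cc, function(x) x$FP / max(1, x$FP + x$TP), numeric(1))
  tpr <- vapply(cc, function(x) x$TP / (x$TP + x$FN), numeric(1))
  padj <- bh_adjust(pvals)
  wc <- confusion_at(padj, truth, alpha)
  wp <- list(FDP = wc$FP / max(1, wc$FP + wc$TP),
             TPR = wc$TP / (wc$TP + wc$FN),
             n_rejected = wc$FP + wc$TP,
             achieved = (wc$FP / max(1, wc$FP + wc$TP)) <= alpha)
  structure(data.frame(threshold = th, FDP = fdp, TPR = tpr),
            working_point = wp, alpha = alpha, type = "fdptpr",
            class = c("eval_curve", "data.frame"))
}

#' ROC curve and AUC
#'
#' Standard receiver operating characteristic over all distinct score
#' thresholds (higher scores rank the positive class first); tied scores are
#' grouped. The area under the curve is computed by the trapezoidal rule.
#'
#' @param scores Numeric vector; larger values indicate the positive class.
#' @param truth Logical vector (both classes required).
#' @return An `eval_curve` data.frame with columns `threshold`, `FPR`,
#'   `TPR`, and attributes `auc` and `type = "roc"`. Constant scores give
#'   AUC 0.5 with a warning.
#' @export
roc_curve <- function(scores, truth) {
  truth <- as.logical(truth)
  if (!any(truth) || all(truth)) {
    stop("'truth' must contain at least one TRUE and one FALSE")
  }
  stopifnot(length(scores) == length(truth))
  if (length(unique(scores)) == 1L) {
    warning("constant scores: ROC is the diagonal, AUC 0.5")
    out <- data.frame(threshold = c(Inf, scores[1L]),
                      FPR = c(0, 1), TPR = c(0, 1))
    return(structure(out, auc = 0.5, type = "roc",
                     class = c("eval_curve", "data.frame")))
  }
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; t <- truth[o]
  # group ties
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(t); fp <- cumsum(!t)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / sum(truth))
  fpr <- c(0, fp[last] / sum(!truth))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(data.frame(threshold = c(Inf, s[last]), FPR = fpr, TPR = tpr),
            auc = auc, type = "roc",
            class = c("eval_curve", "data.frame"))
}

#' @export
print.eval_curve <- function(x, ...) {
  if (attr(x, "type") == "roc") {
    cat(sprintf("ROC curve over %d thresholds; AUC = %.4f\n",
                nrow(x) - 1L, attr(x, "auc")))
  } else {
    wp <- attr(x, "working_point")
    cat(sprintf(
      "FDP-TPR curve over %d thresholds; at BH %.2g: FDP %.4f, TPR %.4f (%s)\n",
      nrow(x), attr(x, "alpha"), wp$FDP, wp$TPR,
      if (wp$achieved) "controlled" else "exceeded"))
  }
  invisible(x)
}

#' @export
plot.eval_curve <- function(x, ...) {
  if (attr(x, "type") == "roc") {
    graphics::plot(x$FPR, x$TPR, type = "l", xlab = "FPR", ylab = "TPR", ...)
    graphics::abline(0, 1, lty = 3)
  } else {
    graphics::plot(x$FDP, x$TPR, type = "l", xlab = "FDP", ylab = "TPR", ...)
    wp <- attr(x, "working_point")
    graphics::points(wp$FDP, wp$TPR, pch = if (wp$achieved) 16 else 1)
    graphics::abline(v = attr(x, "alpha"), lty = 3)
  }
  invisible(x)
}

#' Mock-null split of homogeneous cells
#'
#' Draws two disjoint, equally sized groups of cells from a homogeneous
#' population, optionally stratified by a batch variable: with a batch
#' column, `group_size / nbatches` cells are sampled without replacement
#' from each batch for each group, so batch composition is balanced and any
#' gene declared DE between the groups is a false positive.
#'
#' @param cell_metadata A data.frame with one row per cell.
#' @param group_size Number of cells per group.
#' @param batch_column Optional name of a batch column in `cell_metadata`.
#' @param seed Integer seed.
#' @return A list with integer index vectors `group1` and `group2`
#'   (disjoint, each of length `group_size`).
#' @export
mock_null_split <- function(cell_metadata, group_size, batch_column = NULL,
                            seed = 1L) {
  set.seed(seed)
  ncells <- nrow(cell_metadata)
  if (is.null(batch_column)) {
    if (2 * group_size > ncells) stop("not enough cells for two disjoint groups")
    idx <- sample.int(ncells, 2 * group_size)
    return(list(group1 = sort(idx[seq_len(group_size)]),
                group2 = sort(idx[group_size + seq_len(group_size)])))
  }
  batch <- as.factor(cell_metadata[[batch_column]])
  nb <- nlevels(batch)
  if (group_size %% nb != 0) {
    stop("'group_size' must be divisible by the number of batches")
  }
  per <- group_size / nb
  g1 <- g2 <- integer(0)
  for (b in levels(batch)) {
    pool <- which(batch == b)
    if (length(pool) < 2 * per) {
      stop(sprintf("batch '%s' has %d cells; needs at least %d",
                   b, length(pool), 2 * per))
    }
    pick <- sample(pool, 2 * per)
    g1 <- c(g1, pick[seq_len(per)])
    g2 <- c(g2, pick[per + seq_len(per)])
  }
  list(group1 = sort(g1), group2 = sort(g2))
}

#' Per-comparison error rate
#'
#' Fraction of genes with unadjusted p-value at or below `alpha`. On a
#' complete-null (mock) comparison this estimates the actual
#' per-comparison type I error rate, to be compared with the nominal level.
#'
#' @param pvals Raw p-values in `[0, 1]` (`NA` ignored).
#' @param alpha Nominal level (default 0.05).
#' @return The observed rejection fraction.
#' @export
pcer <- function(pvals, alpha = 0.05) {
  p <- pvals[!is.na(pvals)]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  if (!length(p)) return(NA_real_)
  mean(p <= alpha)
}

#' P-value distribution diagnostics
#'
#' Fixed-bin histogram counts and a one-sample Kolmogorov-Smirnov statistic
#' against the uniform distribution, plus the direction of deviation
#' (mean above/below 0.5 flags conservative/anti-conservative behavior).
#'
#' @param pvals Raw p-values (`NA` dropped).
#' @param bins Number of equal-width histogram bins (default 20).
#' @return A list with `breaks`, `counts`, `ks_stat`, `ks_p`, `mean_p` and
#'   `skew` (`"conservative"`, `"anti-conservative"` or `"balanced"`).
#' @export
pvalue_diagnostics <- function(pvals, bins = 20L) {
  p <- pvals[!is.na(pvals)]
  breaks <- seq(0, 1, length.out = bins + 1L)
  counts <- as.vector(table(cut(p, breaks, include.lowest = TRUE)))
  ks <- suppressWarnings(stats::ks.test(p, "punif"))
  mp <- mean(p)
  skew <- if (mp > 0.52) "conservative" else if (mp < 0.48)
    "anti-conservative" else "balanced"
  list(breaks = breaks, counts = counts,
       ks_stat = unname(ks$statistic), ks_p = ks$p.value,
       mean_p = mp, skew = skew)
}
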