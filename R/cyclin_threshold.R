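# Cyclin-threshold analysis of paired cytometry tables: a dividing
# ("permissive") condition and a division-blocked ("restrictive") condition
# measured on the same strain. Within size bins spanning the dividing-size
# range, the cyclin level required to trigger division is estimated from the
# brightest cells, and the fraction of blocked cells above that threshold is
# compared with the septation probability of dividing cells.

.check_cells <- function(table, need_fluor = FALSE) {
  if (!is.data.frame(table) || NROW(table) == 0)
    stop("per-cell table must be a non-empty data.frame")
  if (is.null(table$size) || any(!is.finite(table$size)) ||
      any(table$size <= 0))
    stop("'size' must be finite and > 0")
  if (need_fluor) {
    if (is.null(table$fluor) || any(!is.finite(table$fluor)) ||
        any(table$fluor < 0))
      stop("'fluor' must be finite and >= 0")
  }
  invisible(table)
}

.condition_rows <- function(table, cond) {
  if (is.null(table$condition)) rep(TRUE, nrow(table))
  else table$condition == cond
}

#' Assign cells to equal-width size bins
#'
#' Bins rows into \code{n_bins} equal-width bins over \code{size_range};
#' rows outside the range are excluded. Bins are half-open \code{[lo, hi)}
#' with the last bin closed, so a cell exactly on an interior edge belongs
#' to the right-hand bin.
#'
#' @param table per-cell data.frame with a \code{size} column.
#' @param n_bins number of bins (default 8, the published binning).
#' @param size_range length-2 numeric. Default: the range of division sizes
#'   observed in the permissive condition, i.e. of septated cells (septated
#'   length equals division length in fission yeast).
#' @return the retained rows with an integer \code{bin} column added;
#'   attribute \code{"edges"} carries the bin edges.
#' @export
assign_bins <- function(table, n_bins = 8, size_range = NULL) {
  .check_cells(table)
  if (!is.numeric(n_bins) || n_bins < 1) stop("'n_bins' must be >= 1")
  n_bins <- as.integer(n_bins)
  if (is.null(size_range)) {
    sept <- .septated_flag(table) & .condition_rows(table, "permissive")
    if (!any(sept))
      stop("no septated permissive cells to derive 'size_range' from")
    size_range <- range(table$size[sept])
  }
  if (length(size_range) != 2 || !all(is.finite(size_range)) ||
      size_range[1] >= size_range[2])
    stop("'size_range' must be an increasing length-2 numeric")
  edges <- seq(size_range[1], size_range[2], length.out = n_bins + 1L)
  keep <- table$size >= size_range[1] & table$size <= size_range[2]
  out <- table[keep, , drop = FALSE]
  out$bin <- findInterval(out$size, edges, rightmost.closed = TRUE)
  rownames(out) <- NULL
  attr(out, "edges") <- edges
  out
}

#' Within-bin cyclin threshold from the brightest cells
#'
#' The cyclin level required to trigger division within a size bin is
#' estimated as the mean fluorescence of the \code{k} brightest cells in the
#' bin (dividing condition): cells at the top of the within-bin distribution
#' are the ones about to divide.
#'
#' @param fluor_values fluorescence values (AU) of one bin.
#' @param k number of brightest cells to average (default 10).
#' @return mean of the \code{k} largest values, or \code{NA} (with a
#'   warning) when the bin holds fewer than \code{k} cells — such bins are
#'   excluded from the global mean.
#' @examples
#' bin_threshold(1:20)   # mean(11:20) = 15.5
#' @export
bin_threshold <- function(fluor_values, k = 10) {
  if (k < 1) stop("'k' must be >= 1")
  if (length(fluor_values) < k) {
    warning(sprintf("bin has %d < k = %d cells; flagged NA",
                    length(fluor_values), k))
    return(NA_real_)
  }
  mean(sort(fluor_values, decreasing = TRUE)[seq_len(k)])
}

#' Global cyclin threshold
#'
#' Unweighted mean of the valid per-bin thresholds (the published 180 AU is
#' this quantity on the original images).
#'
#' @param thresholds numeric vector of per-bin thresholds; \code{NA} entries
#'   (bins with fewer than \code{k} cells) are dropped.
#' @return scalar threshold (AU).
#' @export
global_threshold <- function(thresholds) {
  ok <- is.finite(thresholds)
  if (!any(ok)) stop("no valid per-bin thresholds")
  mean(thresholds[ok])
}

.per_bin <- function(binned, n_bins, f) {
  vapply(seq_len(n_bins), function(b) {
    rows <- binned$bin == b
    if (!any(rows)) NA_real_ else f(binned[rows, , drop = FALSE])
  }, numeric(1))
}

#' Septation probability per size bin
#'
#' Fraction of cells within each size bin of the dividing (permissive)
#' condition that carry a septum. Empty bins are flagged \code{NA}, not 0.
#'
#' @param binned a permissive-condition table from [assign_bins()].
#' @param n_bins number of bins (defaults to the binning attribute).
#' @return numeric vector of per-bin probabilities (NA = empty bin).
#' @export
p_septation_per_bin <- function(binned, n_bins = NULL) {
  if (is.null(binned$bin)) stop("table must come from assign_bins()")
  if (is.null(n_bins)) n_bins <- length(attr(binned, "edges")) - 1L
  sept <- .septated_flag(binned)
  vapply(seq_len(n_bins), function(b) {
    rows <- binned$bin == b
    if (!any(rows)) NA_real_ else mean(sept[rows])
  }, numeric(1))
}

#' Suprathreshold probability per size bin
#'
#' Fraction of division-blocked (restrictive) cells per size bin whose
#' cyclin fluorescence strictly exceeds the threshold — the cells that would
#' have divided were division permitted.
#'
#' @param binned a restrictive-condition table from [assign_bins()].
#' @param threshold cyclin threshold in AU (> 0), typically
#'   [global_threshold()].
#' @param n_bins number of bins (defaults to the binning attribute).
#' @return numeric vector of per-bin probabilities (NA = empty bin).
#' @export
p_suprathreshold_per_bin <- function(binned, threshold, n_bins = NULL) {
  if (is.null(binned$bin)) stop("table must come from assign_bins()")
  if (!is.finite(threshold) || threshold < 0) stop("'threshold' must be >= 0")
  if (is.null(n_bins)) n_bins <- length(attr(binned, "edges")) - 1L
  .per_bin(binned, n_bins, function(d) mean(d$fluor > threshold))
}

#' Overlap probability per size bin
#'
#' Fraction of dividing-condition cells per bin whose cyclin fluorescence
#' falls inside the overlap interval shared with the blocked condition — a
#' per-bin measure of how much of the dividing population still sits at
#' pre-anaphase cyclin levels.
#'
#' @param binned a permissive-condition table from [assign_bins()].
#' @param overlap_interval length-2 numeric \code{c(lo, hi)} in AU, or a
#'   2-column matrix with one row per bin.
#' @param n_bins number of bins (defaults to the binning attribute).
#' @return numeric vector of per-bin probabilities (NA = empty bin).
#' @export
p_overlap_per_bin <- function(binned, overlap_interval, n_bins = NULL) {
  if (is.null(binned$bin)) stop("table must come from assign_bins()")
  if (is.null(n_bins)) n_bins <- length(attr(binned, "edges")) - 1L
  iv <- overlap_interval
  if (is.null(dim(iv))) iv <- matrix(iv, n_bins, 2, byrow = TRUE)
  if (ncol(iv) != 2 || nrow(iv) != n_bins)
    stop("'overlap_interval' must be c(lo, hi) or an n_bins x 2 matrix")
  if (any(stats::na.omit(iv[, 1] > iv[, 2])))
    stop("overlap interval has lo > hi")
  vapply(seq_len(n_bins), function(b) {
    rows <- binned$bin == b
    if (!any(rows) || !all(is.finite(iv[b, ]))) return(NA_real_)
    mean(binned$fluor[rows] >= iv[b, 1] & binned$fluor[rows] <= iv[b, 2])
  }, numeric(1))
}

#' Pearson correlation between per-bin probability series
#'
#' @param x,y per-bin numeric vectors of equal length; bins missing (NA) in
#'   either series are dropped pairwise. At least 3 complete pairs and
#'   non-zero variance in both series are required.
#' @return Pearson r.
#' @export
threshold_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need at least 3 paired bins")
  if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0)
    stop("zero variance in a series")
  stats::cor(x[ok], y[ok])
}

#' CoV of cyclin in a size window at the first decile of division size
#'
#' Places a window at the stated decile (default the 1st) of the
#' division-size distribution (septated cells of the dividing condition) and
#' compares two coefficients of variation: of cyclin fluorescence among
#' division-blocked cells inside the window, and of division size itself.
#' Under the threshold model the two scale together — noisier cyclin
#' expression degrades size fidelity.
#'
#' @param table per-cell table holding both conditions (columns \code{size},
#'   \code{septated}, \code{fluor}, \code{condition}).
#' @param decile quantile of division size at which to center the window
#'   (default 0.1); linear-interpolation quantile.
#' @param half_window half-width of the window in size units (the published
#'   window is +/- 100 pixels^2 on area measurements).
#' @return list with \code{cov_division_size}, \code{cov_fluor_in_window},
#'   \code{center}, \code{n_window}, and \code{low_confidence} (TRUE when
#'   fewer than 10 blocked cells fall in the window).
#' @export
decile_window_cov <- function(table, decile = 0.1, half_window) {
  .check_cells(table, need_fluor = TRUE)
  if (!is.finite(decile) || decile <= 0 || decile >= 1)
    stop("'decile' must be in (0, 1)")
  if (is.na(half_window) || half_window <= 0)
    stop("'half_window' must be > 0")   # Inf allowed: whole-population CoV
  sept <- .septated_flag(table)
  div_sizes <- table$size[sept & .condition_rows(table, "permissive")]
  if (length(div_sizes) < 2) stop("need >= 2 permissive septated cells")
  center <- unname(stats::quantile(div_sizes, decile))
  restr <- .condition_rows(table, "restrictive") &
    abs(table$size - center) <= half_window
  fl <- table$fluor[restr]
  n_window <- length(fl)
  cov_fluor <- if (n_window >= 2 && mean(fl) > 0) stats::sd(fl) / mean(fl)
               else NA_real_
  list(cov_division_size = stats::sd(div_sizes) / mean(div_sizes),
       cov_fluor_in_window = cov_fluor,
       center = center, n_window = n_window,
       low_confidence = n_window < 10)
}

#' Full cyclin-threshold analysis of a paired cytometry table
#'
#' Runs the whole pipeline on a table holding a dividing (permissive) and a
#' division-blocked (restrictive) condition: size bins spanning the
#' dividing-size range, per-bin thresholds from the brightest \code{k}
#' dividing cells, the global (mean) threshold, per-bin P(septation)
#' (permissive), P(cyclin > threshold) (restrictive), the overlap
#' probability, and the two correlations relating them.
#'
#' @param table per-cell data.frame with columns \code{size},
#'   \code{septated}, \code{fluor}, \code{condition} (values
#'   \code{"permissive"} / \code{"restrictive"}).
#' @param n_bins number of size bins (default 8).
#' @param k brightest cells averaged per bin (default 10).
#' @param size_range optional; defaults to the permissive division-size
#'   range.
#' @param overlap_interval optional \code{c(lo, hi)} or per-bin matrix; by
#'   default derived per bin as [5th percentile of restrictive fluorescence,
#'   95th percentile of permissive fluorescence], clipped to lo <= hi and
#'   reported alongside the result.
#' @param threshold optional fixed threshold (AU); defaults to
#'   [global_threshold()] of the per-bin estimates.
#' @return An object of class \code{"threshold_result"}: \code{bin_edges},
#'   \code{per_bin} data.frame (\code{bin_lo, bin_hi, threshold,
#'   p_septation, p_suprathreshold, p_overlap, overlap_lo, overlap_hi}),
#'   \code{global_threshold}, \code{correlation_sept_vs_supra},
#'   \code{correlation_overlap_vs_supra}, \code{n_bins}, \code{k}.
#' @examples
#' \donttest{
#' tab <- rbind(synth_cyclin_table(4000, condition = "permissive", seed = 1),
#'              synth_cyclin_table(4000, condition = "restrictive", seed = 2))
#' threshold_analysis(tab)
#' }
#' @export
threshold_analysis <- function(table, n_bins = 8, k = 10, size_range = NULL,
                               overlap_interval = NULL, threshold = NULL) {
  .check_cells(table, need_fluor = TRUE)
  if (is.null(table$condition))
    stop("table must carry a 'condition' column")
  perm_all <- table[table$condition == "permissive", , drop = FALSE]
  restr_all <- table[table$condition == "restrictive", , drop = FALSE]
  if (nrow(perm_all) == 0 || nrow(restr_all) == 0)
    stop("both 'permissive' and 'restrictive' rows are required")
  if (is.null(size_range)) {
    sept <- .septated_flag(perm_all)
    if (!any(sept)) stop("no septated permissive cells define the size range")
    size_range <- range(perm_all$size[sept])
  }
  perm <- assign_bins(perm_all, n_bins, size_range)
  restr <- assign_bins(restr_all, n_bins, size_range)
  edges <- attr(perm, "edges")
  thr_bin <- vapply(seq_len(n_bins), function(b) {
    fl <- perm$fluor[perm$bin == b]
    if (length(fl) < k) NA_real_ else bin_threshold(fl, k)
  }, numeric(1))
  thr_global <- global_threshold(thr_bin)
  if (is.null(threshold)) threshold <- thr_global
  p_sept <- p_septation_per_bin(perm, n_bins)
  p_supra <- p_suprathreshold_per_bin(restr, threshold, n_bins)
  if (is.null(overlap_interval)) {
    iv <- t(vapply(seq_len(n_bins), function(b) {
      fr <- restr$fluor[restr$bin == b]
      fp <- perm$fluor[perm$bin == b]
      if (!length(fr) || !length(fp)) return(c(NA_real_, NA_real_))
      lo <- unname(stats::quantile(fr, 0.05))
      hi <- unname(stats::quantile(fp, 0.95))
      if (lo > hi) lo <- hi
      c(lo, hi)
    }, numeric(2)))
  } else {
    iv <- overlap_interval
    if (is.null(dim(iv))) iv <- matrix(iv, n_bins, 2, byrow = TRUE)
  }
  p_over <- p_overlap_per_bin(perm, iv, n_bins)
  structure(list(
    bin_edges = edges,
    per_bin = data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                         threshold = thr_bin, p_septation = p_sept,
                         p_suprathreshold = p_supra, p_overlap = p_over,
                         overlap_lo = iv[, 1], overlap_hi = iv[, 2]),
    global_threshold = thr_global,
    threshold_used = threshold,
    correlation_sept_vs_supra = threshold_correlation(p_sept, p_supra),
    correlation_overlap_vs_supra = threshold_correlation(p_over, p_supra),
    n_bins = n_bins, k = k),
    class = "threshold_result")
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf("Cyclin-threshold analysis (%d bins, k = %d brightest)\n",
              x$n_bins, x$k))
  cat(sprintf("  global threshold: %.4g AU (used: %.4g)\n",
              x$global_threshold, x$threshold_used))
  cat(sprintf("  r[P(septation), P(>threshold)]  = %+.3f\n",
              x$correlation_sept_vs_supra))
  cat(sprintf("  r[P(overlap),   P(>threshold)]  = %+.3f\n",
              x$correlation_overlap_vs_supra))
  invisible(x)
}

#' @param x a \code{threshold_result}.
#' @param ... unused.
#' @rdname threshold_analysis
#' @export
as.data.frame.threshold_result <- function(x, ...) x$per_bin
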