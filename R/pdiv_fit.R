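# Estimating the size-to-division dose-response from septation snapshots:
# bin cells by size, take the septated fraction per bin, and fit a Hill
# curve to the fractions by nonlinear least squares.

.septated_flag <- function(table) {
  if (!is.null(table$septated)) {
    s <- table$septated
    if (is.logical(s)) return(s)
    if (all(s %in% c(0, 1))) return(s == 1)
    stop("'septated' must be logical or 0/1")
  }
  if (!is.null(table$phase)) return(table$phase == "septated")
  stop("table must have a 'septated' (or 'phase') column")
}

#' Septated fraction per size bin
#'
#' Bins cells into uniform size bins and computes the fraction septated per
#' bin — the snapshot surrogate for the probability of division at that
#' size. Bins with fewer than \code{min_count} cells are dropped (sparse
#' extreme-size bins would otherwise dominate the fit).
#'
#' @param table a per-cell table with columns \code{size} (> 0) and
#'   \code{septated} (logical or 0/1); a [snapshot_series()] data.frame
#'   (with a \code{phase} column) is also accepted.
#' @param bin_width bin width in size units (default 1, the published
#'   binning).
#' @param min_count minimum cells per retained bin (default 10).
#' @return An object of class \code{c("binned_septation", "data.frame")}
#'   with columns \code{bin_lo, bin_hi, center, n_total, n_septated,
#'   fraction}.
#' @export
bin_fraction_septated <- function(table, bin_width = 1, min_count = 10) {
  if (NROW(table) == 0) stop("empty table")
  if (!is.finite(bin_width) || bin_width <= 0) stop("'bin_width' must be > 0")
  size <- table$size
  if (is.null(size) || any(!is.finite(size)) || any(size <= 0))
    stop("table must have finite positive 'size'")
  sept <- .septated_flag(table)
  lo <- floor(min(size))
  hi <- ceiling(max(size))
  edges <- seq(lo, hi, by = bin_width)
  if (edges[length(edges)] < hi) edges <- c(edges, edges[length(edges)] + bin_width)
  # half-open [lo, hi) bins, last bin closed
  bin <- findInterval(size, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1L
  n_total <- tabulate(bin, nbins = nb)
  n_sept <- tabulate(bin[sept], nbins = nb)
  out <- data.frame(bin_lo = edges[-length(edges)], bin_hi = edges[-1],
                    center = (edges[-length(edges)] + edges[-1]) / 2,
                    n_total = n_total, n_septated = n_sept,
                    fraction = ifelse(n_total > 0, n_sept / n_total, NA_real_))
  out <- out[out$n_total >= max(1, min_count), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("binned_septation", "data.frame"),
            bin_width = bin_width, min_count = min_count)
}

.rss_hill <- function(par, x, y, w) sum(w * (y - par[1] / (1 + (par[2] / x)^par[3]))^2)

#' Fit a Hill curve to binned septation fractions
#'
#' Nonlinear least squares of the per-bin septated fraction against bin
#' center, under the three-parameter Hill model
#' \code{pmax * s^n / (ec50^n + s^n)}. The fit is unweighted by default
#' (each retained bin counts equally, as in the published analysis);
#' count-weighted fitting is available.
#'
#' @param binned a [bin_fraction_septated()] result, or any data.frame with
#'   \code{center}, \code{fraction} (and \code{n_total} if
#'   \code{weighted = TRUE}) columns.
#' @param init optional [hill_curve()] starting point. The default start is
#'   \code{pmax = max(fraction)}, \code{ec50 =} the bin center whose fraction
#'   is nearest \code{pmax/2}, \code{n = 4}.
#' @param weighted logical; weight squared residuals by bin counts.
#' @return An object of class \code{"hill_fit"}: \code{curve} (the fitted
#'   [hill_curve()]), \code{rss}, \code{se} (named standard errors, NA when
#'   unavailable), \code{converged}, \code{data} (the fitted bins),
#'   \code{fitted}.
#' @details Parameters are bounded: \code{pmax} in (0, 1], \code{ec50} in
#'   (0, max bin center], \code{n} in (0, 100]. Fitting uses
#'   \code{\link[stats]{nls}} (\code{algorithm = "port"}); if that fails
#'   (degenerate data, e.g. monotone-decreasing fractions), a bounded
#'   quasi-Newton minimization of the residual sum of squares is used and
#'   the fit is flagged \code{converged = FALSE} if it also fails or stops
#'   on a bound. No exception is raised for non-convergence.
#' @examples
#' centers <- 8:20
#' frac <- hill_eval(hill_curve(0.1, 14, 14), centers)
#' fit <- fit_hill(data.frame(center = centers, fraction = frac))
#' coef(fit)
#' @export
fit_hill <- function(binned, init = NULL, weighted = FALSE) {
  x <- binned$center
  y <- binned$fraction
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 bins to fit a Hill curve")
  if (all(y == 0)) stop("all fractions are zero; nothing to fit")
  if (stats::var(y) == 0) stop("fractions are all equal; nothing to fit")
  w <- if (weighted) {
    if (is.null(binned$n_total)) stop("weighted fit needs 'n_total'")
    binned$n_total[keep]
  } else rep(1, length(x))
  if (is.null(init)) {
    p0 <- max(y)
    start <- c(pmax = min(p0, 1),
               ec50 = x[which.min(abs(y - p0 / 2))],
               n = 4)
  } else {
    stopifnot(inherits(init, "hill_curve"))
    start <- c(pmax = init$pmax, ec50 = init$ec50, n = init$n)
  }
  lower <- c(1e-8, 1e-8, 1e-8)
  upper <- c(1, max(x), 100)
  start <- pmin(pmax(start, lower), upper)
  se <- c(pmax = NA_real_, ec50 = NA_real_, n = NA_real_)
  converged <- FALSE
  est <- start
  fit <- tryCatch(
    stats::nls(y ~ pmax / (1 + (ec50 / x)^n),
               data = data.frame(x = x, y = y),
               start = as.list(start), weights = w,
               algorithm = "port", lower = lower, upper = upper,
               control = stats::nls.control(maxiter = 500, warnOnly = FALSE)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    est <- stats::coef(fit)
    converged <- fit$convInfo$isConv
    se_try <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                       error = function(e) NULL)
    if (!is.null(se_try)) se[names(se_try)] <- se_try
  } else {
    opt <- tryCatch(
      stats::optim(start, .rss_hill, x = x, y = y, w = w,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt)) {
      est <- opt$par
      on_bound <- any(abs(est - lower) < 1e-10) ||
        any(abs(est - c(Inf, upper[2:3])) < 1e-10)
      converged <- opt$convergence == 0 && !on_bound
    }
  }
  curve <- hill_curve(max(est[["pmax"]], 1e-12),
                      max(est[["ec50"]], 1e-12),
                      max(est[["n"]], 1e-12))
  fitted <- hill_eval(curve, x)
  boundary <- any(est <= lower + 1e-8) || est[["n"]] >= upper[3] - 1e-8 ||
    est[["ec50"]] >= upper[2] - 1e-8
  structure(list(curve = curve,
                 rss = sum(w * (y - fitted)^2),
                 se = se, converged = converged, boundary = boundary,
                 data = data.frame(center = x, fraction = y, weight = w),
                 fitted = fitted),
            class = "hill_fit")
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: pmax = %.4g, EC50 = %.4g, n = %.4g  (RSS %.3g%s)\n",
              x$curve$pmax, x$curve$ec50, x$curve$n, x$rss,
              if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' @export
summary.hill_fit <- function(object, ...) {
  tab <- cbind(Estimate = coef(object), `Std. Error` = object$se)
  cat(sprintf("Hill dose-response fit over %d size bins (%s)\n",
              nrow(object$data),
              if (object$converged) "converged" else "NOT converged"))
  stats::printCoefmat(tab, na.print = "NA")
  cat(sprintf("Residual sum of squares: %.4g\n", object$rss))
  invisible(tab)
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(pmax = object$curve$pmax, ec50 = object$curve$ec50, n = object$curve$n)
}

#' @export
residuals.hill_fit <- function(object, ...) {
  object$data$fraction - object$fitted
}

#' @param object,x a \code{hill_fit}.
#' @param newdata numeric vector of sizes (defaults to the fitted bin
#'   centers).
#' @rdname fit_hill
#' @export
predict.hill_fit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  hill_eval(object$curve, newdata)
}

#' @param nsim,seed number of binomial resamples of the per-bin fractions and
#'   the seed used to draw them (requires bin counts in the fitted data).
#' @rdname fit_hill
#' @export
simulate.hill_fit <- function(object, nsim = 1, seed = NULL, ...) {
  w <- object$data$weight
  if (any(w <= 1)) stop("simulate() needs per-bin counts (a weighted fit)")
  .with_seed(seed, {
    p <- object$fitted
    as.data.frame(replicate(nsim, stats::rbinom(length(p), round(w), p) / round(w)))
  })
}

#' @param ... further plot arguments.
#' @rdname fit_hill
#' @export
plot.hill_fit <- function(x, ...) {
  d <- x$data
  graphics::plot(d$center, d$fraction, pch = 16, xlab = "size (bin center)",
                 ylab = "fraction septated", ylim = c(0, max(d$fraction) * 1.1),
                 ...)
  s <- seq(min(d$center), max(d$center), length.out = 200)
  graphics::lines(s, hill_eval(x$curve, s), col = "firebrick", lwd = 2)
  invisible(x)
}

#' Convert a septated fraction to a per-minute division rate
#'
#' A snapshot septated fraction reflects both the rate of entering septation
#' and the ~30 min spent septated. \code{mode = "literal"} divides the
#' fraction by the septation time (\code{fraction / septation_time}), the
#' published normalization. \code{mode = "steady_state"} inverts the
#' steady-state occupancy relation \code{fraction = h*tau / (1 + h*tau)},
#' returning \code{h = fraction / (tau * (1 - fraction))}; unlike the literal
#' form it can exceed \code{1/tau} and is the exact inverse of
#' [occupancy_from_rate()].
#'
#' @param fraction septated fraction(s) in [0, 1].
#' @param septation_time minutes spent septated (> 0; ~30 physiologically).
#' @param mode \code{"literal"} or \code{"steady_state"}.
#' @return per-minute rate(s).
#' @examples
#' rate_from_fraction(0.9, 30)                  # 0.03
#' rate_from_fraction(0.75, 30, "steady_state") # 0.1
#' @export
rate_from_fraction <- function(fraction, septation_time,
                               mode = c("literal", "steady_state")) {
  mode <- match.arg(mode)
  if (!is.finite(septation_time) || septation_time <= 0)
    stop("'septation_time' must be > 0")
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop("'fraction' must be in [0, 1]")
  if (mode == "literal") return(fraction / septation_time)
  if (any(fraction == 1))
    stop("steady-state inversion is infinite at fraction = 1")
  fraction / (septation_time * (1 - fraction))
}

#' Steady-state septated occupancy from a per-minute rate
#'
#' The renewal relation \code{h*tau / (1 + h*tau)}: cells entering a
#' \code{tau}-minute septated state at per-minute hazard \code{h} spend that
#' fraction of steady-state time septated. Inverse of
#' [rate_from_fraction()] in \code{"steady_state"} mode.
#'
#' @param rate per-minute rate(s), >= 0.
#' @param septation_time minutes (> 0).
#' @return occupancy fraction(s) in [0, 1).
#' @export
occupancy_from_rate <- function(rate, septation_time) {
  if (!is.finite(septation_time) || septation_time <= 0)
    stop("'septation_time' must be > 0")
  if (any(!is.finite(rate)) || any(rate < 0)) stop("'rate' must be >= 0")
  rate * septation_time / (1 + rate * septation_time)
}

#' Independent Hill fits over a time course of snapshots
#'
#' Bins and fits each per-cell table independently, preserving order, so
#' shifts of the dose-response (e.g. an EC50 drop after Wee1 inhibition) can
#' be followed across sample time points. A table that cannot be fitted is
#' flagged in place; the rest of the series is still returned.
#'
#' @param tables a (optionally named) list of per-cell tables, each with
#'   \code{size} and \code{septated} columns.
#' @param bin_width,min_count passed to [bin_fraction_septated()].
#' @param ... passed to [fit_hill()].
#' @return A list of class \code{"pdiv_timecourse"}; each element is a
#'   \code{hill_fit}, or a list with \code{converged = FALSE} and an
#'   \code{error} message for unfittable tables.
#' @export
pdiv_timecourse <- function(tables, bin_width = 1, min_count = 10, ...) {
  stopifnot(is.list(tables), length(tables) >= 1)
  fits <- lapply(tables, function(tab) {
    tryCatch(fit_hill(bin_fraction_septated(tab, bin_width, min_count), ...),
             error = function(e)
               structure(list(converged = FALSE, error = conditionMessage(e)),
                         class = "hill_fit_failure"))
  })
  structure(fits, class = "pdiv_timecourse")
}

#' @export
print.pdiv_timecourse <- function(x, ...) {
  cat(sprintf("P(Div) time course: %d fits\n", length(x)))
  labs <- names(x)
  if (is.null(labs)) labs <- as.character(seq_along(x))
  for (i in seq_along(x)) {
    f <- x[[i]]
    if (inherits(f, "hill_fit_failure"))
      cat(sprintf("  [%s] failed: %s\n", labs[i], f$error))
    else
      cat(sprintf("  [%s] pmax %.3g, EC50 %.3g, n %.3g%s\n", labs[i],
                  f$curve$pmax, f$curve$ec50, f$curve$n,
                  if (f$converged) "" else " (not converged)"))
  }
  invisible(x)
}
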