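# Homeostasis metrics over completed-cycle division records: Fantes-plot
# regression, CoV of division size, boxplot-style summaries, and sweeps of
# the Hill parameters.

.as_records <- function(records) {
  if (inherits(records, "pdiv_sim")) records <- records$records
  if (!is.data.frame(records) ||
      !all(c("birth_size", "division_size") %in% names(records)))
    stop("'records' must be a division-record data.frame (or pdiv_sim)")
  records
}

#' Fantes-plot regression of extension on birth size
#'
#' Ordinary least squares of length extension (division size minus birth
#' size) on birth size over completed cycles. The slope is the classical
#' discriminator of size-control modes: -1 for a perfect sizer, 0 for a
#' perfect adder, positive (e^(gT) - 1) for a timer; intermediate negative
#' slopes quantify partial size correction.
#'
#' @param records a division-record data.frame (columns \code{birth_size},
#'   \code{division_size}, optionally \code{extension}) or a
#'   [run_simulation()] result. Only completed cycles should be included;
#'   [run_simulation()] already excludes the founder generation.
#' @return An object of class \code{"fantes_fit"}: \code{slope},
#'   \code{intercept}, \code{r} (Pearson correlation), \code{n_records}.
#' @examples
#' rec <- data.frame(birth_size = c(6, 7, 8), division_size = 14)
#' fantes_fit(rec)$slope   # exactly -1: a perfect sizer
#' @export
fantes_fit <- function(records) {
  records <- .as_records(records)
  if (nrow(records) < 3) stop("need at least 3 division records")
  b <- records$birth_size
  ext <- if (!is.null(records$extension)) records$extension
         else records$division_size - b
  if (stats::var(b) == 0) stop("zero variance in birth size")
  fit <- stats::lm.fit(cbind(1, b), ext)
  r <- if (stats::var(ext) == 0) 0 else stats::cor(b, ext)
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1]),
                 r = r, n_records = nrow(records)),
            class = "fantes_fit")
}

#' @export
print.fantes_fit <- function(x, ...) {
  cat(sprintf("Fantes fit (n = %d): slope %.4f, intercept %.4f, r %.3f\n",
              x$n_records, x$slope, x$intercept, x$r))
  invisible(x)
}

#' @export
coef.fantes_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' Coefficient of variation of division size
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean of
#' division sizes; the standard measure of cell-size fidelity (~0.09 for
#' wild-type-like populations).
#'
#' @param records division records (or [run_simulation()] result), or a bare
#'   numeric vector of division sizes.
#' @return dimensionless CoV.
#' @export
division_cov <- function(records) {
  x <- if (is.numeric(records)) records
       else .as_records(records)$division_size
  if (length(x) < 2) stop("need at least 2 values")
  m <- mean(x)
  if (m <= 0) stop("mean division size must be > 0")
  stats::sd(x) / m
}

#' Boxplot-style distribution summary
#'
#' Quartiles by linear interpolation; whiskers extend to the furthest point
#' within 1.5 interquartile ranges of the box (whichever of the two limits
#' is nearer); values beyond the whiskers are listed as outliers.
#'
#' @param values numeric vector, length >= 1.
#' @return list with \code{q25, median, q75, whisker_low, whisker_high,
#'   outliers}.
#' @examples
#' distribution_summary(c(1, 2, 3, 4, 100))$outliers  # 100
#' @export
distribution_summary <- function(values) {
  if (length(values) == 0 || any(!is.finite(values)))
    stop("'values' must be non-empty and finite")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75)))
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(q25 = q[1], median = q[2], q75 = q[3],
       whisker_low = min(values[inside]),
       whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Sweep the Hill parameters of the P(Div) simulation
#'
#' Runs the pdiv-rule simulation over a grid of (EC50, Hill coefficient)
#' values, \code{reps} replicates per grid point with distinct derived
#' seeds, and records the replicate-averaged mean division size, CoV of
#' division size, and Fantes slope. This reproduces the heatmap analysis of
#' how the dose-response shape trades off mean size against homeostasis
#' strength.
#'
#' @param base_config a [sim_config()] with \code{rule = "pdiv"}; its Hill
#'   \code{pmax} and all non-Hill parameters are held fixed.
#' @param ec50_values,n_values grid axes (defaults 8..20 by 1 and 2..30 by
#'   2).
#' @param reps replicates per grid point (default 3).
#' @return An object of class \code{"sweep_result"}: \code{ec50_grid},
#'   \code{n_grid}, matrices \code{mean_size}, \code{cov}, \code{fantes_slope}
#'   (rows = EC50, cols = n; NA where a replicate produced too few records),
#'   \code{reps}, \code{seed}.
#' @details Per-replicate seeds are derived deterministically from
#'   \code{base_config$seed} and the grid coordinates via [derive_seed()], so
#'   the sweep is reproducible and its cells are independent. Failures in a
#'   grid cell are recorded as NA without aborting the sweep.
#' @seealso [as.data.frame.sweep_result()], [plot.sweep_result()]
#' @export
sweep_grid <- function(base_config, ec50_values = 8:20,
                       n_values = seq(2, 30, by = 2), reps = 3) {
  stopifnot(inherits(base_config, "sim_config"))
  if (base_config$rule != "pdiv") stop("sweep_grid requires the 'pdiv' rule")
  if (length(ec50_values) == 0 || length(n_values) == 0)
    stop("empty grid")
  if (reps < 1) stop("'reps' must be >= 1")
  base_seed <- if (is.null(base_config$seed)) 0L else base_config$seed
  pmax0 <- base_config$rule_params$pmax
  dims <- c(length(ec50_values), length(n_values))
  mean_size <- cov <- slope <- matrix(NA_real_, dims[1], dims[2],
                                      dimnames = list(ec50_values, n_values))
  for (i in seq_along(ec50_values)) {
    for (j in seq_along(n_values)) {
      ms <- cv <- sl <- numeric(0)
      for (r in seq_len(reps)) {
        cfg <- base_config
        cfg$rule_params <- hill_curve(pmax0, ec50_values[i], n_values[j])
        cfg$seed <- derive_seed(base_seed,
                                sprintf("sweep/%g/%g/%d",
                                        ec50_values[i], n_values[j], r))
        res <- tryCatch({
          sim <- run_simulation(cfg)
          rec <- sim$records
          if (nrow(rec) < 3) NULL
          else c(mean(rec$division_size), division_cov(rec),
                 fantes_fit(rec)$slope)
        }, error = function(e) NULL)
        if (!is.null(res)) {
          ms <- c(ms, res[1]); cv <- c(cv, res[2]); sl <- c(sl, res[3])
        }
      }
      if (length(ms)) {
        mean_size[i, j] <- mean(ms)
        cov[i, j] <- mean(cv)
        slope[i, j] <- mean(sl)
      }
    }
  }
  structure(list(ec50_grid = ec50_values, n_grid = n_values,
                 mean_size = mean_size, cov = cov, fantes_slope = slope,
                 reps = reps, seed = base_seed),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Hill-parameter sweep: %d EC50 x %d n grid, %d reps (seed %d)\n",
              length(x$ec50_grid), length(x$n_grid), x$reps, x$seed))
  cat(sprintf("  mean division size %.3g..%.3g; Fantes slope %.3g..%.3g\n",
              min(x$mean_size, na.rm = TRUE), max(x$mean_size, na.rm = TRUE),
              min(x$fantes_slope, na.rm = TRUE),
              max(x$fantes_slope, na.rm = TRUE)))
  invisible(x)
}

#' Tidy data.frame of a sweep
#'
#' @param x a [sweep_grid()] result.
#' @param ... unused.
#' @return data.frame with columns \code{ec50, n, mean_size, cov,
#'   fantes_slope, reps} (one row per grid point).
#' @export
as.data.frame.sweep_result <- function(x, ...) {
  g <- expand.grid(ec50 = x$ec50_grid, n = x$n_grid)
  data.frame(g, mean_size = as.vector(x$mean_size),
             cov = as.vector(x$cov),
             fantes_slope = as.vector(x$fantes_slope),
             reps = x$reps)
}

#' Heatmaps of a Hill-parameter sweep
#'
#' @param x a [sweep_grid()] result.
#' @param which one of \code{"mean_size"}, \code{"cov"},
#'   \code{"fantes_slope"}.
#' @param ... passed to [graphics::image()].
#' @export
plot.sweep_result <- function(x, which = c("mean_size", "cov",
                                           "fantes_slope"), ...) {
  which <- match.arg(which)
  z <- x[[which]]
  graphics::image(x$ec50_grid, x$n_grid, z, xlab = "EC50",
                  ylab = "Hill coefficient", main = which,
                  col = grDevices::hcl.colors(64, "viridis"), ...)
  invisible(x)
}
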