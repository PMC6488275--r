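# Synthetic per-cell cytometry tables with the statistical structure the
# analyses assume: steady-state size distributions with size-dependent
# septation (Hill hazard), and noisy size-correlated cyclin fluorescence
# under dividing and division-blocked conditions. Stand-ins for
# imaging-cytometry snapshots; no optics or segmentation error is modelled.

# lognormal multiplier with unit mean and coefficient of variation cv
.lognorm_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

.sample_rows <- function(pool, n_cells) {
  if (nrow(pool) >= n_cells) pool[sample.int(nrow(pool), n_cells), ,
                                  drop = FALSE]
  else pool[sample.int(nrow(pool), n_cells, replace = TRUE), , drop = FALSE]
}

.cells_frame <- function(size, septated, fluor, condition) {
  data.frame(cell_id = seq_along(size), size = size,
             septated = as.logical(septated), fluor = fluor,
             condition = condition)
}

#' Synthetic septation snapshot under the P(Div) model
#'
#' Simulates a population dividing under a size-dependent Hill hazard with a
#' septated (non-elongating) period, lets it reach steady state, and samples
#' per-cell (size, septated) rows pooled from post-burn-in snapshots — a
#' stand-in for an imaging-cytometry snapshot of an asynchronous culture.
#' The septated fraction at size s approaches the renewal occupancy
#' h(s)*tau / (1 + h(s)*tau).
#'
#' @param n_cells rows to sample.
#' @param hill per-minute division hazard, a [hill_curve()] with
#'   \code{pmax > 0}.
#' @param septation_duration minutes septated before the split (default 30).
#' @param growth_rate per-minute fractional growth (default 0.006).
#' @param seed integer seed; the whole table is deterministic given it.
#' @param t_max simulated minutes (default 1000).
#' @param burn_in minutes discarded before sampling; the default, 5 mean
#'   cycle times (~110 min each under the default hazard), is well past the
#'   initialization transient.
#' @param sample_interval minutes between pooled snapshots (default 10).
#' @return a per-cell data.frame: \code{cell_id, size, septated, fluor} (NA;
#'   this generator carries no fluorescence), \code{condition}
#'   (\code{"permissive"}).
#' @examples
#' tab <- synth_snapshot(2000, seed = 1)
#' head(bin_fraction_septated(tab))
#' @export
synth_snapshot <- function(n_cells, hill = hill_curve(0.1, 14, 14),
                           septation_duration = 30, growth_rate = 0.006,
                           seed = NULL, t_max = 1000, burn_in = 550,
                           sample_interval = 10) {
  if (!is.numeric(n_cells) || n_cells < 1) stop("'n_cells' must be >= 1")
  stopifnot(inherits(hill, "hill_curve"))
  if (hill$pmax <= 0)
    stop("'hill' must have pmax > 0: the population never divides otherwise")
  if (burn_in >= t_max) stop("'burn_in' must be < 't_max'")
  cfg <- sim_config("pdiv", growth_rate = growth_rate, t_max = t_max,
                    septation_duration = septation_duration,
                    rule_params = hill, seed = seed)
  snaps <- snapshot_series(cfg, sample_interval)
  pool <- snaps[snaps$time >= burn_in, , drop = FALSE]
  rows <- .with_seed(if (is.null(seed)) NULL else derive_seed(seed, "sample"),
                     .sample_rows(pool, n_cells))
  .cells_frame(rows$size, rows$phase == "septated", NA_real_, "permissive")
}

#' Synthetic cyclin-fluorescence table (dividing or division-blocked)
#'
#' Simulates the cyclin-accumulation division rule with a septated period
#' and samples per-cell rows carrying the true cyclin amount times
#' multiplicative lognormal measurement noise as \code{fluor}. In the
#' \code{"permissive"} condition cells divide on their cyclin threshold and
#' rows are pooled from post-burn-in snapshots. In the \code{"restrictive"}
#' condition the same population is run to \code{t_max}, the division
#' trigger is then disabled (an unattainable threshold, emulating a
#' temperature shift-up of a cdc25-ts strain) for
#' \code{restrictive_extra_minutes} while growth and cyclin accumulation
#' continue, and the final population is sampled.
#'
#' @param n_cells rows to sample.
#' @param condition \code{"permissive"} or \code{"restrictive"}.
#' @param cyclin a [cdc13_params()].
#' @param growth_rate per-minute fractional growth (default 0.006).
#' @param septation_duration minutes septated (default 30).
#' @param expression_noise_cv lognormal CV of measured fluorescence around
#'   the true cyclin amount (default 0.1).
#' @param restrictive_extra_minutes division-blocked growth time before
#'   sampling (default 60; the published shift is "short", under one cycle).
#' @param n_init,t_max,burn_in,sample_interval simulation span and sampling
#'   grid as in [synth_snapshot()]; defaults 10 cells, 1000 min, 550 min,
#'   10 min.
#' @param seed integer seed.
#' @return a per-cell data.frame: \code{cell_id, size, septated, fluor,
#'   condition}.
#' @examples
#' perm <- synth_cyclin_table(1000, seed = 1)
#' restr <- synth_cyclin_table(1000, condition = "restrictive", seed = 2)
#' @export
synth_cyclin_table <- function(n_cells,
                               condition = c("permissive", "restrictive"),
                               cyclin = cdc13_params(),
                               growth_rate = 0.006,
                               septation_duration = 30,
                               expression_noise_cv = 0.1,
                               restrictive_extra_minutes = 60,
                               n_init = 10, t_max = 1000, burn_in = 550,
                               sample_interval = 10, seed = NULL) {
  condition <- match.arg(condition)
  if (!is.numeric(n_cells) || n_cells < 1) stop("'n_cells' must be >= 1")
  stopifnot(inherits(cyclin, "cdc13_params"))
  if (expression_noise_cv < 0) stop("'expression_noise_cv' must be >= 0")
  cfg <- sim_config("cdc13", growth_rate = growth_rate, n_init = n_init,
                    t_max = t_max, septation_duration = septation_duration,
                    rule_params = cyclin, seed = seed)
  rows <- .with_seed(cfg$seed, {
    if (condition == "permissive") {
      out <- .sim_engine(cfg, snapshot_every = sample_interval)
      pool <- out$snapshots[out$snapshots$time >= burn_in, , drop = FALSE]
      .sample_rows(pool, n_cells)
    } else {
      out <- .sim_engine(cfg)
      out2 <- .sim_engine(cfg, state = out$state, t_start = t_max,
                          t_end = t_max + restrictive_extra_minutes,
                          disable_trigger = TRUE)
      .sample_rows(.state_snapshot(out2$state,
                                   t_max + restrictive_extra_minutes),
                   n_cells)
    }
  })
  fluor <- rows$cyclin_amount *
    .with_seed(if (is.null(seed)) NULL else derive_seed(seed, "noise"),
               .lognorm_noise(nrow(rows), expression_noise_cv))
  .cells_frame(rows$size, rows$phase == "septated", fluor, condition)
}

#' Multiplicative lognormal measurement noise on fluorescence
#'
#' Multiplies \code{fluor} by i.i.d. lognormal factors with unit mean and
#' the stated coefficient of variation; sizes and all other columns are
#' untouched. Fluorescence is positive and its measurement error is
#' multiplicative, hence the lognormal choice.
#'
#' @param table per-cell data.frame with a \code{fluor} column.
#' @param cv coefficient of variation of the noise (>= 0; 0 returns the
#'   table unchanged).
#' @param seed optional integer seed.
#' @return the table with noisy \code{fluor}.
#' @export
add_measurement_noise <- function(table, cv, seed = NULL) {
  if (!is.finite(cv) || cv < 0) stop("'cv' must be >= 0")
  if (is.null(table$fluor)) stop("table has no 'fluor' column")
  if (cv == 0) return(table)
  table$fluor <- table$fluor *
    .with_seed(seed, .lognorm_noise(nrow(table), cv))
  table
}
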