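#' Parameters of the cyclin (Cdc13) accumulation division rule
#'
#' Cyclin B (Cdc13) is synthesized noisily as the cell grows and triggers
#' division once a threshold is crossed; it is reset at division (APC/C
#' degradation) to a birth level proportional to birth size.
#'
#' @param synthesis_rate cyclin synthesized per minute (AU/min), or AU per
#'   size unit per minute when \code{synthesis_mode = "size_proportional"}.
#' @param synthesis_noise_sd SD of the Gaussian noise added to synthesis each
#'   minute (AU/min).
#' @param degradation_rate cyclin degraded per minute outside mitosis (AU/min).
#' @param threshold_mean,threshold_sd per-cell division threshold drawn at
#'   birth from N(threshold_mean, threshold_sd), in AU (amount mode) or
#'   AU per size unit (concentration mode).
#' @param birth_level_factor cyclin at birth is
#'   \code{birth_level_factor * birth_size}.
#' @param synthesis_mode \code{"size_proportional"} (default; synthesis scales
#'   with current size, so concentration relaxes towards
#'   \code{synthesis_rate/growth_rate}) or \code{"absolute"} (literal constant
#'   AU/min).
#' @param threshold_mode \code{"concentration"} (default; the statistic
#'   compared with the threshold is amount/size) or \code{"amount"}.
#'
#' @details The defaults are the published constants of the accumulation
#'   model (0.07, 0.05, 0.0001, 6, 0.3, 0.7). Taken literally those constants
#'   are mutually inconsistent (constant 0.07 AU/min can never reach a
#'   concentration of 6 at size ~7, while an amount threshold of 6 from a
#'   birth amount of ~4.9 gives ~16-min cycles); the default mode pair
#'   \code{size_proportional} + \code{concentration} is the one reading that
#'   yields realistic ~110-min cycles. All four combinations are selectable.
#'
#' @return An object of class \code{"cdc13_params"}.
#' @export
cdc13_params <- function(synthesis_rate = 0.07,
                         synthesis_noise_sd = 0.05,
                         degradation_rate = 0.0001,
                         threshold_mean = 6,
                         threshold_sd = 0.3,
                         birth_level_factor = 0.7,
                         synthesis_mode = c("size_proportional", "absolute"),
                         threshold_mode = c("concentration", "amount")) {
  synthesis_mode <- match.arg(synthesis_mode)
  threshold_mode <- match.arg(threshold_mode)
  vals <- c(synthesis_rate, synthesis_noise_sd, degradation_rate,
            threshold_sd, birth_level_factor)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all cdc13 rates and noise parameters must be finite and >= 0")
  if (!is.finite(threshold_mean) || threshold_mean <= 0)
    stop("'threshold_mean' must be > 0")
  structure(list(synthesis_rate = synthesis_rate,
                 synthesis_noise_sd = synthesis_noise_sd,
                 degradation_rate = degradation_rate,
                 threshold_mean = threshold_mean,
                 threshold_sd = threshold_sd,
                 birth_level_factor = birth_level_factor,
                 synthesis_mode = synthesis_mode,
                 threshold_mode = threshold_mode),
            class = "cdc13_params")
}

#' Gaussian rule parameters for the deterministic division rules
#'
#' Each cell draws a private threshold at birth from
#' N(\code{mean}, \code{sd}): the amount of size to add (adder), the target
#' division size (sizer), or the cycle duration in minutes (timer).
#'
#' @param mean,sd Gaussian mean and standard deviation; \code{sd = 0} gives
#'   the deterministic rule.
#' @return An object of class \code{"gaussian_rule"}.
#' @export
gaussian_rule <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0) stop("'mean' must be > 0")
  if (!is.finite(sd) || sd < 0) stop("'sd' must be >= 0")
  structure(list(mean = mean, sd = sd), class = "gaussian_rule")
}

.default_rule_params <- function(rule) {
  switch(rule,
         adder = gaussian_rule(6.75, 1),
         sizer = gaussian_rule(14.5, 1.2),
         timer = gaussian_rule(100, 5),
         pdiv  = hill_curve(0.1, 14, 14),
         cdc13 = cdc13_params())
}

# Published per-rule initial-population Gaussians (mean, sd) and cell counts.
.default_init <- function(rule) {
  switch(rule,
         adder = c(6.75, 0.675),
         sizer = c(7.25, 0.725),
         timer = c(7, 0.7),
         pdiv  = c(14, 1.4),
         cdc13 = c(7, 0.7))
}

#' Configuration of an agent-based division simulation
#'
#' Assembles the full parameter set of a discrete-time (1-minute step)
#' population simulation under one of five division-control rules. Defaults
#' for each rule are the published parameter blocks: exponential growth at
#' 0.006 per minute (size doubling in ~116 min), 20 initial cells (10 for the
#' cyclin rule), 1000 minutes of simulated time, daughters sized
#' \code{1.05 * division_size / 2} with +/- N(0, 1) asymmetry.
#'
#' @param rule one of \code{"adder"}, \code{"sizer"}, \code{"timer"},
#'   \code{"pdiv"}, \code{"cdc13"}.
#' @param growth_rate fractional size increase per minute (exponential
#'   growth). Default 0.006 for all rules; the alternative printed value
#'   0.0029 for the pdiv rule may be supplied explicitly.
#' @param dt time step in minutes; the model is defined at \code{dt = 1}.
#' @param n_init number of initial cells (default 20; 10 for \code{cdc13}).
#' @param t_max simulated minutes.
#' @param init_mean,init_sd Gaussian for initial sizes (truncated > 0);
#'   per-rule published defaults.
#' @param daughter_factor daughters receive
#'   \code{daughter_factor * division_size / 2} on average (default 1.05,
#'   i.e. septation adds ~5\% combined length).
#' @param asymmetry_sd SD of the Gaussian noise added to one daughter and
#'   subtracted from the other (default 1).
#' @param septation_duration minutes spent in the non-growing septated state
#'   between the division trigger and the actual split (default 0 =
#'   instantaneous division; ~30 min is the physiological value).
#' @param min_cycle_duration minimal cycle timer in minutes: no rule may
#'   trigger division before this age (default 0).
#' @param rule_params a [hill_curve()] (pdiv), [cdc13_params()] (cdc13) or
#'   [gaussian_rule()] (adder/sizer/timer); per-rule published defaults.
#' @param seed integer seed; all randomness in [run_simulation()] flows from
#'   it. \code{NULL} leaves the RNG state untouched.
#'
#' @return An object of class \code{"sim_config"}.
#' @examples
#' cfg <- sim_config("pdiv", seed = 1)
#' cfg$rule_params
#' @export
sim_config <- function(rule = c("pdiv", "adder", "sizer", "timer", "cdc13"),
                       growth_rate = 0.006,
                       dt = 1,
                       n_init = NULL,
                       t_max = 1000,
                       init_mean = NULL,
                       init_sd = NULL,
                       daughter_factor = 1.05,
                       asymmetry_sd = 1,
                       septation_duration = 0,
                       min_cycle_duration = 0,
                       rule_params = NULL,
                       seed = NULL) {
  rule <- match.arg(rule)
  if (!is.finite(growth_rate) || growth_rate < 0)
    stop("'growth_rate' must be >= 0")
  if (!identical(as.numeric(dt), 1)) stop("'dt' is fixed at 1 minute")
  if (is.null(n_init)) n_init <- if (rule == "cdc13") 10L else 20L
  n_init <- as.integer(n_init)
  if (is.na(n_init) || n_init < 1L) stop("'n_init' must be >= 1")
  if (!is.finite(t_max) || t_max <= 0) stop("'t_max' must be > 0")
  ini <- .default_init(rule)
  if (is.null(init_mean)) init_mean <- ini[1]
  if (is.null(init_sd)) init_sd <- ini[2]
  if (!is.finite(init_mean) || init_mean <= 0) stop("'init_mean' must be > 0")
  if (!is.finite(init_sd) || init_sd < 0) stop("'init_sd' must be >= 0")
  if (!is.finite(daughter_factor) || daughter_factor <= 0)
    stop("'daughter_factor' must be > 0")
  if (!is.finite(asymmetry_sd) || asymmetry_sd < 0)
    stop("'asymmetry_sd' must be >= 0")
  if (!is.finite(septation_duration) || septation_duration < 0)
    stop("'septation_duration' must be >= 0")
  if (!is.finite(min_cycle_duration) || min_cycle_duration < 0)
    stop("'min_cycle_duration' must be >= 0")
  if (is.null(rule_params)) rule_params <- .default_rule_params(rule)
  ok <- switch(rule,
               pdiv  = inherits(rule_params, "hill_curve"),
               cdc13 = inherits(rule_params, "cdc13_params"),
               inherits(rule_params, "gaussian_rule"))
  if (!ok)
    stop(sprintf("'rule_params' of class %s does not match rule '%s'",
                 paste(class(rule_params), collapse = "/"), rule))
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("'seed' must be an integer")
  }
  structure(list(rule = rule, growth_rate = growth_rate, dt = 1,
                 n_init = n_init, t_max = as.numeric(t_max),
                 init_mean = init_mean, init_sd = init_sd,
                 daughter_factor = daughter_factor,
                 asymmetry_sd = asymmetry_sd,
                 septation_duration = septation_duration,
                 min_cycle_duration = min_cycle_duration,
                 rule_params = rule_params, seed = seed),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("Simulation config: rule '%s'\n", x$rule))
  cat(sprintf("  growth %g/min, %d initial cells ~ N(%g, %g), t_max %g min\n",
              x$growth_rate, x$n_init, x$init_mean, x$init_sd, x$t_max))
  cat(sprintf("  daughters %g*D/2 +/- N(0, %g); septation %g min; min cycle %g min\n",
              x$daughter_factor, x$asymmetry_sd, x$septation_duration,
              x$min_cycle_duration))
  rp <- x$rule_params
  cat("  rule params: ",
      if (inherits(rp, "hill_curve")) format(rp)
      else if (inherits(rp, "gaussian_rule"))
        sprintf("N(%g, %g)", rp$mean, rp$sd)
      else sprintf("cdc13(%s synthesis, %s threshold %g +/- %g)",
                   rp$synthesis_mode, rp$threshold_mode,
                   rp$threshold_mean, rp$threshold_sd),
      "\n", sep = "")
  if (!is.null(x$seed)) cat(sprintf("  seed %d\n", x$seed))
  invisible(x)
}
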