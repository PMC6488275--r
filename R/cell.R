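#' A single cell's state
#'
#' The elementary unit of the agent-based simulator. Exported mainly so the
#' per-cell update rules ([grow_step()], [cdc13_update()],
#' [division_decision()], [divide_cell()]) can be used and tested directly;
#' [run_simulation()] applies the identical rules vectorized over the
#' population.
#'
#' @param size current length (arbitrary length units, > 0).
#' @param birth_size length at birth (> 0); defaults to \code{size}.
#' @param birth_time minutes.
#' @param age minutes since birth (>= 0).
#' @param cyclin cyclin (Cdc13) amount in AU; used only by the cdc13 rule.
#' @param phase \code{"growing"} or \code{"septated"}. Septated cells no
#'   longer elongate: fission yeast stops growing during mitosis and
#'   septates at the length at which it will divide.
#' @param septation_entry_time minutes, required when \code{phase} is
#'   \code{"septated"}.
#' @param rule_threshold the rule-specific private threshold drawn at birth
#'   (size to add, target size, target age, or cyclin threshold); \code{NA}
#'   for the pdiv rule, which has no per-cell threshold.
#' @param record_birth logical; \code{FALSE} for initial-population founders,
#'   whose first division has no observed birth and therefore produces no
#'   division record.
#' @return An object of class \code{"cell_state"}.
#' @export
cell_state <- function(size, birth_size = size, birth_time = 0, age = 0,
                       cyclin = 0, phase = c("growing", "septated"),
                       septation_entry_time = NA_real_,
                       rule_threshold = NA_real_,
                       record_birth = TRUE) {
  phase <- match.arg(phase)
  if (!is.finite(size) || size <= 0) stop("'size' must be > 0")
  if (!is.finite(birth_size) || birth_size <= 0)
    stop("'birth_size' must be > 0")
  if (!is.finite(age) || age < 0) stop("'age' must be >= 0")
  if (phase == "septated" && !is.finite(septation_entry_time))
    stop("septated cells must carry 'septation_entry_time'")
  structure(list(size = size, birth_size = birth_size,
                 birth_time = birth_time, age = age, cyclin = cyclin,
                 phase = phase, septation_entry_time = septation_entry_time,
                 rule_threshold = rule_threshold,
                 record_birth = isTRUE(record_birth)),
            class = "cell_state")
}

#' @export
print.cell_state <- function(x, ...) {
  cat(sprintf("cell: size %.4g (born %.4g at t=%g), age %g min, %s",
              x$size, x$birth_size, x$birth_time, x$age, x$phase))
  if (x$cyclin > 0) cat(sprintf(", cyclin %.4g AU", x$cyclin))
  cat("\n")
  invisible(x)
}

#' Exponential growth over one time step
#'
#' Growing cells elongate multiplicatively: \code{size * (1 + growth_rate)^dt}
#' per step, so a rate of 0.006/min doubles size in ~116 min. Septated cells
#' do not elongate but still age.
#'
#' @param cell a [cell_state()].
#' @param growth_rate fractional increase per minute (>= 0).
#' @param dt minutes (default 1).
#' @return the updated \code{cell_state}.
#' @examples
#' grow_step(cell_state(10), 0.006)$size  # 10.06
#' @export
grow_step <- function(cell, growth_rate, dt = 1) {
  if (!is.finite(growth_rate) || growth_rate < 0)
    stop("'growth_rate' must be >= 0")
  if (cell$phase == "growing")
    cell$size <- cell$size * (1 + growth_rate)^dt
  cell$age <- cell$age + dt
  cell
}

#' One-minute cyclin accumulation update
#'
#' Adds noisy cyclin synthesis and subtracts degradation over one step:
#' \code{amount + s*dt + N(0, synthesis_noise_sd)*dt - degradation_rate*dt},
#' floored at 0, where \code{s} is \code{synthesis_rate} (absolute mode) or
#' \code{synthesis_rate * size} (size-proportional mode).
#'
#' @param cell a [cell_state()].
#' @param params a [cdc13_params()].
#' @param dt minutes; the model is defined at \code{dt = 1}.
#' @return the updated \code{cell_state}.
#' @export
cdc13_update <- function(cell, params, dt = 1) {
  if (!inherits(params, "cdc13_params")) stop("'params' must be cdc13_params")
  s <- if (params$synthesis_mode == "absolute") params$synthesis_rate
       else params$synthesis_rate * cell$size
  noise <- if (params$synthesis_noise_sd > 0)
    stats::rnorm(1, 0, params$synthesis_noise_sd) else 0
  cell$cyclin <- max(0, cell$cyclin + (s + noise - params$degradation_rate) * dt)
  cell
}

#' Division decision for one cell under a given rule
#'
#' Applies the rule's trigger: adder — added size reaches the per-cell
#' threshold; sizer — size reaches the threshold; timer — age reaches the
#' threshold; pdiv — a Uniform(0,1) draw falls below the Hill probability at
#' the current size; cdc13 — the cyclin statistic (amount, or concentration =
#' amount/size) reaches the threshold. Every rule returns \code{FALSE} while
#' \code{age < min_cycle_duration}.
#'
#' @param cell a [cell_state()] in the growing phase, with
#'   \code{rule_threshold} drawn at birth (except pdiv).
#' @param rule one of \code{"adder"}, \code{"sizer"}, \code{"timer"},
#'   \code{"pdiv"}, \code{"cdc13"}.
#' @param rule_params the matching parameter object (see [sim_config()]).
#' @param min_cycle_duration minutes; minimal timer element, default 0.
#' @return logical: divide now?
#' @export
division_decision <- function(cell, rule, rule_params,
                              min_cycle_duration = 0) {
  rule <- match.arg(rule, c("adder", "sizer", "timer", "pdiv", "cdc13"))
  if (cell$phase != "growing") stop("only growing cells decide to divide")
  if (cell$age < min_cycle_duration) return(FALSE)
  switch(rule,
         adder = (cell$size - cell$birth_size) >= cell$rule_threshold,
         sizer = cell$size >= cell$rule_threshold,
         timer = cell$age >= cell$rule_threshold,
         pdiv  = stats::runif(1) < hill_eval(rule_params, cell$size),
         cdc13 = {
           stat <- if (rule_params$threshold_mode == "concentration")
             cell$cyclin / cell$size else cell$cyclin
           stat >= cell$rule_threshold
         })
}

# Draw per-cell rule thresholds at birth (truncated > 0 for the Gaussian
# rules; the pdiv rule carries no threshold).
.draw_thresholds <- function(n, rule, rule_params) {
  if (n == 0L) return(numeric(0))
  if (rule == "pdiv") return(rep(NA_real_, n))
  m <- if (rule == "cdc13") rule_params$threshold_mean else rule_params$mean
  s <- if (rule == "cdc13") rule_params$threshold_sd else rule_params$sd
  thr <- stats::rnorm(n, m, s)
  while (any(bad <- thr <= 0)) thr[bad] <- stats::rnorm(sum(bad), m, s)
  thr
}

# Symmetric daughter-size draw: base +/- eps with eps ~ N(0, sd), redrawn
# while either daughter would be <= 0 (unbiased; eps is symmetric).
.draw_daughters <- function(base, asymmetry_sd) {
  n <- length(base)
  eps <- if (asymmetry_sd > 0) stats::rnorm(n, 0, asymmetry_sd) else numeric(n)
  while (any(bad <- (base - abs(eps)) <= 0))
    eps[bad] <- stats::rnorm(sum(bad), 0, asymmetry_sd)
  list(d1 = base + eps, d2 = base - eps)
}

#' Divide one cell into two daughters
#'
#' Daughters receive \code{daughter_factor * division_size / 2 +/- eps} with
#' \code{eps ~ N(0, asymmetry_sd)} (redrawn if either daughter would be
#' non-positive), so the two daughters always sum to exactly
#' \code{daughter_factor * division_size}. Both daughters draw fresh rule
#' thresholds; under the cdc13 rule they start with cyclin
#' \code{birth_level_factor * birth_size}. A completed-cycle record is
#' emitted unless the mother was an unrecorded founder.
#'
#' @param cell the dividing [cell_state()].
#' @param config a [sim_config()].
#' @param time current simulation time in minutes (the division time).
#' @return a list with \code{daughters} (list of two \code{cell_state}) and
#'   \code{record} (one-row data.frame, or \code{NULL} for founders).
#' @export
divide_cell <- function(cell, config, time) {
  stopifnot(inherits(config, "sim_config"))
  dd <- .draw_daughters(config$daughter_factor * cell$size / 2,
                        config$asymmetry_sd)
  thr <- .draw_thresholds(2L, config$rule, config$rule_params)
  blf <- if (config$rule == "cdc13") config$rule_params$birth_level_factor else 0
  mk <- function(sz, th) cell_state(size = sz, birth_size = sz,
                                    birth_time = time, age = 0,
                                    cyclin = blf * sz, phase = "growing",
                                    rule_threshold = th, record_birth = TRUE)
  rec <- NULL
  if (cell$record_birth)
    rec <- data.frame(birth_time = cell$birth_time, division_time = time,
                      birth_size = cell$birth_size, division_size = cell$size,
                      extension = cell$size - cell$birth_size,
                      duration = time - cell$birth_time)
  list(daughters = list(mk(dd$d1, thr[1]), mk(dd$d2, thr[2])), record = rec)
}

#' Draw an initial population
#'
#' @param config a [sim_config()]; sizes are drawn from
#'   N(\code{init_mean}, \code{init_sd}) truncated > 0, at time 0 and age 0.
#'   Founders are flagged so that their first (birth-less) division produces
#'   no record.
#' @return list of [cell_state()] objects of length \code{n_init}.
#' @export
init_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_init
  sz <- stats::rnorm(n, config$init_mean, config$init_sd)
  while (any(bad <- sz <= 0))
    sz[bad] <- stats::rnorm(sum(bad), config$init_mean, config$init_sd)
  thr <- .draw_thresholds(n, config$rule, config$rule_params)
  blf <- if (config$rule == "cdc13") config$rule_params$birth_level_factor else 0
  lapply(seq_len(n), function(i)
    cell_state(size = sz[i], birth_size = sz[i], birth_time = 0, age = 0,
               cyclin = blf * sz[i], phase = "growing",
               rule_threshold = thr[i], record_birth = FALSE))
}
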