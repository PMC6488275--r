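#' Hill dose-response curve from cell size to division probability
#'
#' Constructs the three-parameter Hill function that maps cell size onto a
#' per-time-step probability of division,
#' \deqn{p(s) = p_{max} \frac{s^n}{EC_{50}^n + s^n}.}
#' This is the central object of the probabilistic ("P(Div)") model of
#' cell-size control: larger cells are more likely to commit to division,
#' with \code{ec50} setting the size scale and \code{n} the ultrasensitivity
#' of the response.
#'
#' @param pmax maximum per-step division probability, in \code{[0, 1]}.
#'   \code{pmax = 0} is permitted as the degenerate never-divide curve.
#' @param ec50 size at which the probability reaches \code{pmax/2}; must be
#'   positive. Units follow the size measurements (arbitrary length units in
#'   simulations).
#' @param n Hill coefficient (dimensionless, > 0). Larger values give a more
#'   switch-like size dependence.
#'
#' @return An object of class \code{"hill_curve"}: a list with elements
#'   \code{pmax}, \code{ec50}, \code{n}.
#'
#' @examples
#' hc <- hill_curve(0.1, 14, 14)
#' hill_eval(hc, 14)   # half-maximum at the EC50: 0.05
#' @seealso [hill_eval()], [fit_hill()]
#' @export
hill_curve <- function(pmax, ec50, n) {
  stopifnot(length(pmax) == 1L, length(ec50) == 1L, length(n) == 1L)
  if (!is.finite(pmax) || pmax < 0 || pmax > 1)
    stop("'pmax' must be a probability in [0, 1]")
  if (!is.finite(ec50) || ec50 <= 0)
    stop("'ec50' must be > 0")
  if (!is.finite(n) || n <= 0)
    stop("'n' (Hill coefficient) must be > 0")
  structure(list(pmax = as.numeric(pmax), ec50 = as.numeric(ec50),
                 n = as.numeric(n)),
            class = "hill_curve")
}

#' Evaluate a Hill curve
#'
#' @param curve a [hill_curve()] object.
#' @param size numeric vector of sizes, all >= 0.
#' @return numeric vector of probabilities in \code{[0, pmax]}.
#'
#' @details Evaluation uses the numerically stable form
#'   \code{pmax / (1 + (ec50/s)^n)}, which avoids overflow of \code{s^n}
#'   for large sizes and Hill coefficients; \code{hill_eval(curve, 0)} is 0.
#' @examples
#' hill_eval(hill_curve(0.1, 14, 14), c(0, 14, 16))
#' @export
hill_eval <- function(curve, size) {
  if (!inherits(curve, "hill_curve")) stop("'curve' must be a hill_curve")
  size <- as.numeric(size)
  if (any(!is.finite(size)) || any(size < 0))
    stop("'size' must be finite and >= 0")
  p <- numeric(length(size))
  pos <- size > 0
  p[pos] <- curve$pmax / (1 + (curve$ec50 / size[pos])^curve$n)
  p
}

#' @export
print.hill_curve <- function(x, ...) {
  cat(sprintf("Hill curve: pmax = %g, EC50 = %g, n = %g\n",
              x$pmax, x$ec50, x$n))
  invisible(x)
}

#' @export
format.hill_curve <- function(x, ...) {
  sprintf("Hill(pmax=%g, ec50=%g, n=%g)", x$pmax, x$ec50, x$n)
}
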