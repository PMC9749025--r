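# The Ratchet&Pawl potential (RPP): a history-dependent one-sided bias on a
# scalar ratcheting coordinate s.  With rho(t) = (s - target)^2, the bias is
# zero while rho improves on its running best (the pawl) and half-harmonic in
# rho on retreat:
#
#   V = k/2 (rho - rho_best)^2   if rho > rho_best, else 0
#
# so k carries units of kcal/mol/A^4.  The pawl (rho_best) is updated after
# the force evaluation of each step.

#' Ratchet&Pawl parameters
#'
#' @param k force constant, kcal/mol/A^4 (default 0.024).
#' @param direction unit vector of the ratcheting direction (the membrane
#'   normal analog); normalized internally, must be nonzero.
#' @param origin binding-site reference coordinates.
#' @param target value of the ratcheting coordinate treated as fully
#'   unbound, Angstrom.
#' @param mode "projection" (s = (x - origin) . direction) or "radial"
#'   (s = |x - origin|, for landscapes whose egress channels fan out from
#'   one site).
#' @return a `ratchet_params`.
#' @export
ratchet_params <- function(k = 0.024, direction = c(1, 0), origin = NULL,
                           target = 10, mode = c("projection", "radial")) {
  mode <- match.arg(mode)
  stopifnot(k >= 0)
  nrm <- sqrt(sum(direction^2))
  if (nrm < 1e-12) stop("direction must be a nonzero vector")
  direction <- direction / nrm
  if (is.null(origin)) origin <- numeric(length(direction))
  stopifnot(length(origin) == length(direction))
  structure(list(k = k, direction = direction, origin = origin,
                 target = target, mode = mode),
            class = "ratchet_params")
}

#' The ratcheting coordinate
#'
#' Projection of the displacement from the binding-site origin onto the
#' ratchet direction ("projection" mode) or its Euclidean norm ("radial").
#'
#' @param x coordinates.
#' @param params a [ratchet_params()].
#' @return s in Angstrom.
#' @export
ratchet_coordinate <- function(x, params) {
  stopifnot(inherits(params, "ratchet_params"),
            length(x) == length(params$origin))
  d <- x - params$origin
  if (params$mode == "radial") sqrt(sum(d^2)) else sum(d * params$direction)
}

#' Initialize the ratchet state
#'
#' @param s0 initial value of the ratcheting coordinate.
#' @param params a [ratchet_params()].
#' @return a `ratchet_state` with `rho_best = (s0 - target)^2`.
#' @export
ratchet_state <- function(s0, params) {
  structure(list(rho_best = (s0 - params$target)^2, s_current = s0,
                 bias_energy = 0),
            class = "ratchet_state")
}

#' RPP bias energy and force at a coordinate value
#'
#' Evaluates rho = (s - target)^2 against the pawl: V = k/2 (rho -
#' rho_best)^2 when rho > rho_best, else 0, with force -dV/ds by the chain
#' rule.  The returned state has `rho_best` updated to min(rho_best, rho)
#' (pawl moves at step end).
#'
#' @param s ratcheting coordinate, Angstrom.
#' @param state a [ratchet_state()].
#' @param params a [ratchet_params()].
#' @return list with `energy` (kcal/mol), `force` (on s, kcal/mol/A), and
#'   the updated `state`.
#' @export
rpp_energy_force <- function(s, state, params) {
  stopifnot(inherits(state, "ratchet_state"),
            inherits(params, "ratchet_params"))
  rho <- (s - params$target)^2
  if (rho > state$rho_best) {
    dr <- rho - state$rho_best
    energy <- 0.5 * params$k * dr^2
    force <- -params$k * dr * 2 * (s - params$target)
  } else {
    energy <- 0
    force <- 0
  }
  state$rho_best <- min(state$rho_best, rho)
  state$s_current <- s
  state$bias_energy <- energy
  list(energy = energy, force = force, state = state)
}
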