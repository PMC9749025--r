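# Seeded overdamped Langevin (Euler-Maruyama) dynamics with uniform
# potential scaling and pluggable Ratchet&Pawl / metadynamics biases.  The
# inner loop lives in compiled code; seeds go through R's RNG so identical
# seeds give bit-identical trajectories.

#' Simulation configuration
#'
#' @param dt integration step, ps.
#' @param temperature Kelvin (default 300).
#' @param friction friction coefficient, 1/ps.
#' @param scale uniform potential scaling factor beta in (0, 1]; forces are
#'   `-scale * grad U` (scaled MD).  Default 1 (unscaled).
#' @param n_steps number of integration steps.
#' @param save_stride save every `save_stride` steps (frame 0 always saved).
#' @param seed integer RNG seed.
#' @return a `sim_config`.
#' @export
sim_config <- function(dt = 0.01, temperature = 300, friction = 1,
                       scale = 1, n_steps = 10000, save_stride = 10,
                       seed = 1) {
  stopifnot(dt > 0, friction > 0, scale > 0, scale <= 1,
            n_steps >= 1, save_stride >= 1)
  structure(list(dt = dt, temperature = temperature, friction = friction,
                 scale = scale, n_steps = as.integer(n_steps),
                 save_stride = as.integer(save_stride),
                 seed = as.integer(seed)),
            class = "sim_config")
}

new_trajectory <- function(frames, times, metadata = list()) {
  frames <- as.matrix(frames)
  structure(list(frames = frames, times = times, metadata = metadata),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory>", nrow(x$frames), "frames, dim", ncol(x$frames),
      sprintf("t = [%g, %g] ps\n", min(x$times), max(x$times)))
  invisible(x)
}

# shared driver around the compiled engine
run_engine <- function(potential, config, x0,
                       rpp = NULL, stop_rule = NULL, metad = NULL) {
  stopifnot(inherits(potential, "model_potential"),
            inherits(config, "sim_config"),
            length(x0) == potential$dim)
  set.seed(config$seed)
  use_rpp <- !is.null(rpp)
  use_metad <- !is.null(metad)
  stop_kind <- 0L
  stop_normal <- numeric(potential$dim)
  stop_offset <- 0
  stop_grace <- 1L
  if (!is.null(stop_rule)) {
    stop_kind <- switch(stop_rule$kind, halfspace = 1L, radius = 2L,
                        stop("unknown stop rule: ", stop_rule$kind))
    if (stop_kind == 1L) stop_normal <- stop_rule$normal
    stop_offset <- stop_rule$offset
    if (!is.null(stop_rule$grace)) stop_grace <- as.integer(stop_rule$grace)
  }
  res <- engine_run(
    potential$cpp_kind, potential$cpp_params, as.numeric(x0),
    potential$domain,
    config$dt, config$temperature, config$friction, config$scale,
    config$n_steps, config$save_stride,
    use_rpp,
    if (use_rpp) rpp$k else 0,
    if (use_rpp) rpp$direction else numeric(potential$dim),
    if (use_rpp) rpp$origin else numeric(potential$dim),
    if (use_rpp) rpp$target else 0,
    if (use_rpp) identical(rpp$mode, "radial") else FALSE,
    stop_kind, stop_normal, stop_offset, stop_grace,
    use_metad,
    if (use_metad) metad$cv_kind else 0L,
    if (use_metad) metad$cv_index else 1L,
    if (use_metad) metad$ref else matrix(0, 1, potential$dim),
    if (use_metad) metad$lambda else 1,
    if (use_metad) metad$params$omega0 else 0,
    if (use_metad) metad$params$sigma_s else 1,
    if (use_metad) metad$params$sigma_z else 1,
    if (use_metad) metad$params$bias_factor else 2,
    if (use_metad) metad$hill_stride else 1L,
    if (use_metad) metad$grid_lo else numeric(2),
    if (use_metad) metad$grid_hi else numeric(2))
  res
}

#' Integrate overdamped Langevin dynamics on a model potential
#'
#' Euler-Maruyama integration of dx = -(scale/friction) grad U dt +
#' sqrt(2 kB T dt / friction) dW with reflective domain boundaries.
#'
#' @param potential a `model_potential`.
#' @param config a [sim_config()].
#' @param x0 initial coordinates (default: domain centre).
#' @return a `trajectory`; `metadata$config` echoes the configuration.
#' @export
integrate_dynamics <- function(potential, config, x0 = NULL) {
  if (is.null(x0)) x0 <- colMeans(potential$domain)
  res <- run_engine(potential, config, x0)
  new_trajectory(res$frames, res$times,
                 list(config = config, potential = potential$kind))
}

#' Ratchet-and-pawl biased scaled dynamics with a stop rule
#'
#' Runs [integrate_dynamics()] with the Ratchet&Pawl bias on the ratcheting
#' coordinate, halting at the first frame satisfying the unbound-region stop
#' predicate (confirmed over a one-step grace window against boundary
#' jitter).
#'
#' @param potential a `model_potential` (typically an egress landscape).
#' @param config a [sim_config()]; use `scale < 1` for sMD-RPP.
#' @param ratchet a [ratchet_params()].
#' @param stop_rule list: `kind` "halfspace" (fields `normal`, `offset`:
#'   unbound when `x . normal > offset`) or "radius" (unbound when the
#'   distance from the ratchet origin exceeds `offset`); optional `grace`.
#' @param x0 initial coordinates (default: ratchet origin).
#' @return a `trajectory` with `metadata$exited` (logical),
#'   `metadata$exit_step`, `metadata$rpp` (per-frame bias log: s, rho,
#'   rho_best, V) and `metadata$rpp_work`.
#' @export
run_smd_rpp <- function(potential, config, ratchet, stop_rule, x0 = NULL) {
  stopifnot(inherits(ratchet, "ratchet_params"))
  if (is.null(x0)) x0 <- ratchet$origin
  res <- run_engine(potential, config, x0, rpp = ratchet,
                    stop_rule = stop_rule)
  rpp_log <- res$colvar[, 4:7, drop = FALSE]
  colnames(rpp_log) <- c("s", "rho", "rho_best", "V")
  new_trajectory(res$frames, res$times,
                 list(config = config, potential = potential$kind,
                      exited = res$exited, exit_step = res$exit_step,
                      rpp = rpp_log, rpp_work = res$rpp_work,
                      ratchet = ratchet))
}

#' Run a campaign of seeded sMD-RPP replicas
#'
#' Replica `i` uses seed `config$seed + i - 1` (one generator per replica);
#' seeds are recorded in each trajectory's metadata.
#'
#' @inheritParams run_smd_rpp
#' @param n_replicas number of replicas.
#' @return list of trajectories.
#' @export
run_rpp_campaign <- function(potential, config, ratchet, stop_rule,
                             n_replicas, x0 = NULL) {
  lapply(seq_len(n_replicas), function(i) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i - 1L
    tr <- run_smd_rpp(potential, cfg_i, ratchet, stop_rule, x0 = x0)
    tr$metadata$replica <- i
    tr$metadata$seed <- cfg_i$seed
    tr
  })
}
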