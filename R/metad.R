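# Well-tempered metadynamics: hill deposition with tempered heights, a
# HILLS ledger, analytic bias evaluation, and free-energy reconstruction
# F = -gamma/(gamma-1) V shifted to min 0.  During simulation the bias
# force is interpolated from a deposit grid (6 sigma cutoff) while recorded
# heights use the exact ledger sum, so they obey the well-tempered
# recursion exactly.

#' Well-tempered metadynamics parameters
#'
#' Defaults follow common practice for path-CV unbinding runs: initial hill
#' height 0.2 kcal/mol, bias factor 15, widths 0.1 (progress units) and
#' 1 A^2 (= 0.01 nm^2, deviation units), one hill every 2 ps.
#'
#' @param omega0 initial Gaussian height, kcal/mol.
#' @param sigma_s hill width on the first CV.
#' @param sigma_z hill width on the second CV (A^2 for path deviation).
#' @param bias_factor well-tempered gamma (> 1).
#' @param stride_ps hill deposition interval, ps.
#' @param temperature Kelvin.
#' @return a `metad_params`.
#' @export
metad_params <- function(omega0 = 0.2, sigma_s = 0.1, sigma_z = 1,
                         bias_factor = 15, stride_ps = 2,
                         temperature = 300) {
  stopifnot(omega0 > 0, sigma_s > 0, sigma_z > 0, bias_factor > 1,
            stride_ps > 0)
  structure(list(omega0 = omega0, sigma_s = sigma_s, sigma_z = sigma_z,
                 bias_factor = bias_factor, stride_ps = stride_ps,
                 temperature = temperature),
            class = "metad_params")
}

new_hills_ledger <- function(hills, params, ncv) {
  df <- data.frame(time = hills[, 1], s = hills[, 2])
  if (ncv == 2) df$z <- hills[, 3]
  df$height <- hills[, 4]
  structure(list(hills = df, params = params, ncv = ncv),
            class = "hills_ledger")
}

#' @export
print.hills_ledger <- function(x, ...) {
  cat("<hills_ledger>", nrow(x$hills), "hills,", x$ncv, "CV(s)\n")
  invisible(x)
}

#' Run well-tempered metadynamics on a model potential
#'
#' Deposits a hill every `stride_ps` at the current CV value with height
#' omega0 exp(-V(cv)/(kB dT)), dT = (gamma - 1) T, and applies the bias
#' force through the CV gradients.  Deterministic under a fixed seed.
#'
#' @param potential a `model_potential`.
#' @param config a [sim_config()] (its temperature is used for the
#'   dynamics; `params$temperature` should match).
#' @param params a [metad_params()].
#' @param cv either an integer coordinate index (one CV) or a
#'   [pathcv_params()] (two CVs: S and Z).
#' @param x0 initial coordinates.
#' @param grid_lo,grid_hi CV-space bounds of the internal bias grid;
#'   defaults cover the domain box (coordinate CV) or [0.5, N+0.5] x
#'   [-log(N)/lambda - 1, z_max] (path CVs).
#' @param z_max upper Z bound of the default path-CV grid.
#' @return list with `trajectory`, `ledger` (a `hills_ledger`) and
#'   `colvar` (per saved frame: time, cv values, bias).
#' @export
run_metad <- function(potential, config, params, cv = 1L, x0 = NULL,
                      grid_lo = NULL, grid_hi = NULL, z_max = 30) {
  stopifnot(inherits(params, "metad_params"))
  hill_stride <- max(1L, as.integer(round(params$stride_ps / config$dt)))
  if (inherits(cv, "pathcv_params")) {
    spec <- list(cv_kind = 2L, cv_index = 1L, ref = cv$frames,
                 lambda = cv$lam, params = params,
                 hill_stride = hill_stride)
    if (is.null(grid_lo)) grid_lo <- c(0.5, -log(cv$n) / cv$lam - 1)
    if (is.null(grid_hi)) grid_hi <- c(cv$n + 0.5, z_max)
    ncv <- 2L
  } else {
    spec <- list(cv_kind = 1L, cv_index = as.integer(cv),
                 ref = matrix(0, 1, potential$dim), lambda = 1,
                 params = params, hill_stride = hill_stride)
    if (is.null(grid_lo)) grid_lo <- c(potential$domain[1, cv], 0)
    if (is.null(grid_hi)) grid_hi <- c(potential$domain[2, cv], 0)
    ncv <- 1L
  }
  spec$grid_lo <- grid_lo
  spec$grid_hi <- grid_hi
  if (is.null(x0)) x0 <- colMeans(potential$domain)
  res <- run_engine(potential, config, x0, metad = spec)
  traj <- new_trajectory(res$frames, res$times,
                         list(config = config, potential = potential$kind))
  colvar <- data.frame(time = res$times, s = res$colvar[, 1])
  if (ncv == 2) colvar$z <- res$colvar[, 2]
  colvar$bias <- res$colvar[, 3]
  list(trajectory = traj,
       ledger = new_hills_ledger(res$hills, params, ncv),
       colvar = colvar)
}

#' Metadynamics bias at CV points
#'
#' Exact sum of the deposited anisotropic Gaussians,
#' V = sum_k h_k exp(-(s-s_k)^2/2 sigma_s^2 - (z-z_k)^2/2 sigma_z^2).
#'
#' @param point numeric vector (length 1 or 2 matching the ledger), or a
#'   matrix of points in rows.
#' @param ledger a `hills_ledger`.
#' @return bias in kcal/mol (vector for matrix input).
#' @export
bias_at <- function(point, ledger) {
  stopifnot(inherits(ledger, "hills_ledger"))
  h <- ledger$hills
  if (nrow(h) == 0) {
    if (is.matrix(point)) return(numeric(nrow(point))) else return(0)
  }
  p <- ledger$params
  pts <- if (is.matrix(point)) point else matrix(point, nrow = 1)
  v <- vapply(seq_len(nrow(pts)), function(i) {
    e <- -0.5 * ((pts[i, 1] - h$s) / p$sigma_s)^2
    if (ledger$ncv == 2) {
      e <- e - 0.5 * ((pts[i, 2] - h$z) / p$sigma_z)^2
    }
    sum(h$height * exp(e))
  }, numeric(1))
  if (is.matrix(point)) v else v[1]
}

#' Reconstruct the free-energy surface from a hills ledger
#'
#' Well-tempered estimator from the final bias:
#' F = -gamma/(gamma - 1) V_bias, shifted so min F = 0.
#'
#' @param ledger a `hills_ledger`.
#' @param s_grid grid on the first CV (vector); default 201 points spanning
#'   the deposited hill centres plus 3 sigma.
#' @param z_grid grid on the second CV (2-CV ledgers only).
#' @return a `fes_grid`: list with `s`, optional `z`, matrix/vector `F`
#'   (kcal/mol, min 0) and the ledger parameters.
#' @export
reconstruct_fes <- function(ledger, s_grid = NULL, z_grid = NULL) {
  stopifnot(inherits(ledger, "hills_ledger"), nrow(ledger$hills) > 0)
  p <- ledger$params
  fac <- p$bias_factor / (p$bias_factor - 1)
  h <- ledger$hills
  if (is.null(s_grid)) {
    s_grid <- seq(min(h$s) - 3 * p$sigma_s, max(h$s) + 3 * p$sigma_s,
                  length.out = 201)
  }
  if (ledger$ncv == 1) {
    V <- vapply(s_grid, function(s) sum(h$height *
      exp(-0.5 * ((s - h$s) / p$sigma_s)^2)), numeric(1))
    F <- -fac * V
    F <- F - min(F)
    out <- list(s = s_grid, F = F, params = p, ncv = 1L)
  } else {
    if (is.null(z_grid)) {
      z_grid <- seq(min(h$z) - 3 * p$sigma_z, max(h$z) + 3 * p$sigma_z,
                    length.out = 101)
    }
    gs <- exp(-0.5 * (outer(s_grid, h$s, "-") / p$sigma_s)^2)
    gz <- exp(-0.5 * (outer(z_grid, h$z, "-") / p$sigma_z)^2)
    # V[i, j] = sum_k h_k gs[i, k] gz[j, k]
    V <- gs %*% (h$height * t(gz))
    F <- -fac * V
    F <- F - min(F)
    out <- list(s = s_grid, z = z_grid, F = F, params = p, ncv = 2L)
  }
  structure(out, class = "fes_grid")
}

#' One-dimensional free-energy profile from a FES grid
#'
#' For 1-CV grids, returns the profile as a data.frame; for 2-CV grids,
#' Boltzmann-integrates over the second CV.
#'
#' @param fes a `fes_grid`.
#' @param temperature Kelvin.
#' @return data.frame with columns `s`, `F` (min 0).
#' @export
fes_profile_1d <- function(fes, temperature = 300) {
  stopifnot(inherits(fes, "fes_grid"))
  if (fes$ncv == 1) {
    return(data.frame(s = fes$s, F = fes$F - min(fes$F)))
  }
  kT <- kB * temperature
  F <- -kT * log(rowSums(exp(-fes$F / kT)))
  data.frame(s = fes$s, F = F - min(F))
}

#' Convergence profile of an observable over the ledger history
#'
#' Recomputes `observable` from the ledger truncated at each checkpoint
#' time; convergence is declared when successive changes drop below `tol`.
#'
#' @param ledger a `hills_ledger`.
#' @param checkpoints increasing times, ps (>= 2 values).
#' @param observable function(hills_ledger) -> numeric scalar.
#' @param tol convergence tolerance on successive changes.
#' @return data.frame with `time`, `value`, `delta`, and attribute
#'   `converged`.
#' @export
convergence_profile <- function(ledger, checkpoints, observable,
                                tol = 0.1) {
  stopifnot(inherits(ledger, "hills_ledger"), length(checkpoints) >= 1)
  vals <- vapply(checkpoints, function(tc) {
    sub <- ledger
    sub$hills <- ledger$hills[ledger$hills$time <= tc, , drop = FALSE]
    observable(sub)
  }, numeric(1))
  delta <- c(NA, abs(diff(vals)))
  out <- data.frame(time = checkpoints, value = vals, delta = delta)
  attr(out, "converged") <- length(vals) >= 2 &&
    delta[length(delta)] < tol
  out
}

#' Block-averaged uncertainty of a ledger observable
#'
#' Splits the deposition history into `n_blocks` contiguous blocks, applies
#' `observable` to each cumulative quarter-by-quarter reconstruction, and
#' returns mean and standard error over the last `n_blocks` truncations.
#'
#' @param ledger a `hills_ledger`.
#' @param observable function(hills_ledger) -> numeric scalar.
#' @param n_blocks number of blocks (default 4).
#' @param burn_in fraction of deposition time discarded (default 0.5).
#' @return list with `mean`, `se`, `values`.
#' @export
ledger_block_error <- function(ledger, observable, n_blocks = 4,
                               burn_in = 0.5) {
  tmax <- max(ledger$hills$time)
  cps <- seq(burn_in * tmax, tmax, length.out = n_blocks + 1)[-1]
  vals <- convergence_profile(ledger, cps, observable, tol = Inf)$value
  list(mean = mean(vals), se = stats::sd(vals) / sqrt(length(vals)),
       values = vals)
}
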