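# Alchemical decoupling on toy pair systems: lambda schedules, soft-core
# pair potentials, Metropolis sampling per window, Bennett acceptance ratio
# estimation, and analytic restraint/standard-state corrections assembled
# through the double-decoupling thermodynamic cycle.
#
# Coupling convention: lam = 0 fully coupled, lam = 1 fully decoupled.

#' Alchemical lambda schedule
#'
#' Defaults: 20 vdW windows 0.05..1.0 in steps of 0.05 and 11 electrostatic
#' windows 0.0..1.0 in steps of 0.1; electrostatics are annihilated before
#' vdW decoupling completes.
#'
#' @param vdw strictly increasing values in [0, 1].
#' @param coul strictly increasing values in [0, 1].
#' @return a `lambda_schedule`.
#' @export
lambda_schedule <- function(vdw = seq(0.05, 1, by = 0.05),
                            coul = seq(0, 1, by = 0.1)) {
  stopifnot(all(diff(vdw) > 0), all(diff(coul) > 0),
            all(vdw >= 0), all(vdw <= 1), all(coul >= 0), all(coul <= 1))
  structure(list(vdw = vdw, coul = coul), class = "lambda_schedule")
}

#' Soft-core parameters
#'
#' @param alpha soft-core parameter (default 0.5).
#' @param power soft-core lambda power (default 1).
#' @param sigma soft-core radius of interaction, Angstrom (default 3).
#' @return a `softcore_params`.
#' @export
softcore_params <- function(alpha = 0.5, power = 1, sigma = 3) {
  stopifnot(alpha >= 0, sigma > 0)
  structure(list(alpha = alpha, power = power, sigma = sigma),
            class = "softcore_params")
}

softcore_r6 <- function(r, lam, sc) {
  sc$alpha * sc$sigma^6 * lam^sc$power + r^6
}

#' Soft-core Lennard-Jones pair energy
#'
#' Shifted-distance soft core: r_eff^6 = alpha sigma^6 lam^power + r^6 and
#' energy (1 - lam) * 4 eps [(sigma_lj/r_eff)^12 - (sigma_lj/r_eff)^6].
#' Exact LJ at lam = 0, exactly zero at lam = 1, finite at r = 0 for
#' lam > 0.
#'
#' @param r separation, Angstrom (vectorized).
#' @param lam coupling parameter in [0, 1].
#' @param sc a [softcore_params()].
#' @param eps LJ well depth, kcal/mol.
#' @param sigma_lj LJ radius, Angstrom.
#' @return energy, kcal/mol.
#' @export
softcore_pair_energy <- function(r, lam, sc, eps, sigma_lj) {
  if (lam >= 1) return(rep(0, length(r)))
  r6 <- softcore_r6(r, lam, sc)
  s6 <- sigma_lj^6 / r6
  (1 - lam) * 4 * eps * (s6^2 - s6)
}

#' Soft-core Coulomb pair energy
#'
#' Same shifted distance as the vdW soft core:
#' (1 - lam) * C q1 q2 / r_eff with r_eff = (alpha sigma^6 lam^power +
#' r^6)^(1/6).
#'
#' @inheritParams softcore_pair_energy
#' @param q1,q2 charges in elementary units.
#' @return energy, kcal/mol.
#' @export
softcore_coulomb_energy <- function(r, lam, sc, q1, q2) {
  if (lam >= 1) return(rep(0, length(r)))
  (1 - lam) * coulomb_const * q1 * q2 / softcore_r6(r, lam, sc)^(1 / 6)
}

# ---- restraints ------------------------------------------------------------

#' Boresch-style restraint set
#'
#' One distance plus optionally two angles and three dihedrals with
#' harmonic reference values.  Angle/dihedral force constants are given in
#' kcal/mol/deg^2 (converted internally), the distance constant in
#' kcal/mol/A^2.  A point-particle ligand admits only the distance
#' restraint; the full six-coordinate set is used by the analytic
#' correction.
#'
#' @param r0 reference distance, Angstrom.
#' @param k_r distance force constant, kcal/mol/A^2 (default 10).
#' @param theta0 reference angles (degrees, length 2) or `NULL`.
#' @param k_theta angle force constant, kcal/mol/deg^2 (default 10).
#' @param phi0 reference dihedrals (degrees, length 3) or `NULL`.
#' @param k_phi dihedral force constant, kcal/mol/deg^2 (default 10).
#' @return a `boresch_restraint`.
#' @export
boresch_restraint <- function(r0, k_r = 10, theta0 = NULL, k_theta = 10,
                              phi0 = NULL, k_phi = 10) {
  stopifnot(r0 > 0, k_r > 0)
  if (!is.null(theta0)) {
    stopifnot(length(theta0) == 2, k_theta > 0)
    if (any(theta0 < 10 | theta0 > 170)) {
      warning("angle reference within 10 degrees of 0/180: the Gaussian ",
              "(rigid-rotor) approximation of the correction may be poor")
    }
  }
  if (!is.null(phi0)) stopifnot(length(phi0) == 3, k_phi > 0)
  structure(list(r0 = r0, k_r = k_r, theta0 = theta0, k_theta = k_theta,
                 phi0 = phi0, k_phi = k_phi),
            class = "boresch_restraint")
}

#' Analytic restraint release free energy with standard-state correction
#'
#' Free energy of releasing the restraints on a decoupled ligand into the
#' reference volume (default the standard-state volume 1660 A^3 per
#' molecule).  For the full six-coordinate set the rigid-rotor Gaussian
#' formula is used:
#' deltaG = -kT log( 8 pi^2 V0 sqrt(prod k_i) /
#'                   (r0^2 sin(thetaA) sin(thetaB) (2 pi kT)^3) ).
#' For a distance-only restraint the radial partition function
#' Z = 4 pi int r^2 exp(-k_r (r - r0)^2 / 2 kT) dr is integrated
#' numerically (exact, no Gaussian approximation) and
#' deltaG = -kT log(V0 / Z).
#'
#' @param restraint a [boresch_restraint()].
#' @param temperature Kelvin.
#' @param v0 reference volume, A^3 (default 1660, i.e. 1 M standard state).
#' @return deltaG of releasing the restraint, kcal/mol (negative for stiff
#'   restraints).
#' @export
boresch_correction <- function(restraint, temperature = 300, v0 = 1660) {
  stopifnot(inherits(restraint, "boresch_restraint"))
  kT <- kB * temperature
  deg2 <- (180 / pi)^2 # kcal/mol/deg^2 -> kcal/mol/rad^2
  if (is.null(restraint$theta0)) {
    r <- seq(max(0, restraint$r0 - 20 * sqrt(kT / restraint$k_r)),
             restraint$r0 + 20 * sqrt(kT / restraint$k_r),
             length.out = 20001)
    z <- 4 * pi * trapz(r, r^2 *
      exp(-restraint$k_r * (r - restraint$r0)^2 / (2 * kT)))
    return(-kT * log(v0 / z))
  }
  stopifnot(!is.null(restraint$phi0))
  ks <- c(restraint$k_r,
          rep(restraint$k_theta * deg2, 2),
          rep(restraint$k_phi * deg2, 3))
  th <- restraint$theta0 * pi / 180
  -kT * log(8 * pi^2 * v0 * sqrt(prod(ks)) /
            (restraint$r0^2 * sin(th[1]) * sin(th[2]) * (2 * pi * kT)^3))
}

trapz <- function(x, y) {
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# ---- toy pair system -------------------------------------------------------

#' Toy receptor-ligand system for alchemical decoupling
#'
#' One "ligand" particle interacting with fixed "receptor" sites through
#' Lennard-Jones plus Coulomb terms inside a cubic box; the minimal system
#' where decoupling, restraints and the thermodynamic cycle are all
#' meaningful and quadrature-checkable.
#'
#' The default receptor is a tetrahedral cage of four sites at the LJ
#' minimum distance from the origin with a weak uniform negative charge, so
#' the pocket centre is the bound minimum and the restraint anchor sits in
#' the well it restrains.
#'
#' @param sites matrix of receptor site coordinates (rows), Angstrom.
#' @param eps LJ well depths per site, kcal/mol (recycled).
#' @param sigma_lj LJ radii per site, Angstrom (recycled).
#' @param charges site charges, e (recycled).
#' @param q_ligand ligand charge, e.
#' @param box cubic box edge, Angstrom.
#' @param sc a [softcore_params()].
#' @param restraint a [boresch_restraint()] anchored at `anchor`, or `NULL`.
#' @param anchor restraint anchor coordinates (default origin).
#' @return a `fep_system`.
#' @export
fep_system <- function(sites = 3.37 / sqrt(3) *
                         rbind(c(1, 1, 1), c(1, -1, -1),
                               c(-1, 1, -1), c(-1, -1, 1)),
                       eps = 0.3, sigma_lj = 3, charges = -0.05,
                       q_ligand = 0.5, box = 14,
                       sc = softcore_params(),
                       restraint = boresch_restraint(r0 = 0.5, k_r = 10),
                       anchor = c(0, 0, 0)) {
  sites <- as.matrix(sites)
  n <- nrow(sites)
  structure(list(sites = sites, eps = rep_len(eps, n),
                 sigma_lj = rep_len(sigma_lj, n),
                 charges = rep_len(charges, n), q_ligand = q_ligand,
                 box = box, sc = sc, restraint = restraint,
                 anchor = anchor),
            class = "fep_system")
}

#' Potential energy of the toy system at a coupling state
#'
#' @param system a [fep_system()].
#' @param x ligand coordinates (length 3).
#' @param lam_vdw,lam_coul coupling parameters (0 coupled, 1 decoupled).
#' @param restrained include the restraint term.
#' @return energy, kcal/mol.
#' @export
fep_energy <- function(system, x, lam_vdw = 0, lam_coul = 0,
                       restrained = TRUE) {
  d <- system$sites - matrix(x, nrow(system$sites), 3, byrow = TRUE)
  r <- sqrt(rowSums(d^2))
  u <- sum(softcore_pair_energy(r, lam_vdw, system$sc, system$eps,
                                system$sigma_lj)) +
       sum(softcore_coulomb_energy(r, lam_coul, system$sc,
                                   system$q_ligand, system$charges))
  if (restrained && !is.null(system$restraint)) {
    rr <- sqrt(sum((x - system$anchor)^2))
    u <- u + system$restraint$k_r / 2 * (rr - system$restraint$r0)^2
  }
  u
}

#' Metropolis Monte Carlo sampling of a scalar energy function
#'
#' Isotropic Gaussian proposals, rejected outside the cubic box; returns
#' thinned samples after equilibration.  Seeded and deterministic.
#'
#' @param energy function(x) -> kcal/mol.
#' @param x0 initial coordinates.
#' @param box cubic box edge (proposals outside [-box/2, box/2]^d are
#'   rejected); `Inf` disables the wall.
#' @param n_samples samples to return.
#' @param n_equil equilibration sweeps.
#' @param thin proposals between stored samples.
#' @param step proposal standard deviation, Angstrom.
#' @param temperature Kelvin.
#' @param seed integer seed.
#' @return matrix `n_samples` x d; attribute `acceptance`.
#' @export
mc_sample <- function(energy, x0, box = Inf, n_samples = 500,
                      n_equil = 500, thin = 5, step = 0.6,
                      temperature = 300, seed = 1) {
  set.seed(seed)
  kT <- kB * temperature
  d <- length(x0)
  x <- x0
  u <- energy(x)
  if (!is.finite(u)) stop("non-finite energy at the initial configuration")
  out <- matrix(NA_real_, n_samples, d)
  n_acc <- 0L
  n_tot <- n_equil + n_samples * thin
  stored <- 0L
  for (it in seq_len(n_tot)) {
    prop <- x + rnorm(d, sd = step)
    if (all(abs(prop) <= box / 2)) {
      up <- energy(prop)
      if (is.finite(up) && runif(1) < exp((u - up) / kT)) {
        x <- prop
        u <- up
        n_acc <- n_acc + 1L
      }
    }
    if (it > n_equil && (it - n_equil) %% thin == 0) {
      stored <- stored + 1L
      out[stored, ] <- x
    }
  }
  attr(out, "acceptance") <- n_acc / n_tot
  out
}

#' Sample one alchemical window and record neighbour energy differences
#'
#' Runs Metropolis sampling at the window's coupling state and stores, for
#' the same configurations, the potential-energy differences to each
#' neighbouring state (the forward/reverse inputs of BAR).
#'
#' @param system a [fep_system()].
#' @param state list with `vdw`, `coul` coupling values of this window.
#' @param neighbors list of neighbour states (same shape as `state`).
#' @param restrained logical: keep the restraint on.
#' @param n_samples,n_equil,thin,step,temperature,seed passed to
#'   [mc_sample()].
#' @return list with `samples` (coordinates) and `du` (matrix, one column
#'   per neighbour), plus the state echo.
#' @export
sample_window <- function(system, state, neighbors, restrained = TRUE,
                          n_samples = 500, n_equil = 500, thin = 5,
                          step = 0.6, temperature = 300, seed = 1) {
  en <- function(x) fep_energy(system, x, state$vdw, state$coul,
                               restrained = restrained)
  r_start <- if (is.null(system$restraint)) 0.5 else system$restraint$r0
  x0 <- system$anchor + c(r_start, 0, 0)
  xs <- mc_sample(en, x0, box = system$box, n_samples = n_samples,
                  n_equil = n_equil, thin = thin, step = step,
                  temperature = temperature, seed = seed)
  du <- vapply(neighbors, function(nb) {
    vapply(seq_len(nrow(xs)), function(i) {
      fep_energy(system, xs[i, ], nb$vdw, nb$coul,
                 restrained = restrained) -
        fep_energy(system, xs[i, ], state$vdw, state$coul,
                   restrained = restrained)
    }, numeric(1))
  }, numeric(nrow(xs)))
  if (any(!is.finite(du))) {
    stop(sprintf("non-finite energy difference in window (vdw=%g, coul=%g)",
                 state$vdw, state$coul))
  }
  list(state = state, samples = xs, du = as.matrix(du))
}

# ---- BAR -------------------------------------------------------------------

#' Bennett acceptance ratio estimate for one window pair
#'
#' Solves the BAR self-consistency equation by root bracketing to a
#' residual below 1e-10 and reports the standard BAR variance estimate.
#' `w_f` are energy differences U_1 - U_0 evaluated on samples from state
#' 0; `w_r` are U_0 - U_1 on samples from state 1.
#'
#' @param w_f forward energy differences, kcal/mol.
#' @param w_r reverse energy differences, kcal/mol.
#' @param temperature Kelvin.
#' @param overlap_warn warn when the estimated uncertainty exceeds this
#'   value (poor phase-space overlap), kcal/mol.
#' @return list with `dg` (deltaG from state 0 to 1, kcal/mol) and `se`.
#' @export
bar_estimate <- function(w_f, w_r, temperature = 300, overlap_warn = 1) {
  stopifnot(length(w_f) > 0, length(w_r) > 0,
            all(is.finite(w_f)), all(is.finite(w_r)))
  kT <- kB * temperature
  nf <- length(w_f)
  nr <- length(w_r)
  M <- log(nf / nr)
  g <- function(dg) {
    sum(1 / (1 + exp(M + (w_f - dg) / kT))) -
      sum(1 / (1 + exp(-M + (w_r + dg) / kT)))
  }
  # g is increasing in dg; bracket then bisect to |residual| < 1e-10
  span <- max(abs(c(w_f, w_r)), kT)
  lo <- -span - 10 * kT
  hi <- span + 10 * kT
  while (g(lo) > 0) lo <- lo - span
  while (g(hi) < 0) hi <- hi + span
  for (it in seq_len(400)) {
    dg <- (lo + hi) / 2
    gv <- g(dg)
    if (abs(gv) < 1e-10 || (hi - lo) < .Machine$double.eps * max(1, abs(dg)))
      break
    if (gv > 0) hi <- dg else lo <- dg
  }
  ff <- 1 / (1 + exp(M + (w_f - dg) / kT))
  fr <- 1 / (1 + exp(-M + (w_r + dg) / kT))
  var_beta <- (mean(ff^2) / mean(ff)^2 - 1) / nf +
              (mean(fr^2) / mean(fr)^2 - 1) / nr
  se <- kT * sqrt(max(var_beta, 0))
  if (!is.finite(se)) se <- Inf # no measurable overlap at all
  if (se > overlap_warn) {
    warning(sprintf(
      "BAR uncertainty %.2f kcal/mol exceeds %.2f: poor overlap", se,
      overlap_warn))
  }
  list(dg = dg, se = se)
}

#' Crooks-consistent synthetic work samples
#'
#' Gaussian forward/reverse work distributions satisfying the Crooks
#' relation for a known free-energy difference: W_f ~ N(dg + s^2/2kT, s^2)
#' and W_r ~ N(-dg + s^2/2kT, s^2).
#'
#' @param n_f,n_r sample counts.
#' @param dg true free-energy difference, kcal/mol.
#' @param sigma work standard deviation, kcal/mol.
#' @param temperature Kelvin.
#' @param seed integer seed.
#' @return list with `w_f`, `w_r`, `dg`.
#' @export
crooks_samples <- function(n_f, n_r, dg, sigma, temperature = 300,
                           seed = 1) {
  set.seed(seed)
  kT <- kB * temperature
  mu <- sigma^2 / (2 * kT)
  list(w_f = rnorm(n_f, dg + mu, sigma),
       w_r = rnorm(n_r, -dg + mu, sigma),
       dg = dg)
}

# ---- cycle -----------------------------------------------------------------

#' Run the alchemical double-decoupling cycle on a toy system
#'
#' Legs: (1) restrain the coupled ligand (one BAR pair between the
#' unrestrained and restrained coupled states), (2) annihilate
#' electrostatics at full vdW over the `coul` schedule, (3) decouple vdW
#' with charges off over `c(0, vdw)` states, (4) release the restraint
#' analytically into `v_ref`.  The standard-state binding free energy is
#' `deltaG_bind = -(restrain + coul + vdw + release)`.
#'
#' @param system a [fep_system()] (must carry a restraint).
#' @param schedule a [lambda_schedule()].
#' @param temperature Kelvin.
#' @param v_ref reference volume, A^3 (1660 = 1 M standard state).
#' @param n_samples,n_equil,thin,step Monte Carlo controls per window.
#' @param seed base seed; window w uses `seed + w`.
#' @return a `fep_result`: list with `legs` (data.frame: leg, dg, se),
#'   `dg_bind`, `se_bind`, `pairs` (per-pair BAR table).
#' @export
run_fep_cycle <- function(system, schedule = lambda_schedule(),
                          temperature = 300, v_ref = 1660,
                          n_samples = 400, n_equil = 400, thin = 4,
                          step = 0.6, seed = 1) {
  stopifnot(inherits(system, "fep_system"), !is.null(system$restraint))
  states <- c(
    lapply(schedule$coul, function(lc) list(vdw = 0, coul = lc,
                                            leg = "coul")),
    lapply(schedule$vdw, function(lv) list(vdw = lv, coul = 1,
                                           leg = "vdw")))
  # state (vdw=0, coul=1) closes the coul leg and opens the vdw leg
  n_states <- length(states)
  windows <- vector("list", n_states)
  for (w in seq_len(n_states)) {
    nbrs <- list()
    if (w > 1) nbrs$prev <- states[[w - 1]]
    if (w < n_states) nbrs$nxt <- states[[w + 1]]
    windows[[w]] <- sample_window(system, states[[w]], nbrs,
                                  restrained = TRUE,
                                  n_samples = n_samples, n_equil = n_equil,
                                  thin = thin, step = step,
                                  temperature = temperature,
                                  seed = seed + w)
  }
  pairs <- data.frame()
  for (w in seq_len(n_states - 1)) {
    fw <- windows[[w]]$du[, "nxt"]
    rv <- windows[[w + 1]]$du[, "prev"]
    est <- bar_estimate(fw, rv, temperature, overlap_warn = 2)
    pairs <- rbind(pairs, data.frame(
      from_vdw = states[[w]]$vdw, from_coul = states[[w]]$coul,
      to_vdw = states[[w + 1]]$vdw, to_coul = states[[w + 1]]$coul,
      leg = states[[w + 1]]$leg, dg = est$dg, se = est$se))
  }
  # restrain-on leg: BAR between unrestrained and restrained coupled states
  en_off <- function(x) fep_energy(system, x, 0, 0, restrained = FALSE)
  restr_u <- function(x) {
    rr <- sqrt(sum((x - system$anchor)^2))
    system$restraint$k_r / 2 * (rr - system$restraint$r0)^2
  }
  x0 <- system$anchor + c(system$restraint$r0, 0, 0)
  xs_off <- mc_sample(en_off, x0, box = system$box, n_samples = n_samples,
                      n_equil = n_equil, thin = thin, step = step,
                      temperature = temperature, seed = seed)
  w_f <- apply(xs_off, 1, restr_u)
  w_r <- -apply(windows[[1]]$samples, 1, restr_u)
  restrain <- bar_estimate(w_f, w_r, temperature, overlap_warn = 2)

  release <- boresch_correction(system$restraint, temperature, v0 = v_ref)
  dg_coul <- sum(pairs$dg[pairs$leg == "coul"])
  se_coul <- sqrt(sum(pairs$se[pairs$leg == "coul"]^2))
  dg_vdw <- sum(pairs$dg[pairs$leg == "vdw"])
  se_vdw <- sqrt(sum(pairs$se[pairs$leg == "vdw"]^2))
  legs <- data.frame(
    leg = c("restrain", "coul", "vdw", "release"),
    dg = c(restrain$dg, dg_coul, dg_vdw, release),
    se = c(restrain$se, se_coul, se_vdw, 0))
  dg_bind <- -sum(legs$dg)
  se_bind <- sqrt(sum(legs$se^2))
  structure(list(legs = legs, dg_bind = dg_bind, se_bind = se_bind,
                 pairs = pairs, v_ref = v_ref,
                 temperature = temperature),
            class = "fep_result")
}

#' @export
print.fep_result <- function(x, ...) {
  cat("<fep_result> deltaG_bind =", sprintf("%.3f +/- %.3f kcal/mol\n",
      x$dg_bind, x$se_bind))
  print(x$legs, row.names = FALSE)
  invisible(x)
}

#' Quadrature oracle for the toy binding free energy
#'
#' deltaG_bind = -kT log( int_box exp(-U(x)/kT) dx / v_ref ) on a regular
#' 3-D grid over the box, with the fully coupled unrestrained potential.
#'
#' @param system a [fep_system()].
#' @param temperature Kelvin.
#' @param v_ref reference volume, A^3.
#' @param n_grid grid points per dimension.
#' @return deltaG_bind, kcal/mol.
#' @export
fep_binding_oracle <- function(system, temperature = 300, v_ref = 1660,
                               n_grid = 120) {
  kT <- kB * temperature
  ax <- seq(-system$box / 2, system$box / 2, length.out = n_grid)
  dv <- diff(ax[1:2])^3
  total <- 0
  for (xi in ax) {
    g <- as.matrix(expand.grid(y = ax, z = ax))
    pts <- cbind(xi, g)
    u <- numeric(nrow(pts))
    for (s in seq_len(nrow(system$sites))) {
      d <- pts - matrix(system$sites[s, ], nrow(pts), 3, byrow = TRUE)
      r <- pmax(sqrt(rowSums(d^2)), 1e-9)
      s6 <- system$sigma_lj[s]^6 / r^6
      u <- u + 4 * system$eps[s] * (s6^2 - s6) +
        coulomb_const * system$q_ligand * system$charges[s] / r
    }
    total <- total + sum(exp(-pmin(u, 700 * kT) / kT)) * dv
  }
  -kT * log(total / v_ref)
}
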