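# Model energy landscapes with analytic gradients.  Each potential carries
# its parameters, a domain box, closures for energy/gradient, and the packed
# representation (cpp_kind, cpp_params) used by the compiled dynamics engine.

new_model_potential <- function(kind, dim, params, domain, cpp_kind,
                                cpp_params) {
  stopifnot(is.matrix(domain), nrow(domain) == 2, ncol(domain) == dim)
  obj <- list(kind = kind, dim = dim, params = params, domain = domain,
              cpp_kind = cpp_kind, cpp_params = cpp_params)
  class(obj) <- "model_potential"
  obj
}

#' Evaluate a model potential
#'
#' @param potential a `model_potential`.
#' @param x numeric coordinate vector of length `potential$dim`.
#' @return energy in kcal/mol.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "model_potential"),
            length(x) == potential$dim)
  pot_energy_cpp(potential$cpp_kind, potential$cpp_params, as.numeric(x))
}

#' Analytic gradient of a model potential
#'
#' @inheritParams potential_energy
#' @return force components, kcal/mol/Angstrom.
#' @export
potential_gradient <- function(potential, x) {
  stopifnot(inherits(potential, "model_potential"),
            length(x) == potential$dim)
  pot_gradient_cpp(potential$cpp_kind, potential$cpp_params, as.numeric(x))
}

#' @export
print.model_potential <- function(x, ...) {
  cat("<model_potential>", x$kind, "dim =", x$dim, "\n")
  cat("  domain:", paste(apply(x$domain, 2, function(d)
    sprintf("[%g, %g]", d[1], d[2])), collapse = " x "), "\n")
  invisible(x)
}

#' Isotropic harmonic well
#'
#' U(x) = sum_d k_d/2 (x_d - c_d)^2.
#'
#' @param k spring constants, kcal/mol/A^2 (recycled to `dim`).
#' @param center well centre (defines `dim`).
#' @param halfwidth domain half width around the centre.
#' @return a `model_potential`.
#' @export
harmonic_well <- function(k = 2, center = 0, halfwidth = 10) {
  dim <- length(center)
  k <- rep_len(k, dim)
  domain <- rbind(center - halfwidth, center + halfwidth)
  new_model_potential("harmonic", dim, list(k = k, center = center), domain,
                      1L, c(dim, k, center))
}

#' One-dimensional double well
#'
#' U(x) = h ((x^2 - a^2)/a^2)^2 + eps x / (2 a): two minima near x = -a and
#' x = +a separated by a barrier of height about `h`; `eps` tilts the wells,
#' raising the right basin by about `eps` relative to the left.
#'
#' @param h barrier height, kcal/mol.
#' @param a half separation of the minima, Angstrom.
#' @param eps basin asymmetry, kcal/mol.
#' @param halfwidth domain half width.
#' @return a `model_potential`.
#' @export
double_well_1d <- function(h = 3, a = 1, eps = 0, halfwidth = 3) {
  new_model_potential("double_well_1d", 1L,
                      list(h = h, a = a, eps = eps),
                      rbind(-halfwidth, halfwidth),
                      2L, c(h, a, eps))
}

#' The Mueller-Brown surface
#'
#' The canonical four-Gaussian two-dimensional test surface.  The canonical
#' constants give barriers of order 100 energy units; `scale` rescales them
#' (default 1 keeps the published constants).
#'
#' @param scale overall multiplicative factor.
#' @param params optional list overriding any of `A`, `a`, `b`, `c`,
#'   `x0`, `y0` (length-4 numeric each).
#' @return a `model_potential` with `dim = 2`.
#' @export
mueller_brown <- function(scale = 1, params = list()) {
  p <- list(A = c(-200, -100, -170, 15),
            a = c(-1, -1, -6.5, 0.7),
            b = c(0, 0, 11, 0.6),
            c = c(-10, -10, -6.5, 0.7),
            x0 = c(1, 0, -0.5, -1),
            y0 = c(0, 0.5, 1.5, 1))
  for (nm in names(params)) {
    stopifnot(nm %in% names(p), length(params[[nm]]) == 4)
    p[[nm]] <- as.numeric(params[[nm]])
  }
  p$scale <- scale
  new_model_potential("mueller_brown", 2L, p,
                      rbind(c(-2, -0.5), c(1.5, 2.5)),
                      3L, c(scale, p$A, p$a, p$b, p$c, p$x0, p$y0))
}

#' Model egress landscape: one bound well, several exit channels
#'
#' A two-dimensional landscape with a bound well at the origin and
#' `n_channels` exit channels through a surrounding barrier ring.  In polar
#' coordinates U(r, theta) = B(theta) f(r) + W(r) with the radial bump
#' f(r) = (r/r_b)^2 exp(1 - (r/r_b)^2) peaking at exactly 1 at r = r_b, the
#' angular barrier profile B lowered to the declared barrier heights at the
#' channel angles (von Mises bumps, amplitudes solved exactly), and a
#' compact-support bound well W(r) = -depth (1 - (r/r_w)^2)^2 for r < r_w.
#' Each channel's saddle sits at (r_b, theta_j) with energy equal to its
#' declared barrier (to ~1e-10 for the default geometry).  Channel angles
#' are spread evenly around the circle with a small seeded jitter, so every
#' angular region drains into some channel and a radially ratcheted ligand
#' is never forced over the base ring.
#'
#' @param n_channels number of exit channels (>= 1).
#' @param barriers channel saddle energies, kcal/mol (recycled).
#' @param seed integer seed for the angle jitter.
#' @param r_b barrier ring radius, Angstrom.
#' @param depth bound-well depth, kcal/mol.
#' @param base_barrier ring height between channels; default
#'   `max(barriers) + 8`.
#' @return an `egress_landscape`, which is also a `model_potential`.
#' @export
make_egress_landscape <- function(n_channels, barriers, seed = 1,
                                  r_b = 10, depth = 5, base_barrier = NULL) {
  stopifnot(n_channels >= 1)
  barriers <- rep_len(barriers, n_channels)
  if (any(barriers <= 0)) stop("barriers must be positive")
  if (is.null(base_barrier)) base_barrier <- max(barriers) + 15
  stopifnot(base_barrier > max(barriers))
  r_w <- r_b / 2

  # channel angles: evenly spread around the circle plus seeded jitter
  base_ang <- seq(0, 360, length.out = n_channels + 1)[seq_len(n_channels)]
  jit_span <- 0.15 * 360 / n_channels
  set.seed(seed)
  angles <- (base_ang + runif(n_channels, -jit_span, jit_span)) * pi / 180
  angles <- ((angles + pi) %% (2 * pi)) - pi

  d_min <- if (n_channels == 1) pi else
    min(diff(c(sort(angles), min(angles) + 2 * pi)))
  # wide channels (sd ~ 1/sqrt(kappa)) whose angular gradient guides a
  # ratcheted ligand into a channel, while cross-talk between channels
  # stays below ~1e-9 so the solved saddle energies are exact
  kappa <- max(16 / d_min^2, 22 / (1 - cos(d_min)))

  # amplitudes solved so B(theta_j) = barriers[j] exactly
  M <- outer(seq_len(n_channels), seq_len(n_channels), function(i, j)
    exp(kappa * (cos(angles[i] - angles[j]) - 1)))
  amp <- solve(M, base_barrier - barriers)

  half <- 2.5 * r_b
  pot <- new_model_potential(
    "egress", 2L,
    list(n_channels = n_channels, barriers = barriers, angles = angles,
         r_b = r_b, depth = depth, base_barrier = base_barrier,
         kappa = kappa, r_w = r_w, seed = seed),
    rbind(c(-half, -half), c(half, half)),
    4L, c(r_b, kappa, depth, r_w, base_barrier, n_channels,
          as.numeric(rbind(angles, amp))))
  pot$channels <- data.frame(angle = angles, barrier = barriers,
                             saddle_r = r_b)
  class(pot) <- c("egress_landscape", class(pot))
  pot
}

#' Saddle energies of an egress landscape
#'
#' Evaluates the landscape at each channel's analytic saddle location.
#'
#' @param landscape an `egress_landscape`.
#' @return numeric vector of saddle energies, kcal/mol.
#' @export
saddle_energies <- function(landscape) {
  stopifnot(inherits(landscape, "egress_landscape"))
  vapply(seq_len(nrow(landscape$channels)), function(j) {
    a <- landscape$channels$angle[j]
    potential_energy(landscape, landscape$params$r_b * c(cos(a), sin(a)))
  }, numeric(1))
}

# ---- config round trip -----------------------------------------------------

#' Serialize a model potential to a flat config file
#'
#' @param potential a `model_potential`.
#' @param path destination file.
#' @return `path` invisibly.
#' @export
potential_to_config <- function(potential, path) {
  cfg <- list(potential = potential$kind,
              dim = potential$dim,
              domain_lo = potential$domain[1, ],
              domain_hi = potential$domain[2, ])
  for (nm in names(potential$params)) {
    cfg[[paste0("param_", nm)]] <- potential$params[[nm]]
  }
  write_config(cfg, path)
}

#' Rebuild a model potential from a flat config file
#'
#' Inverse of [potential_to_config()]; energies of the round-tripped
#' potential are bit-identical to the original.
#'
#' @param path config file written by [potential_to_config()].
#' @return a `model_potential`.
#' @export
potential_from_config <- function(path) {
  cfg <- read_config(path)
  p <- cfg[grepl("^param_", names(cfg))]
  names(p) <- sub("^param_", "", names(p))
  switch(cfg$potential,
    harmonic = harmonic_well(k = p$k, center = p$center,
                             halfwidth = cfg$domain_hi[1] - p$center[1]),
    double_well_1d = double_well_1d(h = p$h, a = p$a, eps = p$eps,
                                    halfwidth = cfg$domain_hi[1]),
    mueller_brown = mueller_brown(scale = p$scale,
                                  params = p[c("A", "a", "b", "c", "x0", "y0")]),
    egress = make_egress_landscape(p$n_channels, p$barriers, seed = p$seed,
                                   r_b = p$r_b, depth = p$depth,
                                   base_barrier = p$base_barrier),
    stop("unknown potential kind: ", cfg$potential))
}

# ---- quadrature oracle -----------------------------------------------------

#' Deterministic Boltzmann quadrature oracle
#'
#' Ground truth for free-energy tests: tabulates Boltzmann weights of a model
#' potential on a regular grid over its domain box.
#'
#' @param potential a `model_potential` (dim 1 or 2).
#' @param temperature Kelvin.
#' @param n_grid grid points per dimension.
#' @return a `boltzmann_oracle`.
#' @export
boltzmann_oracle <- function(potential, temperature = 300, n_grid = 401) {
  stopifnot(inherits(potential, "model_potential"), potential$dim <= 2)
  axes <- lapply(seq_len(potential$dim), function(d)
    seq(potential$domain[1, d], potential$domain[2, d], length.out = n_grid))
  if (potential$dim == 1) {
    U <- vapply(axes[[1]], function(x) potential_energy(potential, x),
                numeric(1))
    dim(U) <- c(n_grid, 1L)
  } else {
    U <- outer(seq_len(n_grid), seq_len(n_grid), Vectorize(function(i, j)
      potential_energy(potential, c(axes[[1]][i], axes[[2]][j]))))
  }
  kT <- kB * temperature
  w <- exp(-(U - min(U)) / kT)
  # domain adequacy: Boltzmann weight at the box edge should be negligible
  edge <- if (potential$dim == 1) max(w[c(1, n_grid), 1]) else
    max(w[1, ], w[n_grid, ], w[, 1], w[, n_grid])
  if (edge > 1e-6 * max(w)) {
    warning("Boltzmann weight at the domain edge exceeds 1e-6 of the maximum;",
            " the domain box may be too small")
  }
  structure(list(potential = potential, temperature = temperature,
                 axes = axes, U = U, weight = w),
            class = "boltzmann_oracle")
}

#' Marginal free-energy profile by grid quadrature
#'
#' F(s) = -kB T log integral exp(-U/kB T) delta(cv - s) dx, evaluated by
#' binning grid Boltzmann weights on the collective variable and shifted so
#' min F = 0.  Deterministic: repeated calls are bit-identical.
#'
#' @param oracle a [boltzmann_oracle()].
#' @param cv coordinate projection: an integer coordinate index, or a
#'   function mapping a coordinate vector to a scalar.
#' @param breaks bin edges on the cv, or a single bin count (default 101).
#' @return data.frame with columns `s` (bin midpoints) and `F` (kcal/mol).
#' @export
free_energy_quadrature <- function(oracle, cv = 1L, breaks = 101L) {
  stopifnot(inherits(oracle, "boltzmann_oracle"))
  dim <- oracle$potential$dim
  if (dim == 1) {
    pts <- matrix(oracle$axes[[1]], ncol = 1)
  } else {
    pts <- as.matrix(expand.grid(oracle$axes[[1]], oracle$axes[[2]]))
  }
  s <- if (is.function(cv)) apply(pts, 1, cv) else pts[, cv]
  w <- as.numeric(oracle$weight)
  if (length(breaks) == 1) {
    breaks <- seq(min(s), max(s), length.out = breaks + 1)
  }
  bin <- cut(s, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  mass <- vapply(seq_len(length(breaks) - 1), function(b)
    sum(w[which(bin == b)]), numeric(1))
  kT <- kB * oracle$temperature
  F <- ifelse(mass > 0, -kT * log(mass), NA_real_)
  F <- F - min(F, na.rm = TRUE)
  data.frame(s = (head(breaks, -1) + tail(breaks, -1)) / 2, F = F)
}

#' Basin free-energy difference from a 1-D profile
#'
#' Boltzmann-integrates the profile over the two sides of `split`:
#' deltaF = F_right - F_left with F_side = -kB T log sum exp(-F/kB T).
#'
#' @param profile data.frame with columns `s`, `F` (as from
#'   [free_energy_quadrature()] or [fes_profile_1d()]).
#' @param split cv value separating the basins.
#' @param temperature Kelvin.
#' @return deltaF in kcal/mol.
#' @export
basin_delta_f <- function(profile, split, temperature = 300) {
  kT <- kB * temperature
  ok <- is.finite(profile$F)
  left <- ok & profile$s < split
  right <- ok & profile$s >= split
  stopifnot(any(left), any(right))
  -kT * log(sum(exp(-profile$F[right] / kT))) +
    kT * log(sum(exp(-profile$F[left] / kT)))
}

# ---- synthetic streamline bundles ------------------------------------------

#' Generate synthetic streamline bundles
#'
#' Seeded fixture for streamline clustering: `n_bundles` template curves
#' (parallel gentle arcs offset laterally by `separation`), each replicated
#' `n_per_bundle` times with Gaussian coordinate noise.  Bundle labels are
#' kept in the `label` attribute for test assertions.
#'
#' @param n_bundles number of template curves.
#' @param n_per_bundle streamlines per template.
#' @param separation lateral offset between adjacent templates, Angstrom.
#' @param noise per-point Gaussian noise sd, Angstrom.
#' @param seed integer seed.
#' @param n_points points per streamline.
#' @param length curve length, Angstrom.
#' @return list of streamlines (matrices n_points x 2) with attributes
#'   `label` (integer vector) and `templates` (list of matrices).
#' @export
generate_streamline_bundles <- function(n_bundles, n_per_bundle,
                                        separation, noise, seed = 1,
                                        n_points = 30, length = 20) {
  stopifnot(separation > 0, noise >= 0)
  set.seed(seed)
  t <- seq(0, 1, length.out = n_points)
  templates <- lapply(seq_len(n_bundles), function(j) {
    cbind(t * length,
          (j - 1) * separation + 0.05 * length * sin(pi * t))
  })
  out <- list()
  label <- integer(0)
  for (j in seq_len(n_bundles)) {
    for (r in seq_len(n_per_bundle)) {
      pts <- templates[[j]]
      if (noise > 0) {
        pts <- pts + matrix(rnorm(base::length(pts), sd = noise),
                            ncol = 2)
      }
      out[[base::length(out) + 1]] <- pts
      label <- c(label, j)
    }
  }
  attr(out, "label") <- label
  attr(out, "templates") <- templates
  out
}
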