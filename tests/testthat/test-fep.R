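test_that("lambda schedules default to the 20 + 11 window layout", {
  sch <- lambda_schedule()
  expect_length(sch$vdw, 20)
  expect_equal(sch$vdw[1], 0.05)
  expect_equal(sch$vdw[20], 1)
  expect_equal(sch$coul, seq(0, 1, by = 0.1))
  expect_error(lambda_schedule(vdw = c(0.5, 0.2)))
})

test_that("soft-core endpoints and the r = 0 core are exact", {
  sc <- softcore_params(alpha = 0.5, power = 1, sigma = 3)
  r <- c(0.5, 1, 2.8, 3.4, 6)
  lj <- function(r) 4 * 0.3 * ((3 / r)^12 - (3 / r)^6)
  expect_equal(softcore_pair_energy(r, 0, sc, 0.3, 3), lj(r),
               tolerance = 1e-12)
  expect_equal(softcore_pair_energy(r, 1, sc, 0.3, 3), rep(0, 5))
  # finite at r = 0 for lam > 0, by direct substitution
  reff6 <- 0.5 * 3^6 * 0.5
  expect_equal(softcore_pair_energy(0, 0.5, sc, 0.3, 3),
               0.5 * 4 * 0.3 * (3^12 / reff6^2 - 3^6 / reff6))
  # coulomb endpoints share the shifted distance
  expect_equal(softcore_coulomb_energy(r, 0, sc, 0.5, -0.05),
               coulomb_const * 0.5 * -0.05 / r, tolerance = 1e-12)
  expect_equal(softcore_coulomb_energy(r, 1, sc, 0.5, -0.05), rep(0, 5))
  expect_true(is.finite(softcore_coulomb_energy(0, 0.3, sc, 1, 1)))
})

test_that("BAR recovers the truth from Crooks-consistent samples", {
  cs <- crooks_samples(4000, 4000, dg = 2.5, sigma = 1.5, seed = 11)
  est <- bar_estimate(cs$w_f, cs$w_r)
  expect_lt(abs(est$dg - 2.5), 3 * est$se)
  # all-zero work means zero free energy difference
  z <- bar_estimate(rep(0, 50), rep(0, 50))
  expect_equal(z$dg, 0, tolerance = 1e-9)
  # bias study: 20 seeded repeats at n = 1e4, mean bias < 1 pooled SE
  reps <- vapply(1:20, function(s) {
    cs <- crooks_samples(10000, 10000, dg = 1.2, sigma = 2, seed = 100 + s)
    unlist(bar_estimate(cs$w_f, cs$w_r))
  }, numeric(2))
  bias <- mean(reps[1, ]) - 1.2
  expect_lt(abs(bias), mean(reps[2, ]) / sqrt(20) * 3)
  expect_lt(abs(bias), mean(reps[2, ]))
})

test_that("BAR agrees with exponential averaging at large n", {
  kT <- kB * 300
  cs <- crooks_samples(1e5, 1e5, dg = 0.8, sigma = 1, seed = 9)
  est <- bar_estimate(cs$w_f, cs$w_r)
  exp_avg <- -kT * log(mean(exp(-cs$w_f / kT)))
  expect_lt(abs(est$dg - exp_avg), 0.02)
})

test_that("poor overlap is flagged rather than silently returned", {
  cs <- crooks_samples(200, 200, dg = 0, sigma = 25, seed = 3)
  expect_warning(bar_estimate(cs$w_f, cs$w_r, overlap_warn = 0.5),
                 "overlap")
})

test_that("window sampling recovers a harmonic closed form via BAR", {
  # U_lam = k(lam)/2 x^2 with k0 = 2, k1 = 6: dF = (kT/2) log(k1/k0)
  kT <- kB * 300
  k0 <- 2
  k1 <- 6
  x0 <- mc_sample(function(x) k0 / 2 * sum(x^2), c(0, 0, 0),
                  n_samples = 2500, thin = 4, seed = 5)
  x1 <- mc_sample(function(x) k1 / 2 * sum(x^2), c(0, 0, 0),
                  n_samples = 2500, thin = 4, seed = 6)
  w_f <- (k1 - k0) / 2 * rowSums(x0^2)
  w_r <- (k0 - k1) / 2 * rowSums(x1^2)
  est <- bar_estimate(w_f, w_r)
  truth <- 3 * kT / 2 * log(k1 / k0)
  expect_lt(abs(est$dg - truth), 3 * est$se + 0.01)
})

test_that("identical neighbour states give identically zero differences", {
  sys <- fep_system()
  w <- sample_window(sys, list(vdw = 0.3, coul = 1),
                     list(same = list(vdw = 0.3, coul = 1)),
                     n_samples = 50, n_equil = 50, seed = 1)
  expect_true(all(w$du == 0))
})

test_that("standard error shrinks roughly as sqrt(n)", {
  sys <- fep_system()
  se_of <- function(n, seed) {
    a <- sample_window(sys, list(vdw = 0.5, coul = 1),
                       list(nxt = list(vdw = 0.6, coul = 1)),
                       n_samples = n, n_equil = 300, seed = seed)
    b <- sample_window(sys, list(vdw = 0.6, coul = 1),
                       list(prev = list(vdw = 0.5, coul = 1)),
                       n_samples = n, n_equil = 300, seed = seed + 1)
    bar_estimate(a$du[, "nxt"], b$du[, "prev"])$se
  }
  r <- se_of(400, 21) / se_of(1600, 77)
  expect_gt(r, 2 / 1.3)
  expect_lt(r, 2 * 1.3)
})

test_that("Boresch correction matches six-dimensional quadrature within 1%", {
  br <- boresch_restraint(r0 = 5, k_r = 10, theta0 = c(60, 80),
                          phi0 = c(30, -60, 120))
  kT <- kB * 300
  k_ang <- 10 * (180 / pi)^2
  gauss <- function(f, center, k, lower, upper) {
    s <- sqrt(kT / k)
    integrate(f, max(lower, center - 12 * s), min(upper, center + 12 * s),
              rel.tol = 1e-10)$value
  }
  z_r <- gauss(function(r) r^2 * exp(-10 * (r - 5)^2 / (2 * kT)), 5, 10,
               0, Inf)
  z_t <- function(t0) gauss(function(t)
    sin(t) * exp(-k_ang * (t - t0)^2 / (2 * kT)), t0, k_ang, 0, pi)
  z_p <- gauss(function(p) exp(-k_ang * p^2 / (2 * kT)), 0, k_ang,
               -pi, pi)
  z6 <- z_r * z_t(60 * pi / 180) * z_t(80 * pi / 180) * z_p^3
  quad <- -kT * log(8 * pi^2 * 1660 / z6)
  an <- boresch_correction(br, 300)
  expect_lt(abs(an - quad) / abs(quad), 0.01)
})

test_that("Boresch correction scales analytically in k and T", {
  br <- boresch_restraint(r0 = 5, k_r = 10, theta0 = c(60, 80),
                          phi0 = c(30, -60, 120))
  br4 <- boresch_restraint(r0 = 5, k_r = 40, theta0 = c(60, 80),
                           k_theta = 40, phi0 = c(30, -60, 120), k_phi = 40)
  kT <- kB * 300
  expect_equal(boresch_correction(br4, 300) - boresch_correction(br, 300),
               -6 * (kT / 2) * log(4), tolerance = 1e-12)
  # explicit temperature dependence
  for (temp in c(250, 350)) {
    kT2 <- kB * temp
    th <- c(60, 80) * pi / 180
    ks <- c(10, rep(10 * (180 / pi)^2, 5))
    direct <- -kT2 * log(8 * pi^2 * 1660 * sqrt(prod(ks)) /
                         (25 * sin(th[1]) * sin(th[2]) *
                          (2 * pi * kT2)^3))
    expect_equal(boresch_correction(br, temp), direct, tolerance = 1e-12)
  }
  expect_warning(boresch_restraint(r0 = 3, theta0 = c(5, 90),
                                   phi0 = c(0, 0, 0)), "10 degrees")
})

test_that("zero-charge solute has a null electrostatic leg", {
  sys <- fep_system(q_ligand = 0)
  res <- run_fep_cycle(sys, lambda_schedule(vdw = c(0.25, 0.5, 0.75, 1)),
                       n_samples = 150, n_equil = 150, thin = 2, seed = 4)
  dg_coul <- res$legs$dg[res$legs$leg == "coul"]
  se_coul <- res$legs$se[res$legs$leg == "coul"]
  expect_lt(abs(dg_coul), 3 * se_coul + 1e-6)
})

test_that("cycle bookkeeping is an identity", {
  sys <- fep_system()
  res <- run_fep_cycle(sys, lambda_schedule(vdw = c(0.5, 1),
                                            coul = c(0, 0.5, 1)),
                       n_samples = 100, n_equil = 100, thin = 2, seed = 8)
  expect_equal(res$dg_bind, -sum(res$legs$dg), tolerance = 1e-12)
  expect_equal(res$se_bind, sqrt(sum(res$legs$se^2)), tolerance = 1e-12)
})

test_that("restrained cycle with correction matches a box-reference run", {
  # with v_ref = V_box, releasing the restraint into the box is the exact
  # inverse of restraining: total binding estimates must agree
  sys <- fep_system()
  sch <- lambda_schedule(vdw = seq(0.1, 1, by = 0.1),
                         coul = seq(0, 1, by = 0.2))
  v_box <- sys$box^3
  res <- run_fep_cycle(sys, sch, v_ref = v_box, n_samples = 500,
                       n_equil = 800, thin = 10, seed = 13)
  oracle <- fep_binding_oracle(sys, v_ref = v_box, n_grid = 120)
  expect_lt(abs(res$dg_bind - oracle), 0.1 + 3 * res$se_bind)
})
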