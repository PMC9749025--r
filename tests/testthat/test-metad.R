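test_that("hill heights follow the well-tempered recursion exactly", {
  # pinned CV: run metadynamics in a stiff well so the CV barely moves,
  # then check heights against the direct recursion at the deposited points
  pot <- harmonic_well(k = 500, center = 0)
  mp <- metad_params(omega0 = 0.2, sigma_s = 0.1, bias_factor = 5,
                     stride_ps = 0.05)
  cfg <- sim_config(dt = 0.005, n_steps = 5000, save_stride = 10, seed = 2)
  res <- run_metad(pot, cfg, mp, cv = 1L, x0 = 0)
  h <- res$ledger$hills
  expect_gt(nrow(h), 100)
  expect_true(all(h$height <= 0.2 + 1e-12))
  expect_true(all(h$height > 0))
  dT <- (5 - 1) * 300
  for (k in c(2, 50, nrow(h))) {
    v_prev <- sum(h$height[seq_len(k - 1)] *
      exp(-0.5 * ((h$s[k] - h$s[seq_len(k - 1)]) / 0.1)^2))
    expect_equal(h$height[k], 0.2 * exp(-v_prev / (kB * dT)),
                 tolerance = 1e-10)
  }
  # heights decay (monotone up to CV jitter): compare quarters
  q <- split(h$height, cut(seq_len(nrow(h)), 4))
  expect_true(all(diff(vapply(q, mean, numeric(1))) < 0))
})

test_that("near-ordinary metadynamics keeps heights near omega0", {
  pot <- harmonic_well(k = 500, center = 0)
  mp <- metad_params(omega0 = 0.2, sigma_s = 0.1, bias_factor = 1e8,
                     stride_ps = 0.05)
  cfg <- sim_config(dt = 0.005, n_steps = 2000, save_stride = 10, seed = 2)
  res <- run_metad(pot, cfg, mp, cv = 1L, x0 = 0)
  expect_true(all(abs(res$ledger$hills$height - 0.2) < 1e-6))
})

test_that("bias_at equals the brute-force Gaussian sum", {
  set.seed(14)
  mp <- metad_params(sigma_s = 0.3, sigma_z = 0.7)
  hills <- cbind(seq_len(40) * 2, rnorm(40), rnorm(40),
                 runif(40, 0.01, 0.2))
  led <- egressr:::new_hills_ledger(hills, mp, 2L)
  pts <- cbind(rnorm(25), rnorm(25))
  expect_equal(bias_at(pts, led), bias_brute_force(pts, led),
               tolerance = 1e-12)
  # 1-CV ledger and the single-hill identities
  led1 <- egressr:::new_hills_ledger(cbind(2, 1.5, 0, 0.2), mp, 1L)
  expect_equal(bias_at(1.5, led1), 0.2)
  expect_equal(bias_at(1.5 + 0.3, led1), 0.2 * exp(-0.5))
  expect_equal(bias_at(3, egressr:::new_hills_ledger(
    matrix(numeric(0), 0, 4), mp, 1L)), 0)
})

test_that("reconstructed double-well FES matches the quadrature oracle", {
  pot <- double_well_1d(h = 3, a = 1, eps = 1.2, halfwidth = 2.5)
  oracle_prof <- free_energy_quadrature(
    boltzmann_oracle(pot, n_grid = 2001), breaks = 200)
  dF_oracle <- basin_delta_f(oracle_prof, 0)
  mp <- metad_params(omega0 = 0.2, sigma_s = 0.1, bias_factor = 15,
                     stride_ps = 2)
  cfg <- sim_config(dt = 0.005, n_steps = 2e6, save_stride = 100, seed = 3)
  res <- run_metad(pot, cfg, mp, cv = 1L, x0 = -1)
  fes <- reconstruct_fes(res$ledger,
                         s_grid = seq(-2.2, 2.2, length.out = 221))
  dF <- basin_delta_f(fes_profile_1d(fes), 0)
  expect_lt(abs(dF - dF_oracle), 0.5 * kB * 300)
})

test_that("two seeds agree on the basin free-energy difference", {
  pot <- double_well_1d(h = 2.5, a = 1, eps = 0.9, halfwidth = 2.5)
  mp <- metad_params(omega0 = 0.2, sigma_s = 0.1, bias_factor = 15,
                     stride_ps = 2)
  obs <- function(led) {
    fes <- reconstruct_fes(led, s_grid = seq(-2.2, 2.2, length.out = 181))
    basin_delta_f(fes_profile_1d(fes), 0)
  }
  est <- lapply(c(3, 71), function(seed) {
    cfg <- sim_config(dt = 0.005, n_steps = 1.5e6, save_stride = 100,
                      seed = seed)
    res <- run_metad(pot, cfg, mp, cv = 1L, x0 = -1)
    ledger_block_error(res$ledger, obs)
  })
  pooled_se <- sqrt(est[[1]]$se^2 + est[[2]]$se^2 + 1e-4)
  expect_lt(abs(est[[1]]$mean - est[[2]]$mean),
            2 * pooled_se + 0.25 * kB * 300)
})

test_that("harmonic FES curvature is recovered within 10 percent", {
  pot <- harmonic_well(k = 2, center = 0, halfwidth = 4)
  mp <- metad_params(omega0 = 0.2, sigma_s = 0.1, bias_factor = 15,
                     stride_ps = 2)
  cfg <- sim_config(dt = 0.005, n_steps = 1.5e6, save_stride = 100,
                    seed = 8)
  res <- run_metad(pot, cfg, mp, cv = 1L, x0 = 0)
  fes <- reconstruct_fes(res$ledger,
                         s_grid = seq(-1.2, 1.2, length.out = 121))
  fit <- lm(fes$F ~ poly(fes$s, 2, raw = TRUE))
  expect_equal(unname(2 * coef(fit)[3]), 2, tolerance = 0.1)
})

test_that("convergence profile truncates the ledger consistently", {
  pot <- double_well_1d(h = 2, a = 1, eps = 0.6, halfwidth = 2.5)
  mp <- metad_params(omega0 = 0.2, sigma_s = 0.1, bias_factor = 15,
                     stride_ps = 2)
  cfg <- sim_config(dt = 0.005, n_steps = 6e5, save_stride = 100, seed = 5)
  res <- run_metad(pot, cfg, mp, cv = 1L, x0 = -1)
  obs <- function(led) {
    fes <- reconstruct_fes(led, s_grid = seq(-2.2, 2.2, length.out = 121))
    basin_delta_f(fes_profile_1d(fes), 0)
  }
  tmax <- max(res$ledger$hills$time)
  cp <- convergence_profile(res$ledger, seq(0.25, 1, by = 0.25) * tmax,
                            obs, tol = 0.25)
  # single checkpoint at the full ledger reproduces the direct observable
  expect_equal(cp$value[4], obs(res$ledger))
  expect_true(attr(cp, "converged"))
  # zero-length prefix of deposition means no hills: empty ledger errors
  expect_error(reconstruct_fes(
    egressr:::new_hills_ledger(matrix(numeric(0), 0, 4), mp, 1L)))
})

test_that("metad FES error shrinks with run length (seeded median)", {
  pot <- double_well_1d(h = 2, a = 1, eps = 0.8, halfwidth = 2.5)
  oracle <- basin_delta_f(free_energy_quadrature(
    boltzmann_oracle(pot, n_grid = 2001), breaks = 200), 0)
  mp <- metad_params(omega0 = 0.2, sigma_s = 0.1, bias_factor = 15,
                     stride_ps = 2)
  obs <- function(led) {
    fes <- reconstruct_fes(led, s_grid = seq(-2.2, 2.2, length.out = 121))
    basin_delta_f(fes_profile_1d(fes), 0)
  }
  errs <- sapply(1:5, function(rep) {
    cfg <- sim_config(dt = 0.005, n_steps = 1e6, save_stride = 200,
                      seed = 40 + rep)
    res <- run_metad(pot, cfg, mp, cv = 1L, x0 = -1)
    tmax <- max(res$ledger$hills$time)
    cp <- convergence_profile(res$ledger, c(0.3, 1) * tmax, obs, tol = Inf)
    abs(cp$value - oracle)
  })
  expect_lte(median(errs[2, ]), median(errs[1, ]) + 0.05)
})

test_that("zero deposition steps leave an empty ledger and zero bias", {
  pot <- harmonic_well(k = 2)
  mp <- metad_params(stride_ps = 2)
  cfg <- sim_config(dt = 0.01, n_steps = 100, save_stride = 10, seed = 1)
  res <- run_metad(pot, cfg, mp, cv = 1L, x0 = 0) # stride > run length
  expect_equal(nrow(res$ledger$hills), 0)
  expect_equal(bias_at(0, res$ledger), 0)
})
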