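straight_path <- function(n = 8, spacing = 1) {
  structure(list(frames = cbind(seq(0, by = spacing, length.out = n), 0),
                 spacing = rep(spacing^2 / 2, n - 1), gap_fills = list()),
            class = "guess_path")
}

test_that("msd is the mean of squared deviations", {
  expect_equal(msd_aligned(c(1, 2), c(1, 2)), 0)
  expect_equal(msd_aligned(3, 1), 4)
  expect_equal(msd_aligned(c(1, 3), c(0, 0)), 5)
  expect_error(msd_aligned(c(1, 2), 1), "dimension")
})

test_that("auto lambda follows the 2.3 / median-msd rule", {
  # adjacent msd all 1: frames sqrt(2) apart in 2-D
  frames <- cbind(seq(0, by = sqrt(2), length.out = 5), 0)
  expect_equal(auto_lambda(frames), 2.3)
  expect_equal(auto_lambda(2 * frames), 2.3 / 4)
  expect_error(auto_lambda(matrix(1, 4, 2)), "degenerate")
})

test_that("path cv takes node values at the reference frames", {
  gp <- straight_path(8, spacing = 3) # lam * msd >> 20 between nodes
  p <- pathcv_params(gp, lam = 10)
  for (k in c(1, 4, 8)) {
    v <- path_cv(gp$frames[k, ], p)
    expect_equal(v$s, k, tolerance = 1e-6)
    expect_equal(v$z, 0, tolerance = 1e-6)
  }
  expect_equal(sum(path_cv(c(2.2, 0.7), p)$w), 1)
})

test_that("midpoint symmetry and perpendicular monotonicity of z", {
  frames <- rbind(c(0, 0), c(2, 0), c(4, 0))
  p <- pathcv_params(frames, lam = 1)
  mid <- path_cv(c(1, 0), p)
  # x equidistant from frames 1 and 2; frame 3 pulls s slightly upward,
  # so compare against the two-frame symmetric value via direct weights
  w <- exp(-1 * c(msd_aligned(c(1, 0), frames[1, ]),
                  msd_aligned(c(1, 0), frames[2, ]),
                  msd_aligned(c(1, 0), frames[3, ])))
  expect_equal(mid$s, sum(c(1, 2, 3) * w) / sum(w))
  expect_equal(mid$w[1], mid$w[2])

  z_at <- function(delta) path_cv(c(2, delta), p)$z
  zs <- vapply(c(0.5, 1, 2), z_at, numeric(1))
  expect_true(all(diff(zs) > 0))
  expect_gt(zs[1], z_at(0))
})

test_that("two-frame midpoint gives s = 1.5 exactly", {
  frames <- rbind(c(0, 0), c(2, 0), c(200, 0)) # third frame negligible
  p <- pathcv_params(frames, lam = 2)
  expect_equal(path_cv(c(1, 0), p)$s, 1.5, tolerance = 1e-10)
})

test_that("analytic path-cv gradients match finite differences", {
  set.seed(21)
  gp <- straight_path(6, spacing = 1.2)
  frames <- gp$frames + matrix(rnorm(12, sd = 0.1), ncol = 2)
  p <- pathcv_params(frames)
  h <- 1e-6
  worst_s <- worst_z <- 0
  for (i in 1:100) {
    x <- c(runif(1, -1, 7), runif(1, -2, 2))
    g <- path_cv_gradient(x, p)
    for (d in 1:2) {
      e <- c(0, 0)
      e[d] <- h
      fs <- (path_cv(x + e, p)$s - path_cv(x - e, p)$s) / (2 * h)
      fz <- (path_cv(x + e, p)$z - path_cv(x - e, p)$z) / (2 * h)
      worst_s <- max(worst_s, abs(g$ds[d] - fs) / max(1e-8, abs(fs)))
      worst_z <- max(worst_z, abs(g$dz[d] - fz) / max(1e-8, abs(fz)))
    }
  }
  expect_lt(worst_s, 1e-4)
  expect_lt(worst_z, 1e-4)
})

test_that("gradient limits: on-path symmetry point and flat-weight lambda", {
  frames <- rbind(c(0, 0), c(2, 0), c(4, 0))
  p <- pathcv_params(frames, lam = 1)
  g <- path_cv_gradient(c(2, 0.5), p) # mirror-symmetric about frame 2
  expect_equal(g$dz[1], 0, tolerance = 1e-12)
  p_flat <- pathcv_params(frames, lam = 1e-9)
  g_flat <- path_cv_gradient(c(1.3, 0.4), p_flat)
  expect_lt(max(abs(g_flat$ds)), 1e-6)
})

test_that("reparametrization sanity at auto-tuned lambda", {
  set.seed(31)
  # gently curved path, auto lambda
  t <- seq(0, 1, length.out = 10)
  frames <- cbind(10 * t, 2 * sin(pi * t))
  p <- pathcv_params(frames)
  expect_true(p$lam * median(rowSums(diff(frames)^2) / 2) >= 1)
  expect_true(p$lam * median(rowSums(diff(frames)^2) / 2) <= 5)
  for (i in seq_len(10)) {
    expect_lt(abs(path_cv(frames[i, ], p)$s - i), 0.25)
  }
})

test_that("s and z are invariant under joint rigid translation", {
  set.seed(4)
  frames <- cbind(cumsum(runif(6, 0.8, 1.2)), rnorm(6, 0, 0.2))
  p <- pathcv_params(frames)
  x <- c(2.7, 0.3)
  shift <- c(13.4, -7.7)
  p2 <- pathcv_params(frames + matrix(shift, 6, 2, byrow = TRUE),
                      lam = p$lam)
  v1 <- path_cv(x, p)
  v2 <- path_cv(x + shift, p2)
  expect_equal(v1$s, v2$s)
  expect_equal(v1$z, v2$z)
})

test_that("z on reference frames equals the direct self-term sum", {
  set.seed(6)
  frames <- cbind(seq(0, 9, length.out = 8), rnorm(8, 0, 0.3))
  p <- pathcv_params(frames)
  for (i in c(2, 5, 7)) {
    msd <- vapply(seq_len(8), function(j)
      msd_aligned(frames[i, ], frames[j, ]), numeric(1))
    direct <- -log(sum(exp(-p$lam * msd))) / p$lam
    z <- path_cv(frames[i, ], p)$z
    expect_lt(abs(z - direct), 0.1 * max(abs(direct), 0.01))
  }
})

test_that("R and compiled path-cv evaluations agree", {
  set.seed(9)
  frames <- cbind(seq(0, 6, length.out = 7), rnorm(7, 0, 0.5))
  p <- pathcv_params(frames)
  for (i in 1:20) {
    x <- runif(2, -1, 7)
    cpp <- pathcv_eval_cpp(x, p$frames, p$lam)
    msd <- vapply(seq_len(7), function(j)
      msd_aligned(x, frames[j, ]), numeric(1))
    w <- exp(-p$lam * (msd - min(msd)))
    expect_equal(cpp$s, sum(seq_len(7) * w) / sum(w), tolerance = 1e-12)
    expect_equal(cpp$z, min(msd) - log(sum(w)) / p$lam, tolerance = 1e-12)
  }
})

test_that("progress rescale maps 1..N onto 0..s_max", {
  expect_equal(rescale_progress(1, 13), 0)
  expect_equal(rescale_progress(13, 13), 60)
  expect_equal(rescale_progress(7, 13), 30)
})
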