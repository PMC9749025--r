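paraboloid_grid <- function(n = 11) {
  ax <- seq(-1, 1, length.out = n)
  outer(ax, ax, function(x, y) x^2 + y^2)
}

test_that("find_minima: single well, symmetric double well, flat plateau", {
  m <- find_minima(paraboloid_grid(11))
  expect_equal(nrow(m), 1)
  expect_equal(unname(unlist(m[1, c("i", "j")])), c(6, 6))

  ax <- seq(-1.5, 1.5, length.out = 31)
  dw <- outer(ax, ax, function(x, y) (x^2 - 1)^2 + y^2)
  m2 <- find_minima(dw)
  expect_equal(nrow(m2), 2)
  expect_equal(m2$F[1], m2$F[2])

  flat <- matrix(1, 9, 9)
  expect_equal(nrow(find_minima(flat)), 1)
})

test_that("every reported minimum sits at or below its neighbourhood", {
  set.seed(33)
  F <- matrix(runif(100), 10, 10)
  m <- find_minima(F)
  for (r in seq_len(nrow(m))) {
    nb <- F[(m$i[r] - 1):(m$i[r] + 1), (m$j[r] - 1):(m$j[r] + 1)]
    expect_true(all(m$F[r] <= nb))
  }
})

test_that("flat grid path: max equals the flat value, Chebyshev length", {
  F <- matrix(2.5, 8, 6)
  r <- mfep_search(F, c(1, 1), c(8, 6))
  expect_equal(r$max_energy, 2.5)
  expect_equal(nrow(r$path), max(8 - 1, 6 - 1) + 1)
  r4 <- mfep_search(F, c(1, 1), c(8, 6), eight = FALSE)
  expect_equal(nrow(r4$path), (8 - 1) + (6 - 1) + 1)
})

test_that("two-channel grid routes through the lower saddle", {
  F <- matrix(0, 7, 7)
  F[4, ] <- 20
  F[4, 2] <- 4
  F[4, 6] <- 10
  r <- mfep_search(F, c(1, 4), c(7, 4))
  expect_equal(r$max_energy, 4)
  expect_true(any(r$path[, 1] == 4 & r$path[, 2] == 2))
  expect_false(any(r$path[, 1] == 4 & r$path[, 2] == 6))
})

test_that("search equals the exhaustive oracle on seeded 5x5 grids", {
  set.seed(55)
  for (i in 1:100) {
    F <- matrix(runif(25, 0, 10), 5, 5)
    ends <- sample(25, 2)
    start <- c((ends[1] - 1) %% 5 + 1, (ends[1] - 1) %/% 5 + 1)
    end <- c((ends[2] - 1) %% 5 + 1, (ends[2] - 1) %/% 5 + 1)
    a <- mfep_search(F, start, end)
    b <- mfep_exhaustive(F, start, end)
    expect_equal(a$max_energy, b$max_energy)
    expect_equal(a$sum_energy, b$sum_energy)
  }
})

test_that("no sampled random walk beats the optimum on 6x6 grids", {
  set.seed(77)
  for (i in 1:20) {
    F <- matrix(runif(36, 0, 10), 6, 6)
    opt <- mfep_search(F, c(1, 1), c(6, 6))
    for (w in 1:50) {
      # random monotone-ish simple path
      pos <- c(1, 1)
      path_max <- F[1, 1]
      path_sum <- F[1, 1]
      while (!all(pos == c(6, 6))) {
        step <- c(sample(0:1, 1), sample(0:1, 1))
        if (all(step == 0)) next
        pos <- pmin(pos + step, c(6, 6))
        path_max <- max(path_max, F[pos[1], pos[2]])
        path_sum <- path_sum + F[pos[1], pos[2]]
      }
      better <- path_max < opt$max_energy - 1e-12 ||
        (abs(path_max - opt$max_energy) < 1e-12 &&
         path_sum < opt$sum_energy - 1e-12)
      expect_false(better)
    }
  }
})

test_that("path structure: simple, 8-connected, correct endpoints", {
  set.seed(88)
  for (i in 1:10) {
    F <- matrix(runif(48, 0, 5), 8, 6)
    r <- mfep_search(F, c(2, 1), c(7, 6))
    expect_equal(unname(r$path[1, ]), c(2, 1))
    expect_equal(unname(r$path[nrow(r$path), ]), c(7, 6))
    expect_false(any(duplicated(r$path)))
    steps <- abs(diff(r$path))
    expect_true(all(steps <= 1) && all(rowSums(steps) >= 1))
  }
})

test_that("monotonicity under off-path and on-path perturbations", {
  set.seed(99)
  F <- matrix(runif(36, 1, 9), 6, 6)
  r <- mfep_search(F, c(1, 1), c(6, 6))
  on_path <- matrix(FALSE, 6, 6)
  on_path[r$path] <- TRUE
  off <- which(!on_path, arr.ind = TRUE)
  for (k in sample(nrow(off), 5)) {
    F2 <- F
    F2[off[k, 1], off[k, 2]] <- F2[off[k, 1], off[k, 2]] + 50
    r2 <- mfep_search(F2, c(1, 1), c(6, 6))
    expect_equal(r2$max_energy, r$max_energy)
    expect_equal(r2$sum_energy, r$sum_energy)
  }
  mid <- r$path[ceiling(nrow(r$path) / 2), ]
  F3 <- F
  F3[mid[1], mid[2]] <- F3[mid[1], mid[2]] + 50
  r3 <- mfep_search(F3, c(1, 1), c(6, 6))
  expect_gte(r3$max_energy, r$max_energy)
})

test_that("reversing the endpoints reverses the path", {
  set.seed(12)
  F <- matrix(runif(30, 0, 6), 6, 5)
  a <- mfep_search(F, c(1, 1), c(6, 5))
  b <- mfep_search(F, c(6, 5), c(1, 1))
  expect_equal(a$max_energy, b$max_energy)
  expect_equal(a$sum_energy, b$sum_energy)
})

test_that("masked grids report unreachable ends distinctly", {
  F <- matrix(1, 5, 5)
  F[, 3] <- NA
  r <- mfep_search(F, c(1, 1), c(5, 5))
  expect_false(r$reachable)
})

test_that("profiles along paths are normalized and consistent", {
  F <- matrix(0, 7, 7)
  F[4, ] <- 20
  F[4, 2] <- 4
  F[4, 6] <- 10
  r <- mfep_search(F, c(1, 4), c(7, 4))
  prof <- profile_along_path(F, r)
  expect_equal(range(prof$xi), c(0, 1))
  expect_equal(max(prof$F) + F[1, 4], r$max_energy)

  flat <- mfep_search(matrix(3, 5, 5), c(1, 1), c(5, 5))
  pf <- profile_along_path(matrix(3, 5, 5), flat)
  expect_true(all(pf$F == 0))

  ramp <- matrix(rep(0:4, each = 5), 5, 5)
  rr <- mfep_search(ramp, c(3, 1), c(3, 5))
  pr <- profile_along_path(ramp, rr)
  expect_true(all(diff(pr$F) >= 0))
  expect_equal(pr$F[nrow(pr)], 4)
})
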