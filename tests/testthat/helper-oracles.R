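# Independent reference implementations used across the suite.

# central finite-difference gradient check at seeded random interior points;
# returns the worst relative error
fd_gradient_error <- function(pot, n_points = 100, h = 1e-5, seed = 42,
                              margin = 0.5) {
  set.seed(seed)
  worst <- 0
  for (i in seq_len(n_points)) {
    x <- runif(pot$dim, pot$domain[1, ] + margin, pot$domain[2, ] - margin)
    g <- potential_gradient(pot, x)
    fd <- vapply(seq_len(pot$dim), function(d) {
      e <- numeric(pot$dim)
      e[d] <- h
      (potential_energy(pot, x + e) - potential_energy(pot, x - e)) / (2 * h)
    }, numeric(1))
    rel <- max(abs(g - fd)) / max(1e-8, max(abs(fd)))
    worst <- max(worst, rel)
  }
  worst
}

# plain-loop QuickBundles reference: recomputes every centroid from scratch
# at each step instead of keeping running sums
qb_reference <- function(streamlines, threshold, n_points = 12) {
  res <- lapply(streamlines, egressr::resample_streamline,
                n_points = n_points)
  members <- list()   # list of integer vectors
  flips <- list()     # matching flip flags
  centroid_of <- function(ids, fl) {
    acc <- 0
    for (k in seq_along(ids)) {
      s <- res[[ids[k]]]
      if (fl[k]) s <- s[n_points:1, , drop = FALSE]
      acc <- acc + s
    }
    acc / length(ids)
  }
  assignment <- integer(length(res))
  for (i in seq_along(res)) {
    s <- res[[i]]
    placed <- FALSE
    for (cid in seq_along(members)) {
      cen <- centroid_of(members[[cid]], flips[[cid]])
      direct <- mean(sqrt(rowSums((s - cen)^2)))
      flip <- mean(sqrt(rowSums((s[n_points:1, , drop = FALSE] - cen)^2)))
      if (min(direct, flip) < threshold) {
        members[[cid]] <- c(members[[cid]], i)
        flips[[cid]] <- c(flips[[cid]], flip < direct)
        assignment[i] <- cid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      members[[length(members) + 1]] <- i
      flips[[length(flips) + 1]] <- FALSE
      assignment[i] <- length(members)
    }
  }
  assignment
}

# brute-force Gaussian-sum bias (explicit double loop)
bias_brute_force <- function(points, ledger) {
  p <- ledger$params
  h <- ledger$hills
  out <- numeric(nrow(points))
  for (i in seq_len(nrow(points))) {
    acc <- 0
    for (k in seq_len(nrow(h))) {
      e <- -0.5 * ((points[i, 1] - h$s[k]) / p$sigma_s)^2
      if (ledger$ncv == 2) {
        e <- e - 0.5 * ((points[i, 2] - h$z[k]) / p$sigma_z)^2
      }
      acc <- acc + h$height[k] * exp(e)
    }
    out[i] <- acc
  }
  out
}

# default egress campaign pieces shared by pathfind/acceptance tests
campaign_fixture <- function(n_replicas = 50, base_seed = 1) {
  land <- make_egress_landscape(3, c(4, 6, 10), seed = 1)
  sim <- sim_config(dt = 0.01, scale = 0.6, n_steps = 2e6,
                    save_stride = 20, seed = base_seed)
  ratchet <- ratchet_params(k = 0.024, direction = c(1, 0),
                            origin = c(0, 0), target = 13, mode = "radial")
  stop_rule <- list(kind = "radius", offset = 12)
  trajs <- run_rpp_campaign(land, sim, ratchet, stop_rule, n_replicas)
  list(landscape = land, sim = sim, ratchet = ratchet,
       stop_rule = stop_rule, trajs = trajs)
}
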