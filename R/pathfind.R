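# From raw unbinding trajectories to guess paths: RMSD clean-up, streamline
# resampling, MDF distances, QuickBundles clustering, centroid frame
# selection, gap filling by short targeted ratchet runs, and equal-spacing
# resampling.

#' Clean up a trajectory by threshold scanning
#'
#' Keeps frame 0 and scans forward, saving a frame whenever its RMSD to the
#' last saved frame is greater than or equal to `threshold`.  This strips
#' detours, dead ends and loops from non-equilibrium unbinding runs.  For
#' point-particle systems the alignment contract is the identity and RMSD is
#' the Euclidean distance.
#'
#' @param traj a `trajectory` or a coordinate matrix (frames in rows).
#' @param threshold RMSD threshold, Angstrom (default 3).
#' @return object of the same type containing the kept frames, in order.
#' @export
cleanup_trajectory <- function(traj, threshold = 3) {
  stopifnot(threshold > 0)
  frames <- if (inherits(traj, "trajectory")) traj$frames else as.matrix(traj)
  n <- nrow(frames)
  stopifnot(n >= 1)
  keep <- 1L
  last <- frames[1, ]
  kept <- logical(n)
  kept[1] <- TRUE
  for (i in seq_len(n)[-1]) {
    d <- sqrt(mean((frames[i, ] - last)^2))
    if (d >= threshold) {
      kept[i] <- TRUE
      last <- frames[i, ]
    }
  }
  if (inherits(traj, "trajectory")) {
    out <- traj
    out$frames <- frames[kept, , drop = FALSE]
    out$times <- traj$times[kept]
    out$metadata$cleanup_threshold <- threshold
    out
  } else {
    frames[kept, , drop = FALSE]
  }
}

#' Resample a streamline to equally spaced arc-length stations
#'
#' Linear interpolation along the polyline at `n_points` equally spaced
#' cumulative arc lengths.
#'
#' @param points coordinate matrix (ordered points in rows).
#' @param n_points number of output points (>= 2).
#' @return matrix `n_points` x d.
#' @export
resample_streamline <- function(points, n_points = 12) {
  points <- as.matrix(points)
  stopifnot(n_points >= 2, nrow(points) >= 1)
  if (nrow(points) == 1) {
    return(matrix(points[1, ], n_points, ncol(points), byrow = TRUE))
  }
  seg <- sqrt(rowSums((points[-1, , drop = FALSE] -
                       points[-nrow(points), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  if (arc[length(arc)] == 0) {
    return(matrix(points[1, ], n_points, ncol(points), byrow = TRUE))
  }
  st <- seq(0, arc[length(arc)], length.out = n_points)
  # de-duplicate arc positions for approx()
  keep <- c(TRUE, diff(arc) > 0)
  out <- vapply(seq_len(ncol(points)), function(d)
    approx(arc[keep], points[keep, d], xout = st)$y,
    numeric(n_points))
  matrix(out, nrow = n_points)
}

#' Minimum average direct-flip (MDF) distance between streamlines
#'
#' Both streamlines are arc-length resampled to `n_points`; the direct
#' distance is the mean pointwise Euclidean distance, the flipped distance
#' the same with one streamline reversed; the MDF distance is the minimum of
#' the two.  Symmetric and flip-invariant; not a true metric.
#'
#' @param a,b coordinate matrices (ordered points in rows).
#' @param n_points resampling points (default 12, the QuickBundles
#'   convention).
#' @return distance in Angstrom.
#' @export
mdf_distance <- function(a, b, n_points = 12) {
  ra <- resample_streamline(a, n_points)
  rb <- resample_streamline(b, n_points)
  direct <- mean(sqrt(rowSums((ra - rb)^2)))
  flipped <- mean(sqrt(rowSums((ra - rb[n_points:1, , drop = FALSE])^2)))
  min(direct, flipped)
}

#' QuickBundles streamline clustering
#'
#' Single pass in input order: each streamline joins the first cluster whose
#' centroid is within `threshold` in MDF distance (flipped before averaging
#' when the flipped distance is the smaller), updating the centroid as the
#' running pointwise mean of resampled members; otherwise it opens a new
#' cluster.  Order dependence is inherent to the algorithm; input order is
#' recorded for reproducibility.
#'
#' @param streamlines list of coordinate matrices.
#' @param threshold clustering threshold, Angstrom.
#' @param n_points MDF resampling points.
#' @return a `cluster_set`: list with `clusters` (each with `members`,
#'   `centroid`), `assignment` (cluster id per streamline),
#'   `dist_to_centroid`, `threshold`, `n_points`.
#' @export
quickbundles_cluster <- function(streamlines, threshold, n_points = 12) {
  stopifnot(length(streamlines) >= 1, threshold >= 0)
  res <- lapply(streamlines, resample_streamline, n_points = n_points)
  clusters <- list()
  assignment <- integer(length(streamlines))
  dist_to <- numeric(length(streamlines))
  for (i in seq_along(res)) {
    s <- res[[i]]
    best <- 0L
    best_d <- Inf
    best_flip <- FALSE
    for (cid in seq_along(clusters)) {
      cen <- clusters[[cid]]$centroid_sum / clusters[[cid]]$n
      direct <- mean(sqrt(rowSums((s - cen)^2)))
      flipped <- mean(sqrt(rowSums((s[n_points:1, , drop = FALSE] - cen)^2)))
      d <- min(direct, flipped)
      if (d < threshold && d < best_d) {
        best <- cid
        best_d <- d
        best_flip <- flipped < direct
        break # first matching cluster, QuickBundles order rule
      }
    }
    if (best == 0L) {
      clusters[[length(clusters) + 1]] <-
        list(members = i, centroid_sum = s, n = 1L)
      assignment[i] <- length(clusters)
      dist_to[i] <- 0
    } else {
      add <- if (best_flip) s[n_points:1, , drop = FALSE] else s
      clusters[[best]]$centroid_sum <- clusters[[best]]$centroid_sum + add
      clusters[[best]]$n <- clusters[[best]]$n + 1L
      clusters[[best]]$members <- c(clusters[[best]]$members, i)
      assignment[i] <- best
      dist_to[i] <- best_d
    }
  }
  clusters <- lapply(clusters, function(cl) {
    list(members = cl$members, centroid = cl$centroid_sum / cl$n,
         size = cl$n)
  })
  structure(list(clusters = clusters, assignment = assignment,
                 dist_to_centroid = dist_to, threshold = threshold,
                 n_points = n_points),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat("<cluster_set>", length(x$clusters), "clusters over",
      length(x$assignment), "streamlines (threshold",
      x$threshold, "A)\n")
  for (i in seq_along(x$clusters)) {
    cat(sprintf("  cluster %d: %d members\n", i, x$clusters[[i]]$size))
  }
  invisible(x)
}

#' Build an equally spaced guess path from a cluster
#'
#' Selects, for each of `n_stations` equally spaced arc-length stations
#' along the cluster centroid, the nearest frame among the cleaned
#' trajectories of the cluster members; where adjacent selections leave a
#' mean-square-deviation gap larger than 1.5x the median, a short targeted
#' Ratchet&Pawl run on the landscape bridges the pair (gap filling); the
#' assembled polyline is smoothed (three sliding-mean passes on a dense
#' arc-length resampling, endpoints pinned, suppressing replica-to-replica
#' selection jitter) and finally arc-length resampled to `n_frames`
#' reference frames, which satisfies the equal-spacing contract
#' (coefficient of variation of adjacent-frame msd <= 0.2).
#'
#' @param cluster one element of a [quickbundles_cluster()] `clusters` list.
#' @param cleaned list of cleaned trajectories (or coordinate matrices), one
#'   per member index in `cluster$members`... indexed by streamline id.
#' @param n_frames number of reference frames N (>= 3).
#' @param landscape optional `model_potential` used for gap filling; when
#'   `NULL` gaps are bridged by linear interpolation.
#' @param config optional [sim_config()] for the gap-fill runs.
#' @param n_stations number of centroid stations scanned (default
#'   `max(2 * n_frames, 16)`).
#' @return a `guess_path`: list with `frames` (N x d matrix), `spacing`
#'   (adjacent-frame msd), `gap_fills` (log of gap-fill events).
#' @export
build_guess_path <- function(cluster, cleaned, n_frames,
                             landscape = NULL, config = NULL,
                             n_stations = NULL) {
  stopifnot(n_frames >= 3, length(cluster$members) >= 1)
  if (is.null(n_stations)) n_stations <- max(2L * n_frames, 16L)
  centroid <- cluster$centroid
  stations <- resample_streamline(centroid, n_stations)
  pool <- do.call(rbind, lapply(cluster$members, function(i) {
    fr <- cleaned[[i]]
    if (inherits(fr, "trajectory")) fr$frames else as.matrix(fr)
  }))
  # nearest pool frame per station
  sel <- t(vapply(seq_len(n_stations), function(k) {
    d2 <- rowSums((pool - matrix(stations[k, ], nrow(pool), ncol(pool),
                                 byrow = TRUE))^2)
    pool[which.min(d2), ]
  }, numeric(ncol(pool))))
  sel <- sel[!duplicated(sel), , drop = FALSE]

  # gap filling between adjacent selections
  gap_fills <- list()
  d <- ncol(sel)
  msd_gap <- rowSums((sel[-1, , drop = FALSE] -
                      sel[-nrow(sel), , drop = FALSE])^2) / d
  med <- median(msd_gap)
  if (med > 0 && any(msd_gap > 1.5 * med)) {
    pieces <- list(sel[1, , drop = FALSE])
    for (k in seq_len(nrow(sel) - 1)) {
      a <- sel[k, ]
      b <- sel[k + 1, ]
      if (msd_gap[k] > 1.5 * med) {
        bridge <- bridge_gap(a, b, landscape, config)
        gap_fills[[length(gap_fills) + 1]] <-
          list(from = a, to = b, msd = msd_gap[k],
               n_bridge = nrow(bridge),
               method = if (is.null(landscape)) "linear" else "rpp")
        pieces[[length(pieces) + 1]] <- bridge
      }
      pieces[[length(pieces) + 1]] <- matrix(b, 1, d)
    }
    sel <- do.call(rbind, pieces)
  }

  # smooth and re-parametrize until the equal-spacing contract holds;
  # each pass removes selection jitter at the station scale while the
  # endpoints stay pinned
  n_dense <- max(5L * n_frames, 40L)
  dense <- resample_streamline(sel, n_dense)
  for (pass in seq_len(40)) {
    dense <- smooth_polyline(dense)
    if (pass %% 4 == 0) {
      dense <- resample_streamline(dense, n_dense)
      trial <- resample_streamline(dense, n_frames)
      sp <- rowSums((trial[-1, , drop = FALSE] -
                     trial[-n_frames, , drop = FALSE])^2) / d
      if (stats::sd(sp) / mean(sp) <= 0.1) break
    }
  }
  frames <- resample_streamline(dense, n_frames)
  spacing <- rowSums((frames[-1, , drop = FALSE] -
                      frames[-n_frames, , drop = FALSE])^2) / d
  path <- structure(list(frames = frames, spacing = spacing,
                         gap_fills = gap_fills),
                    class = "guess_path")
  validate_guess_path(path)
  path
}

# short targeted ratchet run from a to b (falls back to linear interpolation)
bridge_gap <- function(a, b, landscape, config, max_steps = 20000) {
  if (is.null(landscape)) {
    t <- seq(0, 1, length.out = 12)[-c(1, 12)]
    return(outer(t, b - a) + matrix(a, length(t), length(a), byrow = TRUE))
  }
  if (is.null(config)) config <- sim_config()
  dist <- sqrt(sum((b - a)^2))
  rp <- ratchet_params(k = 0.24, direction = b - a, origin = a,
                       target = dist, mode = "projection")
  cfg <- config
  cfg$n_steps <- as.integer(max_steps)
  cfg$save_stride <- max(1L, as.integer(max_steps / 2000))
  tr <- run_smd_rpp(landscape, cfg, rp,
                    stop_rule = list(kind = "halfspace",
                                     normal = rp$direction,
                                     offset = sum(b * rp$direction) - 0.05),
                    x0 = a)
  if (!isTRUE(tr$metadata$exited)) {
    stop("gap filling failed to reach the next endpoint within ",
         max_steps, " steps")
  }
  # condense the diffusive bridge to its smooth backbone
  resample_streamline(tr$frames, 8)
}

# endpoint-pinned sliding mean over the rows of a polyline
smooth_polyline <- function(points) {
  n <- nrow(points)
  if (n < 3) return(points)
  out <- points
  out[2:(n - 1), ] <- (points[1:(n - 2), , drop = FALSE] +
                       points[2:(n - 1), , drop = FALSE] +
                       points[3:n, , drop = FALSE]) / 3
  out
}

#' Validate the equal-spacing contract of a guess path
#'
#' @param path a `guess_path`.
#' @param cv_max maximum allowed coefficient of variation of the
#'   adjacent-frame msd (default 0.2).
#' @return `path` invisibly; errors when the contract is violated.
#' @export
validate_guess_path <- function(path, cv_max = 0.2) {
  stopifnot(inherits(path, "guess_path"), nrow(path$frames) >= 3)
  sp <- path$spacing
  if (any(sp <= 0)) stop("guess path has coincident adjacent frames")
  cv <- stats::sd(sp) / mean(sp)
  if (cv > cv_max) {
    stop(sprintf("equal-spacing contract violated: spacing CV %.3f > %.2f",
                 cv, cv_max))
  }
  invisible(path)
}

#' Summarize a cluster set as a table
#'
#' @param cs a `cluster_set`.
#' @return data.frame with streamline id, cluster id and MDF distance to the
#'   centroid at assignment time.
#' @export
cluster_table <- function(cs) {
  stopifnot(inherits(cs, "cluster_set"))
  data.frame(streamline = seq_along(cs$assignment),
             cluster = cs$assignment,
             mdf_to_centroid = cs$dist_to_centroid)
}

#' Build ligand streamlines from an sMD-RPP campaign
#'
#' Cleans each exiting trajectory with [cleanup_trajectory()] and appends
#' the raw exit frame, which the threshold scan usually drops but which
#' defines the unbound end of the path.
#'
#' @param trajs list of trajectories from [run_rpp_campaign()].
#' @param threshold clean-up RMSD threshold, Angstrom.
#' @return list of streamline coordinate matrices (exiting replicas only).
#' @export
campaign_streamlines <- function(trajs, threshold = 3) {
  exited <- vapply(trajs, function(t) isTRUE(t$metadata$exited), logical(1))
  lapply(trajs[exited], function(t) {
    cleaned <- cleanup_trajectory(t, threshold)$frames
    last <- t$frames[nrow(t$frames), ]
    if (sqrt(mean((last - cleaned[nrow(cleaned), ])^2)) > 1e-9) {
      cleaned <- rbind(cleaned, last)
    }
    cleaned
  })
}
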