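# Minima and minimum free energy paths on gridded free-energy surfaces.
# The MFEP objective is lexicographic: minimise the maximum node energy
# along the path (MEPSA-style node-by-node flooding), then the sum of node
# energies among paths achieving it; remaining exact ties are broken by
# node index order, making the result deterministic.

#' Locate local minima on a gridded FES
#'
#' Interior nodes that are less than or equal to all their 8-connected
#' neighbours; plateaus of equal-valued touching minima are merged into one
#' minimum represented by the lowest linear index.
#'
#' @param fes a `fes_grid` (2-CV) or a numeric matrix of energies.
#' @return data.frame with `i`, `j` (grid indices), `s`, `z` (if axes are
#'   known), `F`, and `basin` label.
#' @export
find_minima <- function(fes) {
  F <- if (inherits(fes, "fes_grid")) fes$F else as.matrix(fes)
  nr <- nrow(F); nc <- ncol(F)
  stopifnot(nr >= 3, nc >= 3)
  is_min <- matrix(FALSE, nr, nc)
  for (i in 2:(nr - 1)) {
    for (j in 2:(nc - 1)) {
      nb <- F[(i - 1):(i + 1), (j - 1):(j + 1)]
      is_min[i, j] <- all(F[i, j] <= nb)
    }
  }
  idx <- which(is_min, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(data.frame(i = integer(0), j = integer(0), F = numeric(0),
                      basin = integer(0)))
  }
  # merge equal-valued 8-connected plateaus
  lin <- (idx[, 2] - 1) * nr + idx[, 1]
  basin <- seq_along(lin)
  repeat {
    changed <- FALSE
    for (a in seq_along(lin)) for (b in seq_along(lin)) {
      if (basin[a] != basin[b] &&
          abs(idx[a, 1] - idx[b, 1]) <= 1 &&
          abs(idx[a, 2] - idx[b, 2]) <= 1 &&
          F[idx[a, 1], idx[a, 2]] == F[idx[b, 1], idx[b, 2]]) {
        basin[basin == max(basin[a], basin[b])] <- min(basin[a], basin[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  rep_rows <- vapply(unique(basin), function(b) min(which(basin == b)),
                     integer(1))
  out <- data.frame(i = idx[rep_rows, 1], j = idx[rep_rows, 2],
                    F = F[idx[rep_rows, , drop = FALSE]],
                    basin = seq_along(rep_rows))
  if (inherits(fes, "fes_grid") && fes$ncv == 2) {
    out$s <- fes$s[out$i]
    out$z <- fes$z[out$j]
  }
  out[order(out$F), , drop = FALSE]
}

#' Minimum free energy path between two grid nodes
#'
#' Returns the 8-connected (or 4-connected) simple path minimising,
#' lexicographically, (1) the maximum node energy and (2) the sum of node
#' energies.  Masked nodes (`NA`/`Inf`) are impassable; an unreachable end
#' is reported distinctly.
#'
#' @param fes a `fes_grid` (2-CV) or numeric matrix.
#' @param start,end nodes as `c(i, j)` grid indices.
#' @param eight logical: allow diagonal moves (default TRUE).
#' @return an `mfep_result`: list with `path` (matrix of i, j), `profile`
#'   (energy along the path), `max_energy`, `sum_energy`, `reachable`.
#' @export
mfep_search <- function(fes, start, end, eight = TRUE) {
  F <- if (inherits(fes, "fes_grid")) fes$F else as.matrix(fes)
  nr <- nrow(F)
  s_lin <- (start[2] - 1) * nr + start[1] - 1L
  e_lin <- (end[2] - 1) * nr + end[1] - 1L
  stopifnot(s_lin != e_lin, start[1] >= 1, start[1] <= nr,
            end[1] >= 1, end[1] <= nr,
            start[2] >= 1, start[2] <= ncol(F),
            end[2] >= 1, end[2] <= ncol(F))
  Fm <- F
  Fm[!is.finite(Fm)] <- NA_real_
  res <- mfep_search_cpp(Fm, as.integer(s_lin), as.integer(e_lin), eight)
  if (!res$reachable) {
    return(structure(list(reachable = FALSE), class = "mfep_result"))
  }
  lin <- res$path - 1L
  path <- cbind(i = lin %% nr + 1L, j = lin %/% nr + 1L)
  profile <- F[path]
  structure(list(path = path, profile = profile,
                 max_energy = res$max_energy,
                 sum_energy = res$sum_energy,
                 reachable = TRUE),
            class = "mfep_result")
}

#' Exhaustive-enumeration MFEP oracle
#'
#' Branch-and-bound enumeration of all simple paths (exact for the
#' lexicographic (max, sum) objective; requires non-negative energies).
#' Intended as an independent reference for small grids.
#'
#' @inheritParams mfep_search
#' @return list with `path` (i, j matrix), `max_energy`, `sum_energy`.
#' @export
mfep_exhaustive <- function(fes, start, end, eight = TRUE) {
  F <- if (inherits(fes, "fes_grid")) fes$F else as.matrix(fes)
  nr <- nrow(F)
  s_lin <- (start[2] - 1) * nr + start[1] - 1L
  e_lin <- (end[2] - 1) * nr + end[1] - 1L
  res <- mfep_exhaustive_cpp(F, as.integer(s_lin), as.integer(e_lin), eight)
  lin <- res$path - 1L
  list(path = cbind(i = lin %% nr + 1L, j = lin %/% nr + 1L),
       max_energy = res$max_energy, sum_energy = res$sum_energy)
}

#' Normalized energy profile along an MFEP
#'
#' Energy at each path node against cumulative arc length rescaled to
#' [0, 1], shifted so the profile starts at zero (bound-state alignment).
#'
#' @param fes a `fes_grid` or matrix (must match the search grid).
#' @param result an `mfep_result`.
#' @return data.frame with `xi` (normalized coordinate), `F` (kcal/mol,
#'   start at 0) and grid indices.
#' @export
profile_along_path <- function(fes, result) {
  stopifnot(inherits(result, "mfep_result"), isTRUE(result$reachable))
  F <- if (inherits(fes, "fes_grid")) fes$F else as.matrix(fes)
  path <- result$path
  if (inherits(fes, "fes_grid") && fes$ncv == 2) {
    xy <- cbind(fes$s[path[, 1]], fes$z[path[, 2]])
  } else {
    xy <- path
  }
  seg <- sqrt(rowSums((xy[-1, , drop = FALSE] -
                       xy[-nrow(xy), , drop = FALSE])^2))
  arc <- c(0, cumsum(seg))
  xi <- if (max(arc) > 0) arc / max(arc) else
    seq(0, 1, length.out = nrow(path))
  prof <- F[path]
  data.frame(xi = xi, F = prof - prof[1], i = path[, 1], j = path[, 2])
}

#' Mean path-deviation of an MFEP in CV space
#'
#' Report comparing a guess path (which lies at Z = 0 by construction) with
#' the MFEP: the mean |Z| of the MFEP nodes.
#'
#' @param fes a 2-CV `fes_grid`.
#' @param result an `mfep_result` on that grid.
#' @return mean absolute Z of the path nodes.
#' @export
mfep_guess_deviation <- function(fes, result) {
  stopifnot(inherits(fes, "fes_grid"), fes$ncv == 2,
            isTRUE(result$reachable))
  mean(abs(fes$z[result$path[, 2]]))
}
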