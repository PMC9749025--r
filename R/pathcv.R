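# Path collective variables after Branduardi-style definitions: progress
# S in [1, N] and deviation Z (A^2) relative to N reference frames, built
# from exponentially weighted mean square deviations with smoothing
# parameter lambda.  Log-sum-exp evaluation keeps both finite whenever any
# msd is finite; analytic gradients support biasing.

#' Path-CV parameters
#'
#' @param reference a `guess_path` or an N x d matrix of reference frames
#'   (N >= 3).
#' @param lam smoothing parameter lambda, 1/A^2; `NULL` auto-tunes via
#'   [auto_lambda()].
#' @param align alignment contract: function mapping (x, ref_frame) to the
#'   aligned x.  Identity for point-particle systems; the hook exists so a
#'   superposition step can honour a Calpha-alignment convention.
#' @return a `pathcv_params`.
#' @export
pathcv_params <- function(reference, lam = NULL, align = NULL) {
  frames <- if (inherits(reference, "guess_path")) reference$frames else
    as.matrix(reference)
  stopifnot(nrow(frames) >= 3)
  if (is.null(lam)) lam <- auto_lambda(frames)
  stopifnot(lam > 0)
  structure(list(frames = frames, lam = lam, align = align,
                 n = nrow(frames)),
            class = "pathcv_params")
}

#' Mean square deviation after alignment
#'
#' @param x coordinates.
#' @param ref_frame reference coordinates of the same length.
#' @param params optional `pathcv_params` providing the alignment contract.
#' @return msd in A^2 (mean over coordinates of squared deviations).
#' @export
msd_aligned <- function(x, ref_frame, params = NULL) {
  if (length(x) != length(ref_frame)) stop("dimension mismatch")
  if (!is.null(params) && !is.null(params$align)) {
    x <- params$align(x, ref_frame)
  }
  mean((x - ref_frame)^2)
}

#' Auto-tune the path-CV smoothing parameter
#'
#' lambda = 2.3 / median adjacent-frame msd, the standard heuristic that
#' keeps neighbouring frame weights distinguishable (roughly e^-2.3 ~ 0.1
#' between adjacent frames).
#'
#' @param reference a `guess_path` or matrix of reference frames.
#' @return lambda in 1/A^2.
#' @export
auto_lambda <- function(reference) {
  frames <- if (inherits(reference, "guess_path")) reference$frames else
    as.matrix(reference)
  n <- nrow(frames)
  stopifnot(n >= 2)
  msd <- rowSums((frames[-1, , drop = FALSE] -
                  frames[-n, , drop = FALSE])^2) / ncol(frames)
  m <- median(msd)
  if (m <= 0) stop("degenerate reference: identical adjacent frames ",
                   "(equal-spacing contract violated upstream)")
  2.3 / m
}

#' Evaluate the path collective variables
#'
#' w_i proportional to exp(-lambda msd(x, X_i));
#' s = sum i w_i / sum w_i; z = -(1/lambda) log sum_i exp(-lambda msd_i).
#'
#' @param x coordinates.
#' @param params a [pathcv_params()].
#' @return list with `s` (dimensionless, in [1, N]), `z` (A^2) and the
#'   normalized per-frame weights `w`.
#' @export
path_cv <- function(x, params) {
  stopifnot(inherits(params, "pathcv_params"),
            length(x) == ncol(params$frames))
  if (!is.null(params$align)) {
    msd <- vapply(seq_len(params$n), function(i)
      msd_aligned(x, params$frames[i, ], params), numeric(1))
    lam <- params$lam
    m <- min(msd)
    w <- exp(-lam * (msd - m))
    sw <- sum(w)
    return(list(s = sum(seq_len(params$n) * w) / sw,
                z = m - log(sw) / lam, w = w / sw))
  }
  out <- pathcv_eval_cpp(as.numeric(x), params$frames, params$lam)
  msd <- rowSums((params$frames -
                  matrix(x, params$n, ncol(params$frames), byrow = TRUE))^2) /
         ncol(params$frames)
  m <- min(msd)
  w <- exp(-params$lam * (msd - m))
  list(s = out$s, z = out$z, w = w / sum(w))
}

#' Analytic gradients of the path collective variables
#'
#' d s/d x = -lambda sum_i (i - s) w_i d msd_i/d x and
#' d z/d x = sum_i w_i d msd_i/d x, with d msd_i/d x = 2 (x - X_i)/d.
#'
#' @inheritParams path_cv
#' @return list with gradients `ds` and `dz` (vectors of length d).
#' @export
path_cv_gradient <- function(x, params) {
  stopifnot(inherits(params, "pathcv_params"),
            length(x) == ncol(params$frames))
  out <- pathcv_eval_cpp(as.numeric(x), params$frames, params$lam)
  list(ds = out$ds, dz = out$dz)
}

#' Affine presentation rescale of the progress variable
#'
#' S runs 1..N internally; published surfaces often display the bound state
#' at 0 and the unbound state at some `s_max` (e.g. 60).  This is a labeled
#' presentation transform only.
#'
#' @param s internal progress values in [1, N].
#' @param n number of reference frames N.
#' @param s_max display value of the unbound end (default 60).
#' @return rescaled values in [0, s_max].
#' @export
rescale_progress <- function(s, n, s_max = 60) {
  (s - 1) / (n - 1) * s_max
}
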