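# Plain-text interchange formats: multi-model XYZ for trajectories and
# guess paths, PLUMED-dialect COLVAR/HILLS whitespace tables, and the
# three-column ASCII FES grid.  All values are written in package units
# (kcal/mol, Angstrom, ps); headers record the convention.

#' Write coordinates as multi-model XYZ
#'
#' One XYZ model per frame (or per streamline); missing third coordinates
#' are padded with zero.  The comment line carries `time= <ps>` for
#' trajectories or `model= <i>`.
#'
#' @param x a `trajectory`, a coordinate matrix, or a list of matrices
#'   (one model per element, e.g. streamlines or guess-path frames).
#' @param path destination file.
#' @param element dummy element symbol.
#' @return `path` invisibly.
#' @export
write_xyz <- function(x, path, element = "C") {
  models <- NULL
  comments <- NULL
  if (inherits(x, "trajectory")) {
    models <- lapply(seq_len(nrow(x$frames)), function(i)
      matrix(x$frames[i, ], 1))
    comments <- sprintf("time= %.6f", x$times)
  } else if (is.list(x)) {
    models <- lapply(x, as.matrix)
    comments <- sprintf("model= %d", seq_along(x))
  } else {
    models <- lapply(seq_len(nrow(x)), function(i) matrix(x[i, ], 1))
    comments <- sprintf("model= %d", seq_len(nrow(x)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(models)) {
    m <- models[[i]]
    if (ncol(m) < 3) m <- cbind(m, matrix(0, nrow(m), 3 - ncol(m)))
    writeLines(as.character(nrow(m)), con)
    writeLines(comments[i], con)
    writeLines(sprintf("%s %.10g %.10g %.10g", element,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-model XYZ file
#'
#' @param path file written by [write_xyz()] (or any plain XYZ).
#' @param dim number of coordinate columns to keep (trailing zero-padded
#'   columns are dropped when `dim` is smaller than 3).
#' @return list with `models` (list of matrices) and `comments`.
#' @export
read_xyz <- function(path, dim = 3) {
  lines <- readLines(path, warn = FALSE)
  models <- list()
  comments <- character(0)
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comments <- c(comments, lines[i + 1])
    block <- lines[(i + 2):(i + 1 + n)]
    fields <- do.call(rbind, strsplit(trimws(block), "\\s+"))
    m <- matrix(as.numeric(fields[, 2:4]), ncol = 3)
    models[[length(models) + 1]] <- m[, seq_len(dim), drop = FALSE]
    i <- i + 2 + n
  }
  list(models = models, comments = comments)
}

#' Write a COLVAR-dialect table
#'
#' Whitespace table with a `#! FIELDS ...` header naming the columns.
#'
#' @param df data.frame of numeric columns.
#' @param path destination file.
#' @return `path` invisibly.
#' @export
write_colvar <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  writeLines(do.call(sprintf, c(
    list(paste(rep("%.10g", ncol(df)), collapse = " ")),
    lapply(df, as.numeric))), con)
  invisible(path)
}

#' Read a COLVAR/HILLS-dialect table
#'
#' Tolerates comment lines; column names come from the `#! FIELDS` header.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_colvar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#! FIELDS", lines, value = TRUE)
  if (length(hdr) == 0) stop("no '#! FIELDS' header in ", path)
  fields <- strsplit(trimws(sub("^#! FIELDS", "", hdr[1])), "\\s+")[[1]]
  data <- lines[!grepl("^#", lines)]
  data <- data[nzchar(trimws(data))]
  if (length(data) == 0) {
    df <- as.data.frame(matrix(numeric(0), 0, length(fields)))
    names(df) <- fields
    return(df)
  }
  mat <- do.call(rbind, strsplit(trimws(data), "\\s+"))
  df <- as.data.frame(matrix(as.numeric(mat), nrow = nrow(mat)))
  names(df) <- fields
  df
}

#' Write a hills ledger as a HILLS-dialect file
#'
#' Header `#! FIELDS time s [z] sigma_s [sigma_z] height biasf`; the
#' write-read round trip is exact at the printed precision.
#'
#' @param ledger a `hills_ledger`.
#' @param path destination file.
#' @return `path` invisibly.
#' @export
write_hills <- function(ledger, path) {
  stopifnot(inherits(ledger, "hills_ledger"))
  p <- ledger$params
  h <- ledger$hills
  df <- data.frame(time = h$time, s = h$s)
  if (ledger$ncv == 2) {
    df$z <- h$z
    df$sigma_s <- p$sigma_s
    df$sigma_z <- p$sigma_z
  } else {
    df$sigma_s <- p$sigma_s
  }
  df$height <- h$height
  df$biasf <- p$bias_factor
  write_colvar(df, path)
}

#' Read a HILLS-dialect file into a hills ledger
#'
#' @param path file written by [write_hills()] or PLUMED-style.
#' @param temperature Kelvin (ledger metadata; not stored in the file).
#' @return a `hills_ledger`.
#' @export
read_hills <- function(path, temperature = 300) {
  df <- read_colvar(path)
  if (nrow(df) == 0) stop("empty HILLS file: ", path)
  ncv <- if ("z" %in% names(df)) 2L else 1L
  params <- metad_params(
    omega0 = max(df$height), sigma_s = df$sigma_s[1],
    sigma_z = if (ncv == 2) df$sigma_z[1] else 1,
    bias_factor = df$biasf[1], temperature = temperature)
  hills <- cbind(df$time, df$s, if (ncv == 2) df$z else 0, df$height)
  new_hills_ledger(hills, params, ncv)
}

#' Write a FES grid as three-column ASCII
#'
#' Columns `s z F` (or `s F` for one CV) with a `#! FIELDS` header.
#'
#' @param fes a `fes_grid`.
#' @param path destination file.
#' @return `path` invisibly.
#' @export
write_fes <- function(fes, path) {
  stopifnot(inherits(fes, "fes_grid"))
  if (fes$ncv == 1) {
    df <- data.frame(s = fes$s, F = fes$F)
  } else {
    g <- expand.grid(s = fes$s, z = fes$z)
    df <- data.frame(s = g$s, z = g$z, F = as.numeric(fes$F))
  }
  write_colvar(df, path)
}

#' Read a FES grid file
#'
#' @param path file written by [write_fes()].
#' @return a `fes_grid` (without metadynamics parameters).
#' @export
read_fes <- function(path) {
  df <- read_colvar(path)
  if (!"z" %in% names(df)) {
    out <- list(s = df$s, F = df$F, params = NULL, ncv = 1L)
  } else {
    s <- sort(unique(df$s))
    z <- sort(unique(df$z))
    F <- matrix(NA_real_, length(s), length(z))
    F[cbind(match(df$s, s), match(df$z, z))] <- df$F
    out <- list(s = s, z = z, F = F, params = NULL, ncv = 2L)
  }
  structure(out, class = "fes_grid")
}
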