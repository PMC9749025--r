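# Flat key=value configuration files.  Values are parsed as numeric when
# possible, as logical for true/false, and as comma-separated numeric vectors.

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment.  Numeric-looking
#' values (including comma-separated vectors) are coerced to numeric,
#' `true`/`false` to logical, everything else stays character.
#'
#' @param path file path.
#' @return named list.
#' @export
read_config <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) {
      stop("malformed config line (no '='): ", ln)
    }
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    out[[key]] <- parse_config_value(val)
  }
  out
}

parse_config_value <- function(val) {
  if (tolower(val) %in% c("true", "false")) {
    return(tolower(val) == "true")
  }
  parts <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
  num <- suppressWarnings(as.numeric(parts))
  if (length(num) > 0 && !anyNA(num)) {
    return(num)
  }
  val
}

#' Write a flat key=value configuration file
#'
#' @param config named list; numeric vectors are written comma-separated with
#'   full precision.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  fmt <- function(v) {
    if (is.logical(v)) return(tolower(as.character(v)))
    if (is.numeric(v)) return(paste(format(v, digits = 17), collapse = ", "))
    as.character(v)
  }
  lines <- vapply(names(config), function(k) {
    paste0(k, " = ", fmt(config[[k]]))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
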