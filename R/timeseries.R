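#' Construct a validated time series
#'
#' A `ccm_series` is an equally spaced, complete sequence of real
#' observations. Equal spacing is assumed rather than checked (beyond the
#' optional time column handled by [read_series()]); missing or non-finite
#' values are rejected outright, because state-space reconstruction requires
#' complete data sampled at regular intervals. If your data contain gaps,
#' interpolate them upstream with a method appropriate to the system before
#' loading — no imputation is performed here.
#'
#' @param values numeric vector of observations, length >= 2, all finite.
#' @param name label used in direction strings and plots.
#' @param step sampling interval, informational only (the algorithm works in
#'   index units).
#' @return a numeric vector of class `ccm_series` with attributes `name` and
#'   `step`.
#' @examples
#' s <- ccm_series(sin(1:50), name = "x")
#' length(s)
#' @export
ccm_series <- function(values, name = "series", step = 1) {
  values <- as.numeric(values)
  if (length(values) < 2)
    stop("a time series needs at least 2 observations, got ", length(values))
  if (anyNA(values) || !all(is.finite(values)))
    stop("time series '", name, "' contains missing or non-finite values; ",
         "interpolate or filter upstream before loading")
  structure(values, name = as.character(name)[1], step = step,
            class = "ccm_series")
}

#' @export
print.ccm_series <- function(x, ...) {
  cat(sprintf("<ccm_series '%s'> %d observations, step = %s\n",
              attr(x, "name"), length(x), format(attr(x, "step"))))
  print(utils::head(as.numeric(x), 8))
  if (length(x) > 8) cat("...\n")
  invisible(x)
}

series_name <- function(x) {
  nm <- attr(x, "name")
  if (is.null(nm)) "series" else nm
}

#' Read time series from delimited text
#'
#' Reads a CSV or TSV file with one column per variable, an optional header
#' row, and an optional leading time column. The time column is detected as a
#' first column forming an arithmetic progression; it is dropped from the
#' data and its common difference recorded as the sampling step.
#'
#' @param path file path; the delimiter is sniffed (tab if the first line
#'   contains tabs, otherwise comma) unless `sep` is given.
#' @param columns which variable columns to keep: character names or numeric
#'   positions (1-based, counted after removal of any time column). `NULL`
#'   keeps all.
#' @param sep field separator, or `NULL` to sniff.
#' @param header `NA` to auto-detect (non-numeric first row), or TRUE/FALSE.
#' @return a named list of [ccm_series()] objects, all the same length.
#' @export
read_series <- function(path, columns = NULL, sep = NULL, header = NA) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", first)) "\t" else ","
  if (is.na(header)) {
    fields <- strsplit(first, sep, fixed = TRUE)[[1]]
    header <- any(is.na(suppressWarnings(as.numeric(fields))))
  }
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE)
  if (!header) names(df) <- paste0("V", seq_along(df))
  num <- vapply(df, is.numeric, logical(1))
  if (!all(num))
    stop("non-numeric column(s) in ", path, ": ",
         paste(names(df)[!num], collapse = ", "))

  step <- 1
  if (ncol(df) >= 3 && nrow(df) >= 3) {
    d <- diff(df[[1]])
    if (length(unique(round(d, 10))) == 1 && d[1] != 0) {
      step <- d[1]
      df <- df[-1]
    }
  }
  if (!is.null(columns)) {
    if (is.character(columns)) {
      missing_cols <- setdiff(columns, names(df))
      if (length(missing_cols))
        stop("column(s) not found: ", paste(missing_cols, collapse = ", "))
      df <- df[columns]
    } else {
      df <- df[as.integer(columns)]
    }
  }
  if (ncol(df) < 1) stop("no usable data columns in ", path)
  out <- lapply(names(df), function(nm) ccm_series(df[[nm]], nm, step))
  names(out) <- names(df)
  out
}

#' Thin a series by keeping every k-th observation
#'
#' Retains every k-th observation starting from the first, so a series of
#' length N becomes one of length `ceiling(N / k)`. Used to study how
#' cross-map convergence degrades as sampling gets sparser: a 60-point series
#' thinned by k = 2 and k = 3 yields 30 and 20 observations.
#'
#' @param x a [ccm_series()] or numeric vector.
#' @param k positive integer thinning factor; `k = 1` is the identity.
#' @return a `ccm_series` of the retained observations.
#' @export
thin <- function(x, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  kept <- as.numeric(x)[seq(1L, length(x), by = k)]
  step <- attr(x, "step")
  ccm_series(kept, name = series_name(x),
             step = if (is.null(step)) k else step * k)
}
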