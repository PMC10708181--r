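#' Geometric mean
#'
#' @param x positive numeric vector.
#' @param na.rm drop missing values before averaging.
#' @return exp(mean(log(x))).
#' @keywords internal
geomean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

## INFO-level logging: plain message(), so callers can sink it to a file
log_info <- function(...) {
  message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_columns <- function(dt, cols, what) {
  missing <- setdiff(cols, names(dt))
  if (length(missing) > 0L) {
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}

as_dt <- function(x) {
  if (data.table::is.data.table(x)) data.table::copy(x)
  else data.table::as.data.table(x)
}
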