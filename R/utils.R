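`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Reporting-style rounding (0.885 -> 0.89 at 2 d.p.), as opposed to base R's
#' round-half-even. Used wherever values are rounded to a table's printed
#' precision.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small epsilon guards against 0.005 stored as 0.00499999...
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

stop_ctx <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "edaresonance_error")))
}

assert_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop_ctx("%s is missing required column(s): %s", what,
             paste(miss, collapse = ", "), class = "missing_column_error")
  }
  invisible(df)
}

# binary codings are stored as integer 0/1; accept yes/no and logicals on input
as_binary <- function(x, what = "coding") {
  if (is.character(x)) {
    lx <- tolower(trimws(x))
    if (!all(lx %in% c("yes", "no"))) {
      stop_ctx("%s must be yes/no, got: %s", what,
               paste(unique(setdiff(lx, c("yes", "no"))), collapse = ", "),
               class = "validation_error")
    }
    return(as.integer(lx == "yes"))
  }
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    if (any(is.na(x)) || !all(x %in% c(0, 1))) {
      stop_ctx("%s must be binary 0/1 with no missing values", what,
               class = "validation_error")
    }
    return(as.integer(x))
  }
  stop_ctx("%s has unsupported type %s", what, class(x)[1],
           class = "validation_error")
}

# draw a sub-seed deterministically from a master seed (kept well below 2^31)
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}
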