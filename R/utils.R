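#' @keywords internal
"_PACKAGE"

## Classed conditions so callers can distinguish rejection causes.
cbs_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "cbs_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Parse timestamps into UTC POSIXct
#'
#' All lifecycle arithmetic in the package is done in UTC. Accepts POSIXct
#' (re-expressed in UTC), `Date`, or ISO-8601 character strings
#' (`"2021-03-01T06:00:00Z"` or `"2021-03-01 06:00:00"`).
#'
#' @param x timestamps to coerce.
#' @return POSIXct vector with `tzone = "UTC"`.
#' @export
as_utc <- function(x) {
  if (inherits(x, "POSIXct")) {
    attr(x, "tzone") <- "UTC"
    return(x)
  }
  if (inherits(x, "Date")) {
    return(as.POSIXct(as.character(x), tz = "UTC"))
  }
  if (is.character(x)) {
    y <- gsub("T", " ", x, fixed = TRUE)
    y <- sub("Z$", "", y)
    out <- as.POSIXct(y, tz = "UTC",
                      tryFormats = c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                     "%Y-%m-%d"))
    return(out)
  }
  if (is.numeric(x)) {
    return(as.POSIXct(x, origin = "1970-01-01", tz = "UTC"))
  }
  cbs_stop("cannot interpret timestamps", "cbs_bad_input")
}

fmt_utc <- function(t) {
  ifelse(is.na(t), NA_character_,
         format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
}

hours_between <- function(from, to) as.numeric(difftime(to, from, units = "hours"))

#' Ratio of counts with integer-percent rendering
#'
#' All system-attribute metrics are ratios of counts rendered as integer
#' percentages under a single round-half-up rule (92.5 renders as 93).
#' A zero denominator yields a typed null (`NA` percent and fraction)
#' rather than an error, so degenerate ledgers propagate nulls instead of
#' dividing by zero.
#'
#' @param numerator,denominator non-negative counts, `numerator <= denominator`.
#' @return object of class `cbs_pct`: list with `numerator`, `denominator`,
#'   `fraction` and `percent` (integer, round-half-up; `NA` when the
#'   denominator is zero).
#' @examples
#' pct(115, 138)  # renders 83
#' pct(0, 0)      # null percent
#' @export
pct <- function(numerator, denominator) {
  if (length(numerator) != 1L || length(denominator) != 1L ||
      is.na(numerator) || is.na(denominator) ||
      numerator < 0 || denominator < 0) {
    cbs_stop("pct() needs single non-negative counts", "cbs_bad_input")
  }
  if (numerator > denominator) {
    cbs_stop(sprintf("numerator (%s) exceeds denominator (%s)",
                     numerator, denominator), "cbs_bad_input")
  }
  if (denominator == 0) {
    out <- list(numerator = 0L, denominator = 0L,
                fraction = NA_real_, percent = NA_integer_)
  } else {
    out <- list(numerator = as.integer(numerator),
                denominator = as.integer(denominator),
                fraction = numerator / denominator,
                percent = round_half_up_pct(numerator, denominator))
  }
  structure(out, class = "cbs_pct")
}

## Exact round-half-up of 100*n/d using integer arithmetic when possible.
round_half_up_pct <- function(n, d) {
  if (n == as.integer(n) && d == as.integer(d) && d <= 1e7) {
    return(as.integer((200 * n + d) %/% (2 * d)))
  }
  as.integer(floor(100 * n / d + 0.5))
}

#' @export
print.cbs_pct <- function(x, ...) {
  if (is.na(x$percent)) {
    cat(sprintf("--%% (%d/%d; empty denominator)\n", x$numerator, x$denominator))
  } else {
    cat(sprintf("%d%% (%d/%d)\n", x$percent, x$numerator, x$denominator))
  }
  invisible(x)
}

pct_or_na <- function(p) if (is.null(p)) NA_integer_ else p$percent

## deterministic zero-padded ids
make_ids <- function(prefix, n, width = 5) {
  if (n == 0) return(character(0))
  sprintf(paste0(prefix, "%0", width, "d"), seq_len(n))
}
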