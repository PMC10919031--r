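#' Define the coded-SMS dialect
#'
#' Volunteers report via a simple coded SMS from non-smart phones: the bare
#' digits of a configured signal code constitute a signal, a single fixed
#' token (default `"0"`) is the weekly zero report, and anything else is
#' classified malformed. Classification is total: every payload maps to
#' exactly one of signal/zero/malformed, and malformed is a classification,
#' never an error. The true platform grammar is richer; this dialect is a
#' documented synthetic stand-in (`synthetic_standin = TRUE`).
#'
#' @param allowed_codes integer vector of configured signal codes.
#' @param zero_token payload string denoting the weekly zero report; must not
#'   parse as a signal code.
#' @return object of class `cbs_dialect`.
#' @export
dialect_config <- function(allowed_codes = configured_codes(default_ccd_config()),
                           zero_token = "0") {
  allowed_codes <- as.integer(allowed_codes)
  if (any(is.na(allowed_codes)) || any(allowed_codes <= 0)) {
    cbs_stop("allowed_codes must be positive integers", "cbs_bad_config")
  }
  tok <- trimws(zero_token)
  if (grepl("^[0-9]+$", tok) && as.integer(tok) %in% allowed_codes) {
    cbs_stop("zero_token must not collide with a signal code", "cbs_bad_config")
  }
  structure(list(allowed_codes = allowed_codes, zero_token = tok,
                 synthetic_standin = TRUE),
            class = "cbs_dialect")
}

classify_payload <- function(payload, dialect) {
  p <- trimws(payload)
  status <- rep("malformed", length(p))
  code <- rep(NA_integer_, length(p))
  is_zero <- p == dialect$zero_token
  status[is_zero] <- "zero"
  numeric_like <- !is_zero & grepl("^[0-9]{1,9}$", p)
  parsed <- suppressWarnings(as.integer(p[numeric_like]))
  ok <- parsed %in% dialect$allowed_codes
  idx <- which(numeric_like)[ok]
  status[idx] <- "signal"
  code[idx] <- parsed[ok]
  list(parse_status = status, code = code)
}

#' Parse one coded volunteer submission
#'
#' Pure function of (payload, dialect): the same payload always yields the
#' same classification.
#'
#' @param payload raw SMS text.
#' @param received_at receipt timestamp.
#' @param volunteer_id sender.
#' @param dialect a `cbs_dialect`.
#' @param report_id optional id (one is generated if omitted).
#' @return one-row report data.frame.
#' @export
parse_report <- function(payload, received_at, volunteer_id,
                         dialect = dialect_config(), report_id = NULL) {
  cl <- classify_payload(payload, dialect)
  data.frame(
    report_id = if (is.null(report_id))
      sprintf("R-%s-%s", volunteer_id, format(as_utc(received_at), "%Y%m%d%H%M%S"))
      else report_id,
    volunteer_id = volunteer_id,
    received_at = as_utc(received_at),
    payload = payload,
    parse_status = cl$parse_status,
    code = cl$code,
    stringsAsFactors = FALSE)
}

#' Parse a table of raw submissions
#'
#' @param raw data.frame with columns `volunteer_id`, `received_at`,
#'   `payload` (and optionally `report_id`).
#' @param dialect a `cbs_dialect`.
#' @return reports data.frame in ledger schema, ordered by
#'   (received_at, volunteer_id, report_id).
#' @export
parse_reports <- function(raw, dialect = dialect_config()) {
  if (nrow(raw) == 0) return(empty_reports())
  cl <- classify_payload(raw$payload, dialect)
  out <- data.frame(
    report_id = if ("report_id" %in% names(raw)) raw$report_id
      else make_ids("R", nrow(raw)),
    volunteer_id = raw$volunteer_id,
    received_at = as_utc(raw$received_at),
    payload = raw$payload,
    parse_status = cl$parse_status,
    code = cl$code,
    stringsAsFactors = FALSE)
  out[order(out$received_at, out$volunteer_id, out$report_id), , drop = FALSE]
}

#' Share of reports sent in the correct format
#'
#' Data-quality metric: reports parsed as a signal or a zero report,
#' compared with all reports sent (malformed included in the denominator).
#'
#' @param reports reports data.frame (ledger schema).
#' @return list with `numerator`, `denominator` and `percent`
#'   (a [pct()] object; null percent on an empty input).
#' @export
correct_format_rate <- function(reports) {
  den <- nrow(reports)
  num <- sum(reports$parse_status != "malformed")
  list(numerator = num, denominator = den, percent = pct(num, den))
}

#' ISO-8601 week label for timestamps
#'
#' @param t timestamps.
#' @return character vector like `"2021-W07"` (ISO year and week).
#' @export
iso_week <- function(t) format(as_utc(t), "%G-W%V", tz = "UTC")

#' Enumerate the ISO weeks covering a period
#'
#' @param period_start,period_end period bounds.
#' @return data.frame with `week` (label), `week_start`, `week_end`
#'   (Monday 00:00 inclusive to next Monday 00:00 exclusive, UTC).
#' @export
week_calendar <- function(period_start, period_end) {
  ps <- as_utc(period_start); pe <- as_utc(period_end)
  d0 <- as.Date(ps); d1 <- as.Date(pe)
  monday0 <- d0 - (as.integer(format(d0, "%u")) - 1L)
  mondays <- seq(monday0, d1, by = "7 days")
  ws <- as.POSIXct(paste(mondays, "00:00:00"), tz = "UTC")
  ws <- ws[ws < pe]
  data.frame(week = iso_week(ws), week_start = ws,
             week_end = ws + 7 * 24 * 3600, stringsAsFactors = FALSE)
}

#' Weekly reporting completeness
#'
#' For each week of the calendar, the fraction of active volunteers that
#' submitted at least one report (of any parse status) in that week. A
#' volunteer enters a week's denominator only when the active interval
#' overlaps the week; weeks with zero active volunteers are excluded from
#' the period average, which is the unweighted mean of the weekly fractions.
#'
#' @param reports reports data.frame.
#' @param roster volunteers data.frame (ledger schema, with
#'   `active_from`/`active_to`).
#' @param calendar output of [week_calendar()].
#' @return list with `weekly` (data.frame: week, n_reported, n_active,
#'   fraction) and `average` (`NA` if no week has active volunteers).
#' @export
weekly_completeness <- function(reports, roster, calendar) {
  n_wk <- nrow(calendar)
  n_reported <- integer(n_wk); n_active <- integer(n_wk)
  if (nrow(reports)) {
    rep_week <- iso_week(reports$received_at)
  } else rep_week <- character(0)
  for (i in seq_len(n_wk)) {
    act <- roster$active_from < calendar$week_end[i] &
           roster$active_to > calendar$week_start[i]
    n_active[i] <- sum(act)
    in_week <- rep_week == calendar$week[i]
    reporters <- unique(reports$volunteer_id[in_week])
    n_reported[i] <- length(intersect(reporters, roster$volunteer_id[act]))
  }
  frac <- ifelse(n_active > 0, n_reported / pmax(n_active, 1L), NA_real_)
  weekly <- data.frame(week = calendar$week, n_reported = n_reported,
                       n_active = n_active, fraction = frac,
                       stringsAsFactors = FALSE)
  avg <- if (any(n_active > 0)) mean(frac[n_active > 0]) else NA_real_
  list(weekly = weekly, average = avg)
}
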