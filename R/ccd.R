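#' Define a community case definition (CCD)
#'
#' A CCD pairs a coded health signal that lay volunteers can recognise with
#' the community alert threshold that turns signals into a health event. A
#' threshold of 1 means every kept signal is its own event; a threshold
#' above 1 is a spatiotemporal cluster rule and must carry both a temporal
#' window and a spatial radius.
#'
#' @param code small positive integer signal code sent by SMS.
#' @param name short label for the health signal.
#' @param case_definition free-text sign/symptom rule.
#' @param target_events free-text public-health events of concern.
#' @param threshold_count reports needed to trigger an event (>= 1).
#' @param window_hours temporal window of the cluster rule; `NA` for
#'   single-report CCDs.
#' @param radius_km spatial radius of the cluster rule; `NA` for
#'   single-report CCDs.
#' @param valid_from,valid_to validity interval of this definition (config
#'   versioning: definitions can be revised mid-programme, e.g. when a
#'   COVID-19 case definition is realigned). `NA` = open-ended.
#' @return a one-row data.frame of class `cbs_ccd`.
#' @export
ccd_definition <- function(code, name, case_definition = "", target_events = "",
                           threshold_count = 1L, window_hours = NA_real_,
                           radius_km = NA_real_,
                           valid_from = NA, valid_to = NA) {
  code <- as.integer(code)
  threshold_count <- as.integer(threshold_count)
  if (is.na(code) || code <= 0) cbs_stop("code must be a positive integer", "cbs_bad_config")
  if (is.na(threshold_count) || threshold_count < 1) {
    cbs_stop("threshold_count must be >= 1", "cbs_bad_config")
  }
  has_win <- !is.na(window_hours); has_rad <- !is.na(radius_km)
  if (threshold_count > 1 && !(has_win && has_rad)) {
    cbs_stop("cluster CCDs (threshold_count > 1) need window_hours and radius_km",
             "cbs_bad_config")
  }
  if (threshold_count == 1 && (has_win || has_rad)) {
    cbs_stop("single-report CCDs must not carry window_hours/radius_km",
             "cbs_bad_config")
  }
  if (has_win && window_hours <= 0) cbs_stop("window_hours must be positive", "cbs_bad_config")
  if (has_rad && radius_km <= 0) cbs_stop("radius_km must be positive", "cbs_bad_config")
  out <- data.frame(
    code = code, name = name, case_definition = case_definition,
    target_events = target_events, threshold_count = threshold_count,
    window_hours = as.numeric(window_hours), radius_km = as.numeric(radius_km),
    valid_from = if (all(is.na(valid_from))) as.POSIXct(NA, tz = "UTC") else as_utc(valid_from),
    valid_to = if (all(is.na(valid_to))) as.POSIXct(NA, tz = "UTC") else as_utc(valid_to),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cbs_ccd", "data.frame")
  out
}

#' Assemble a CCD configuration
#'
#' @param ... `ccd_definition()` rows (or data.frames of them).
#' @return data.frame of class `cbs_ccd_config`.
#' @export
ccd_config <- function(...) {
  defs <- list(...)
  if (length(defs) == 0) cbs_stop("empty CCD configuration", "cbs_bad_config")
  cfg <- do.call(rbind, lapply(defs, as.data.frame))
  ## codes must be unique among definitions whose validity intervals overlap
  for (cd in unique(cfg$code)) {
    rows <- cfg[cfg$code == cd, , drop = FALSE]
    if (nrow(rows) > 1) {
      for (i in seq_len(nrow(rows) - 1)) {
        for (j in (i + 1):nrow(rows)) {
          a0 <- rows$valid_from[i]; a1 <- rows$valid_to[i]
          b0 <- rows$valid_from[j]; b1 <- rows$valid_to[j]
          disjoint <- (!is.na(a1) && !is.na(b0) && a1 <= b0) ||
                      (!is.na(b1) && !is.na(a0) && b1 <= a0)
          if (!disjoint) {
            cbs_stop(sprintf("code %d has overlapping definitions", cd),
                     "cbs_bad_config")
          }
        }
      }
    }
  }
  class(cfg) <- c("cbs_ccd_config", "data.frame")
  cfg
}

#' The Somaliland 2021 CCD configuration
#'
#' Four signals: acute diarrhoeal disease (code 2, cluster threshold of
#' 5 reports within 7 days in 20 km), fever and rash (code 4), fever with
#' cough/difficulty breathing and tiredness (code 9), and a cluster of
#' unusual illness or death (code 14), each of the latter three alerting on
#' a single report.
#'
#' @return a `cbs_ccd_config`.
#' @export
default_ccd_config <- function() {
  ccd_config(
    ccd_definition(2L, "Acute diarrhoeal disease (ADD)",
                   "Diarrhoea as 3 or more loose or liquid stools over 24 h",
                   "Cholera", threshold_count = 5L,
                   window_hours = 168, radius_km = 20),
    ccd_definition(4L, "Fever and rash",
                   "Fever and rash, often with runny nose, tiredness, headache",
                   "Measles, chicken pox", threshold_count = 1L),
    ccd_definition(9L, "Fever, cough/difficulty breathing, tiredness",
                   "Three or more of: cough, difficulty breathing, fever, runny nose, tiredness, headache, feeling unwell, sore throat, diarrhoea, loss of smell or taste",
                   "COVID-19", threshold_count = 1L),
    ccd_definition(14L, "Cluster of unusual illness or death",
                   "Three or more people suddenly sick or dead with the same signs in the same village area within two weeks",
                   "Unknown emerging event", threshold_count = 1L)
  )
}

#' Look up the CCD active for a code at a timestamp
#'
#' @param config a `cbs_ccd_config`.
#' @param code signal code.
#' @param at timestamp (defaults select the open-ended definition).
#' @return one-row data.frame, or `NULL` when no definition is active.
#' @export
active_ccd <- function(config, code, at = NULL) {
  rows <- config[config$code == code, , drop = FALSE]
  if (nrow(rows) == 0) return(NULL)
  if (is.null(at)) {
    open <- rows[is.na(rows$valid_to), , drop = FALSE]
    return(if (nrow(open)) open[1, , drop = FALSE] else rows[nrow(rows), , drop = FALSE])
  }
  at <- as_utc(at)
  ok <- (is.na(rows$valid_from) | rows$valid_from <= at) &
        (is.na(rows$valid_to) | at < rows$valid_to)
  if (!any(ok)) return(NULL)
  rows[which(ok)[1], , drop = FALSE]
}

configured_codes <- function(config) sort(unique(config$code))

#' Write / read a CCD configuration as JSON
#'
#' @param config a `cbs_ccd_config`.
#' @param path file path.
#' @return `read_ccd_config` returns a `cbs_ccd_config`.
#' @export
write_ccd_config <- function(config, path) {
  df <- as.data.frame(config)
  df$valid_from <- fmt_utc(df$valid_from)
  df$valid_to <- fmt_utc(df$valid_to)
  jsonlite::write_json(df, path, auto_unbox = FALSE, digits = NA, na = "null",
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ccd_config
#' @export
read_ccd_config <- function(path) {
  df <- jsonlite::read_json(path, simplifyVector = TRUE)
  defs <- lapply(seq_len(nrow(df)), function(i) {
    ccd_definition(df$code[i], df$name[i], df$case_definition[i],
                   df$target_events[i], df$threshold_count[i],
                   if (is.null(df$window_hours)) NA else df$window_hours[i],
                   if (is.null(df$radius_km)) NA else df$radius_km[i],
                   valid_from = if (is.null(df$valid_from)) NA else df$valid_from[i],
                   valid_to = if (is.null(df$valid_to)) NA else df$valid_to[i])
  })
  do.call(ccd_config, defs)
}
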