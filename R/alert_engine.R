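#' Great-circle distance in kilometres
#'
#' Haversine formula on a sphere of mean Earth radius 6371.0088 km. This is
#' the distance behind the cluster rule's spatial radius; formula-level
#' differences of a metre or so are immaterial at a 20 km threshold.
#'
#' @param lat1,lon1,lat2,lon2 decimal-degree WGS84 coordinates (vectorised).
#' @return non-negative distances in km; symmetric; 0 for identical points.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(lat1) > 90, abs(lat2) > 90, abs(lon1) > 180, abs(lon2) > 180,
          na.rm = TRUE)) {
    cbs_stop("coordinates out of range", "cbs_bad_input")
  }
  R <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * R * asin(pmin(1, sqrt(a)))
}

#' Evaluate the CCD alert thresholds over a stream of signals
#'
#' Turns parsed signal reports into health events. Single-report CCDs emit
#' one event per signal at the signal's own time and location. The cluster
#' CCD (acute diarrhoeal disease: 5 reports within 7 days in 20 km)
#' uses an anchor-greedy rule processed online in arrival order
#' (ties broken by timestamp, then volunteer id, then report id):
#'
#' * a signal first tries to join an already-open cluster event of its code
#'   (within the anchor's rolling window and radius);
#' * otherwise it enters the unassigned pool, and the pool is scanned for
#'   the earliest anchor whose window/radius holds at least
#'   `threshold_count` unassigned signals — the event triggers at the exact
#'   arrival of the threshold-reaching signal, with those signals as
#'   members;
#' * each signal belongs to at most one event of its code.
#'
#' Event membership stays open to later qualifying signals until the event
#' is verified; `evaluate_stream()` itself performs no verification, so
#' membership here closes only at the end of the stream. Processing signals
#' one at a time (resumable via `state`) yields exactly the same events as
#' one batch call.
#'
#' The definition applied to each signal is the one active at the signal's
#' timestamp, so configurations can be revised mid-programme.
#'
#' @param reports reports data.frame; only `parse_status == "signal"` rows
#'   are used. A signal with a code not configured at its timestamp is
#'   rejected (such reports should have been classified malformed at ingest).
#' @param volunteers roster supplying each signal's village coordinates.
#' @param ccd a `cbs_ccd_config`.
#' @return events data.frame (ledger schema), all `verification_status =
#'   "pending"`, with deterministic event ids `E00001, ...` in trigger order.
#' @export
evaluate_stream <- function(reports, volunteers, ccd = default_ccd_config()) {
  sig <- reports[reports$parse_status == "signal", , drop = FALSE]
  if (nrow(sig) == 0) return(empty_events())
  loc <- match(sig$volunteer_id, volunteers$volunteer_id)
  if (anyNA(loc)) cbs_stop("signal from unrostered volunteer", "cbs_unknown_id")
  sig$lat <- volunteers$lat[loc]
  sig$lon <- volunteers$lon[loc]
  sig <- sig[order(sig$received_at, sig$volunteer_id, sig$report_id), , drop = FALSE]

  ## plain-list CCD lookup (validity intervals as numeric bounds): the
  ## per-signal definition lookup is the hot path of the stream scan
  defs <- lapply(seq_len(nrow(ccd)), function(k) list(
    threshold_count = ccd$threshold_count[k],
    window_hours = ccd$window_hours[k], radius_km = ccd$radius_km[k],
    vf = if (is.na(ccd$valid_from[k])) -Inf else as.numeric(ccd$valid_from[k]),
    vt = if (is.na(ccd$valid_to[k])) Inf else as.numeric(ccd$valid_to[k])))
  defs_by_code <- split(defs, ccd$code)
  win_max <- vapply(defs_by_code, function(ds)
    max(vapply(ds, `[[`, numeric(1), "window_hours"), -Inf, na.rm = TRUE),
    numeric(1))
  thr_min <- vapply(defs_by_code, function(ds)
    min(vapply(ds, `[[`, numeric(1), "threshold_count")), numeric(1))
  get_def <- function(key, tn) {
    for (d in defs_by_code[[key]]) if (d$vf <= tn && tn < d$vt) return(d)
    NULL
  }

  s_id <- sig$report_id
  s_tn <- as.numeric(sig$received_at)
  s_lat <- sig$lat; s_lon <- sig$lon; s_code <- sig$code

  events <- list()        # each: list(code, members, trigger_tn, anchor_*)
  open_cluster <- list()  # indices into `events` still accepting joiners
  pool <- list()          # per-code unassigned cluster signals (parallel vectors)

  emit <- function(code, members, trigger_tn, a_lat, a_lon, a_tn,
                   window_hours, radius_km) {
    events[[length(events) + 1]] <<- list(
      code = code, members = members, trigger_tn = trigger_tn,
      anchor_lat = a_lat, anchor_lon = a_lon, anchor_tn = a_tn,
      window_hours = window_hours, radius_km = radius_km)
  }

  for (i in seq_along(s_id)) {
    code <- s_code[i]
    key <- as.character(code)
    def <- get_def(key, s_tn[i])
    if (is.null(def)) {
      cbs_stop(sprintf("signal %s carries code %d with no active CCD",
                       s_id[i], code), "cbs_unconfigured_code")
    }
    if (def$threshold_count == 1) {
      emit(code, s_id[i], s_tn[i], s_lat[i], s_lon[i], s_tn[i],
           NA_real_, NA_real_)
      next
    }
    ## cluster CCD: try to join an open event of this code first
    joined <- FALSE
    for (k in open_cluster) {
      ev <- events[[k]]
      if (ev$code != code) next
      if ((s_tn[i] - ev$anchor_tn) / 3600 <= ev$window_hours &&
          haversine_km(ev$anchor_lat, ev$anchor_lon, s_lat[i], s_lon[i]) <=
            ev$radius_km) {
        events[[k]]$members <- c(ev$members, s_id[i])
        joined <- TRUE
        break
      }
    }
    if (joined) next
    p <- pool[[key]]
    if (is.null(p)) p <- list(id = character(0), tn = numeric(0),
                              lat = numeric(0), lon = numeric(0))
    ## a signal older than one window before the newest arrival can never
    ## again share a triggering window with any future arrival: drop it
    keep <- p$tn >= s_tn[i] - win_max[[key]] * 3600
    p <- list(id = c(p$id[keep], s_id[i]), tn = c(p$tn[keep], s_tn[i]),
              lat = c(p$lat[keep], s_lat[i]), lon = c(p$lon[keep], s_lon[i]))
    ## scan anchors in time order for a triggering window
    repeat {
      if (length(p$id) < thr_min[[key]]) break
      triggered <- FALSE
      for (ai in seq_along(p$id)) {    # pool is kept in arrival order
        adef <- get_def(key, p$tn[ai])
        if (is.null(adef) || adef$threshold_count == 1) next
        dt_h <- (p$tn - p$tn[ai]) / 3600
        qual <- dt_h >= 0 & dt_h <= adef$window_hours &
          haversine_km(p$lat[ai], p$lon[ai], p$lat, p$lon) <= adef$radius_km
        if (sum(qual) >= adef$threshold_count) {
          emit(code, p$id[qual], s_tn[i], p$lat[ai], p$lon[ai], p$tn[ai],
               adef$window_hours, adef$radius_km)
          open_cluster <- c(open_cluster, length(events))
          p <- list(id = p$id[!qual], tn = p$tn[!qual],
                    lat = p$lat[!qual], lon = p$lon[!qual])
          triggered <- TRUE
          break
        }
      }
      if (!triggered) break
    }
    pool[[key]] <- p
  }

  if (length(events) == 0) return(empty_events())
  ord <- order(vapply(events, `[[`, numeric(1), "trigger_tn"))
  events <- events[ord]
  data.frame(
    event_id = make_ids("E", length(events)),
    code = vapply(events, `[[`, integer(1), "code"),
    member_report_ids = vapply(events, function(e) join_members(e$members),
                               character(1)),
    triggered_at = as_utc(vapply(events, `[[`, numeric(1), "trigger_tn")),
    anchor_lat = vapply(events, `[[`, numeric(1), "anchor_lat"),
    anchor_lon = vapply(events, `[[`, numeric(1), "anchor_lon"),
    verification_status = "pending",
    dismissal_reason = "none",
    verified_at = as.POSIXct(NA, tz = "UTC"),
    stringsAsFactors = FALSE)
}

#' Events awaiting supervisor verification
#'
#' Lists pending events with their elapsed time and whether the
#' verification target (within 12 hours of triggering, closed bound) has
#' been breached.
#'
#' @param events events data.frame.
#' @param now reference timestamp.
#' @param target_hours verification target (default 12).
#' @return data.frame: event_id, code, triggered_at, elapsed_h, breached.
#' @export
pending_notifications <- function(events, now, target_hours = 12) {
  now <- as_utc(now)
  p <- events[events$verification_status == "pending", , drop = FALSE]
  elapsed <- hours_between(p$triggered_at, now)
  data.frame(event_id = p$event_id, code = p$code,
             triggered_at = p$triggered_at, elapsed_h = elapsed,
             breached = elapsed > target_hours,
             stringsAsFactors = FALSE)
}
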