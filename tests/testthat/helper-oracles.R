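## Independent oracles and generators used across the suite. These re-derive
## results with different code paths (loops over raw tables, geosphere
## distances, exhaustive window scans) and must stay independent of the
## package internals they check.

## spherical law of cosines -- second distance formula
law_of_cosines_km <- function(lat1, lon1, lat2, lon2) {
  R <- 6371.0088
  to_rad <- pi / 180
  ca <- sin(lat1 * to_rad) * sin(lat2 * to_rad) +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * cos((lon2 - lon1) * to_rad)
  R * acos(pmin(1, pmax(-1, ca)))
}

## brute-force recount of ledger summary counts by row-wise loops
oracle_recount <- function(ledger) {
  r <- ledger$reports; e <- ledger$events; a <- ledger$alerts
  cnt <- list(n_reports = 0L, n_correct_format = 0L, n_signals_sent = 0L,
              n_events = nrow(e), n_events_kept = 0L, n_events_dismissed = 0L,
              n_events_pending = 0L, n_signals_verified = 0L,
              n_signals_kept = 0L, n_alerts_escalated = nrow(a),
              n_alerts_closed = 0L, n_dismissed_by_authorities = 0L,
              n_documented = 0L, n_action_taken = 0L, n_lab_confirmed = 0L,
              n_verified_within_12h = 0L, n_verified_within_24h = 0L,
              n_closed_within_48h = 0L)
  for (i in seq_len(nrow(r))) {
    cnt$n_reports <- cnt$n_reports + 1L
    if (r$parse_status[i] != "malformed") cnt$n_correct_format <- cnt$n_correct_format + 1L
    if (r$parse_status[i] == "signal") cnt$n_signals_sent <- cnt$n_signals_sent + 1L
  }
  for (i in seq_len(nrow(e))) {
    st <- e$verification_status[i]
    nmem <- length(strsplit(e$member_report_ids[i], ";", fixed = TRUE)[[1]])
    if (st == "kept") {
      cnt$n_events_kept <- cnt$n_events_kept + 1L
      cnt$n_signals_kept <- cnt$n_signals_kept + nmem
    }
    if (st == "dismissed") cnt$n_events_dismissed <- cnt$n_events_dismissed + 1L
    if (st == "pending") cnt$n_events_pending <- cnt$n_events_pending + 1L
    if (st != "pending") {
      cnt$n_signals_verified <- cnt$n_signals_verified + nmem
      dh <- as.numeric(difftime(e$verified_at[i], e$triggered_at[i], units = "hours"))
      if (dh <= 12) cnt$n_verified_within_12h <- cnt$n_verified_within_12h + 1L
      if (dh <= 24) cnt$n_verified_within_24h <- cnt$n_verified_within_24h + 1L
    }
  }
  for (i in seq_len(nrow(a))) {
    if (a$status[i] %in% c("closed", "dismissed_by_authorities")) {
      cnt$n_alerts_closed <- cnt$n_alerts_closed + 1L
      dh <- as.numeric(difftime(a$closed_at[i], a$escalated_at[i], units = "hours"))
      if (dh <= 48) cnt$n_closed_within_48h <- cnt$n_closed_within_48h + 1L
      if (a$documented[i]) cnt$n_documented <- cnt$n_documented + 1L
      if (a$action_taken[i]) cnt$n_action_taken <- cnt$n_action_taken + 1L
      if (a$lab_confirmed[i]) cnt$n_lab_confirmed <- cnt$n_lab_confirmed + 1L
    }
    if (a$status[i] == "dismissed_by_authorities") {
      cnt$n_dismissed_by_authorities <- cnt$n_dismissed_by_authorities + 1L
    }
  }
  cnt
}

## exhaustive anchor-greedy cluster detector over a signal table with
## explicit lat/lon columns; processes arrivals one at a time, scanning all
## unassigned signals as candidate anchors and all (anchor, member) pairs.
oracle_cluster_events <- function(sig, threshold = 5, window_h = 168,
                                  radius_km = 20) {
  ord <- order(sig$received_at, sig$volunteer_id, sig$report_id)
  sig <- sig[ord, , drop = FALSE]
  n <- nrow(sig)
  D <- geosphere::distm(cbind(sig$lon, sig$lat),
                        fun = function(a, b)
                          geosphere::distHaversine(a, b, r = 6371008.8)) / 1000
  dist_km <- function(i, j) D[i, j]
  assigned <- rep(NA_integer_, n)     # event index per signal
  events <- list()                    # anchor index, member indices, trigger
  for (k in seq_len(n)) {
    tk <- as.numeric(sig$received_at[k])
    ## join the earliest open event whose anchor window/radius admits k
    joined <- FALSE
    for (ei in seq_along(events)) {
      anc <- events[[ei]]$anchor
      if ((tk - as.numeric(sig$received_at[anc])) / 3600 <= window_h &&
          dist_km(anc, k) <= radius_km) {
        events[[ei]]$members <- c(events[[ei]]$members, k)
        assigned[k] <- ei
        joined <- TRUE
        break
      }
    }
    if (joined) next
    repeat {
      un <- which(is.na(assigned) & seq_len(n) <= k)
      fired <- FALSE
      for (anc in un) {   # candidate anchors in arrival order
        qual <- un[vapply(un, function(u) {
          dt <- (as.numeric(sig$received_at[u]) -
                 as.numeric(sig$received_at[anc])) / 3600
          dt >= 0 && dt <= window_h && dist_km(anc, u) <= radius_km
        }, logical(1))]
        if (length(qual) >= threshold) {
          events[[length(events) + 1]] <- list(anchor = anc, members = qual,
                                               trigger = sig$received_at[k])
          assigned[qual] <- length(events)
          fired <- TRUE
          break
        }
      }
      if (!fired) break
    }
  }
  lapply(events, function(e) list(
    members = sort(sig$report_id[e$members]),
    trigger = e$trigger))
}

## canonical representation of an events table for set comparison
canon_events <- function(events) {
  if (nrow(events) == 0) return(list())
  out <- lapply(seq_len(nrow(events)), function(i) list(
    members = sort(strsplit(events$member_report_ids[i], ";", fixed = TRUE)[[1]]),
    trigger = events$triggered_at[i]))
  out[order(vapply(out, function(e) paste(e$members, collapse = "|"), character(1)))]
}

## random small signal stream (single cluster code 2), each signal from its
## own volunteer so locations vary freely
random_stream <- function(n, seed, box_deg = 0.6, span_h = 400) {
  set.seed(seed)
  t0 <- as_utc("2021-03-01")
  vol <- data.frame(
    volunteer_id = sprintf("V%02d", seq_len(n)),
    village_id = sprintf("G%02d", seq_len(n)),
    phone_token = sprintf("P%02d", seq_len(n)),
    lat = 9.5 + runif(n, 0, box_deg),
    lon = 44.0 + runif(n, 0, box_deg),
    active_from = t0 - 86400, active_to = t0 + 600 * 3600,
    stringsAsFactors = FALSE)
  rep <- data.frame(
    report_id = sprintf("R%02d", seq_len(n)),
    volunteer_id = vol$volunteer_id,
    received_at = t0 + round(sort(runif(n, 0, span_h)) * 3600),
    payload = "2", parse_status = "signal", code = 2L,
    stringsAsFactors = FALSE)
  list(volunteers = vol, reports = rep)
}

## small pending-events ledger for lifecycle tests: three single-report
## events (code 4) and one ADD cluster, all pending
mini_ledger <- function() {
  t0 <- as_utc("2021-02-01")
  vol <- data.frame(
    volunteer_id = c("VA", "VB"), village_id = c("G1", "G2"),
    phone_token = c("p1", "p2"), lat = c(9.8, 9.81), lon = c(44.2, 44.21),
    active_from = t0 - 86400, active_to = t0 + 90 * 86400,
    stringsAsFactors = FALSE)
  raw <- data.frame(
    report_id = sprintf("r%02d", 1:8),
    volunteer_id = c("VA", "VB", "VA", rep(c("VA", "VB"), length.out = 5)),
    received_at = t0 + 3600 * c(1, 5, 9, 20:24),
    payload = c("4", "4", "4", rep("2", 5)),
    stringsAsFactors = FALSE)
  reports <- parse_reports(raw, dialect_config())
  events <- evaluate_stream(reports, vol)
  cbs_ledger("mini", t0 - 86400, t0 + 90 * 86400, volunteers = vol,
             reports = reports, events = events)
}

## random small simulated programme for property tests
rand_sim_config <- function(seed) {
  set.seed(seed)
  sim_config(
    n_villages = sample(4:10, 1),
    volunteers_per_village = sample(1:3, 1),
    period_start = "2021-03-01", period_end = "2021-05-31",
    p_weekly_report = runif(1, 0.3, 0.9),
    p_malformed = runif(1, 0, 0.08),
    background_rates = c("2" = runif(1, 0, 0.15), "4" = runif(1, 0, 0.1),
                         "9" = runif(1, 0, 0.2), "14" = runif(1, 0, 0.05)),
    p_verify_within_12h = runif(1, 0.5, 1),
    p_supervisor_dismiss = runif(1, 0, 0.3),
    p_close_within_48h = runif(1, 0.4, 1),
    p_dismissed_by_authorities = runif(1, 0, 0.15),
    p_documented = runif(1, 0.2, 1),
    seed = seed)
}

empty_reports_df <- function() {
  parse_reports(data.frame(volunteer_id = character(0),
                           received_at = character(0),
                           payload = character(0), stringsAsFactors = FALSE))
}

expect_cbs_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
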