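#' Describe an injected spatiotemporal outbreak
#'
#' Signals are drawn from volunteers whose villages lie within
#' `spread_km` of the epicentre, at times within `spread_h` after `start`.
#' With `2 * spread_km` at most the cluster radius and `spread_h` at most
#' the cluster window, an injection of at least the threshold count is
#' detected with probability one by construction.
#'
#' @param code signal code (default 2, acute diarrhoeal disease).
#' @param start outbreak start time.
#' @param epicentre_lat,epicentre_lon outbreak centre.
#' @param n_signals number of outbreak signals.
#' @param spread_km spatial spread around the epicentre (km).
#' @param spread_h temporal spread after `start` (hours).
#' @export
outbreak_injection <- function(code = 2L, start, epicentre_lat, epicentre_lon,
                               n_signals, spread_km = 5, spread_h = 72) {
  list(code = as.integer(code), start = as_utc(start),
       epicentre_lat = epicentre_lat, epicentre_lon = epicentre_lon,
       n_signals = as.integer(n_signals), spread_km = spread_km,
       spread_h = spread_h)
}

#' Configuration of a synthetic CBS programme
#'
#' Defaults emulate one region-year of the Somaliland programme at the
#' Togdheer scale: 67 villages with two volunteers each reporting over the
#' 52 ISO weeks of 2021, weekly reporting compliance 0.66, a 2 percent
#' malformed-report rate, background signal rates sized to roughly 550
#' signals per year with the observed code composition, supervisor
#' verification mostly within 12 h, closure mostly within 48 h, and
#' outcome documentation near 64 percent. Background signals are placed
#' uniformly over villages and time, so spatial clustering arises only
#' through explicit outbreak injections.
#'
#' @param n_villages number of villages.
#' @param volunteers_per_village volunteers per village (programme practice:
#'   two or more, active in pairs).
#' @param lat_range,lon_range coordinate box for village points (decimal
#'   degrees).
#' @param period_start,period_end reporting period.
#' @param p_weekly_report probability a volunteer submits the weekly zero
#'   report in a given week.
#' @param p_malformed probability any submission is garbled into an
#'   unparseable payload.
#' @param background_rates named numeric vector: expected background
#'   signals per village-week for each code.
#' @param outbreaks list of [outbreak_injection()]s.
#' @param p_verify_within_12h mass of the verification-delay mixture inside
#'   0-12 h (uniform component); the remainder is a 12 h + log-normal tail.
#' @param verify_tail_meanlog,verify_tail_sdlog log-normal tail parameters
#'   (hours).
#' @param p_supervisor_dismiss probability a verified event is dismissed.
#' @param dismissal_reason_mix named probabilities over dismissal reasons.
#' @param p_close_within_48h mass of the closure-delay mixture inside
#'   0-48 h; remainder is 48 h + log-normal tail.
#' @param close_tail_meanlog,close_tail_sdlog closure tail parameters (hours).
#' @param p_dismissed_by_authorities probability an escalated alert is
#'   closed as authority-dismissed.
#' @param p_documented probability a closed alert has a documented outcome.
#' @param p_action_given_documented probability of documented action taken.
#' @param p_lab_given_action probability of a laboratory confirmation among
#'   action-taken alerts.
#' @param seed RNG seed (mandatory; identical config + seed gives a
#'   byte-identical ledger).
#' @param region region label.
#' @return object of class `cbs_sim_config`.
#' @export
sim_config <- function(n_villages = 67L,
                       volunteers_per_village = 2L,
                       lat_range = c(8.5, 11.0),
                       lon_range = c(43.5, 47.0),
                       period_start = "2021-01-04",
                       period_end = "2022-01-03",
                       p_weekly_report = 0.66,
                       p_malformed = 0.02,
                       background_rates = c("2" = 0.033, "4" = 0.025,
                                            "9" = 0.090, "14" = 0.009),
                       outbreaks = list(),
                       p_verify_within_12h = 0.84,
                       verify_tail_meanlog = log(10), verify_tail_sdlog = 0.6,
                       p_supervisor_dismiss = 0.10,
                       dismissal_reason_mix = c(not_matching_ccd = 0.8,
                                                duplicate = 0.1,
                                                sent_incorrectly = 0.1),
                       p_close_within_48h = 0.715,
                       close_tail_meanlog = log(24), close_tail_sdlog = 0.6,
                       p_dismissed_by_authorities = 0.05,
                       p_documented = 0.635,
                       p_action_given_documented = 0.90,
                       p_lab_given_action = 0.11,
                       seed,
                       region = "synthetic") {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    cbs_stop("a seed is mandatory", "cbs_bad_config")
  }
  probs <- c(p_weekly_report, p_malformed, p_verify_within_12h,
             p_supervisor_dismiss, p_close_within_48h,
             p_dismissed_by_authorities, p_documented,
             p_action_given_documented, p_lab_given_action)
  if (any(probs < 0 | probs > 1)) {
    cbs_stop("probabilities must lie in [0, 1]", "cbs_bad_config")
  }
  if (any(background_rates < 0)) cbs_stop("rates must be >= 0", "cbs_bad_config")
  if (n_villages < 1 || volunteers_per_village < 1) {
    cbs_stop("need at least one village and one volunteer per village",
             "cbs_bad_config")
  }
  cfg <- as.list(environment())
  cfg$period_start <- as_utc(period_start)
  cfg$period_end <- as_utc(period_end)
  structure(cfg, class = "cbs_sim_config")
}

#' @export
print.cbs_sim_config <- function(x, ...) {
  cat(sprintf("<cbs_sim_config> %d villages x %d volunteers, %s to %s, seed %d\n",
              x$n_villages, x$volunteers_per_village,
              format(x$period_start, "%Y-%m-%d"),
              format(x$period_end, "%Y-%m-%d"), x$seed))
  invisible(x)
}

draw_mixture_delay <- function(n, p_within, bound, tail_meanlog, tail_sdlog) {
  within <- stats::runif(n) < p_within
  d <- numeric(n)
  d[within] <- stats::runif(sum(within), 0, bound)
  d[!within] <- bound + stats::rlnorm(sum(!within), tail_meanlog, tail_sdlog)
  d
}

#' Simulate a complete synthetic CBS programme
#'
#' Generates the roster, the weekly zero reports, background and injected
#' signals, garbles a fraction of payloads, parses everything through the
#' coded-SMS dialect, runs the alert engine, and then drives every
#' triggered event through the verification-escalation-closure lifecycle
#' with delays and decisions drawn from the configured distributions.
#'
#' @param config a [sim_config()].
#' @return a `cbs_ledger`.
#' @export
simulate_programme <- function(config) {
  if (!inherits(config, "cbs_sim_config")) {
    cbs_stop("config must come from sim_config()", "cbs_bad_config")
  }
  set.seed(config$seed, kind = "Mersenne-Twister")
  ccd <- default_ccd_config()
  dialect <- dialect_config(configured_codes(ccd))

  ## roster
  n_vol <- config$n_villages * config$volunteers_per_village
  vil_lat <- stats::runif(config$n_villages, config$lat_range[1], config$lat_range[2])
  vil_lon <- stats::runif(config$n_villages, config$lon_range[1], config$lon_range[2])
  vil_of <- rep(seq_len(config$n_villages), each = config$volunteers_per_village)
  volunteers <- data.frame(
    volunteer_id = make_ids("V", n_vol, 4),
    village_id = sprintf("VG%03d", vil_of),
    phone_token = sprintf("T%04x", seq_len(n_vol) + 4096L),
    lat = vil_lat[vil_of], lon = vil_lon[vil_of],
    active_from = config$period_start, active_to = config$period_end,
    stringsAsFactors = FALSE)

  cal <- week_calendar(config$period_start, config$period_end)
  cal <- cal[cal$week_end <= config$period_end + 1, , drop = FALSE]
  n_wk <- nrow(cal)

  ## weekly zero reports: one Bernoulli per volunteer-week, sent near week end
  vw <- expand.grid(vol = seq_len(n_vol), wk = seq_len(n_wk))
  sent <- stats::runif(nrow(vw)) < config$p_weekly_report
  vw <- vw[sent, , drop = FALSE]
  zero_raw <- data.frame(
    volunteer_id = volunteers$volunteer_id[vw$vol],
    received_at = cal$week_start[vw$wk] + (6 * 24 + stats::runif(nrow(vw), 8, 20)) * 3600,
    payload = dialect$zero_token, stringsAsFactors = FALSE)

  ## background signals: Poisson per village-week-code, uniform in the week
  bg_list <- list()
  for (code in names(config$background_rates)) {
    lam <- config$background_rates[[code]]
    if (lam <= 0) next
    counts <- stats::rpois(config$n_villages * n_wk, lam)
    idx <- rep(seq_along(counts), counts)
    if (length(idx) == 0) next
    vil <- ((idx - 1) %% config$n_villages) + 1
    wk <- ((idx - 1) %/% config$n_villages) + 1
    vol_in_vil <- sample.int(config$volunteers_per_village, length(idx), replace = TRUE)
    vol <- (vil - 1) * config$volunteers_per_village + vol_in_vil
    bg_list[[code]] <- data.frame(
      volunteer_id = volunteers$volunteer_id[vol],
      received_at = cal$week_start[wk] + stats::runif(length(idx), 0, 7 * 24) * 3600,
      payload = code, stringsAsFactors = FALSE)
  }

  ## injected outbreaks: volunteers within spread_km of the epicentre
  ob_list <- list()
  for (ob in config$outbreaks) {
    d <- haversine_km(volunteers$lat, volunteers$lon,
                      ob$epicentre_lat, ob$epicentre_lon)
    cand <- which(d <= ob$spread_km)
    if (length(cand) == 0) cand <- order(d)[1]
    vol <- cand[sample.int(length(cand), ob$n_signals, replace = TRUE)]
    ob_list[[length(ob_list) + 1]] <- data.frame(
      volunteer_id = volunteers$volunteer_id[vol],
      received_at = ob$start + sort(stats::runif(ob$n_signals, 0, ob$spread_h)) * 3600,
      payload = as.character(ob$code), stringsAsFactors = FALSE)
  }

  raw <- do.call(rbind, c(list(zero_raw), bg_list, ob_list))
  ## garble a fraction of payloads into unparseable text
  garbled <- stats::runif(nrow(raw)) < config$p_malformed
  raw$payload[garbled] <- paste0("X", raw$payload[garbled])
  raw <- raw[order(raw$received_at, raw$volunteer_id), , drop = FALSE]
  raw$report_id <- make_ids("R", nrow(raw), 6)
  raw$received_at <- as_utc(round(as.numeric(raw$received_at)))

  reports <- parse_reports(raw, dialect)
  events <- evaluate_stream(reports, volunteers, ccd)

  ledger <- cbs_ledger(config$region, config$period_start, config$period_end,
                       volunteers = volunteers, reports = reports,
                       events = events, ccd = ccd, validate = FALSE)

  ## lifecycle: verify every event, escalate kept ones, close every alert.
  ## Applied as one vectorised pass with the identical transition semantics
  ## (and the same append-only log records) as verify_event / escalate_event
  ## / close_alert; the per-event functions are the authoritative interface
  ## for interactive use.
  n_ev <- nrow(events)
  if (n_ev > 0) {
    v_delay <- draw_mixture_delay(n_ev, config$p_verify_within_12h, 12,
                                  config$verify_tail_meanlog, config$verify_tail_sdlog)
    dismiss <- stats::runif(n_ev) < config$p_supervisor_dismiss
    reasons <- sample(names(config$dismissal_reason_mix), n_ev, replace = TRUE,
                      prob = config$dismissal_reason_mix)
    ver_at <- events$triggered_at + round(v_delay * 3600)
    ledger$events$verification_status <- ifelse(dismiss, "dismissed", "kept")
    ledger$events$dismissal_reason <- ifelse(dismiss, reasons, "none")
    ledger$events$verified_at <- ver_at

    kept_idx <- which(!dismiss)
    n_al <- length(kept_idx)
    if (n_al > 0) {
      alerts <- data.frame(
        alert_id = make_ids("A", n_al, 5),
        event_id = events$event_id[kept_idx],
        escalated_at = ver_at[kept_idx],
        status = "escalated", closed_at = as.POSIXct(NA, tz = "UTC"),
        documented = FALSE, action_taken = FALSE, lab_confirmed = FALSE,
        notes = "", stringsAsFactors = FALSE)
      c_delay <- draw_mixture_delay(n_al, config$p_close_within_48h, 48,
                                    config$close_tail_meanlog, config$close_tail_sdlog)
      dba <- stats::runif(n_al) < config$p_dismissed_by_authorities
      doc <- stats::runif(n_al) < config$p_documented
      act <- doc & (stats::runif(n_al) < config$p_action_given_documented)
      lab <- act & (stats::runif(n_al) < config$p_lab_given_action)
      alerts$status <- ifelse(dba, "dismissed_by_authorities", "closed")
      alerts$closed_at <- alerts$escalated_at + round(c_delay * 3600)
      alerts$documented <- doc
      alerts$action_taken <- act
      alerts$lab_confirmed <- lab
      ledger$alerts <- alerts
    }
    ## transition log in the order the interactive operations would emit it
    log <- vector("list", n_ev + 2L * n_al)
    li <- 0L
    ai <- 0L
    for (i in seq_len(n_ev)) {
      li <- li + 1L
      log[[li]] <- list(at = fmt_utc(ver_at[i]), op = "verify",
                        id = events$event_id[i],
                        detail = if (dismiss[i]) paste0("dismissed:", reasons[i])
                                 else "kept")
      if (!dismiss[i]) {
        ai <- ai + 1L
        li <- li + 1L
        log[[li]] <- list(at = fmt_utc(ver_at[i]), op = "escalate",
                          id = sprintf("A%05d", ai), detail = events$event_id[i])
      }
    }
    if (n_al > 0) {
      for (j in seq_len(n_al)) {
        li <- li + 1L
        log[[li]] <- list(
          at = fmt_utc(ledger$alerts$closed_at[j]), op = "close",
          id = ledger$alerts$alert_id[j],
          detail = paste0(ledger$alerts$status[j],
                          if (doc[j]) ";documented" else "",
                          if (act[j]) ";action" else "",
                          if (lab[j]) ";lab" else ""))
      }
    }
    ledger$log <- log[seq_len(li)]
  }
  validate_ledger(ledger)
  ledger
}

#' Configured-versus-recovered rate report for the simulator
#'
#' Runs `n_replicates` independent simulations (seeds derived from the
#' config seed), computes the attribute metrics on each, and compares the
#' replicate means with the rates the configuration implies: weekly
#' completeness (reporting compliance plus the background-signal
#' contribution, exact when no outbreaks are injected), correct-format
#' share, verification within 12 h, closure within 48 h, and outcome
#' documentation.
#'
#' @param config a [sim_config()].
#' @param n_replicates at least 2.
#' @return data.frame of class `cbs_recovery`: one row per rate with the
#'   configured value, replicate mean, replicate SD, Monte-Carlo standard
#'   error of the mean, and deviation (all on the 0-1 scale).
#' @export
parameter_recovery_report <- function(config, n_replicates) {
  if (n_replicates < 2) cbs_stop("need n_replicates >= 2", "cbs_bad_config")
  ## expected weekly presence: weekly report OR at least one background signal
  lam_vol <- sum(config$background_rates) / config$volunteers_per_village
  p_presence <- 1 - (1 - config$p_weekly_report) * exp(-lam_vol)
  configured <- c(weekly_completeness = p_presence,
                  correct_format = 1 - config$p_malformed,
                  verified_within_12h = config$p_verify_within_12h,
                  closed_within_48h = config$p_close_within_48h,
                  documented_outcome = config$p_documented)
  est <- matrix(NA_real_, n_replicates, length(configured),
                dimnames = list(NULL, names(configured)))
  for (r in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- (config$seed + 7919L * r) %% .Machine$integer.max
    led <- simulate_programme(cfg)
    s <- summary(led)
    est[r, ] <- c(
      s$weekly_completeness_avg,
      if (s$n_reports > 0) s$n_correct_format / s$n_reports else NA,
      if (s$n_events > 0) s$n_verified_within_12h / s$n_events else NA,
      if (s$n_alerts_closed > 0) s$n_closed_within_48h / s$n_alerts_closed else NA,
      if (s$n_alerts_closed > 0) s$n_documented / s$n_alerts_closed else NA)
  }
  mean_est <- colMeans(est, na.rm = TRUE)
  sd_est <- apply(est, 2, stats::sd, na.rm = TRUE)
  out <- data.frame(
    rate = names(configured),
    configured = unname(configured),
    mean_estimate = unname(mean_est),
    sd_estimate = unname(sd_est),
    mc_se = unname(sd_est / sqrt(n_replicates)),
    deviation = unname(mean_est - configured),
    stringsAsFactors = FALSE)
  class(out) <- c("cbs_recovery", "data.frame")
  out
}

#' @export
print.cbs_recovery <- function(x, ...) {
  cat("Parameter recovery (configured vs replicate-mean estimate):\n")
  print.data.frame(cbind(x[, 1, drop = FALSE],
                         round(x[, -1], 4)), row.names = FALSE)
  invisible(x)
}
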