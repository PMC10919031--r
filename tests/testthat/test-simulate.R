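test_that("identical config and seed give byte-identical serialised ledgers", {
  cfg <- rand_sim_config(808)
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  write_ledger(simulate_programme(cfg), d1)
  write_ledger(simulate_programme(cfg), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_equal(f1, f2)
  for (f in f1) {
    expect_equal(unname(tools::md5sum(file.path(d1, f))),
                 unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("config invariants are enforced before any generation", {
  expect_cbs_error(sim_config(p_weekly_report = 1.2, seed = 1), "cbs_bad_config")
  expect_cbs_error(sim_config(background_rates = c("2" = -0.1), seed = 1),
                   "cbs_bad_config")
  expect_cbs_error(sim_config(n_villages = 0, seed = 1), "cbs_bad_config")
  expect_error(sim_config(), class = "cbs_error")  # seed mandatory
})

test_that("an injected outbreak is the only event under zero background", {
  cfg <- sim_config(
    n_villages = 12, volunteers_per_village = 2,
    p_weekly_report = 0.5, p_malformed = 0,
    background_rates = c("2" = 0, "4" = 0, "9" = 0, "14" = 0),
    outbreaks = list(outbreak_injection(
      code = 2, start = "2021-04-10", epicentre_lat = 9.7,
      epicentre_lon = 44.8, n_signals = 6, spread_km = 8, spread_h = 48)),
    seed = 55L)
  led <- simulate_programme(cfg)
  expect_equal(nrow(led$events), 1)
  expect_equal(led$events$code, 2L)
  expect_equal(length(strsplit(led$events$member_report_ids, ";")[[1]]), 6)
})

test_that("injected outbreaks at or above threshold are always detected", {
  for (seed in 1:12) {
    set.seed(seed)
    n_sig <- sample(5:9, 1)
    cfg <- sim_config(
      n_villages = 10, volunteers_per_village = 2,
      p_weekly_report = 0.4, p_malformed = 0,
      background_rates = c("2" = 0, "4" = 0, "9" = 0, "14" = 0),
      outbreaks = list(outbreak_injection(
        code = 2, start = as_utc("2021-03-01") + seed * 86400,
        epicentre_lat = runif(1, 8.6, 10.9), epicentre_lon = runif(1, 43.6, 46.9),
        n_signals = n_sig, spread_km = 8, spread_h = runif(1, 24, 120))),
      seed = 7700L + seed)
    led <- simulate_programme(cfg)
    expect_gte(nrow(led$events), 1)
    sizes <- vapply(strsplit(led$events$member_report_ids, ";"), length, integer(1))
    expect_equal(sum(sizes), n_sig)
  }
})

test_that("weekly completeness recovers a configured 64% compliance", {
  ## roster of about 139 volunteers reporting over 52 weeks, signals off
  cfg <- sim_config(n_villages = 67, volunteers_per_village = 2,
                    p_weekly_report = 0.64, p_malformed = 0,
                    background_rates = c("2" = 0, "4" = 0, "9" = 0, "14" = 0),
                    seed = 6464L)
  s <- summary(simulate_programme(cfg))
  se <- sqrt(0.64 * 0.36 / (134 * 52))
  expect_lt(abs(s$weekly_completeness_avg - 0.64), 3 * se)
})

test_that("fixtures reproduce every marginal count exactly, both regions", {
  map <- c(events_triggered = "n_events", events_kept = "n_events_kept",
           events_dismissed = "n_events_dismissed",
           dismissed_by_authorities = "n_dismissed_by_authorities",
           documented = "n_documented", action_taken = "n_action_taken",
           lab_confirmed = "n_lab_confirmed", total_reports = "n_reports",
           correct_format = "n_correct_format", signals_sent = "n_signals_sent",
           signals_verified = "n_signals_verified", signals_kept = "n_signals_kept",
           verified_within_12h = "n_verified_within_12h",
           verified_within_24h = "n_verified_within_24h",
           closed_within_48h = "n_closed_within_48h")
  for (spec in list(awdal_fixture_spec(), togdheer_fixture_spec())) {
    led <- fixture_from_marginals(spec)
    s <- summary(led)
    for (fld in names(map)) {
      expect_equal(s[[map[[fld]]]], as.integer(spec[[fld]]),
                   info = paste(spec$region, fld))
    }
    expect_equal(unname(s$per_code_escalated[names(spec$per_code_escalated)]),
                 unname(as.integer(spec$per_code_escalated)),
                 info = spec$region)
    expect_equal(s$n_alerts_escalated, spec$events_kept, info = spec$region)
    expect_equal(s$n_alerts_closed, spec$events_kept, info = spec$region)
    ## fixtures are deterministic: two builds are identical
    expect_identical(led, fixture_from_marginals(spec))
  }
})

test_that("inconsistent fixture specs are rejected naming the violated rule", {
  base <- awdal_fixture_spec()
  tweak <- function(...) {
    s <- base
    mods <- list(...)
    for (nm in names(mods)) s[[nm]] <- mods[[nm]]
    s
  }
  expect_error(fixture_from_marginals(tweak(documented = 120L)),
               "documented")
  expect_error(fixture_from_marginals(tweak(events_dismissed = 20L)),
               "events_kept")
  expect_error(fixture_from_marginals(tweak(signals_kept = 150L)),
               "cluster")
  expect_error(fixture_from_marginals(tweak(lab_confirmed = 70L)),
               "lab_confirmed")
})

test_that("a degenerate all-certain config recovers every rate at exactly 100%", {
  cfg <- sim_config(n_villages = 8, volunteers_per_village = 2,
                    period_start = "2021-03-01", period_end = "2021-05-31",
                    p_weekly_report = 1, p_malformed = 0,
                    background_rates = c("2" = 0, "4" = 0.3, "9" = 0.3, "14" = 0),
                    p_verify_within_12h = 1, p_supervisor_dismiss = 0,
                    p_close_within_48h = 1, p_dismissed_by_authorities = 0,
                    p_documented = 1, seed = 9L)
  rec <- parameter_recovery_report(cfg, n_replicates = 3)
  expect_equal(rec$mean_estimate,
               c(1, 1, 1, 1, 1) * c(1, 1, 1, 1, 1), tolerance = 1e-12)
  expect_equal(rec$deviation, rep(0, 5), tolerance = 1e-12)
})

test_that("configured rates are recovered within Monte-Carlo error", {
  cfg <- sim_config(n_villages = 25, volunteers_per_village = 2,
                    p_weekly_report = 0.66, p_malformed = 0.04,
                    background_rates = c("2" = 0, "4" = 0.15, "9" = 0.25, "14" = 0.02),
                    p_verify_within_12h = 0.93, p_supervisor_dismiss = 0.05,
                    p_close_within_48h = 0.76, p_documented = 0.64,
                    seed = 1234L)
  rec <- parameter_recovery_report(cfg, n_replicates = 6)
  ## binomial SE floors keep the 3-SE band honest when replicate SDs are tiny
  n_units <- c(50 * 52 * 6, 6 * 3000, 6 * 500, 6 * 450, 6 * 450)
  floor_se <- sqrt(rec$configured * (1 - rec$configured) / n_units)
  tol <- 3 * pmax(rec$mc_se, floor_se)
  expect_true(all(abs(rec$deviation) <= tol),
              info = paste(rec$rate, round(rec$deviation, 4), round(tol, 4),
                           collapse = "; "))
})
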