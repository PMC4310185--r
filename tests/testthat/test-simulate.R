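# a small-but-structured config keeps the generator tests fast
small_cfg <- function(...) {
  sim_config(n_patients = 300, ...)
}

test_that("identical seeds give identical databases", {
  d1 <- simulate_ehr(small_cfg(), seed = 7)
  d2 <- simulate_ehr(small_cfg(), seed = 7)
  expect_identical(d1$events, d2$events)
  expect_identical(d1$demographics, d2$demographics)
  d3 <- simulate_ehr(small_cfg(), seed = 8)
  expect_false(identical(d1$events, d3$events))
})

test_that("the generator does not disturb the caller's RNG stream", {
  set.seed(123)
  before <- .Random.seed
  invisible(simulate_ehr(small_cfg(), seed = 5))
  expect_identical(.Random.seed, before)
})

test_that("code frequencies have a sub-50-count rare tail at defaults", {
  db <- simulate_ehr(sim_config(n_patients = 1000), seed = 3)
  dx_counts <- table(db$events$code[db$events$class == "diagnosis"])
  expect_gt(sum(dx_counts < 50), 0)
  # and a frequent head, so the vocabulary is non-trivial
  expect_gt(sum(dx_counts >= 50), 5)
})

test_that("with zero effects the readmission rate matches the base hazard", {
  # baseline admissions are never flagged emergency here, so every emergency
  # admission is a planted readmission: for patients with a single baseline
  # admission the planted draw is directly observable as Bernoulli(p0)
  cfg <- sim_config(n_patients = 2000, mean_admissions = 1,
                    emergency_frac = 0, mean_ed_visits = 0,
                    effect_emergency = 0, effect_risk_dx = 0, max_chain = 1,
                    readmit_median_months = 2, readmit_median_drift = 0)
  db <- simulate_ehr(cfg, seed = 11)
  tl <- sim_timeline(cfg)
  adm <- db$events[db$events$class == "admission", ]
  adm$t_end <- date_to_index(dplyr::coalesce(adm$end_date, adm$start_date), tl)
  base <- adm[adm$emergency == 0, ]
  one_base <- names(which(table(base$patient_id) == 1))
  keep <- base$patient_id %in% one_base & base$t_end <= tl$n_units - 30
  readmit <- as.integer(base$patient_id[keep] %in%
                          adm$patient_id[adm$emergency == 1])
  p0 <- stats::plogis(cfg$base_logodds)
  se <- sqrt(p0 * (1 - p0) / length(readmit))
  expect_gt(length(readmit), 400)
  expect_lt(abs(mean(readmit) - p0), 3 * se)
})

test_that("patients with recent emergency visits are readmitted more often", {
  cfg <- sim_config(n_patients = 2000)
  db <- simulate_ehr(cfg, seed = 13)
  tl <- sim_timeline(cfg)
  aps <- find_assessment_points(db$events, cfg$disease_codes, tl)
  aps <- label_assessment_points(aps, db$events, tl, horizons_months = 6)
  ed <- db$events[db$events$class == "emergency", ]
  ed_t <- tibble::tibble(patient_id = ed$patient_id,
                         t = date_to_index(ed$start_date, tl))
  n_recent <- vapply(seq_len(nrow(aps)), function(i)
    sum(ed_t$patient_id == aps$patient_id[i] & ed_t$t == aps$t[i]),
    integer(1))
  rate_hi <- mean(aps$label_6m[n_recent >= 2])
  rate_lo <- mean(aps$label_6m[n_recent <= 1])
  expect_gt(rate_hi, rate_lo)
})

test_that("planted truth maps effects onto the expected feature columns", {
  cfg <- sim_config()
  tr <- planted_truth(cfg)
  expect_setequal(tr$column, c("emergency:ED|uniform|1|0",
                               "diagnosis:R074|uniform|12|0"))
  expect_true(all(tr$sign == 1))
  expect_identical(nrow(planted_truth(
    sim_config(effect_emergency = 0, effect_risk_dx = 0))), 0L)
})

test_that("simulated databases round-trip through the CSV dialect", {
  outdir <- withr::local_tempdir()
  paths <- cmd_simulate(outdir, small_cfg(), seed = 4)
  expect_true(all(file.exists(paths)))
  ev <- read_events(paths["events"])
  db <- simulate_ehr(small_cfg(), seed = 4)
  expect_identical(nrow(ev), nrow(db$events))
  expect_identical(ev$code, db$events$code)
  expect_identical(ev$start_date, db$events$start_date)
  expect_identical(as.integer(ev$emergency), db$events$emergency)
  expect_true(file.exists(file.path(outdir, "manifest.yaml")))
})

test_that("an empty database is still structurally valid", {
  db <- simulate_ehr(sim_config(n_patients = 0), seed = 1)
  expect_identical(nrow(db$events), 0L)
  expect_identical(nrow(db$demographics), 0L)
  expect_named(db$events,
               c("patient_id", "code", "class", "kind", "start_date",
                 "end_date", "emergency"))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(span_years = 2), "at least 4")
  expect_error(sim_config(incidence = 1.5))
})
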