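tl <- month_tl(120)

# one patient with admissions at given months; diagnosis codes attached at
# given admission indices
patient_history <- function(pid, adm_months, emergency, dx_at = integer(0),
                            dx_code = "J449") {
  adm <- make_events(pid, "ADM", "admission", "continuing",
                     format(index_to_date(adm_months, tl)),
                     format(index_to_date(adm_months, tl) + 3),
                     emergency = emergency)
  if (length(dx_at)) {
    dx <- make_events(pid, dx_code, "diagnosis", "point",
                      format(index_to_date(adm_months[dx_at], tl)))
    dplyr::bind_rows(adm, dx)
  } else adm
}

test_that("only discharges at or after the first disease diagnosis become APs", {
  # diagnosed at admission 2 of 3: APs at discharges 2 and 3 only
  ev <- patient_history("P1", c(10L, 30L, 50L), emergency = 1L, dx_at = 2L)
  aps <- find_assessment_points(ev, "J449", tl)
  expect_identical(nrow(aps), 2L)
  expect_true(all(aps$t >= 30L))
  # a never-diagnosed patient contributes nothing
  ev2 <- patient_history("P2", c(10L, 30L), emergency = 1L)
  expect_identical(nrow(find_assessment_points(ev2, "J449", tl)), 0L)
})

test_that("planned discharges are excluded unless unplanned_only is off", {
  ev <- patient_history("P1", c(10L, 30L), emergency = c(0L, 1L), dx_at = 1L)
  aps_unpl <- find_assessment_points(ev, "J449", tl)
  expect_identical(nrow(aps_unpl), 1L)
  aps_all <- find_assessment_points(ev, "J449", tl, unplanned_only = FALSE)
  expect_identical(nrow(aps_all), 2L)
})

test_that("fixed-date APs exist only for already-diagnosed patients", {
  ev <- patient_history("P1", 30L, emergency = 1L, dx_at = 1L)
  before <- find_assessment_points(ev, "J449", tl, mode = "fixed_date",
                                   fixed_dates = index_to_date(10, tl))
  expect_identical(nrow(before), 0L)
  after <- find_assessment_points(ev, "J449", tl, mode = "fixed_date",
                                  fixed_dates = index_to_date(60, tl))
  expect_identical(nrow(after), 1L)
})

test_that("readmission labels use the half-open emergency window (ap, ap+H]", {
  adm <- tibble::tibble(t = c(10L, 11L, 15L), emergency = c(1L, 1L, 0L))
  # no admissions after the AP
  expect_identical(label_readmission(20L, adm, 6), 0L)
  # emergency admission one unit after the AP
  expect_identical(label_readmission(10L, adm, 1), 1L)
  # same-unit admissions are excluded
  expect_identical(label_readmission(11L, adm, 3), 0L)
  # a planned admission inside the horizon does not count
  expect_identical(label_readmission(12L, adm, 6), 0L)
})

test_that("labels are monotone in the horizon", {
  set.seed(21)
  ev <- dplyr::bind_rows(lapply(1:20, function(i)
    patient_history(sprintf("P%02d", i), sort(sample.int(100, 4)),
                    emergency = rbinom(4, 1, 0.6), dx_at = 1L)))
  aps <- find_assessment_points(ev, "J449", tl)
  aps <- label_assessment_points(aps, ev, tl, horizons_months = c(1, 2, 3, 6, 12))
  labs <- as.matrix(aps[paste0("label_", c(1, 2, 3, 6, 12), "m")])
  expect_true(all(diff(t(labs)) >= 0))
})

test_that("label columns agree with the per-AP reference labeller", {
  set.seed(22)
  ev <- dplyr::bind_rows(lapply(1:10, function(i)
    patient_history(sprintf("P%02d", i), sort(sample.int(100, 5)),
                    emergency = rbinom(5, 1, 0.5), dx_at = 1L)))
  aps <- find_assessment_points(ev, "J449", tl)
  got <- label_assessment_points(aps, ev, tl, horizons_months = 6)
  adm_t <- tibble::tibble(
    patient_id = ev$patient_id[ev$class == "admission"],
    t = date_to_index(ev$start_date[ev$class == "admission"], tl),
    emergency = ev$emergency[ev$class == "admission"]
  )
  want <- vapply(seq_len(nrow(aps)), function(i) {
    label_readmission(aps$t[i],
                      adm_t[adm_t$patient_id == aps$patient_id[i], ], 6)
  }, integer(1))
  expect_identical(got$label_6m, want)
})

test_that("the temporal split separates patients and time", {
  aps <- tibble::tibble(
    patient_id = c("A", "A", "B", "C"),
    t = c(10L, 200L, 150L, 50L)
  )
  sp <- temporal_split(aps, 100L)
  # A's post-validation AP is discarded, not moved to validation
  expect_identical(sp$derivation$patient_id, c("A", "C"))
  expect_identical(sp$derivation$t, c(10L, 50L))
  # B's first AP is after the validation point: all of B goes to validation
  expect_identical(sp$validation$patient_id, "B")
  expect_length(intersect(sp$derivation$patient_id,
                          sp$validation$patient_id), 0L)
  # degenerate case: everything before the point leaves validation empty
  sp2 <- temporal_split(aps[aps$t < 100, ], 300L)
  expect_identical(nrow(sp2$validation), 0L)
})

test_that("split hygiene holds on many random cohorts", {
  set.seed(33)
  for (rep in 1:100) {
    n <- sample(5:60, 1)
    aps <- tibble::tibble(
      patient_id = sample(sprintf("P%02d", 1:15), n, replace = TRUE),
      t = sample.int(300, n, replace = TRUE)
    )
    vp <- sample.int(300, 1)
    sp <- temporal_split(aps, vp)
    expect_length(intersect(unique(sp$derivation$patient_id),
                            unique(sp$validation$patient_id)), 0L)
    expect_true(all(sp$derivation$t < vp))
    # validation patients have no AP before the validation point
    expect_true(all(!sp$validation$patient_id %in%
                      aps$patient_id[aps$t < vp]))
  }
})
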