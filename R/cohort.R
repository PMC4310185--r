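#' Find assessment points
#'
#' An assessment point (AP) is a (patient, time) unit of analysis: history
#' before it yields features, events after it yield readmission labels. APs
#' are placed either at hospital discharges (`mode = "discharge"`) or at
#' fixed calendar dates (`mode = "fixed_date"`), and only at or after the
#' patient's first diagnosis with one of the study's disease codes.
#'
#' @param events Events tibble. Admissions are rows of
#'   `class == admission_class` (the discharge unit is taken from `end_date`,
#'   falling back to `start_date`); disease diagnoses are rows of
#'   `class == diagnosis_class` whose `code` is in `disease_codes`.
#' @param disease_codes Character vector defining the study cohort.
#' @param tl An [timeline()].
#' @param mode `"discharge"` or `"fixed_date"`.
#' @param fixed_dates Dates at which to assess (required for
#'   `mode = "fixed_date"`).
#' @param unplanned_only If `TRUE` (default), only discharges from
#'   emergency-flagged admissions generate APs.
#' @param diagnosis_class,admission_class Entity class names.
#' @return Tibble `patient_id, t, source` ordered by patient and time.
#' @export
find_assessment_points <- function(events, disease_codes, tl,
                                   mode = c("discharge", "fixed_date"),
                                   fixed_dates = NULL,
                                   unplanned_only = TRUE,
                                   diagnosis_class = "diagnosis",
                                   admission_class = "admission") {
  mode <- match.arg(mode)
  dx <- events[events$class == diagnosis_class &
                 events$code %in% disease_codes, , drop = FALSE]
  if (nrow(dx) == 0L)
    return(tibble::tibble(patient_id = character(), t = integer(),
                          source = character()))
  first_dx <- dx |>
    dplyr::mutate(t = date_to_index(.data$start_date, tl)) |>
    dplyr::filter(.data$t <= tl$n_units) |>
    dplyr::summarise(first_dx = min(.data$t), .by = "patient_id")

  if (mode == "discharge") {
    adm <- events[events$class == admission_class, , drop = FALSE]
    if (unplanned_only) {
      if (!"emergency" %in% names(adm))
        stop("`unplanned_only = TRUE` requires an `emergency` column on admissions",
             call. = FALSE)
      adm <- adm[!is.na(adm$emergency) & adm$emergency == 1, , drop = FALSE]
    }
    if (nrow(adm) == 0L)
      return(tibble::tibble(patient_id = character(), t = integer(),
                            source = character()))
    end <- dplyr::coalesce(adm$end_date, adm$start_date)
    aps <- tibble::tibble(patient_id = adm$patient_id,
                          t = pmin(date_to_index(end, tl), tl$n_units),
                          source = "discharge") |>
      dplyr::filter(date_to_index(adm$start_date, tl) <= tl$n_units)
  } else {
    if (is.null(fixed_dates))
      stop("`fixed_dates` required for mode = \"fixed_date\"", call. = FALSE)
    ts <- date_to_index(as.Date(fixed_dates), tl)
    ts <- ts[ts <= tl$n_units]
    aps <- tidyr::expand_grid(patient_id = first_dx$patient_id, t = ts) |>
      dplyr::mutate(source = "fixed_date")
  }
  aps |>
    dplyr::inner_join(first_dx, by = "patient_id") |>
    dplyr::filter(.data$t >= .data$first_dx) |>
    dplyr::select("patient_id", "t", "source") |>
    dplyr::arrange(.data$patient_id, .data$t)
}

#' Label unplanned readmission after an assessment point
#'
#' An unplanned readmission is an admission carrying the emergency flag
#' (i.e. following an emergency visit) that starts strictly after the AP and
#' at or before `ap_t + horizon`: the half-open window `(ap_t, ap_t + H]` in
#' timeline units. Same-unit admissions are excluded because features include
#' the AP's own unit. Planned admissions never count.
#'
#' @param ap_t Integer AP time index (vectorized).
#' @param admissions Tibble/data frame of the patient's admissions with
#'   columns `t` (start unit) and `emergency` (0/1).
#' @param horizon_months Positive prediction horizon, in months.
#' @param upm Units per month of the timeline (1 for monthly, 30 for daily).
#' @return Integer 0/1 vector, one per element of `ap_t`.
#' @export
label_readmission <- function(ap_t, admissions, horizon_months, upm = 1L) {
  stopifnot(horizon_months > 0)
  h_units <- horizon_months * upm
  em_t <- admissions$t[!is.na(admissions$emergency) & admissions$emergency == 1]
  vapply(as.integer(ap_t), function(a)
    as.integer(any(em_t > a & em_t <= a + h_units)), integer(1))
}

#' Attach per-horizon readmission labels to assessment points
#'
#' @param aps AP tibble from [find_assessment_points()].
#' @param events Events tibble (admissions supply labels).
#' @param tl An [timeline()].
#' @param horizons_months Prediction horizons in months (default
#'   `c(1, 2, 3, 6, 12)`).
#' @param admission_class Entity class of admissions.
#' @return `aps` with added columns `label_<h>m`, one per horizon.
#' @export
label_assessment_points <- function(aps, events, tl,
                                    horizons_months = c(1, 2, 3, 6, 12),
                                    admission_class = "admission") {
  adm <- events[events$class == admission_class, , drop = FALSE]
  if (!"emergency" %in% names(adm)) adm$emergency <- 0L
  adm_t <- tibble::tibble(
    patient_id = adm$patient_id,
    t = date_to_index(adm$start_date, tl),
    emergency = as.integer(adm$emergency)
  ) |> dplyr::filter(.data$t <= tl$n_units, .data$emergency == 1L)
  upm <- units_per_month(tl)
  out <- aps
  for (h in horizons_months) {
    joined <- dplyr::left_join(
      dplyr::mutate(aps, .row = dplyr::row_number(),
                    lo = .data$t + 1L, hi = .data$t + as.integer(h * upm)),
      adm_t,
      by = dplyr::join_by("patient_id", "lo" <= "t", "hi" >= "t"),
      relationship = "many-to-many", suffix = c("", ".adm")
    )
    lab <- integer(nrow(aps))
    hit <- joined$.row[!is.na(joined$emergency)]
    lab[unique(hit)] <- 1L
    out[[sprintf("label_%gm", h)]] <- lab
  }
  out
}

#' Split assessment points into derivation and validation cohorts
#'
#' The two cohorts are separated both in patients and in time. Patients with
#' any AP strictly before the validation point form the derivation cohort;
#' their APs at or after the validation point are discarded. All remaining
#' patients (whose every AP is at or after the validation point) form the
#' validation cohort.
#'
#' @param aps Labelled AP tibble with columns `patient_id, t`.
#' @param validation_point Time index separating the cohorts.
#' @return A `cohort_split`: list with `derivation`, `validation` (AP
#'   tibbles) and `validation_point`.
#' @export
temporal_split <- function(aps, validation_point) {
  vp <- as.integer(validation_point)
  deriv_patients <- unique(aps$patient_id[aps$t < vp])
  derivation <- aps |>
    dplyr::filter(.data$patient_id %in% deriv_patients, .data$t < vp)
  validation <- aps |>
    dplyr::filter(!.data$patient_id %in% deriv_patients)
  structure(
    list(derivation = derivation, validation = validation,
         validation_point = vp),
    class = "cohort_split"
  )
}

#' @export
print.cohort_split <- function(x, ...) {
  cat(sprintf(paste0("<cohort_split> validation point at unit %d\n",
                     "  derivation: %d APs / %d patients\n",
                     "  validation: %d APs / %d patients\n"),
              x$validation_point,
              nrow(x$derivation), dplyr::n_distinct(x$derivation$patient_id),
              nrow(x$validation), dplyr::n_distinct(x$validation$patient_id)))
  invisible(x)
}

#' @exportS3Method generics::glance
glance.cohort_split <- function(x, ...) {
  tibble::tibble(
    validation_point = x$validation_point,
    n_derivation_aps = nrow(x$derivation),
    n_derivation_patients = dplyr::n_distinct(x$derivation$patient_id),
    n_validation_aps = nrow(x$validation),
    n_validation_patients = dplyr::n_distinct(x$validation$patient_id)
  )
}
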