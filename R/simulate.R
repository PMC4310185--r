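#' Configuration for the synthetic hospital database
#'
#' Defines the study conditions the generator emulates: a multi-year monthly
#' timeline, admission episodes (continuing entities) with emergency flags
#' and attached ICD-10-like diagnosis codes, medication and
#' emergency-department point events, heavy-tailed (Zipf) code frequencies
#' with a rare tail, and a per-discharge logistic readmission hazard whose
#' linear predictor is a weighted sum of the patient's recent event counts.
#'
#' @param n_patients Number of patients (default 2000).
#' @param span_years Study span in years (default 9; must be at least 4 so a
#'   36-month lookback and a temporal split both fit).
#' @param origin First day of the study window.
#' @param mean_admissions Mean number of baseline (non-planted) admissions
#'   per patient over the span.
#' @param emergency_frac Fraction of baseline admissions flagged emergency.
#' @param mean_ed_visits Mean number of community emergency-department
#'   visits per patient over the span (point events not attached to an
#'   admission).
#' @param n_dx_codes,n_med_codes Sizes of the diagnosis and medication code
#'   universes.
#' @param zipf_exponent Power-law exponent of code frequencies (heavier than
#'   1 gives a long sub-50-count rare tail).
#' @param disease_codes Diagnosis code(s) defining the study cohort.
#' @param incidence Probability a patient carries the study disease.
#' @param risk_code Diagnosis code whose recent history raises readmission
#'   risk (chosen outside the Elixhauser map).
#' @param risk_dx_prob Probability an admission records the risk diagnosis.
#' @param base_logodds Baseline per-discharge readmission log-odds.
#' @param effect_emergency Added log-odds per emergency-department visit in
#'   the discharge month (the (1, 0)-kernel window).
#' @param effect_risk_dx Added log-odds per risk-diagnosis event in the 12
#'   months up to discharge (the (12, 0)-kernel window).
#' @param readmit_median_months Median readmission gap at the start of the
#'   study, in months.
#' @param readmit_median_drift Added to the median gap by the end of the
#'   span (time-to-readmission drifts upward across calendar time).
#' @param max_chain Maximum planted readmissions per patient.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_patients = 2000,
                       span_years = 9,
                       origin = as.Date("2003-01-01"),
                       mean_admissions = 2.5,
                       emergency_frac = 0.4,
                       mean_ed_visits = 3,
                       n_dx_codes = 400,
                       n_med_codes = 200,
                       zipf_exponent = 1.3,
                       disease_codes = "J449",
                       incidence = 0.5,
                       risk_code = "R074",
                       risk_dx_prob = 0.3,
                       base_logodds = stats::qlogis(0.15),
                       effect_emergency = 1.0,
                       effect_risk_dx = 1.0,
                       readmit_median_months = 3,
                       readmit_median_drift = 2,
                       max_chain = 8) {
  if (span_years < 4)
    stop("`span_years` must be at least 4", call. = FALSE)
  stopifnot(n_patients >= 0, emergency_frac >= 0, emergency_frac <= 1,
            incidence >= 0, incidence <= 1,
            risk_dx_prob >= 0, risk_dx_prob <= 1)
  cfg <- list(
    n_patients = as.integer(n_patients), span_years = span_years,
    origin = as.Date(origin), mean_admissions = mean_admissions,
    emergency_frac = emergency_frac, mean_ed_visits = mean_ed_visits,
    n_dx_codes = as.integer(n_dx_codes),
    n_med_codes = as.integer(n_med_codes), zipf_exponent = zipf_exponent,
    disease_codes = disease_codes, incidence = incidence,
    risk_code = risk_code, risk_dx_prob = risk_dx_prob,
    base_logodds = base_logodds, effect_emergency = effect_emergency,
    effect_risk_dx = effect_risk_dx,
    readmit_median_months = readmit_median_months,
    readmit_median_drift = readmit_median_drift,
    max_chain = as.integer(max_chain)
  )
  structure(cfg, class = "sim_config")
}

#' Timeline implied by a simulation config
#'
#' @param cfg A [sim_config()].
#' @param unit Timeline unit.
#' @return An [timeline()] spanning the configured study window.
#' @export
sim_timeline <- function(cfg, unit = "month") {
  n <- cfg$span_years * 12L * (if (unit == "day") 30L else 1L)
  timeline(cfg$origin, n_units = n, unit = unit)
}

# ICD-10-like diagnosis code universe: letter + 3 digits, excluding the
# cohort-defining and risk codes
sim_code_universe <- function(cfg) {
  letters10 <- c("A", "B", "C", "D", "E", "F", "G", "I", "J", "K", "L", "M", "N")
  pool <- as.vector(outer(letters10, sprintf("%03d", 0:999), paste0))
  pool <- setdiff(pool, c(cfg$disease_codes, cfg$risk_code))
  dx <- pool[seq(1, by = 17, length.out = cfg$n_dx_codes)]
  med <- sprintf("MED%03d", seq_len(cfg$n_med_codes))
  list(dx = dx, med = med)
}

zipf_weights <- function(n, s) {
  w <- seq_len(n)^(-s)
  w / sum(w)
}

#' Generate a synthetic hospital database
#'
#' Produces demographics and timestamped entity events for `cfg$n_patients`
#' patients. Admissions are continuing entities with start/end dates and an
#' emergency flag; each admission carries point diagnosis events (ICD-10-like
#' codes drawn from a Zipf distribution, the study disease per `incidence`,
#' and the risk diagnosis per `risk_dx_prob`) and medication point events;
#' every emergency admission is accompanied by an emergency-department point
#' event. After each discharge a Bernoulli readmission is drawn from a
#' logistic hazard on the patient's recent event counts; a readmission is
#' realized as a new emergency admission after a gap whose median drifts
#' upward over calendar time.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical seeds give identical databases.
#' @return List with `events` (tibble), `demographics` (tibble), `truth`
#'   (see [planted_truth()]), and `config`.
#' @export
simulate_ehr <- function(cfg = sim_config(), seed = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  tl <- sim_timeline(cfg)
  T_ <- tl$n_units
  uni <- sim_code_universe(cfg)
  w_dx <- zipf_weights(cfg$n_dx_codes, cfg$zipf_exponent)
  w_med <- zipf_weights(cfg$n_med_codes, cfg$zipf_exponent)
  postcodes <- sprintf("PC%02d", 1:25)
  w_pc <- zipf_weights(25, 1.1)

  with_local_seed(seed, {
    n <- cfg$n_patients
    pid <- sprintf("P%05d", seq_len(n))
    age0 <- pmin(95, pmax(18, round(stats::rnorm(n, 65, 15))))
    demographics <- tibble::tibble(
      patient_id = pid,
      birth_date = cfg$origin - round(age0 * 365.25) -
        sample(0:364, n, replace = TRUE),
      gender = sample(c("F", "M"), n, replace = TRUE),
      postcode = sample(postcodes, n, replace = TRUE, prob = w_pc)
    )
    diseased <- stats::runif(n) < cfg$incidence

    ev <- vector("list", n)
    for (i in seq_len(n)) {
      ev[[i]] <- simulate_patient(diseased[i], cfg, tl, uni, w_dx, w_med)
    }
    n_ev <- vapply(ev, function(e) length(e$code), integer(1))
    pull <- function(field, proto) {
      v <- unlist(lapply(ev, `[[`, field), use.names = FALSE)
      if (is.null(v)) proto else v
    }
    events <- tibble::tibble(
      patient_id = rep(pid, n_ev),
      code = pull("code", character(0)),
      class = pull("class", character(0)),
      kind = pull("kind", character(0)),
      start_date = cfg$origin + pull("start_off", integer(0)),
      end_date = cfg$origin + pull("end_off", integer(0)),
      emergency = pull("emergency", integer(0))
    )
    events <- events[order(events$patient_id, events$start_date,
                           events$class, events$code), ]
    list(events = events, demographics = demographics,
         truth = planted_truth(cfg), config = cfg)
  })
}

# one patient's events, as parallel vectors with day offsets from the origin
# (converted to dates once for the whole database)
simulate_patient <- function(diseased, cfg, tl, uni, w_dx, w_med) {
  T_ <- tl$n_units
  ud <- unit_days(tl)
  code <- character(0); class <- character(0); kind <- character(0)
  start_off <- integer(0); end_off <- integer(0); emergency <- integer(0)
  add <- function(co, cl, ki, so, eo, em) {
    m <- length(co)
    code <<- c(code, co)
    class <<- c(class, rep_len(cl, m))
    kind <<- c(kind, rep_len(ki, m))
    start_off <<- c(start_off, so)
    end_off <<- c(end_off, rep_len(eo, m))
    emergency <<- c(emergency, rep_len(em, m))
  }
  day_jitter <- function(n) if (ud > 1L) sample(0:(ud - 3L), n, replace = TRUE)
                            else integer(n)

  n_adm <- stats::rpois(1, cfg$mean_admissions)
  # extra community ED visits unattached to admissions
  n_ed <- stats::rpois(1, cfg$mean_ed_visits)
  ed_units <- integer(0)
  if (n_ed > 0) {
    m <- sample.int(T_, n_ed, replace = TRUE)
    add(rep("ED", n_ed), "emergency", "point",
        (m - 1L) * ud + day_jitter(n_ed), NA_integer_, NA_integer_)
    ed_units <- m
  }
  # queue of (unit, emergency flag) admissions processed in time order;
  # planted readmissions are pushed back onto the unprocessed tail
  q_unit <- sort(sample.int(T_, min(n_adm, T_)))
  q_em <- stats::runif(length(q_unit)) < cfg$emergency_frac
  first <- TRUE
  risk_units <- integer(0)
  planted <- 0L
  k <- 1L
  while (k <= length(q_unit)) {
    mth <- q_unit[k]
    emq <- q_em[k]
    so <- (mth - 1L) * ud + day_jitter(1L)
    los <- stats::rpois(1, 3)
    add("ADM", "admission", "continuing", so, so + los, as.integer(emq))
    n_dx <- 1L + stats::rpois(1, 2)
    dx_codes <- sample(uni$dx, n_dx, replace = TRUE, prob = w_dx)
    if (diseased && (first || stats::runif(1) < 0.3))
      dx_codes <- c(dx_codes, cfg$disease_codes[[1]])
    if (stats::runif(1) < cfg$risk_dx_prob) {
      dx_codes <- c(dx_codes, cfg$risk_code)
      risk_units <- c(risk_units, mth)
    }
    add(dx_codes, "diagnosis", "point", rep(so, length(dx_codes)),
        NA_integer_, NA_integer_)
    n_med <- stats::rpois(1, 2)
    if (n_med > 0)
      add(sample(uni$med, n_med, replace = TRUE, prob = w_med),
          "medication", "point", rep(so, n_med), NA_integer_, NA_integer_)
    if (emq) {
      add("ED", "emergency", "point", so, NA_integer_, NA_integer_)
      ed_units <- c(ed_units, mth)
    }
    first <- FALSE
    # logistic readmission hazard at the discharge unit
    dis_m <- min((so + los) %/% ud + 1L, T_)
    x_e <- sum(ed_units == dis_m)
    x_r <- sum(risk_units >= dis_m - 11L & risk_units <= dis_m)
    p <- stats::plogis(cfg$base_logodds +
                         cfg$effect_emergency * x_e +
                         cfg$effect_risk_dx * x_r)
    if (planted < cfg$max_chain && stats::runif(1) < p) {
      med <- cfg$readmit_median_months +
        cfg$readmit_median_drift * (dis_m / T_)
      gap <- max(1, round(stats::rlnorm(1, log(med), 0.6)))
      nxt <- dis_m + gap
      if (nxt <= T_) {
        # insert into the unprocessed tail, keeping it time-ordered
        ti <- if (k < length(q_unit)) (k + 1L):length(q_unit) else integer(0)
        tu <- c(q_unit[ti], as.integer(nxt))
        te <- c(q_em[ti], TRUE)
        o <- order(tu)
        q_unit <- c(q_unit[seq_len(k)], tu[o])
        q_em <- c(q_em[seq_len(k)], te[o])
        planted <- planted + 1L
      }
    }
    k <- k + 1L
  }
  list(code = code, class = class, kind = kind, start_off = start_off,
       end_off = end_off, emergency = emergency)
}

#' Planted ground truth of a simulation config
#'
#' Maps each nonzero planted effect to the temporal feature column expected
#' to carry it: the same-month emergency-visit effect loads on the
#' bandwidth-1, delay-0 kernel of the ED series; the 12-month risk-diagnosis
#' effect loads on the bandwidth-12, delay-0 kernel of the risk code's
#' series.
#'
#' @param cfg A [sim_config()].
#' @return Tibble `column, sign` (empty when all effects are zero).
#' @export
planted_truth <- function(cfg) {
  rows <- list()
  if (cfg$effect_emergency != 0)
    rows[[1]] <- tibble::tibble(column = "emergency:ED|uniform|1|0",
                                sign = sign(cfg$effect_emergency))
  if (cfg$effect_risk_dx != 0)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      column = sprintf("diagnosis:%s|uniform|12|0", cfg$risk_code),
      sign = sign(cfg$effect_risk_dx))
  if (length(rows) == 0L)
    return(tibble::tibble(column = character(), sign = numeric()))
  dplyr::bind_rows(rows)
}
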