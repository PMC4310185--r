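#' Demographic (static) features at assessment points
#'
#' Age in years at the AP (continuous), a binary gender indicator
#' (`gender_female`), and a one-hot encoding of postcode over the categories
#' seen at least `pool_min` times among derivation rows; rarer derivation
#' postcodes share a pooled `postcode__rare` column, and postcodes never seen
#' in derivation get all-zero indicators.
#'
#' @param aps AP tibble (`patient_id, t`).
#' @param demographics Tibble `patient_id, birth_date, gender, postcode`
#'   (gender coded `"F"`/`"M"`).
#' @param tl An [timeline()].
#' @param derivation_rows Integer indices of `aps` rows belonging to the
#'   derivation cohort (postcode categories are fitted on these only).
#'   Default: all rows.
#' @param pool_min Minimum derivation frequency for a postcode to get its own
#'   indicator (default 50, the rare-event threshold).
#' @return Dense numeric matrix, rows = APs, named columns.
#' @export
static_features <- function(aps, demographics, tl,
                            derivation_rows = seq_len(nrow(aps)),
                            pool_min = 50) {
  idx <- match(aps$patient_id, demographics$patient_id)
  if (anyNA(idx))
    stop("patients missing from demographics table: ",
         paste(utils::head(unique(aps$patient_id[is.na(idx)]), 5), collapse = ", "),
         call. = FALSE)
  demo <- demographics[idx, , drop = FALSE]
  ap_date <- index_to_date(aps$t, tl)
  age <- as.numeric(ap_date - as.Date(demo$birth_date)) / 365.25
  female <- as.numeric(demo$gender == "F")
  pc <- as.character(demo$postcode)
  pc_deriv <- pc[derivation_rows]
  freq <- table(pc_deriv)
  keep_levels <- sort(names(freq)[freq >= pool_min])
  rare_levels <- names(freq)[freq < pool_min]
  cols <- c("age", "gender_female",
            paste0("postcode_", keep_levels), "postcode__rare")
  out <- matrix(0, nrow = nrow(aps), ncol = length(cols),
                dimnames = list(NULL, cols))
  out[, "age"] <- age
  out[, "gender_female"] <- female
  for (lv in keep_levels)
    out[pc == lv, paste0("postcode_", lv)] <- 1
  out[pc %in% rare_levels, "postcode__rare"] <- 1
  out
}

#' Assemble one of the four study feature sets
#'
#' Column composition per feature set:
#' * `baseline_1M` — demographics + 30 comorbidity flags over a 1-month
#'   lookback.
#' * `baseline_3Y` — demographics + 30 comorbidity flags over a 36-month
#'   lookback.
#' * `MR` — the M x N temporal block ([temporal_features()], 36-month history
#'   cap) + demographics.
#' * `MR_comorbidities` — `MR` plus the 30 comorbidity flags (36-month
#'   lookback).
#'
#' @param name One of `"baseline_1M"`, `"baseline_3Y"`, `"MR"`,
#'   `"MR_comorbidities"`.
#' @param aps AP tibble (`patient_id, t`, plus label columns, kept as row
#'   metadata).
#' @param counts Long count tibble (vocabulary already applied).
#' @param bank An [filter_bank()].
#' @param tl An [timeline()].
#' @param demographics Demographics tibble.
#' @param codes Series universe for the temporal block (see
#'   [temporal_features()]).
#' @param events Optional raw events tibble used for the comorbidity block,
#'   so ICD codes are matched before any vocabulary pooling; when `NULL`,
#'   diagnosis codes are reconstructed from `counts`.
#' @param cmap A `comorbidity_map`.
#' @param derivation_rows Row indices used to fit postcode categories.
#' @param history_months Temporal history cap (default 36).
#' @param pool_min Postcode pooling threshold.
#' @return A `feature_matrix`: list with `x` (dgCMatrix, rows = APs), `aps`,
#'   and `name`.
#' @export
build_feature_set <- function(name, aps, counts, bank, tl, demographics,
                              codes = NULL, events = NULL,
                              cmap = elixhauser_map(),
                              derivation_rows = seq_len(nrow(aps)),
                              history_months = 36, pool_min = 50) {
  valid <- c("baseline_1M", "baseline_3Y", "MR", "MR_comorbidities")
  if (!name %in% valid)
    stop("unknown feature set: ", name, " (expected one of ",
         paste(valid, collapse = ", "), ")", call. = FALSE)
  demo <- static_features(aps, demographics, tl,
                          derivation_rows = derivation_rows,
                          pool_min = pool_min)
  blocks <- list()
  if (name %in% c("MR", "MR_comorbidities")) {
    blocks$temporal <- temporal_features(counts, aps, bank, tl, codes = codes,
                                         history_months = history_months)
  }
  blocks$demo <- Matrix::Matrix(demo, sparse = TRUE)
  lookback <- switch(name, baseline_1M = 1, baseline_3Y = 36,
                     MR_comorbidities = 36, NULL)
  if (!is.null(lookback)) {
    ev <- if (is.null(events)) counts_to_events(counts, tl) else events
    blocks$comorb <- Matrix::Matrix(
      comorbidity_features(aps, ev, tl, lookback_months = lookback,
                           cmap = cmap) * 1, sparse = TRUE)
  }
  x <- do.call(cbind, unname(blocks))
  if (anyDuplicated(colnames(x)))
    stop("duplicate feature column names", call. = FALSE)
  structure(list(x = x, aps = aps, name = name), class = "feature_matrix")
}

# re-materialize a minimal point-event table from per-unit counts, for
# comorbidity window arithmetic on already-discretized data
counts_to_events <- function(counts, tl) {
  tibble::tibble(
    patient_id = rep(counts$patient_id, counts$n),
    code = rep(counts$code, counts$n),
    class = rep(counts$class, counts$n),
    kind = "point",
    start_date = index_to_date(rep(counts$t, counts$n), tl),
    end_date = as.Date(NA)
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %s: %d APs x %d features\n",
              x$name, nrow(x$x), ncol(x$x)))
  invisible(x)
}

#' Fit the normalization + square-root transform on derivation rows
#'
#' Per column, min and max are fitted on the derivation rows only; every
#' value is mapped to `(v - min) / (max - min)`, clipped to `[0, 1]` (so
#' validation values outside the derivation range stay in range), and then
#' square-rooted. Constant columns map to all zeros.
#'
#' @param fm A `feature_matrix` (or bare numeric matrix).
#' @param derivation_rows Integer row indices of the derivation cohort.
#' @return List with `x` (transformed dense matrix) and `params`
#'   (a `feature_transform` tibble: `column, min, max`).
#' @export
fit_transform <- function(fm, derivation_rows) {
  x <- if (inherits(fm, "feature_matrix")) fm$x else fm
  x <- as.matrix(x)
  if (ncol(x) == 0L)
    return(list(x = x, params = tibble::tibble(column = character(),
                                               min = numeric(), max = numeric())))
  stopifnot(length(derivation_rows) > 0)
  xd <- x[derivation_rows, , drop = FALSE]
  mins <- apply(xd, 2, min)
  maxs <- apply(xd, 2, max)
  params <- structure(
    tibble::tibble(column = colnames(x), min = mins, max = maxs),
    class = c("feature_transform", class(tibble::tibble()))
  )
  list(x = apply_transform(x, params), params = params)
}

#' Apply fitted transform parameters to a (new) feature matrix
#'
#' @param x Numeric matrix whose columns match `params$column`.
#' @param params A `feature_transform` from [fit_transform()].
#' @return Transformed dense matrix with all values in `[0, 1]`.
#' @export
apply_transform <- function(x, params) {
  x <- as.matrix(x)
  if (!identical(colnames(x), params$column))
    stop("column names do not match transform parameters", call. = FALSE)
  rng <- params$max - params$min
  scale <- ifelse(rng > 0, 1 / rng, 0)
  out <- sweep(x, 2, params$min, "-")
  out <- sweep(out, 2, scale, "*")
  out[out < 0] <- 0
  out[out > 1] <- 1
  sqrt(out)
}
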