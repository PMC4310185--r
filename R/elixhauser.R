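#' The bundled Elixhauser ICD-10 comorbidity map
#'
#' Thirty Elixhauser comorbidity categories with their ICD-10 code prefixes,
#' following the Quan et al. enhanced ICD-10 coding algorithm (with the two
#' hypertension categories combined into one, giving 30 indicators).
#' Prefixes are stored without dots; matching is case- and dot-insensitive.
#'
#' @return A `comorbidity_map`: tibble `comorbidity, icd10_prefix` whose
#'   `comorbidity` factor order fixes the 30-dimensional flag vector layout.
#' @export
elixhauser_map <- function() {
  path <- system.file("extdata", "elixhauser_icd10_quan.csv",
                      package = "ehrtempo", mustWork = TRUE)
  tab <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  structure(tab,
            comorbidities = unique(tab$comorbidity),
            class = c("comorbidity_map", class(tab)))
}

#' Names of the 30 comorbidity flags, in vector order
#'
#' @param cmap A `comorbidity_map` (default: [elixhauser_map()]).
#' @return Character vector of length 30.
#' @export
comorbidity_names <- function(cmap = elixhauser_map()) {
  attr(cmap, "comorbidities")
}

normalize_icd10 <- function(codes) toupper(gsub(".", "", codes, fixed = TRUE))

# flags for each *unique* code: logical matrix codes x comorbidities
match_codes_matrix <- function(codes, cmap) {
  cms <- comorbidity_names(cmap)
  out <- matrix(FALSE, nrow = length(codes), ncol = length(cms),
                dimnames = list(codes, cms))
  if (length(codes) == 0L) return(out)
  for (j in seq_along(cms)) {
    prefixes <- cmap$icd10_prefix[cmap$comorbidity == cms[j]]
    hit <- rep(FALSE, length(codes))
    for (p in prefixes) hit <- hit | startsWith(codes, p)
    out[, j] <- hit
  }
  out
}

apply_quan_exclusions <- function(flags) {
  # complicated diabetes supersedes uncomplicated; metastatic cancer
  # supersedes solid tumour
  if (is.matrix(flags)) {
    flags[flags[, "diabetes_complicated"] > 0, "diabetes_uncomplicated"] <- 0L
    flags[flags[, "metastatic_cancer"] > 0, "solid_tumor"] <- 0L
  } else {
    if (flags[["diabetes_complicated"]] > 0) flags[["diabetes_uncomplicated"]] <- 0L
    if (flags[["metastatic_cancer"]] > 0) flags[["solid_tumor"]] <- 0L
  }
  flags
}

#' Map ICD-10 codes to the 30 Elixhauser comorbidity flags
#'
#' A flag is set when any supplied code matches (by prefix, case- and
#' dot-insensitively) any of the comorbidity's prefixes. Malformed codes
#' (not a letter followed by a digit) are ignored with a warning.
#'
#' @param icd_codes Character vector of ICD-10 codes.
#' @param cmap A `comorbidity_map` (default [elixhauser_map()]).
#' @param exclusions Apply the Quan hierarchy exclusions (complicated
#'   diabetes over uncomplicated, metastatic cancer over solid tumour);
#'   default `TRUE`.
#' @return Named integer 0/1 vector of length 30, in [comorbidity_names()]
#'   order.
#' @export
map_codes <- function(icd_codes, cmap = elixhauser_map(), exclusions = TRUE) {
  codes <- normalize_icd10(icd_codes)
  ok <- !is.na(codes) & grepl("^[A-Z][0-9]", codes)
  if (any(!ok))
    warning(sum(!ok), " malformed ICD-10 code(s) ignored", call. = FALSE)
  codes <- unique(codes[ok])
  m <- match_codes_matrix(codes, cmap)
  flags <- as.integer(colSums(m) > 0)
  names(flags) <- comorbidity_names(cmap)
  if (exclusions) flags <- apply_quan_exclusions(flags)
  flags
}

#' Comorbidity flags at assessment points
#'
#' For each assessment point, collects the diagnosis codes recorded in the
#' closed lookback window `[ap_t - lookback_units, ap_t]` (the AP's own unit
#' included, so the index stay contributes) and maps them through
#' [map_codes()].
#'
#' @param aps AP tibble with columns `patient_id, t`.
#' @param events Events tibble; rows of `class == diagnosis_class` supply
#'   ICD-10 codes.
#' @param tl An [timeline()].
#' @param lookback_months Lookback window in months (the study uses 1 and 36).
#' @param cmap A `comorbidity_map`.
#' @param exclusions See [map_codes()].
#' @param diagnosis_class Entity class carrying ICD codes.
#' @return Integer matrix, rows = APs (in `aps` order), 30 named columns.
#' @export
comorbidity_features <- function(aps, events, tl, lookback_months = 36,
                                 cmap = elixhauser_map(), exclusions = TRUE,
                                 diagnosis_class = "diagnosis") {
  cms <- comorbidity_names(cmap)
  out <- matrix(0L, nrow = nrow(aps), ncol = length(cms),
                dimnames = list(NULL, cms))
  dx <- events[events$class == diagnosis_class, , drop = FALSE]
  if (nrow(dx) == 0L || nrow(aps) == 0L) return(out)
  dx_t <- tibble::tibble(
    patient_id = dx$patient_id,
    code = normalize_icd10(dx$code),
    t = date_to_index(dx$start_date, tl)
  ) |> dplyr::filter(.data$t <= tl$n_units)
  lb <- as.integer(lookback_months * units_per_month(tl))
  win <- tibble::tibble(.ap = seq_len(nrow(aps)),
                        patient_id = aps$patient_id,
                        lo = as.integer(aps$t) - lb,
                        hi = as.integer(aps$t))
  hits <- dplyr::inner_join(
    win, dx_t,
    by = dplyr::join_by("patient_id", "lo" <= "t", "hi" >= "t"),
    relationship = "many-to-many"
  )
  if (nrow(hits) == 0L) return(out)
  ucodes <- unique(hits$code)
  cmat <- match_codes_matrix(ucodes, cmap)           # unique code -> flags
  keep <- rowSums(cmat) > 0
  cmat <- cmat[keep, , drop = FALSE]
  hits <- hits[hits$code %in% rownames(cmat), , drop = FALSE]
  if (nrow(hits) == 0L) return(out)
  # OR the flag rows of each AP's matched codes
  idx <- match(hits$code, rownames(cmat))
  for (j in seq_along(cms)) {
    ap_hit <- unique(hits$.ap[cmat[idx, j]])
    out[ap_hit, j] <- 1L
  }
  if (exclusions) out <- apply_quan_exclusions(out)
  out
}
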