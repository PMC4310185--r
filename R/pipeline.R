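#' Pipeline configuration
#'
#' Collects every tunable of the extraction and evaluation pipeline. Defaults
#' reproduce the study protocol: monthly units, the six-kernel uniform bank
#' over 36 months of history, rare-event pooling below 50 occurrences, a
#' 2000-code dictionary cap per class, horizons of 1/2/3/6/12 months, and
#' assessment points at unplanned discharges.
#'
#' @param origin,n_units,unit Timeline settings (see [timeline()]).
#' @param bank An [filter_bank()] (default [default_filter_bank()]).
#' @param min_count,max_size Vocabulary thresholds (see [build_vocabulary()]).
#' @param disease_codes Cohort-defining diagnosis codes.
#' @param horizons_months Prediction horizons in months.
#' @param validation_point Date or time index separating derivation from
#'   validation.
#' @param ap_mode `"discharge"` or `"fixed_date"`.
#' @param fixed_dates Assessment dates for `ap_mode = "fixed_date"`.
#' @param unplanned_only Restrict APs to emergency-flagged discharges.
#' @param feature_sets Feature sets to evaluate.
#' @param history_months Temporal history cap.
#' @param alpha,nfolds Elastic-net settings.
#' @param seed Integer seed for model fitting.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(origin = as.Date("2003-01-01"),
                            n_units = 108,
                            unit = "month",
                            bank = default_filter_bank(),
                            min_count = 50,
                            max_size = 2000,
                            disease_codes = "J449",
                            horizons_months = c(1, 2, 3, 6, 12),
                            validation_point = NULL,
                            ap_mode = "discharge",
                            fixed_dates = NULL,
                            unplanned_only = TRUE,
                            feature_sets = c("baseline_1M", "baseline_3Y",
                                             "MR", "MR_comorbidities"),
                            history_months = 36,
                            alpha = 0.5,
                            nfolds = 5,
                            seed = 1) {
  if (is.null(validation_point)) validation_point <- ceiling(n_units * 2 / 3)
  structure(
    list(origin = as.Date(origin), n_units = as.integer(n_units), unit = unit,
         bank = bank, min_count = min_count, max_size = max_size,
         disease_codes = disease_codes, horizons_months = horizons_months,
         validation_point = validation_point, ap_mode = ap_mode,
         fixed_dates = fixed_dates, unplanned_only = unplanned_only,
         feature_sets = feature_sets, history_months = history_months,
         alpha = alpha, nfolds = nfolds, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

config_timeline <- function(config) {
  timeline(config$origin, config$n_units, config$unit)
}

# validation point as a time index, whether given as date or index
config_validation_index <- function(config, tl) {
  vp <- config$validation_point
  if (inherits(vp, "Date") || is.character(vp))
    date_to_index(as.Date(vp), tl) else as.integer(vp)
}

#' Read a pipeline config from YAML
#'
#' Recognized keys mirror the arguments of [pipeline_config()]; the filter
#' bank is given as a list of `{family, sigma_months, delay_months}` blocks.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$bank)) {
    y$bank <- filter_bank(lapply(y$bank, function(b)
      kernel(b$family %||% "uniform", b$sigma_months, b$delay_months %||% 0)))
  }
  args <- y[intersect(names(y), names(formals(pipeline_config)))]
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the extraction stages: series, vocabulary, assessment points, split
#'
#' Discretizes events, builds the vocabulary on the derivation period only
#' (events before the validation point, for leakage control), pools rare
#' codes, places and labels assessment points, and performs the
#' patient-and-time-disjoint split.
#'
#' @param events Events tibble.
#' @param config A [pipeline_config()].
#' @param schema Optional schema tibble; when supplied, events are first
#'   expanded onto ancestor codes with [expand_hierarchy()].
#' @return List with `tl, counts, vocab, codes, aps, split` (and `events`,
#'   hierarchy-expanded when a schema was given). `message()`s report M, N
#'   and M x N.
#' @export
extract_features <- function(events, config = pipeline_config(),
                             schema = NULL) {
  tl <- config_timeline(config)
  if (!is.null(schema)) events <- expand_hierarchy(events, schema)
  vp <- config_validation_index(config, tl)
  deriv_events <- events[date_to_index(events$start_date, tl) < vp, ,
                         drop = FALSE]
  vocab <- build_vocabulary(deriv_events, min_count = config$min_count,
                            max_size = config$max_size)
  counts <- discretize_events(apply_vocabulary(events, vocab), tl)
  codes <- vocabulary_codes(vocab)
  aps <- find_assessment_points(events, config$disease_codes, tl,
                                mode = config$ap_mode,
                                fixed_dates = config$fixed_dates,
                                unplanned_only = config$unplanned_only)
  aps <- label_assessment_points(aps, events, tl,
                                 horizons_months = config$horizons_months)
  split <- temporal_split(aps, vp)
  m <- nrow(codes)
  n_k <- length(config$bank)
  message(sprintf("M = %d event series, N = %d kernels, M x N = %d temporal features",
                  m, n_k, m * n_k))
  list(tl = tl, events = events, counts = counts, vocab = vocab,
       codes = codes, aps = aps, split = split)
}

#' End-to-end readmission evaluation
#'
#' Runs [extract_features()] and then [run_experiment()] over the configured
#' feature sets and horizons.
#'
#' @param events Events tibble.
#' @param demographics Demographics tibble.
#' @param config A [pipeline_config()].
#' @param schema Optional schema tibble.
#' @param keep_fits Keep fitted models as an attribute of the result.
#' @return A `readmission_results` tibble (see [run_experiment()]) with the
#'   extraction stages attached as attribute `"stages"`.
#' @export
evaluate_readmission <- function(events, demographics,
                                 config = pipeline_config(), schema = NULL,
                                 keep_fits = FALSE) {
  st <- extract_features(events, config, schema = schema)
  res <- run_experiment(st$split, st$counts, st$events, demographics,
                        config$bank, st$tl, codes = st$codes,
                        feature_sets = config$feature_sets,
                        horizons_months = config$horizons_months,
                        alpha = config$alpha, nfolds = config$nfolds,
                        seed = config$seed, keep_fits = keep_fits)
  attr(res, "stages") <- st
  res
}

write_manifest <- function(outdir, config, seed, stage) {
  cfg <- config
  cfg$bank <- lapply(cfg$bank, unclass)
  cfg$origin <- format(cfg$origin)
  manifest <- list(
    stage = stage,
    seed = seed,
    config_hash = rlang::hash(cfg),
    package_version = as.character(utils::packageVersion("ehrtempo")),
    r_version = as.character(getRversion()),
    written = format(Sys.time(), tz = "UTC")
  )
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
}

#' File-based pipeline commands
#'
#' Thin wrappers tying the stages to fixed artifacts on disk; these back the
#' `simulate`, `extract` and `evaluate` subcommands of the bundled CLI script
#' (`system.file("cli", "ehrtempo.R", package = "ehrtempo")`). Each run
#' writes a `manifest.yaml` (config hash, versions, seed) to the output
#' directory.
#'
#' @param outdir Output directory (created if missing).
#' @param cfg A [sim_config()] (for `cmd_simulate`).
#' @param config A [pipeline_config()] (for extract/evaluate).
#' @param seed Integer seed.
#' @param events_path,demographics_path Input CSVs written by `cmd_simulate`.
#' @return Invisibly, the paths written.
#' @export
cmd_simulate <- function(outdir, cfg = sim_config(), seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  db <- simulate_ehr(cfg, seed = seed)
  paths <- c(events = file.path(outdir, "events.csv"),
             demographics = file.path(outdir, "demographics.csv"),
             truth = file.path(outdir, "truth.yaml"))
  readr::write_csv(db$events, paths["events"])
  readr::write_csv(db$demographics, paths["demographics"])
  yaml::write_yaml(list(planted = purrr::transpose(db$truth)),
                   paths["truth"])
  pc <- pipeline_config(origin = cfg$origin, n_units = cfg$span_years * 12,
                        seed = seed)
  write_manifest(outdir, pc, seed, "simulate")
  invisible(paths)
}

#' @rdname cmd_simulate
#' @export
cmd_extract <- function(events_path, demographics_path, outdir,
                        config = pipeline_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  events <- read_events(events_path)
  demographics <- readr::read_csv(demographics_path, show_col_types = FALSE)
  st <- extract_features(events, config)
  aps_out <- dplyr::bind_rows(
    dplyr::mutate(st$split$derivation, split = "derivation"),
    dplyr::mutate(st$split$validation, split = "validation")
  ) |> dplyr::mutate(ap_date = index_to_date(.data$t, st$tl), .after = "t")
  paths <- c(aps = file.path(outdir, "assessment_points.csv"),
             vocab = file.path(outdir, "vocabulary.csv"),
             features = file.path(outdir, "features_MR.csv"))
  readr::write_csv(aps_out, paths["aps"])
  write_vocabulary(st$vocab, paths["vocab"])
  aps_all <- dplyr::bind_rows(st$split$derivation, st$split$validation)
  fm <- build_feature_set("MR", aps_all, st$counts, config$bank, st$tl,
                          demographics, codes = st$codes,
                          derivation_rows = seq_len(nrow(st$split$derivation)),
                          history_months = config$history_months)
  dense <- as.data.frame(as.matrix(fm$x))
  readr::write_csv(
    dplyr::bind_cols(tibble::tibble(patient_id = aps_all$patient_id,
                                    t = aps_all$t), dense),
    paths["features"])
  write_manifest(outdir, config, config$seed, "extract")
  invisible(paths)
}

#' @rdname cmd_simulate
#' @export
cmd_evaluate <- function(events_path, demographics_path, outdir,
                         config = pipeline_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  events <- read_events(events_path)
  demographics <- readr::read_csv(demographics_path, show_col_types = FALSE)
  res <- evaluate_readmission(events, demographics, config)
  path <- file.path(outdir, "results.csv")
  readr::write_csv(tibble::as_tibble(res), path)
  write_manifest(outdir, config, config$seed, "evaluate")
  invisible(c(results = path))
}
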