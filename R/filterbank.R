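#' One-sided convolution kernels
#'
#' A kernel aggregates an event count series over a window of the past. Each
#' kernel has a bandwidth sigma (the temporal scale, in months) and a delay h
#' (how far the window is shifted into the past, in months); the delay
#' operator shifts the kernel backward so only history before the point
#' t - h is accounted for.
#'
#' The discrete uniform kernel takes value `1/sigma` on the half-open
#' support `0 <= u < sigma` and 0 elsewhere, so its mass is exactly 1 and
#' the convolution equals the mean event rate over the window. The one-sided
#' Gaussian takes value `sqrt(2/(pi sigma^2)) exp(-u^2 / (2 sigma^2))` for
#' `u > 0` and 0 at `u <= 0`; its continuous integral over (0, Inf) is 1 and
#' it is evaluated pointwise at integer offsets without discrete
#' renormalization.
#'
#' @param family `"uniform"` or `"gaussian"`.
#' @param sigma_months Positive bandwidth, in months.
#' @param delay_months Non-negative integer delay, in months.
#' @return An `ehr_kernel` object.
#' @seealso [filter_bank()], [extract_feature()]
#' @export
kernel <- function(family = c("uniform", "gaussian"), sigma_months,
                   delay_months = 0) {
  family <- match.arg(family)
  if (!is.numeric(sigma_months) || length(sigma_months) != 1L || sigma_months <= 0)
    stop("`sigma_months` must be a positive number", call. = FALSE)
  if (!is.numeric(delay_months) || length(delay_months) != 1L || delay_months < 0)
    stop("`delay_months` must be non-negative", call. = FALSE)
  structure(
    list(family = family, sigma_months = sigma_months,
         delay_months = delay_months),
    class = "ehr_kernel"
  )
}

#' @export
print.ehr_kernel <- function(x, ...) {
  cat(sprintf("<ehr_kernel> %s(sigma = %g, delay = %g) months\n",
              x$family, x$sigma_months, x$delay_months))
  invisible(x)
}

#' Uniform kernel value
#'
#' `1/sigma` for offsets `0 <= t < sigma`, 0 elsewhere (one-sided, half-open
#' support so the discrete mass is exactly 1).
#'
#' @param t Integer time offset(s), in timeline units.
#' @param sigma Positive bandwidth in timeline units.
#' @return Kernel value(s).
#' @export
uniform_kernel_value <- function(t, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  ifelse(t >= 0 & t < sigma, 1 / sigma, 0)
}

#' One-sided Gaussian kernel value
#'
#' `sqrt(2/(pi sigma^2)) exp(-t^2/(2 sigma^2))` for `t > 0`, 0 for `t <= 0`.
#'
#' @inheritParams uniform_kernel_value
#' @return Kernel value(s).
#' @export
gaussian_kernel_value <- function(t, sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("`sigma` must be positive", call. = FALSE)
  ifelse(t > 0, sqrt(2 / (pi * sigma^2)) * exp(-t^2 / (2 * sigma^2)), 0)
}

# kernel value at offset u (already delay-adjusted), in timeline units
kernel_value <- function(k, u, upm = 1L) {
  sigma_u <- k$sigma_months * upm
  switch(k$family,
         uniform = uniform_kernel_value(u, sigma_u),
         gaussian = gaussian_kernel_value(u, sigma_u))
}

#' A bank of one-sided kernels
#'
#' @param ... `ehr_kernel` objects, or a single list of them.
#' @return An `ehr_filter_bank` (ordered kernel list). The (family, sigma,
#'   delay) triples must be unique.
#' @export
filter_bank <- function(...) {
  ks <- list(...)
  if (length(ks) == 1L && !inherits(ks[[1]], "ehr_kernel")) ks <- ks[[1]]
  if (length(ks) < 1L) stop("a filter bank needs at least one kernel", call. = FALSE)
  ok <- vapply(ks, inherits, logical(1), "ehr_kernel")
  if (!all(ok)) stop("all elements must be ehr_kernel objects", call. = FALSE)
  key <- vapply(ks, function(k)
    paste(k$family, k$sigma_months, k$delay_months, sep = "|"), character(1))
  if (anyDuplicated(key))
    stop("duplicate (family, sigma, delay) in filter bank", call. = FALSE)
  structure(ks, class = "ehr_filter_bank")
}

#' The default multi-resolution bank
#'
#' Six uniform kernels with (bandwidth, delay) pairs, in months:
#' (1, 0), (3, 0), (6, 0), (12, 0), (12, 12), (12, 24). Together they tile
#' 36 months of history before each assessment point at several temporal
#' resolutions.
#'
#' @return An `ehr_filter_bank` of size 6.
#' @export
default_filter_bank <- function() {
  pairs <- list(c(1, 0), c(3, 0), c(6, 0), c(12, 0), c(12, 12), c(12, 24))
  filter_bank(lapply(pairs, function(p) kernel("uniform", p[1], p[2])))
}

#' @export
print.ehr_filter_bank <- function(x, ...) {
  cat(sprintf("<ehr_filter_bank> N = %d kernels\n", length(x)))
  for (k in x)
    cat(sprintf("  %s(sigma = %g, delay = %g) months\n",
                k$family, k$sigma_months, k$delay_months))
  invisible(x)
}

# canonical column label for one (series, kernel) pair; sigma/delay in months
kernel_label <- function(k) {
  sprintf("%s|%g|%g", k$family, k$sigma_months, k$delay_months)
}

feature_names <- function(classes, codes, bank) {
  if (length(codes) == 0L) return(character(0))
  klab <- vapply(bank, kernel_label, character(1))
  # series-major ordering: all kernels of series 1, then series 2, ...
  as.vector(t(outer(paste0(classes, ":", codes), klab, paste, sep = "|")))
}

#' Convolve one event series with one kernel at time t
#'
#' Computes `X(t) = sum_{h=0}^{t-1} K(h - delay) E(t - h)`: a one-sided
#' convolution over the history up to and including unit `t`. With delay d,
#' events in units `(t-d, t]` contribute nothing.
#'
#' @param series Numeric count vector E(1..T) (e.g. an `event_series`).
#' @param k An [kernel()].
#' @param t Evaluation unit, `1 <= t <= length(series)`.
#' @param upm Units per month of the series' timeline (1 for monthly series,
#'   30 for daily); converts the kernel's month-valued bandwidth and delay.
#' @return The scalar feature value X(t).
#' @export
extract_feature <- function(series, k, t, upm = 1L) {
  stopifnot(inherits(k, "ehr_kernel"))
  t <- as.integer(t)
  if (t < 1L || t > length(series))
    stop("`t` out of range 1..T", call. = FALSE)
  h <- 0:(t - 1L)
  d <- k$delay_months * upm
  sum(kernel_value(k, h - d, upm) * series[t - h])
}

#' Extract the full feature block for one patient at time t
#'
#' Evaluates every (series, kernel) pair, giving M x N named features with
#' deterministic names `class:code|family|sigma|delay` (sigma and delay in
#' months) in series-major order.
#'
#' @param series_list List of count vectors sharing one timeline; names or
#'   `entity_code` attributes supply the code part of the feature names.
#' @param bank An [filter_bank()].
#' @param t Evaluation unit.
#' @param classes Character vector of entity classes, recycled to the series
#'   list (default `"entity"`).
#' @param upm Units per month (see [extract_feature()]).
#' @return Named numeric vector of length `M * N`.
#' @export
extract_block <- function(series_list, bank, t, classes = "entity", upm = 1L) {
  stopifnot(inherits(bank, "ehr_filter_bank"))
  m <- length(series_list)
  if (m == 0L) return(stats::setNames(numeric(0), character(0)))
  lens <- lengths(series_list)
  if (length(unique(lens)) != 1L)
    stop("all series must share one timeline length", call. = FALSE)
  codes <- names(series_list)
  if (is.null(codes))
    codes <- vapply(series_list, function(s) {
      ec <- attr(s, "entity_code")
      if (is.null(ec)) NA_character_ else ec
    }, character(1))
  classes <- rep_len(classes, m)
  vals <- unlist(lapply(series_list, function(s)
    vapply(bank, function(k) extract_feature(s, k, t, upm), numeric(1))),
    use.names = FALSE)
  stats::setNames(vals, feature_names(classes, codes, bank))
}

#' Temporal feature block at many assessment points
#'
#' Sparse, vectorized evaluation of the filter-bank convolution for every
#' assessment point at once, over a capped history window. Equivalent to
#' calling [extract_feature()] per (series, kernel, point) but computed with
#' windowed joins.
#'
#' @param counts Long count tibble from [discretize_events()]
#'   (`patient_id, class, code, t, n`), typically after [apply_vocabulary()].
#' @param aps Assessment point tibble with columns `patient_id, t`.
#' @param bank An [filter_bank()].
#' @param tl The [timeline()] shared by `counts` and `aps`.
#' @param codes Tibble `class, code` fixing the series universe and order
#'   (e.g. [vocabulary_codes()]); codes absent from `counts` yield zero
#'   columns. Default: the distinct class/code pairs present in `counts`.
#' @param history_months History cap H: events more than H months before an
#'   assessment point are ignored (default 36).
#' @return Sparse `dgCMatrix`, rows = assessment points (in `aps` order),
#'   columns = M x N named temporal features.
#' @export
temporal_features <- function(counts, aps, bank, tl,
                              codes = NULL, history_months = 36) {
  stopifnot(inherits(bank, "ehr_filter_bank"), inherits(tl, "ehr_timeline"))
  upm <- units_per_month(tl)
  if (is.null(codes))
    codes <- dplyr::distinct(counts, .data$class, .data$code) |>
      dplyr::arrange(.data$class, .data$code)
  cn <- feature_names(codes$class, codes$code, bank)
  n_ap <- nrow(aps)
  n_k <- length(bank)
  if (n_ap == 0L || nrow(codes) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n_ap, length(cn)),
                                dimnames = list(NULL, cn)))
  series_idx <- stats::setNames(seq_len(nrow(codes)),
                                paste(codes$class, codes$code, sep = "\r"))
  counts <- dplyr::mutate(
    counts, .series = series_idx[paste(.data$class, .data$code, sep = "\r")])
  counts <- counts[!is.na(counts$.series), c("patient_id", ".series", "t", "n")]
  ap_tbl <- tibble::tibble(.ap = seq_len(n_ap),
                           patient_id = aps$patient_id, ap_t = as.integer(aps$t))
  h_units <- history_months * upm
  trip <- vector("list", n_k)
  for (j in seq_len(n_k)) {
    k <- bank[[j]]
    d <- k$delay_months * upm
    # support of K(h - d) within the history cap: h in [lo_h, hi_h]
    if (k$family == "uniform") {
      lo_h <- d
      hi_h <- min(d + k$sigma_months * upm - 1, h_units - 1)
    } else {
      lo_h <- d + 1
      hi_h <- h_units - 1
    }
    if (hi_h < lo_h) next
    win <- dplyr::mutate(ap_tbl,
                         lo = .data$ap_t - as.integer(hi_h),
                         hi = .data$ap_t - as.integer(lo_h))
    hits <- dplyr::inner_join(
      win, counts,
      by = dplyr::join_by("patient_id", "lo" <= "t", "hi" >= "t"),
      relationship = "many-to-many"
    )
    if (nrow(hits) == 0L) next
    w <- kernel_value(k, (hits$ap_t - hits$t) - d, upm)
    agg <- dplyr::summarise(
      dplyr::group_by(tibble::tibble(.ap = hits$.ap, .series = hits$.series,
                                     v = w * hits$n),
                      .data$.ap, .data$.series),
      v = sum(.data$v), .groups = "drop")
    trip[[j]] <- tibble::tibble(i = agg$.ap,
                                col = (agg$.series - 1L) * n_k + j,
                                x = agg$v)
  }
  trip <- dplyr::bind_rows(trip)
  if (nrow(trip) == 0L)
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                x = numeric(0), dims = c(n_ap, length(cn)),
                                dimnames = list(NULL, cn)))
  Matrix::sparseMatrix(i = trip$i, j = trip$col, x = trip$x,
                       dims = c(n_ap, length(cn)),
                       dimnames = list(NULL, cn))
}

#' Plot the kernels of a filter bank
#'
#' Step plot of each kernel's weight as a function of months before the
#' evaluation point.
#'
#' @param object An `ehr_filter_bank`.
#' @param max_months Right edge of the plotted axis.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ehr_filter_bank <- function(object, max_months = 40, ...) {
  df <- purrr::map_dfr(object, function(k) {
    u <- seq(0, max_months, by = 0.25)
    tibble::tibble(
      kernel = sprintf("%s(%g, %g)", k$family, k$sigma_months, k$delay_months),
      months_before = u,
      weight = kernel_value(k, u - k$delay_months)
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$months_before, y = .data$weight,
                                   colour = .data$kernel)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "months before evaluation point", y = "kernel weight",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
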