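# run code with a private RNG stream, restoring the caller's state
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Fit elastic-net logistic regression
#'
#' Penalized logistic regression with a mixed L1/L2 penalty
#' (`alpha = l1_ratio`), suited to feature matrices with many more columns
#' than rows. The regularization strength is chosen by seeded k-fold
#' cross-validation on the derivation rows (maximizing cross-validated AUC
#' when class counts allow, otherwise binomial deviance).
#'
#' @param x Numeric or sparse matrix of transformed features (rows =
#'   derivation APs).
#' @param y Binary 0/1 labels; both classes must be present.
#' @param alpha Elastic-net mixing parameter, default 0.5.
#' @param nfolds Cross-validation folds, default 5.
#' @param seed Integer seed for the fold assignment (fit is deterministic
#'   given the seed).
#' @param lambda Optional regularization path passed to glmnet.
#' @return An `ehr_enet` object wrapping the `cv.glmnet` fit.
#' @export
fit_elastic_net <- function(x, y, alpha = 0.5, nfolds = 5, seed = 1,
                            lambda = NULL) {
  y <- as.integer(y)
  tab <- table(factor(y, levels = c(0, 1)))
  if (any(tab == 0L))
    stop("labels are single-class; cannot fit", call. = FALSE)
  if (!inherits(x, "sparseMatrix")) x <- Matrix::Matrix(as.matrix(x), sparse = TRUE)
  # a design with no varying column admits only the intercept solution
  colvar <- Matrix::colMeans(x^2) - Matrix::colMeans(x)^2
  if (!any(colvar > 1e-18)) {
    return(structure(
      list(cvfit = NULL, constant = TRUE, alpha = alpha, seed = seed,
           nfolds = nfolds, lambda = Inf, measure = "none",
           intercept = stats::qlogis(mean(y)), terms = colnames(x),
           n = length(y), n_pos = unname(tab["1"])),
      class = "ehr_enet"
    ))
  }
  measure <- if (min(tab) >= 8L * nfolds) "auc" else "deviance"
  fit <- with_local_seed(seed, {
    foldid <- sample(rep_len(seq_len(nfolds), length(y)))
    glmnet::cv.glmnet(x, y, family = "binomial", alpha = alpha,
                      type.measure = measure, foldid = foldid,
                      lambda = lambda, standardize = FALSE)
  })
  structure(
    list(cvfit = fit, alpha = alpha, seed = seed, nfolds = nfolds,
         lambda = fit$lambda.min, measure = measure,
         n = length(y), n_pos = unname(tab["1"])),
    class = "ehr_enet"
  )
}

#' @export
print.ehr_enet <- function(x, ...) {
  cat(sprintf(
    "<ehr_enet> alpha = %g, lambda = %.4g (cv %s), n = %d (%d positive)\n",
    x$alpha, x$lambda, x$measure, x$n, x$n_pos))
  invisible(x)
}

#' @export
coef.ehr_enet <- function(object, ...) {
  if (isTRUE(object$constant)) {
    cf <- Matrix::sparseMatrix(i = 1L, j = 1L, x = object$intercept,
                               dims = c(length(object$terms) + 1L, 1L))
    rownames(cf) <- c("(Intercept)", object$terms)
    colnames(cf) <- "s1"
    return(cf)
  }
  stats::coef(object$cvfit, s = "lambda.min")
}

#' @export
predict.ehr_enet <- function(object, newx, type = "response", ...) {
  if (isTRUE(object$constant)) {
    eta <- rep(object$intercept, nrow(newx))
    return(if (type == "response") stats::plogis(eta) else eta)
  }
  if (!inherits(newx, "sparseMatrix"))
    newx <- Matrix::Matrix(as.matrix(newx), sparse = TRUE)
  as.numeric(stats::predict(object$cvfit, newx = newx, s = "lambda.min",
                            type = type))
}

#' @exportS3Method generics::tidy
tidy.ehr_enet <- function(x, all = FALSE, ...) {
  cf <- coef.ehr_enet(x)
  out <- tibble::tibble(term = rownames(cf), estimate = as.numeric(cf))
  if (!all) out <- out[out$estimate != 0 | out$term == "(Intercept)", ]
  out
}

#' @exportS3Method generics::glance
glance.ehr_enet <- function(x, ...) {
  cf <- coef.ehr_enet(x)
  tibble::tibble(alpha = x$alpha, lambda = x$lambda,
                 n = x$n, n_pos = x$n_pos,
                 df = sum(as.numeric(cf)[-1] != 0), cv_measure = x$measure)
}

#' AUC with a Mann-Whitney 95% confidence interval
#'
#' The AUC is computed as the normalized Mann-Whitney U statistic,
#' `U / (n_pos * n_neg)`, counting concordant (positive scored above
#' negative) pairs with ties worth 0.5 — equivalent to the c-statistic. The
#' 95% CI uses the Hanley-McNeil variance with a normal approximation,
#' clipped to `[0, 1]`.
#'
#' @param scores Numeric risk scores.
#' @param labels Binary 0/1 outcome labels; both classes required.
#' @param conf_level Confidence level (default 0.95).
#' @return One-row tibble: `auc, ci_low, ci_high, n_pos, n_neg`.
#' @export
auc_mann_whitney <- function(scores, labels, conf_level = 0.95) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels),
            all(labels %in% c(0L, 1L)))
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be present to compute AUC", call. = FALSE)
  r <- rank(scores)                      # midranks handle ties as 0.5
  u <- sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg)
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble::tibble(
    auc = auc,
    ci_low = max(0, min(auc, auc - z * se)),
    ci_high = min(1, max(auc, auc + z * se)),
    n_pos = n_pos, n_neg = n_neg
  )
}

#' Fit and evaluate every (feature set, horizon) pair on a cohort split
#'
#' For each requested feature set, assembles features over all assessment
#' points, fits the normalization + square-root transform and the elastic net
#' on derivation rows per horizon, scores the validation rows, and reports
#' validation AUC with Mann-Whitney confidence intervals.
#'
#' @param split A `cohort_split` from [temporal_split()] whose AP tables
#'   carry `label_<h>m` columns.
#' @param counts Long count tibble (vocabulary applied).
#' @param events Raw events tibble (for comorbidity mapping).
#' @param demographics Demographics tibble.
#' @param bank An [filter_bank()].
#' @param tl An [timeline()].
#' @param codes Series universe tibble (see [temporal_features()]).
#' @param feature_sets Feature set names (default all four).
#' @param horizons_months Prediction horizons (default `c(1, 2, 3, 6, 12)`).
#' @param cmap A `comorbidity_map`.
#' @param alpha,nfolds,seed Elastic-net settings (regularization strength is
#'   tuned per (set, horizon) pair).
#' @param keep_fits Keep the fitted `ehr_enet` objects as an attribute.
#' @return A `readmission_results` tibble: `feature_set, horizon_months, auc,
#'   ci_low, ci_high, n_pos, n_neg, n_derivation, n_validation`.
#' @export
run_experiment <- function(split, counts, events, demographics, bank, tl,
                           codes = NULL,
                           feature_sets = c("baseline_1M", "baseline_3Y",
                                            "MR", "MR_comorbidities"),
                           horizons_months = c(1, 2, 3, 6, 12),
                           cmap = elixhauser_map(),
                           alpha = 0.5, nfolds = 5, seed = 1,
                           keep_fits = FALSE) {
  stopifnot(inherits(split, "cohort_split"))
  if (nrow(split$validation) == 0L)
    stop("validation cohort is empty", call. = FALSE)
  if (nrow(split$derivation) == 0L)
    stop("derivation cohort is empty", call. = FALSE)
  aps <- dplyr::bind_rows(split$derivation, split$validation)
  idx_deriv <- seq_len(nrow(split$derivation))
  idx_valid <- nrow(split$derivation) + seq_len(nrow(split$validation))
  rows <- list()
  fits <- list()
  for (fs in feature_sets) {
    fm <- build_feature_set(fs, aps, counts, bank, tl, demographics,
                            codes = codes, events = events, cmap = cmap,
                            derivation_rows = idx_deriv)
    tr <- fit_transform(fm, idx_deriv)
    for (h in horizons_months) {
      lab_col <- sprintf("label_%gm", h)
      if (!lab_col %in% names(aps))
        stop("missing label column: ", lab_col, call. = FALSE)
      y <- aps[[lab_col]]
      fit <- fit_elastic_net(tr$x[idx_deriv, , drop = FALSE], y[idx_deriv],
                             alpha = alpha, nfolds = nfolds, seed = seed)
      scores <- predict(fit, tr$x[idx_valid, , drop = FALSE])
      rep <- auc_mann_whitney(scores, y[idx_valid])
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(feature_set = fs, horizon_months = h), rep,
        tibble::tibble(n_derivation = length(idx_deriv),
                       n_validation = length(idx_valid)))
      if (keep_fits) fits[[paste(fs, h, sep = "|")]] <- fit
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("readmission_results", class(out))
  if (keep_fits) attr(out, "fits") <- fits
  out
}

#' Plot a readmission results table
#'
#' Validation AUC by prediction horizon, one line per feature set, with
#' Mann-Whitney 95% confidence bars.
#'
#' @param object A `readmission_results` tibble from [run_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.readmission_results <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$horizon_months),
                               y = .data$auc, colour = .data$feature_set,
                               group = .data$feature_set)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_line(position = ggplot2::position_dodge(width = 0.4),
                       alpha = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      width = 0.2, position = ggplot2::position_dodge(width = 0.4)) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "prediction horizon (months)", y = "validation AUC",
                  colour = "feature set") +
    ggplot2::theme_minimal()
}
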