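# fixture builders shared across test files

# an events tibble row-by-row; dates given as "yyyy-mm-dd" strings
make_events <- function(patient_id, code, class, kind, start_date,
                        end_date = NA, emergency = NA_integer_) {
  tibble::tibble(
    patient_id = patient_id, code = code, class = class, kind = kind,
    start_date = as.Date(start_date), end_date = as.Date(end_date),
    emergency = as.integer(emergency)
  )
}

month_tl <- function(n_units = 120, origin = "2003-01-01") {
  timeline(origin, n_units = n_units, unit = "month")
}

# random point-event fixture for one patient on a monthly timeline
random_point_events <- function(n, tl, codes = c("A1", "A2", "B1"),
                                classes = NULL) {
  code <- sample(codes, n, replace = TRUE)
  if (is.null(classes)) classes <- rep("diagnosis", length(codes))
  cls <- classes[match(code, codes)]
  t <- sample.int(tl$n_units, n, replace = TRUE)
  make_events("P1", code, cls, "point",
              format(index_to_date(t, tl)))
}

# independent brute-force evaluation of the one-sided convolution, looping
# over every (offset, kernel value, count) triple
brute_feature <- function(counts, k, t, upm = 1) {
  total <- 0
  sig <- k$sigma_months * upm
  d <- k$delay_months * upm
  for (h in 0:(t - 1)) {
    u <- h - d
    kv <- if (k$family == "uniform") {
      if (u >= 0 && u < sig) 1 / sig else 0
    } else {
      if (u > 0) sqrt(2 / (pi * sig^2)) * exp(-u^2 / (2 * sig^2)) else 0
    }
    total <- total + kv * counts[t - h]
  }
  total
}

# exhaustive pairwise AUC: concordant pairs count 1, ties 0.5
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
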