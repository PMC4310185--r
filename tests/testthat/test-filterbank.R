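test_that("uniform kernel values match the closed form on its support", {
  expect_equal(uniform_kernel_value(1, 3), 1 / 3)
  expect_identical(uniform_kernel_value(-1, 3), 0)
  expect_identical(uniform_kernel_value(3, 3), 0)   # half-open support
  expect_equal(sum(uniform_kernel_value(0:2, 3)), 1)
  expect_error(uniform_kernel_value(1, 0), "positive")
})

test_that("one-sided gaussian matches its closed form and vanishes at t <= 0", {
  expect_identical(gaussian_kernel_value(0, 2), 0)
  expect_identical(gaussian_kernel_value(-4, 2), 0)
  sig <- 5
  expect_equal(gaussian_kernel_value(sig, sig),
               sqrt(2 / (pi * sig^2)) * exp(-1 / 2))
  expect_error(gaussian_kernel_value(1, -1), "positive")
})

test_that("extract_feature follows the delayed one-sided convolution", {
  T_ <- 60
  s <- integer(T_)
  t <- 40
  s[t] <- 1L
  # event in the current unit: h = 0 term contributes
  expect_equal(extract_feature(s, kernel("uniform", 3), t), 1 / 3)
  # the delay blanks out the most recent 12 units
  expect_equal(extract_feature(s, kernel("uniform", 12, 12), t), 0)
  # an all-zero series gives zero for every kernel and t
  z <- integer(T_)
  for (k in default_filter_bank())
    expect_identical(extract_feature(z, k, 25), 0)
})

test_that("extract_feature matches an independent brute-force sum", {
  set.seed(42)
  kernels <- c(default_filter_bank(),
               list(kernel("gaussian", 2), kernel("gaussian", 6, 3)))
  for (rep in 1:40) {
    counts <- rpois(50, 0.7)
    t <- sample(1:50, 1)
    for (k in kernels) {
      expect_equal(extract_feature(counts, k, t),
                   brute_feature(counts, k, t), tolerance = 1e-12)
    }
  }
})

test_that("the convolution is linear, causal and respects the delay", {
  set.seed(1)
  bank <- default_filter_bank()
  a <- rpois(60, 1)
  b <- rpois(60, 1)
  t <- 45
  for (k in bank) {
    expect_equal(extract_feature(a + b, k, t),
                 extract_feature(a, k, t) + extract_feature(b, k, t))
    # causality: the future never changes X(t)
    a2 <- a
    a2[(t + 1):60] <- a2[(t + 1):60] + 5L
    expect_identical(extract_feature(a2, k, t), extract_feature(a, k, t))
  }
  # delay semantics: units (t - d, t] contribute nothing
  k_del <- kernel("uniform", 12, 12)
  a3 <- a
  a3[(t - 11):t] <- a3[(t - 11):t] + 7L
  expect_identical(extract_feature(a3, k_del, t),
                   extract_feature(a, k_del, t))
})

test_that("extract_block yields M x N uniquely named features in order", {
  bank <- default_filter_bank()
  expect_length(bank, 6L)
  T_ <- 50
  s1 <- structure(integer(T_), entity_code = "X")
  expect_length(extract_block(list(X = integer(T_)), bank, 10), 6L)
  expect_length(extract_block(list(), bank, 10), 0L)
  series <- stats::setNames(replicate(7, rpois(T_, 0.5), simplify = FALSE),
                            paste0("C", 1:7))
  blk <- extract_block(series, bank, 30, classes = "diagnosis")
  expect_length(blk, 42L)
  expect_false(anyDuplicated(names(blk)) > 0)
  expect_identical(names(blk)[1:6],
                   paste0("diagnosis:C1|uniform|",
                          c("1|0", "3|0", "6|0", "12|0", "12|12", "12|24")))
})

test_that("the vectorized block extractor agrees with per-series convolution", {
  set.seed(3)
  tl <- month_tl(80)
  ev <- random_point_events(120, tl, codes = c("A1", "A2", "B1"),
                            classes = c("diagnosis", "diagnosis", "medication"))
  counts <- discretize_events(ev, tl)
  bank <- filter_bank(list(kernel("uniform", 3), kernel("uniform", 12, 12),
                           kernel("gaussian", 2)))
  aps <- tibble::tibble(patient_id = "P1", t = c(40L, 60L, 77L))
  codes <- dplyr::distinct(counts, class, code) |> dplyr::arrange(class, code)
  x <- temporal_features(counts, aps, bank, tl, codes = codes,
                         history_months = 36)
  for (i in seq_len(nrow(aps))) {
    for (j in seq_len(nrow(codes))) {
      s <- build_event_series(ev[ev$code == codes$code[j], ],
                              codes$code[j], tl)
      for (b in seq_along(bank)) {
        col <- (j - 1L) * length(bank) + b
        expect_equal(as.numeric(x[i, col]),
                     extract_feature(s, bank[[b]], aps$t[i]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("mixed or duplicate kernels are rejected", {
  expect_error(filter_bank(list(kernel("uniform", 3), kernel("uniform", 3))),
               "duplicate")
  expect_error(filter_bank(list()), "at least one")
})
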