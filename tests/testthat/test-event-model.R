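tl <- month_tl(24)

test_that("build_event_series handles point, continuing and empty inputs", {
  empty <- make_events(character(0), character(0), character(0), character(0),
                       as.Date(character(0)))
  s0 <- build_event_series(empty, "X", tl)
  expect_identical(sum(s0), 0L)
  expect_length(s0, tl$n_units)

  ev <- make_events("P1", "X", "diagnosis", "point",
                    format(index_to_date(5, tl)))
  s1 <- build_event_series(ev, "X", tl)
  expect_identical(unname(s1[5]), 1L)
  expect_identical(sum(s1), 1L)

  stay <- make_events("P1", "ADM", "admission", "continuing",
                      format(index_to_date(3, tl)),
                      format(index_to_date(5, tl)))
  s2 <- build_event_series(stay, "ADM", tl)
  expect_identical(unname(s2[3:5]), c(1L, 1L, 1L))
  expect_identical(sum(s2), 3L)
})

test_that("a continuing entity with no end date occupies a single unit", {
  ev <- make_events("P1", "ADM", "admission", "continuing",
                    format(index_to_date(7, tl)))
  s <- build_event_series(ev, "ADM", tl)
  expect_identical(sum(s), 1L)
  expect_identical(unname(s[7]), 1L)
})

test_that("point-entity mass is conserved on random fixtures", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(1:60, 1)
    ev <- random_point_events(n, tl)
    counts <- discretize_events(ev, tl)
    expect_identical(sum(counts$n), n)
    for (cd in unique(ev$code)) {
      s <- build_event_series(ev, cd, tl)
      expect_identical(sum(s), sum(ev$code == cd))
    }
  }
})

test_that("overlapping stays sum, so counts can exceed one per unit", {
  ev <- dplyr::bind_rows(
    make_events("P1", "ADM", "admission", "continuing",
                format(index_to_date(3, tl)), format(index_to_date(4, tl))),
    make_events("P1", "ADM", "admission", "continuing",
                format(index_to_date(4, tl)), format(index_to_date(6, tl)))
  )
  s <- build_event_series(ev, "ADM", tl)
  expect_identical(unname(s[4]), 2L)
})

test_that("events past the end of the timeline are dropped with a warning", {
  ev <- dplyr::bind_rows(
    make_events("P1", "X", "diagnosis", "point", format(index_to_date(2, tl))),
    make_events("P1", "X", "diagnosis", "point",
                format(index_to_date(tl$n_units, tl) + 40))
  )
  expect_warning(counts <- discretize_events(ev, tl), "dropped")
  expect_identical(sum(counts$n), 1L)
})

test_that("invalid events and unknown schema codes are rejected", {
  bad <- make_events("P1", "X", "diagnosis", "point", "2003-05-01",
                     "2003-04-01")
  expect_error(validate_events(bad), "end_date before start_date")
  schema <- tibble::tibble(code = "Y", class = "diagnosis", kind = "point",
                           parent_code = NA_character_)
  ev <- make_events("P1", "X", "diagnosis", "point", "2003-02-01")
  expect_error(build_event_series(ev, "X", tl, schema = schema),
               "not in schema")
})

test_that("expand_hierarchy duplicates records onto every ancestor", {
  schema <- tibble::tibble(
    code = c("root", "mid", "leafA", "leafB"),
    class = "procedure", kind = "point",
    parent_code = c(NA, "root", "mid", "mid")
  )
  # no parent: identity
  ev_root <- make_events("P1", "root", "procedure", "point", "2003-02-01")
  expect_identical(nrow(expand_hierarchy(ev_root, schema)), 1L)
  # leaf with two ancestors: 3 records out
  ev_leaf <- make_events("P1", "leafA", "procedure", "point", "2003-02-01")
  out <- expand_hierarchy(ev_leaf, schema)
  expect_identical(nrow(out), 3L)
  expect_setequal(out$code, c("leafA", "mid", "root"))
  # sibling leaves aggregate at the parent: parent series sums to 2, and
  # equals the element-wise sum of the child series
  ev_sib <- dplyr::bind_rows(
    make_events("P1", "leafA", "procedure", "point",
                format(index_to_date(2, tl))),
    make_events("P1", "leafB", "procedure", "point",
                format(index_to_date(9, tl)))
  )
  out2 <- expand_hierarchy(ev_sib, schema)
  s_mid <- build_event_series(out2, "mid", tl)
  s_a <- build_event_series(out2, "leafA", tl)
  s_b <- build_event_series(out2, "leafB", tl)
  expect_identical(sum(s_mid), 2L)
  expect_identical(as.integer(s_mid), as.integer(s_a) + as.integer(s_b))
})

test_that("schema cycles are detected", {
  schema <- tibble::tibble(
    code = c("a", "b"), class = "x", kind = "point",
    parent_code = c("b", "a")
  )
  expect_error(validate_schema(schema), "cycle")
})
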