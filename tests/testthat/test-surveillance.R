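mk_events <- function(n, recorded_a, recorded_b, lag_a = 291, lag_b = 73,
                      severity = "mild") {
  t0 <- as.POSIXct("2009-06-01 08:00:00", tz = "UTC")
  tibble::tibble(
    event_id = sprintf("e%03d", seq_len(n)),
    occurrence_time = t0 + 3600 * seq_len(n),
    severity = rep_len(severity, n),
    recorded_incident_report = rep_len(recorded_a, n),
    submitted_incident_report = dplyr::if_else(
      rep_len(recorded_a, n),
      t0 + 3600 * seq_len(n) + 60 * rep_len(lag_a, n), as.POSIXct(NA)),
    recorded_image_order = rep_len(recorded_b, n),
    submitted_image_order = dplyr::if_else(
      rep_len(recorded_b, n),
      t0 + 3600 * seq_len(n) + 60 * rep_len(lag_b, n), as.POSIXct(NA))) |>
    fall_events()
}

test_that("event validation enforces the submission invariants", {
  ev <- mk_events(3, TRUE, FALSE)
  expect_s3_class(ev$severity, "ordered")

  bad <- ev
  bad$submitted_incident_report[1] <- bad$occurrence_time[1] - 60
  expect_error(fall_events(bad), "precedes")

  bad2 <- ev
  bad2$submitted_image_order[1] <- bad2$occurrence_time[1] + 60
  expect_error(fall_events(bad2), "unrecorded")

  bad3 <- ev
  bad3$submitted_incident_report[1] <- NA
  expect_error(fall_events(bad3), "submission time")

  bad4 <- ev
  bad4$severity <- "catastrophic"
  expect_error(fall_events(bad4), "severity")
})

test_that("lags are minutes from occurrence to submission", {
  ev <- mk_events(2, TRUE, TRUE, lag_a = 291, lag_b = 73)
  expect_equal(lag_minutes(ev, "incident_report")$lag_minutes, c(291, 291))
  expect_equal(lag_minutes(ev, "image_order")$lag_minutes, c(73, 73))

  zero <- mk_events(1, TRUE, FALSE, lag_a = 0)
  expect_equal(lag_minutes(zero, "incident_report")$lag_minutes, 0)
  expect_error(lag_minutes(zero, "image_order"), "not recorded")
  expect_error(lag_minutes(zero, "progress_note"), "unknown source")
})

test_that("lag summaries use linear-interpolation percentiles", {
  s <- summarize_lags(c(10, 20, 30))
  expect_equal(s$median, 20)
  expect_equal(s$n, 3L)
  single <- summarize_lags(5)
  expect_equal(c(single$q25, single$median, single$q75), c(5, 5, 5))
  expect_error(summarize_lags(numeric(0)), "non-empty")

  withr::local_seed(808)
  for (rep in 1:20) {
    x <- stats::rlnorm(sample(2:40, 1), log(100), 1.5)
    s <- summarize_lags(x)
    expect_equal(s$q25, brute_quantile(x, 0.25))
    expect_equal(s$median, brute_quantile(x, 0.5))
    expect_equal(s$q75, brute_quantile(x, 0.75))
    expect_lte(s$q25, s$median)
    expect_lte(s$median, s$q75)
  }
})

test_that("rank-sum comparison is exact for small tie-free samples", {
  res <- compare_lags(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1)
  expect_equal(res$method, "exact")

  # identical samples are maximally compatible with the null
  same <- compare_lags(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1.0)

  # symmetry
  withr::local_seed(909)
  for (rep in 1:10) {
    x <- stats::runif(sample(3:8, 1)) * 100
    y <- stats::runif(sample(3:8, 1)) * 100
    expect_equal(compare_lags(x, y)$p_value, compare_lags(y, x)$p_value)
    expect_equal(compare_lags(x, y)$p_value, brute_wilcoxon_p(x, y),
                 tolerance = 1e-12)
  }
  expect_error(compare_lags(numeric(0), 1:3), "non-empty")
})

test_that("large or tied samples take the corrected normal approximation", {
  withr::local_seed(111)
  x <- stats::rlnorm(60, log(291), 1.6)
  y <- stats::rlnorm(40, log(73), 2.8)
  res <- compare_lags(x, y)
  expect_equal(res$method, "normal_approx")
  ref <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                             correct = TRUE))
  expect_equal(res$p_value, ref$p.value)
})

test_that("severity comparison picks the right test and detects the contrast", {
  # strongly different mild vs moderate+severe mixes
  res <- compare_severity(c(mild = 480, moderate = 6, severe = 7),
                          c(mild = 44, moderate = 5, severe = 8),
                          collapse = list(mild = "mild",
                                          worse = c("moderate", "severe")))
  expect_equal(res$method, "fisher_exact")  # min expected cell < 5
  expect_lt(res$p_value, 0.001)

  ident <- compare_severity(c(mild = 50, moderate = 25, severe = 25),
                            c(mild = 50, moderate = 25, severe = 25))
  expect_equal(ident$p_value, 1.0)

  # 2x2 small-count path equals the hypergeometric enumeration oracle
  small <- compare_severity(c(mild = 8, severe = 2), c(mild = 3, severe = 6))
  expect_equal(small$method, "fisher_exact")
  expect_equal(small$p_value, brute_fisher_p(8, 2, 3, 6), tolerance = 1e-12)

  expect_error(compare_severity(c(mild = 3), c(mild = 4)), "at least two")
  expect_error(
    compare_severity(c(mild = 1, severe = 2), c(mild = 3, severe = 4),
                     collapse = list(odd = c("mild", "severe"))),
    "contiguous")
})

test_that("source overlap partitions events and feeds detection gain", {
  ev <- dplyr::bind_rows(
    mk_events(451, TRUE, FALSE),
    dplyr::mutate(mk_events(15, FALSE, TRUE),
                  event_id = sprintf("x%03d", 1:15)),
    dplyr::mutate(mk_events(42, TRUE, TRUE),
                  event_id = sprintf("y%03d", 1:42))) |>
    fall_events()
  ov <- source_overlap(ev, "incident_report", "image_order")
  expect_equal(ov$only_a, 451)
  expect_equal(ov$only_b, 15)
  expect_equal(ov$both, 42)
  expect_equal(ov$total_a, 493)
  expect_equal(ov$total_b, 57)
  expect_equal(ov$only_a + ov$only_b + ov$both,
               sum(ev$recorded_incident_report | ev$recorded_image_order))
  expect_equal(detection_gain(ov), 3.0)
  expect_equal(detection_gain(3, 3, 10), 23.1)
  expect_equal(detection_gain(10, 0, 5), 0.0)
  expect_true(is.na(detection_gain(0, 4, 0)))

  none <- mk_events(3, FALSE, FALSE)
  ov0 <- source_overlap(none, "incident_report", "image_order")
  expect_equal(c(ov0$only_a, ov0$only_b, ov0$both), c(0, 0, 0))
})

test_that("event streams round-trip through the TSV format", {
  ev <- mk_events(10, c(TRUE, FALSE), c(FALSE, TRUE),
                  severity = c("mild", "moderate", "severe", "mild", "none"))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_event_stream(ev, f, header = "# test stream")
  back <- read_event_stream(f)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ev))
  expect_error(read_event_stream(file.path(tempdir(), "nope.tsv")), "nope")
})
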