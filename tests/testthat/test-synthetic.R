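test_that("corpus simulator is deterministic and validates its config", {
  cfg <- corpus_sim_config(n_positive = 15, n_negative = 15, seed = 77)
  a <- generate_labeled_corpus(cfg)
  b <- generate_labeled_corpus(cfg)
  expect_identical(a$positive, b$positive)
  expect_identical(a$negative, b$negative)
  expect_silent(validate_corpus(a$positive))
  expect_silent(validate_corpus(a$negative))
  expect_equal(nrow(corpus_docs(a$positive)), 15)
  expect_equal(unique(corpus_docs(a$positive)$label), "positive")

  expect_error(corpus_sim_config(planted_patterns = tibble::tibble(
    rule = "a+b -> c", prevalence_positive = 1.2,
    prevalence_negative = 0)), "prevalences")
  expect_error(corpus_sim_config(vocab_size = 2), "vocab_size")
  expect_error(corpus_sim_config(
    sentence_length_range = c(2, 2),
    planted_patterns = tibble::tibble(rule = "a+b -> c",
                                      prevalence_positive = 0.5,
                                      prevalence_negative = 0)),
    "sentence capacity")
})

test_that("extreme prevalences plant the pattern everywhere or nowhere", {
  cfg <- corpus_sim_config(
    n_positive = 12, n_negative = 12, vocab_size = 30,
    planted_patterns = tibble::tibble(rule = "sasaeru+nai -> tentoh",
                                      prevalence_positive = 1.0,
                                      prevalence_negative = 0.0),
    seed = 31)
  corpora <- generate_labeled_corpus(cfg)
  pos_hits <- classify(corpora$positive, "sasaeru+nai -> tentoh")
  neg_hits <- classify(corpora$negative, "sasaeru+nai -> tentoh")
  expect_true(all(pos_hits$flag))
  expect_false(any(neg_hits$flag))
})

test_that("planted prevalences are recovered within binomial bounds", {
  cfg <- corpus_sim_config(
    n_positive = 200, n_negative = 200, vocab_size = 60,
    planted_patterns = tibble::tibble(rule = "sasaeru+nai -> tentoh",
                                      prevalence_positive = 0.3,
                                      prevalence_negative = 0.01),
    seed = 99)
  corpora <- generate_labeled_corpus(cfg)
  pos_rate <- mean(classify(corpora$positive, "sasaeru+nai -> tentoh")$flag)
  neg_rate <- mean(classify(corpora$negative, "sasaeru+nai -> tentoh")$flag)
  # 99% binomial bounds at n = 200
  expect_gte(pos_rate, stats::qbinom(0.005, 200, 0.3) / 200)
  expect_lte(pos_rate, stats::qbinom(0.995, 200, 0.3) / 200)
  expect_lte(neg_rate, stats::qbinom(0.995, 200, 0.01) / 200)
})

test_that("event simulator is deterministic and obeys its invariants", {
  cfg <- event_sim_config(n_events = 50, seed = 5)
  a <- generate_event_stream(cfg)
  b <- generate_event_stream(cfg)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_true(all(a$recorded_progress_note))  # recording probability 1.0
  expect_equal(attr(a, "patient_days"), 267301)

  empty <- generate_event_stream(event_sim_config(n_events = 0, seed = 5))
  expect_equal(nrow(empty), 0)

  expect_error(event_sim_config(recording_probabilities = c(x = 1.5)),
               "lag median|probabilities")
  expect_error(event_sim_config(
    severity_distribution = c(mild = 0.5, severe = 0.4)), "sum to 1")
})

test_that("moderate and severe events are imaged more often", {
  ev <- generate_event_stream(event_sim_config(n_events = 4000, seed = 17))
  worse <- ev$severity >= "moderate"
  expect_gt(mean(ev$recorded_image_order[worse]),
            mean(ev$recorded_image_order[!worse]))
  # boost of 6 on 0.125 = 0.75 for injurious falls
  expect_gt(mean(ev$recorded_image_order[worse]), 0.5)
})

test_that("event-stream rates and lag medians match the configuration", {
  ev <- generate_event_stream(event_sim_config(n_events = 10000, seed = 23))
  n <- nrow(ev)
  # recording rates within 99% binomial bounds
  expect_gte(sum(ev$recorded_incident_report), stats::qbinom(0.005, n, 0.65))
  expect_lte(sum(ev$recorded_incident_report), stats::qbinom(0.995, n, 0.65))
  # severity proportions around 96.9 / 1.4 / 1.8 percent
  sev <- table(ev$severity) / n
  expect_equal(unname(sev[["mild"]]), 492 / 508, tolerance = 0.02)
  expect_equal(unname(sev[["severe"]]), 9 / 508, tolerance = 0.3)
  # lag medians within 10% of the configured per-source medians
  ir <- lag_minutes(ev[ev$recorded_incident_report, ], "incident_report")
  expect_equal(stats::median(ir$lag_minutes), 291, tolerance = 0.1)
  io <- lag_minutes(ev[ev$recorded_image_order, ], "image_order")
  expect_equal(stats::median(io$lag_minutes), 73, tolerance = 0.1)
})
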