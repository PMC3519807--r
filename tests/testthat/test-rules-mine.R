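test_that("candidate enumeration equals brute-force search on small corpora", {
  withr::local_seed(515)
  vocab <- letters[1:5]
  for (rep in 1:6) {
    corp <- random_corpus(8, vocab = vocab, max_sent = 2, max_len = 5)
    min_support <- sample(1:3, 1)
    cand <- enumerate_candidates(corp, max_terms = 3,
                                 min_support = min_support)
    # brute force: all template instances over the vocabulary
    all_rules <- c()
    for (x in vocab) for (y in vocab) {
      if (x <= y) all_rules <- c(all_rules, paste0(x, "+", y))
      all_rules <- c(all_rules, paste(x, "->", y))
      for (z in vocab) {
        if (x <= y) all_rules <- c(all_rules,
                                   paste(paste0(x, "+", y), "->", z),
                                   paste(z, "->", paste0(x, "+", y)))
      }
    }
    tok <- tibble::as_tibble(corp)
    docs <- split(tok, tok$doc_id)
    support <- vapply(all_rules, function(r) {
      sum(vapply(docs, brute_match_rule, TRUE, rule = r))
    }, 0)
    expected <- sort(all_rules[support >= min_support])
    expect_setequal(cand$rule, expected)
    expect_equal(cand$support[order(cand$rule)],
                 unname(support[expected]))
  }
})

test_that("enumeration respects the support floor and term cap", {
  d <- naive_parse("a b.", doc_id = "one")  # a's head is b: linked pair
  cand1 <- enumerate_candidates(d, min_support = 1)
  expect_true("a+b" %in% cand1$rule)
  expect_equal(nrow(enumerate_candidates(d, min_support = 2)), 0)
  two <- enumerate_candidates(d, max_terms = 2, min_support = 1)
  expect_true(all(rule_terms(two$rule) == 2))
  expect_error(enumerate_candidates(d, max_terms = 1), "max_terms")
})

test_that("selection-table scoring matches stats:: and the enumeration oracle", {
  # perfectly balanced table carries no signal
  expect_equal(score_candidate(1, 1, 1, 1)$fisher_p, 1.0)
  # complete separation of 5 vs 5: 2/choose(10,5)
  expect_equal(score_candidate(5, 0, 0, 5)$fisher_p, 2 / 252,
               tolerance = 1e-12)
  sc <- score_candidate(30, 70, 2, 198)
  expect_lt(sc$chi2_p, 0.05)
  expect_lt(sc$fisher_p, 0.05)

  withr::local_seed(77)
  for (rep in 1:60) {
    a <- sample(0:15, 1); b <- sample(0:15, 1)
    c <- sample(0:15, 1); d <- sample(0:15, 1)
    if (a + b == 0 || c + d == 0) next
    got <- score_candidate(a, b, c, d)
    expect_equal(got$fisher_p, brute_fisher_p(a, b, c, d), tolerance = 1e-12)
    if (a + c > 0 && b + d > 0) {
      ft <- stats::fisher.test(matrix(c(a, c, b, d), 2))
      expect_equal(got$fisher_p, ft$p.value, tolerance = 1e-9)
      ct <- suppressWarnings(
        stats::chisq.test(matrix(c(a, c, b, d), 2), correct = FALSE))
      expect_equal(got$chi2_p, ct$p.value, tolerance = 1e-12)
    } else {
      expect_equal(got$chi2_p, 1.0)
      expect_equal(got$fisher_p, 1.0)
    }
  }
})

test_that("chi-square p is invariant under simultaneous row+column swap", {
  withr::local_seed(31)
  for (rep in 1:20) {
    t <- sample(1:30, 4, replace = TRUE)
    expect_equal(score_candidate(t[1], t[2], t[3], t[4])$chi2_p,
                 score_candidate(t[4], t[3], t[2], t[1])$chi2_p,
                 tolerance = 1e-12)
  }
})

test_that("scoring rejects invalid tables", {
  expect_error(score_candidate(-1, 1, 1, 1), "non-negative")
  expect_error(score_candidate(0, 0, 1, 1), "row sums")
})

test_that("identical corpora yield no rules; planted signal is found", {
  withr::local_seed(4242)
  corp <- random_corpus(30, vocab = letters[1:6])
  same <- select_rules(corp, corp, min_support = 2)
  expect_equal(nrow(same), 0)

  cfg <- corpus_sim_config(
    n_positive = 60, n_negative = 60, vocab_size = 40,
    planted_patterns = tibble::tibble(
      rule = c("sasaeru+nai -> tentoh", "decoy1 -> decoy2+decoy3"),
      prevalence_positive = c(0.5, 0.15),
      prevalence_negative = c(0.01, 0.15)),
    seed = 11)
  corpora <- generate_labeled_corpus(cfg)
  rs <- select_rules(corpora$positive, corpora$negative, min_support = 5)
  expect_true(rule_in_set(rs, "sasaeru+nai -> tentoh"))
  expect_false(rule_in_set(rs, "decoy1 -> decoy2+decoy3"))
  # every selected rule is significant and positively enriched
  expect_true(all(rs$selected_p < attr(rs, "alpha")))
  expect_true(all(rs$a / (rs$a + rs$b) > rs$c / (rs$c + rs$d)))
  expect_true(all(rs$a + rs$b == nrow(corpus_docs(corpora$positive))))
  expect_true(all(rs$c + rs$d == nrow(corpus_docs(corpora$negative))))
})

test_that("pre-pruning selection is monotone in alpha", {
  withr::local_seed(88)
  cfg <- corpus_sim_config(n_positive = 50, n_negative = 50, vocab_size = 30,
                           seed = 5)
  corpora <- generate_labeled_corpus(cfg)
  pre_prune <- function(rs) union(rs$rule, attr(rs, "pruned")$rule)
  alphas <- c(0.001, 0.01, 0.05, 0.2)
  sets <- lapply(alphas, function(al) {
    pre_prune(select_rules(corpora$positive, corpora$negative, alpha = al,
                           min_support = 4))
  })
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
})

test_that("redundancy pruning keeps the smaller of two equivalent rules", {
  cfg <- corpus_sim_config(
    n_positive = 40, n_negative = 40, vocab_size = 30,
    planted_patterns = tibble::tibble(rule = "sasaeru+nai -> tentoh",
                                      prevalence_positive = 0.5,
                                      prevalence_negative = 0),
    seed = 21)
  corpora <- generate_labeled_corpus(cfg)
  rs <- select_rules(corpora$positive, corpora$negative, min_support = 5)
  pruned <- attr(rs, "pruned")
  # the full 3-term pattern matches exactly the planted documents, as does
  # its dependency pair: the pair is kept, the 3-term rule pruned
  expect_true("nai+sasaeru" %in% rs$rule)
  expect_false("nai+sasaeru -> tentoh" %in% rs$rule)
  expect_true("nai+sasaeru -> tentoh" %in% pruned$rule)
  kept <- pruned$kept_rule[pruned$rule == "nai+sasaeru -> tentoh"]
  expect_true(all(kept %in% rs$rule))
  expect_true(rule_in_set(rs, "sasaeru+nai -> tentoh"))
})

test_that("classification flags exactly the documents a rule matches", {
  d1 <- naive_parse("the patient fell from bed.", doc_id = "p1")
  d2 <- naive_parse("routine medication round.", doc_id = "p2")
  corp <- fall_corpus(dplyr::bind_rows(tibble::as_tibble(d1),
                                       tibble::as_tibble(d2)))
  res <- classify(corp, "fell -> bed")
  expect_equal(res$doc_id, c("p1", "p2"))
  expect_equal(res$flag, c(TRUE, FALSE))
  expect_equal(res$matched_rules[[1]], "fell -> bed")
  expect_equal(res$n_rules_matched, c(1L, 0L))

  expect_warning(res0 <- classify(corp, character(0)), "empty rule set")
  expect_false(any(res0$flag))
})

test_that("rule category tagging applies lexicons in declared order", {
  lex <- list(fall_motion = c("tentoh", "ochiru"),
              injury = c("kossetsu"))
  expect_equal(tag_rule_category("sasaeru+nai -> tentoh", lex), "fall_motion")
  expect_equal(tag_rule_category("kossetsu -> itami", lex), "injury")
  expect_equal(tag_rule_category("w1 -> w2", lex), "uncategorized")
  expect_equal(tag_rule_category(c("tentoh -> a", "b+c"), lex),
               c("fall_motion", "uncategorized"))
  expect_error(
    tag_rule_category("a+b", list(x = "tentoh", y = c("tentoh", "q"))),
    "overlap")
})

test_that("rule sets round-trip bit-exactly through the text format", {
  cfg <- corpus_sim_config(n_positive = 40, n_negative = 40, vocab_size = 30,
                           seed = 3)
  corpora <- generate_labeled_corpus(cfg)
  rs <- select_rules(corpora$positive, corpora$negative, min_support = 4)
  expect_gt(nrow(rs), 0)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_ruleset(rs, f)
  back <- read_ruleset(f)
  expect_identical(tidy(back), tidy(rs))
  expect_identical(attr(back, "alpha"), attr(rs, "alpha"))
  expect_identical(attr(back, "min_support"),
                   as.integer(attr(rs, "min_support")))
  expect_identical(attr(back, "max_terms"), as.integer(attr(rs, "max_terms")))
  expect_equal(as.integer(attr(back, "provenance")$n_positive), 40L)
  # second write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_ruleset(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("tidy and glance summarise a rule set", {
  cfg <- corpus_sim_config(n_positive = 30, n_negative = 30, vocab_size = 30,
                           seed = 13)
  corpora <- generate_labeled_corpus(cfg)
  rs <- select_rules(corpora$positive, corpora$negative, min_support = 4)
  td <- tidy(rs)
  expect_s3_class(td, "tbl_df")
  expect_false(inherits(td, "fall_ruleset"))
  gl <- glance(rs)
  expect_equal(gl$n_rules, nrow(rs))
  expect_equal(gl$n_positive, 30L)
  expect_equal(gl$alpha, 0.05)
})
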