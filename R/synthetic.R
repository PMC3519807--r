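#' Configuration for the labeled-corpus simulator
#'
#' The simulator emulates the structure of a six-month incident-report
#' training collection: a fall-related (positive) and a fall-unrelated
#' (negative) class, short multi-sentence narratives, and a handful of
#' discriminative syntactic patterns that occur far more often in the
#' positive class. Defaults mirror the modeled study: 277 positive and
#' 2,313 negative documents, and the two worked example rules
#' `"sasaeru+nai -> tentoh"` and `"bed -> zuri+ochiru"` planted at 30%
#' prevalence in positives and 1% in negatives.
#'
#' Background lemmas are drawn from a Zipf distribution over `vocab_size`
#' reserved words (`w001`, `w002`, ...); planted-pattern lemmas never occur
#' as background, so the empirical match rate of a planted rule equals its
#' configured prevalence in expectation.
#'
#' @param n_positive,n_negative Documents per class.
#' @param vocab_size Background vocabulary size.
#' @param sentence_length_range Integer `(min, max)` tokens per sentence.
#' @param sentences_per_doc_range Integer `(min, max)` sentences per
#'   document.
#' @param planted_patterns A data frame with columns `rule`,
#'   `prevalence_positive`, `prevalence_negative`.
#' @param seed Integer seed; generation is byte-identical given the seed.
#' @return A `corpus_sim_config` list.
#' @export
corpus_sim_config <- function(n_positive = 277, n_negative = 2313,
                              vocab_size = 100,
                              sentence_length_range = c(4, 12),
                              sentences_per_doc_range = c(1, 5),
                              planted_patterns = default_planted_patterns(),
                              seed = 1) {
  planted_patterns <- tibble::as_tibble(planted_patterns)
  cfg <- list(n_positive = as.integer(n_positive),
              n_negative = as.integer(n_negative),
              vocab_size = as.integer(vocab_size),
              sentence_length_range = as.integer(sentence_length_range),
              sentences_per_doc_range = as.integer(sentences_per_doc_range),
              planted_patterns = planted_patterns,
              seed = as.integer(seed))
  stopifnot(cfg$n_positive >= 0, cfg$n_negative >= 0,
            length(cfg$sentence_length_range) == 2,
            cfg$sentence_length_range[1] >= 2,
            diff(cfg$sentence_length_range) >= 0,
            length(cfg$sentences_per_doc_range) == 2,
            cfg$sentences_per_doc_range[1] >= 1,
            diff(cfg$sentences_per_doc_range) >= 0)
  if (nrow(planted_patterns) > 0) {
    needed <- c("rule", "prevalence_positive", "prevalence_negative")
    if (!all(needed %in% names(planted_patterns))) {
      stop("planted_patterns needs columns: ", paste(needed, collapse = ", "),
           call. = FALSE)
    }
    prev <- c(planted_patterns$prevalence_positive,
              planted_patterns$prevalence_negative)
    if (any(prev < 0 | prev > 1)) {
      stop("planted prevalences must lie in [0, 1]", call. = FALSE)
    }
    sizes <- rule_terms(planted_patterns$rule)
    if (any(sizes > cfg$sentence_length_range[2])) {
      stop("planted pattern longer than the maximum sentence capacity",
           call. = FALSE)
    }
    n_planted <- length(unique(unlist(lapply(planted_patterns$rule,
                                             rule_lemmas))))
    if (cfg$vocab_size < n_planted) {
      stop("vocab_size must be at least the number of planted lemmas",
           call. = FALSE)
    }
  }
  structure(cfg, class = "corpus_sim_config")
}

# sample one element of x (safe for length-1 vectors, unlike sample())
sample1 <- function(x) x[sample.int(length(x), 1L)]

default_planted_patterns <- function() {
  tibble::tibble(
    rule = c("sasaeru+nai -> tentoh", "bed -> zuri+ochiru"),
    prevalence_positive = 0.30,
    prevalence_negative = 0.01)
}

#' Generate a labeled parsed corpus with planted rule patterns
#'
#' Background tokens are Zipf-distributed reserved lemmas; each non-root
#' token receives a uniformly random head among the other tokens of its
#' sentence, after which cycles are broken into a dependency forest. Each
#' planted pattern is inserted into each document independently with its
#' class-specific prevalence: its `"+"` group is realized as a direct
#' dependency edge and its `"->"` relation as strict document-order
#' precedence. Deterministic given `config$seed`.
#'
#' @param config A [corpus_sim_config()].
#' @return A list with elements `positive` and `negative`, each a
#'   `fall_corpus`.
#' @export
generate_labeled_corpus <- function(config) {
  stopifnot(inherits(config, "corpus_sim_config"))
  withr::with_seed(config$seed, {
    vocab <- sprintf("w%03d", seq_len(config$vocab_size))
    zipf <- (1 / seq_len(config$vocab_size))
    zipf <- zipf / sum(zipf)
    pos <- generate_class(config, "positive", config$n_positive, vocab, zipf,
                          config$planted_patterns$prevalence_positive)
    neg <- generate_class(config, "negative", config$n_negative, vocab, zipf,
                          config$planted_patterns$prevalence_negative)
  })
  list(positive = pos, negative = neg)
}

generate_class <- function(config, label, n_docs, vocab, zipf, prevalences) {
  docs <- tibble::tibble(
    doc_id = sprintf("%s_%04d", substr(label, 1, 3), seq_len(n_docs)),
    label = rep(label, n_docs), source = rep(NA_character_, n_docs))
  rows <- vector("list", n_docs)
  patterns <- config$planted_patterns
  for (k in seq_len(n_docs)) {
    m <- sample1(config$sentences_per_doc_range[1]:
                   config$sentences_per_doc_range[2])
    sent_rows <- lapply(seq_len(m), function(s) {
      n <- sample1(config$sentence_length_range[1]:
                     config$sentence_length_range[2])
      lemma <- sample(vocab, n, replace = TRUE, prob = zipf)
      heads <- random_forest_heads(n)
      tibble::tibble(sentence_index = as.integer(s),
                     token_index = seq_len(n), surface = lemma,
                     lemma = lemma,
                     pos = sample(c("NOUN", "VERB", "PART", "ADJ"), n,
                                  replace = TRUE),
                     head_index = heads)
    })
    doc <- dplyr::bind_rows(sent_rows)
    if (nrow(patterns) > 0) {
      plant <- stats::runif(nrow(patterns)) < prevalences
      used <- integer(0)  # row numbers already claimed by a planted pattern
      deps <- integer(0)  # rows whose head edge realizes a planted "+" link
      for (p in which(plant)) {
        res <- plant_pattern(doc, patterns$rule[p], used, deps)
        doc <- res$doc
        used <- res$used
        deps <- res$deps
      }
    }
    doc$doc_id <- docs$doc_id[k]
    doc$label <- label
    doc$source <- NA_character_
    rows[[k]] <- doc
  }
  tokens <- dplyr::bind_rows(rows)
  if (n_docs == 0) {
    tokens <- tibble::tibble(doc_id = character(), label = character(),
                             source = character(), sentence_index = integer(),
                             token_index = integer(), surface = character(),
                             lemma = character(), pos = character(),
                             head_index = integer())
  }
  fall_corpus(tokens, docs = docs,
              metadata = list(simulated = "true", class = label))
}

# uniformly random head for every token, then break cycles: every cycle in
# the functional head graph gets its smallest member re-rooted
random_forest_heads <- function(n, heads = NULL, protect = integer(0)) {
  if (is.null(heads)) {
    if (n == 1) return(0L)
    heads <- vapply(seq_len(n), function(i) {
      sample1(setdiff(seq_len(n), i))
    }, 0L)
  }
  repeat {
    cyc <- find_head_cycle(heads)
    if (is.null(cyc)) break
    cut <- setdiff(cyc, protect)
    if (length(cut) == 0) cut <- cyc  # degenerate; should not happen
    heads[min(cut)] <- 0L
  }
  heads
}

# returns the members of one cycle, or NULL if the head graph is a forest
find_head_cycle <- function(heads) {
  n <- length(heads)
  state <- integer(n)
  for (start in seq_len(n)) {
    v <- start
    path <- integer(0)
    while (v != 0L && state[v] == 0L) {
      state[v] <- 1L
      path <- c(path, v)
      v <- heads[v]
    }
    if (v != 0L && state[v] == 1L) {
      return(path[seq(which(path == v), length(path))])
    }
    state[path] <- 2L
  }
  NULL
}

# overwrite background tokens with the lemmas of `rule`, realizing "+" as a
# dependency edge and "->" as document-order precedence. `used` tracks row
# numbers claimed by earlier patterns so patterns never collide; `deps`
# tracks rows whose head edge realizes a planted "+" link, which
# cycle-breaking must never cut. A planted dependent's head is always its
# (non-dependent) pair partner, so every head cycle retains an unprotected
# member and cycle-breaking always terminates without touching planted
# edges.
plant_pattern <- function(doc, rule, used, deps = integer(0)) {
  groups <- parse_rule(rule)
  sizes <- vapply(groups, nrow, 0L)
  m <- max(doc$sentence_index)
  placements <- NULL
  if (length(groups) == 2 && m >= 2) {
    # prefer cross-sentence placement: group 1 in an earlier sentence
    s2 <- sample1(2:m)
    s1 <- sample1(seq_len(s2 - 1))
    p1 <- pick_slots(doc, s1, sizes[1], used)
    p2 <- pick_slots(doc, s2, sizes[2], c(used, p1))
    if (!is.null(p1) && !is.null(p2)) placements <- list(p1, p2)
  }
  if (is.null(placements)) {
    # same-sentence placement: all terms in one sentence, in group order
    total <- sum(sizes)
    cand <- sample(seq_len(m))
    for (s in cand) {
      slots <- pick_slots(doc, s, total, used)
      if (!is.null(slots)) {
        slots <- sort(slots)
        placements <- if (length(groups) == 2) {
          list(slots[seq_len(sizes[1])], slots[-seq_len(sizes[1])])
        } else list(slots)
        break
      }
    }
  }
  if (is.null(placements)) {
    # document too crowded by earlier patterns: append a minimal overflow
    # sentence and plant there (keeps planting prevalences exact)
    total <- sum(sizes)
    extra <- tibble::tibble(sentence_index = m + 1L,
                            token_index = seq_len(total),
                            surface = rep("w000", total),
                            lemma = rep("w000", total),
                            pos = rep("NOUN", total),
                            head_index = c(seq_len(total)[-1], 0L))
    new_rows <- nrow(doc) + seq_len(total)
    doc <- dplyr::bind_rows(doc, extra)
    placements <- if (length(groups) == 2) {
      list(new_rows[seq_len(sizes[1])], new_rows[-seq_len(sizes[1])])
    } else list(new_rows)
  }
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    rows <- sort(placements[[gi]])
    doc$lemma[rows] <- g$lemma
    doc$surface[rows] <- g$lemma
    if (nrow(g) == 2) {
      # dependency edge between the pair, then restore forest shape
      i <- rows[1]; j <- rows[2]
      doc$head_index[i] <- doc$token_index[j]
      deps <- c(deps, i)
      s <- doc$sentence_index[i]
      in_s <- which(doc$sentence_index == s)
      doc$head_index[in_s] <- random_forest_heads(
        length(in_s), heads = doc$head_index[in_s],
        protect = match(intersect(deps, in_s), in_s))
    }
  }
  list(doc = doc, used = c(used, unlist(placements)), deps = deps)
}

# k free token slots (row numbers) within sentence s, or NULL
pick_slots <- function(doc, s, k, used) {
  free <- setdiff(which(doc$sentence_index == s), used)
  if (length(free) < k) return(NULL)
  sort(free[sample.int(length(free), k)])
}

#' Configuration for the fall-event-stream simulator
#'
#' Defaults reproduce the statistical structure of a year of hospital fall
#' surveillance: 508 events over 267,301 patient-days; per-source
#' documentation probabilities of 1.00 (progress notes), 0.65 (incident
#' reports), 0.125 (image orders) and 0.025 (discharge summaries);
#' severity split 492:7:9 (mild:moderate:severe); and log-normal
#' submission lags with medians 291 min (incident reports) and 73 min
#' (image orders). Moderate and severe events multiply the image-order
#' recording probability by `severity_imaging_boost` (capped at 1),
#' emulating the clinical reality that injurious falls trigger imaging.
#'
#' Log-normal dispersions are not printed quantities; the defaults are
#' loose fits to the reported quartiles and are fully configurable. Lag
#' medians for progress notes (120 min) and discharge summaries (7 days)
#' are likewise package choices of clinically plausible values.
#'
#' @param n_events Number of fall events.
#' @param patient_days Patient-days over the simulated period (used for
#'   rate calculations downstream).
#' @param start Period start (ISO date); occurrences are uniform over
#'   `period_days` days from `start`.
#' @param period_days Length of the simulated period in days.
#' @param recording_probabilities Named per-source documentation
#'   probabilities.
#' @param lag_median_minutes Named per-source median submission lags.
#' @param lag_log_sd Named per-source log-scale standard deviations.
#' @param severity_distribution Probabilities over
#'   `mild`/`moderate`/`severe` (and optionally `none`); must sum to 1.
#' @param severity_imaging_boost Multiplier on the image-order recording
#'   probability for moderate/severe events.
#' @param seed Integer seed.
#' @return An `event_sim_config` list.
#' @export
event_sim_config <- function(
    n_events = 508, patient_days = 267301, start = "2009-04-01",
    period_days = 365,
    recording_probabilities = c(progress_note = 1.0, incident_report = 0.65,
                                image_order = 0.125,
                                discharge_summary = 0.025),
    lag_median_minutes = c(progress_note = 120, incident_report = 291,
                           image_order = 73, discharge_summary = 10080),
    lag_log_sd = c(progress_note = 1.0, incident_report = 1.6,
                   image_order = 2.8, discharge_summary = 0.5),
    severity_distribution = c(mild = 492, moderate = 7, severe = 9) / 508,
    severity_imaging_boost = 6, seed = 1) {
  cfg <- list(n_events = as.integer(n_events),
              patient_days = as.numeric(patient_days), start = start,
              period_days = as.numeric(period_days),
              recording_probabilities = recording_probabilities,
              lag_median_minutes = lag_median_minutes,
              lag_log_sd = lag_log_sd,
              severity_distribution = severity_distribution,
              severity_imaging_boost = as.numeric(severity_imaging_boost),
              seed = as.integer(seed))
  stopifnot(cfg$n_events >= 0, cfg$patient_days > 0, cfg$period_days > 0,
            cfg$severity_imaging_boost >= 0)
  srcs <- names(recording_probabilities)
  if (is.null(srcs) || any(!nzchar(srcs))) {
    stop("recording_probabilities must be a named vector", call. = FALSE)
  }
  if (any(recording_probabilities < 0 | recording_probabilities > 1)) {
    stop("recording probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!all(srcs %in% names(lag_median_minutes)) ||
      !all(srcs %in% names(lag_log_sd))) {
    stop("every source needs a lag median and a lag log-sd", call. = FALSE)
  }
  if (is.null(names(severity_distribution)) ||
      any(!names(severity_distribution) %in% severity_levels())) {
    stop("severity_distribution must be named with severity levels",
         call. = FALSE)
  }
  if (abs(sum(severity_distribution) - 1) > 1e-8) {
    stop("severity_distribution must sum to 1", call. = FALSE)
  }
  structure(cfg, class = "event_sim_config")
}

#' Generate a synthetic fall-event stream
#'
#' Each event receives a severity from the configured distribution and an
#' occurrence time uniform over the period. Each source documents the
#' event independently with its recording probability (the image-order
#' probability multiplied by `severity_imaging_boost` for moderate and
#' severe events, capped at 1); where recorded, the submission lag is
#' log-normal with the configured per-source median and log-sd.
#' Deterministic given `config$seed`.
#'
#' @param config An [event_sim_config()].
#' @return A validated event tibble (see [fall_events()]), with the
#'   configured `patient_days` attached as attribute `"patient_days"`.
#' @export
generate_event_stream <- function(config) {
  stopifnot(inherits(config, "event_sim_config"))
  srcs <- names(config$recording_probabilities)
  n <- config$n_events
  out <- withr::with_seed(config$seed, {
    start <- as.POSIXct(paste0(config$start, " 00:00:00"), tz = "UTC")
    occurrence <- start + round(stats::runif(n) * config$period_days * 86400)
    severity <- if (n > 0) {
      sample(names(config$severity_distribution), n, replace = TRUE,
             prob = config$severity_distribution)
    } else character(0)
    ev <- tibble::tibble(event_id = sprintf("ev_%05d", seq_len(n)),
                         occurrence_time = occurrence, severity = severity)
    for (src in srcs) {
      p <- rep(config$recording_probabilities[[src]], n)
      if (src == "image_order") {
        boost <- severity %in% c("moderate", "severe")
        p[boost] <- pmin(1, p[boost] * config$severity_imaging_boost)
      }
      rec <- stats::runif(n) < p
      lag_min <- stats::rlnorm(n, meanlog = log(config$lag_median_minutes[[src]]),
                               sdlog = config$lag_log_sd[[src]])
      sub <- occurrence + round(lag_min * 60)
      sub[!rec] <- NA
      ev[[paste0("recorded_", src)]] <- rec
      ev[[paste0("submitted_", src)]] <- sub
    }
    ev
  })
  out <- fall_events(out)
  attr(out, "patient_days") <- config$patient_days
  out
}
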