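#' Enumerate candidate decision rules from a positive corpus
#'
#' Instantiates every rule of the four templates `T1+T2`, `T1 -> T2`,
#' `T1+T2 -> T3` and `T1 -> T2+T3` (the last two only when `max_terms >= 3`)
#' whose lemmas co-occur with the required dependency and precedence
#' relations in at least `min_support` documents of the positive corpus.
#' Pair groups are stored with lemmas sorted, so each dependency pair
#' appears once.
#'
#' @param positive A labeled `fall_corpus` of positive (fall-related)
#'   documents.
#' @param max_terms Maximum number of terms in a rule (2 or 3; larger
#'   values enumerate the same templates).
#' @param min_support Minimum number of positive documents a candidate must
#'   match.
#' @return A tibble with columns `rule` and `support` (positive-document
#'   count), one row per distinct candidate.
#' @export
enumerate_candidates <- function(positive, max_terms = 3, min_support = 5) {
  if (max_terms < 2) stop("max_terms must be at least 2", call. = FALSE)
  if (nrow(corpus_docs(positive)) == 0) {
    stop("positive corpus is empty", call. = FALSE)
  }
  index <- corpus_index(positive)
  L <- index$L
  P <- index$P
  parts <- list()

  # T1+T2: dependency-linked lemma pairs
  parts$pair <- P |>
    dplyr::distinct(.data$doc_id, .data$u, .data$v) |>
    dplyr::count(.data$u, .data$v, name = "support") |>
    dplyr::mutate(rule = paste0(.data$u, "+", .data$v)) |>
    dplyr::select("rule", "support")

  # T1 -> T2: some occurrence of T1 strictly before some occurrence of T2
  parts$prec <- dplyr::inner_join(L, L, by = "doc_id", suffix = c("_l", "_r"),
                                  relationship = "many-to-many") |>
    dplyr::filter(.data$first_pos_l < .data$last_pos_r) |>
    dplyr::count(.data$lemma_l, .data$lemma_r, name = "support") |>
    dplyr::mutate(rule = paste(.data$lemma_l, "->", .data$lemma_r)) |>
    dplyr::select("rule", "support")

  if (max_terms >= 3) {
    # T1+T2 -> T3
    parts$pair_prec <- dplyr::inner_join(P, L, by = "doc_id",
                                         suffix = c("_l", "_r"),
                                         relationship = "many-to-many") |>
      dplyr::filter(.data$first_pos_l < .data$last_pos_r) |>
      dplyr::count(.data$u, .data$v, .data$lemma, name = "support") |>
      dplyr::mutate(rule = paste(paste0(.data$u, "+", .data$v), "->",
                                 .data$lemma)) |>
      dplyr::select("rule", "support")
    # T1 -> T2+T3
    parts$prec_pair <- dplyr::inner_join(L, P, by = "doc_id",
                                         suffix = c("_l", "_r"),
                                         relationship = "many-to-many") |>
      dplyr::filter(.data$first_pos_l < .data$last_pos_r) |>
      dplyr::count(.data$lemma, .data$u, .data$v, name = "support") |>
      dplyr::mutate(rule = paste(.data$lemma, "->",
                                 paste0(.data$u, "+", .data$v))) |>
      dplyr::select("rule", "support")
  }
  dplyr::bind_rows(parts) |>
    dplyr::filter(.data$support >= min_support) |>
    dplyr::arrange(.data$rule)
}

#' Score a 2x2 selection table
#'
#' Given the document counts of a candidate rule --- `a` positive documents
#' matching, `b` positive not matching, `c` negative matching, `d` negative
#' not matching --- returns the p-value of the 1-df chi-square test without
#' continuity correction and the two-sided Fisher exact p (the sum of
#' hypergeometric probabilities of tables no more likely than the observed
#' one, at the conventional `1 + 1e-7` relative tolerance). A table with a
#' zero column margin carries no information about association; both
#' p-values are then reported as 1.
#'
#' All four arguments are recycled to a common length, so thousands of
#' candidate tables are scored in one call.
#'
#' @param a,b,c,d Non-negative integer counts; both row sums (`a+b`, `c+d`)
#'   must be positive.
#' @return A tibble with columns `chi2_p` and `fisher_p`.
#' @examples
#' score_candidate(30, 70, 2, 198)
#' @export
score_candidate <- function(a, b, c, d) {
  n <- max(length(a), length(b), length(c), length(d))
  a <- rep_len(as.numeric(a), n); b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n); d <- rep_len(as.numeric(d), n)
  if (any(a < 0 | b < 0 | c < 0 | d < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (any(a + b == 0 | c + d == 0)) {
    stop("both row sums must be positive", call. = FALSE)
  }
  N <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  degenerate <- c1 == 0 | c2 == 0
  stat <- ifelse(degenerate, 0,
                 N * (a * d - b * c)^2 / (r1 * r2 * pmax(c1, 1) * pmax(c2, 1)))
  chi2_p <- ifelse(degenerate, 1, stats::pchisq(stat, df = 1,
                                                lower.tail = FALSE))
  fisher_p <- vapply(seq_len(n), function(i) {
    if (degenerate[i]) return(1)
    m <- r1[i]; nn <- r2[i]; k <- c1[i]
    support <- max(0, k - nn):min(k, m)
    dens <- stats::dhyper(support, m, nn, k)
    d0 <- stats::dhyper(a[i], m, nn, k)
    min(1, sum(dens[dens <= d0 * (1 + 1e-7)]))
  }, 0)
  tibble::tibble(chi2_p = chi2_p, fisher_p = pmin(pmax(fisher_p, 0), 1))
}

new_ruleset <- function(rules, alpha, min_support, max_terms, provenance) {
  structure(rules,
            alpha = as.numeric(alpha), min_support = as.integer(min_support),
            max_terms = as.integer(max_terms), provenance = provenance,
            class = c("fall_ruleset", class(tibble::tibble())))
}

#' Mine and select category decision rules
#'
#' Runs the full rule-construction procedure: enumerate candidates from the
#' positive corpus ([enumerate_candidates()]), cross-tabulate each
#' candidate's document matches against the two classes, test each 2x2
#' table ([score_candidate()]) and keep rules that are significant at
#' `alpha` *and* enriched in the positive class
#' (`a/(a+b) > c/(c+d)`). The decision p-value is the Fisher exact p when
#' any expected cell count is below 5 and the chi-square p otherwise.
#' After selection, a rule whose set of matched positive documents is
#' identical to that of a strictly smaller selected rule is pruned as
#' redundant. Rules are ordered by decision p, then size, then rule string.
#'
#' @param positive,negative `fall_corpus` objects for the two classes.
#' @param alpha Significance level for selection (default 0.05, no
#'   multiple-testing correction, matching the construction procedure this
#'   package models).
#' @param min_support Minimum positive-document support for a candidate.
#' @param max_terms Maximum rule size.
#' @return A `fall_ruleset`: a tibble with columns `rule`, `total_terms`,
#'   `a`, `b`, `c`, `d`, `chi2_p`, `fisher_p`, `selected_p`, carrying
#'   `alpha`, `min_support`, `max_terms` and `provenance` attributes. Rules
#'   removed by redundancy pruning are recorded in the `pruned` attribute
#'   together with the equivalent kept rule; [rule_in_set()] checks
#'   membership up to that equivalence.
#' @examples
#' cfg <- corpus_sim_config(n_positive = 40, n_negative = 40, seed = 7)
#' corpora <- generate_labeled_corpus(cfg)
#' select_rules(corpora$positive, corpora$negative, min_support = 4)
#' @export
select_rules <- function(positive, negative, alpha = 0.05, min_support = 5,
                         max_terms = 3) {
  n_pos <- nrow(corpus_docs(positive))
  n_neg <- nrow(corpus_docs(negative))
  if (n_pos == 0 || n_neg == 0) {
    stop("both corpora must contain at least one document", call. = FALSE)
  }
  cand <- enumerate_candidates(positive, max_terms = max_terms,
                               min_support = min_support)
  provenance <- list(
    n_positive = n_pos, n_negative = n_neg,
    metadata = attr(positive, "metadata"))
  empty <- tibble::tibble(rule = character(), total_terms = integer(),
                          a = integer(), b = integer(), c = integer(),
                          d = integer(), chi2_p = double(),
                          fisher_p = double(), selected_p = double())
  if (nrow(cand) == 0) {
    return(new_ruleset(empty, alpha, min_support, max_terms, provenance))
  }
  neg_counts <- matched_pairs(negative, cand$rule) |>
    dplyr::count(.data$rule, name = "c")
  scored <- cand |>
    dplyr::left_join(neg_counts, by = "rule") |>
    dplyr::mutate(
      a = .data$support,
      b = n_pos - .data$a,
      c = dplyr::coalesce(.data$c, 0L),
      d = n_neg - .data$c,
      total_terms = rule_terms(.data$rule))
  sc <- score_candidate(scored$a, scored$b, scored$c, scored$d)
  N <- n_pos + n_neg
  min_expected <- with(scored, pmin((a + b) * (a + c), (a + b) * (b + d),
                                    (c + d) * (a + c), (c + d) * (b + d)) / N)
  scored$chi2_p <- sc$chi2_p
  scored$fisher_p <- sc$fisher_p
  scored$selected_p <- ifelse(min_expected < 5, sc$fisher_p, sc$chi2_p)
  selected <- scored |>
    dplyr::filter(.data$selected_p < alpha,
                  .data$a / (.data$a + .data$b) >
                    .data$c / (.data$c + .data$d))
  pruned <- tibble::tibble(rule = character(), total_terms = integer(),
                           kept_rule = character())
  if (nrow(selected) > 0) {
    # prune rules whose positive-document support set duplicates that of a
    # strictly smaller selected rule; record what was pruned and which
    # equivalent rule carries its discriminative behavior
    sig <- matched_pairs(positive, selected$rule) |>
      dplyr::group_by(.data$rule) |>
      dplyr::summarise(signature = paste(sort(.data$doc_id), collapse = "\r"),
                       .groups = "drop")
    selected <- selected |>
      dplyr::left_join(sig, by = "rule") |>
      dplyr::group_by(.data$signature) |>
      dplyr::mutate(.keep_rule = sort(.data$rule[
        .data$total_terms == min(.data$total_terms)])[1],
        .drop = .data$total_terms > min(.data$total_terms)) |>
      dplyr::ungroup()
    pruned <- selected |>
      dplyr::filter(.data$.drop) |>
      dplyr::transmute(rule = .data$rule, total_terms = .data$total_terms,
                       kept_rule = .data$.keep_rule)
    selected <- selected |>
      dplyr::filter(!.data$.drop) |>
      dplyr::select(-"signature", -".keep_rule", -".drop")
  }
  selected <- selected |>
    dplyr::arrange(.data$selected_p, .data$total_terms, .data$rule) |>
    dplyr::select("rule", "total_terms", "a", "b", "c", "d",
                  "chi2_p", "fisher_p", "selected_p")
  out <- new_ruleset(selected, alpha, min_support, max_terms, provenance)
  attr(out, "pruned") <- pruned
  out
}

#' Is a rule's discriminative behavior in a rule set?
#'
#' `TRUE` when the rule was selected directly, or was pruned as redundant
#' in favor of a strictly smaller rule matching exactly the same positive
#' documents (in which case its discriminative behavior is still carried
#' by the set).
#'
#' @param ruleset A `fall_ruleset` from [select_rules()].
#' @param rule Character vector of rule strings (compared on their
#'   canonical form, so `"a+b -> c"` and `"b+a -> c"` are the same rule).
#' @return Logical vector.
#' @export
rule_in_set <- function(ruleset, rule) {
  canon <- function(r) vapply(r, function(x) format_rule(canonical_rule(x)),
                              "", USE.NAMES = FALSE)
  have <- canon(ruleset$rule)
  pruned <- attr(ruleset, "pruned")
  if (!is.null(pruned) && nrow(pruned) > 0) {
    have <- c(have, canon(pruned$rule))
  }
  canon(rule) %in% have
}

# sort lemmas within pair groups so equivalent rules share one string
canonical_rule <- function(rule) {
  lapply(parse_rule(rule), function(g) g[order(g$lemma), , drop = FALSE])
}

#' Classify documents with a rule set
#'
#' A document is flagged positive when at least one rule matches it. The
#' output preserves corpus document order and records which rules matched.
#'
#' @param corpus A `fall_corpus`.
#' @param rules A `fall_ruleset`, or any data frame with a `rule` column,
#'   or a character vector of rule strings.
#' @return A tibble with one row per document: `doc_id`, `label`, `source`,
#'   `flag` (logical), `n_rules_matched`, and `matched_rules` (list column
#'   of rule strings).
#' @export
classify <- function(corpus, rules) {
  rule_strings <- if (is.character(rules)) rules else {
    if (!is.data.frame(rules) || !"rule" %in% names(rules)) {
      stop("`rules` must be a fall_ruleset, a data frame with a `rule` ",
           "column, or a character vector", call. = FALSE)
    }
    rules$rule
  }
  docs <- corpus_docs(corpus)
  if (length(rule_strings) == 0) {
    warning("empty rule set: all documents flagged negative", call. = FALSE)
    return(tibble::tibble(doc_id = docs$doc_id, label = docs$label,
                          source = docs$source, flag = FALSE,
                          n_rules_matched = 0L,
                          matched_rules = rep(list(character(0)),
                                              nrow(docs))))
  }
  mp <- matched_pairs(corpus, rule_strings)
  per_doc <- mp |>
    dplyr::group_by(.data$doc_id) |>
    dplyr::summarise(matched_rules = list(sort(unique(.data$rule))),
                     .groups = "drop")
  out <- docs |>
    dplyr::left_join(per_doc, by = "doc_id") |>
    dplyr::mutate(
      matched_rules = purrr::map(.data$matched_rules,
                                 \(x) if (is.null(x)) character(0) else x),
      n_rules_matched = lengths(.data$matched_rules),
      flag = .data$n_rules_matched > 0L)
  out[, c("doc_id", "label", "source", "flag", "n_rules_matched",
          "matched_rules")]
}

#' Assign rules to thematic categories from user lexicons
#'
#' Rule curation in practice groups mined rules into themes (fall motion,
#' injuries, loss of balance, fall-detection sensors, ...). That grouping
#' is a human judgement; this helper only applies user-supplied lemma
#' lexicons: a rule is tagged with the first declared category whose
#' lexicon shares a lemma with the rule, else `"uncategorized"`.
#'
#' @param rule Character vector of rule strings.
#' @param lexicons Named list of character vectors of lemmas; lexicons must
#'   not overlap.
#' @return Character vector of category names, one per rule.
#' @examples
#' tag_rule_category("sasaeru+nai -> tentoh",
#'                   list(fall_motion = c("tentoh", "ochiru")))
#' @export
tag_rule_category <- function(rule, lexicons) {
  if (length(lexicons) == 0) return(rep("uncategorized", length(rule)))
  if (is.null(names(lexicons)) || any(!nzchar(names(lexicons)))) {
    stop("lexicons must be a named list", call. = FALSE)
  }
  all_terms <- unlist(lexicons, use.names = FALSE)
  if (anyDuplicated(all_terms) > 0) {
    dup <- unique(all_terms[duplicated(all_terms)])
    stop("lexicons overlap on lemma(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  vapply(rule, function(r) {
    lemmas <- rule_lemmas(r)
    for (cat in names(lexicons)) {
      if (length(intersect(lemmas, lexicons[[cat]])) > 0) return(cat)
    }
    "uncategorized"
  }, "", USE.NAMES = FALSE)
}

#' Write a rule set to its line-oriented text format
#'
#' One rule per line: the rule string followed by tab-separated columns
#' `a`, `b`, `c`, `d`, `chi2_p`, `fisher_p`, `selected_p`. Header comments
#' record `alpha`, `min_support`, `max_terms` and provenance. P-values are
#' written with 17 significant digits so that
#' `read_ruleset(write_ruleset(x, f))` is bit-exact.
#'
#' @param ruleset A `fall_ruleset`.
#' @param path Output path.
#' @param extra_header Optional character vector of additional `#` comment
#'   lines (e.g. run provenance from a command-line driver).
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(ruleset, path, extra_header = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# fallnlp rule set", con)
  if (!is.null(extra_header)) writeLines(extra_header, con)
  writeLines(sprintf("# alpha = %.17g", attr(ruleset, "alpha")), con)
  writeLines(sprintf("# min_support = %d",
                     as.integer(attr(ruleset, "min_support"))), con)
  writeLines(sprintf("# max_terms = %d",
                     as.integer(attr(ruleset, "max_terms"))), con)
  prov <- attr(ruleset, "provenance")
  for (key in setdiff(names(prov), "metadata")) {
    writeLines(sprintf("# provenance %s = %s", key,
                       as.character(prov[[key]])), con)
  }
  for (key in names(prov$metadata)) {
    writeLines(sprintf("# provenance meta.%s = %s", key,
                       as.character(prov$metadata[[key]])), con)
  }
  writeLines(paste("# columns: rule", "a", "b", "c", "d", "chi2_p",
                   "fisher_p", "selected_p", sep = "\t"), con)
  if (nrow(ruleset) > 0) {
    writeLines(sprintf("%s\t%d\t%d\t%d\t%d\t%.17g\t%.17g\t%.17g",
                       ruleset$rule, ruleset$a, ruleset$b, ruleset$c,
                       ruleset$d, ruleset$chi2_p, ruleset$fisher_p,
                       ruleset$selected_p), con)
  }
  invisible(path)
}

#' Read a rule set written by [write_ruleset()]
#'
#' @param path Path to a rule-set file.
#' @return A `fall_ruleset`.
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) stop("no such rule file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  grab <- function(key, default = NA) {
    pat <- paste0("^#\\s*", key, "\\s*=\\s*(.*)$")
    hit <- grep(pat, lines, value = TRUE)
    if (length(hit) == 0) return(default)
    sub(pat, "\\1", hit[[1]])
  }
  alpha <- as.numeric(grab("alpha", "0.05"))
  min_support <- as.integer(grab("min_support", "5"))
  max_terms <- as.integer(grab("max_terms", "3"))
  prov <- list()
  prov_lines <- grep("^#\\s*provenance\\s+", lines, value = TRUE)
  meta <- list()
  for (pl in prov_lines) {
    m <- regmatches(pl, regexec("^#\\s*provenance\\s+([^=]+?)\\s*=\\s*(.*)$",
                                pl))[[1]]
    if (length(m) != 3) next
    if (startsWith(m[2], "meta.")) {
      meta[[sub("^meta\\.", "", m[2])]] <- m[3]
    } else prov[[m[2]]] <- m[3]
  }
  prov$metadata <- meta
  body <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(body) == 0) {
    rules <- tibble::tibble(rule = character(), total_terms = integer(),
                            a = integer(), b = integer(), c = integer(),
                            d = integer(), chi2_p = double(),
                            fisher_p = double(), selected_p = double())
  } else {
    fields <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(fields) != 8)
    if (length(bad) > 0) {
      stop("malformed rule line: ", body[bad[1]], call. = FALSE)
    }
    getcol <- function(i) vapply(fields, `[`, "", i)
    rules <- tibble::tibble(
      rule = getcol(1),
      total_terms = rule_terms(getcol(1)),
      a = as.integer(getcol(2)), b = as.integer(getcol(3)),
      c = as.integer(getcol(4)), d = as.integer(getcol(5)),
      chi2_p = as.numeric(getcol(6)), fisher_p = as.numeric(getcol(7)),
      selected_p = as.numeric(getcol(8)))
  }
  new_ruleset(rules, alpha, min_support, max_terms, prov)
}

#' @export
print.fall_ruleset <- function(x, ...) {
  cat("# A category decision rule set: ", nrow(x), " rule(s)\n", sep = "")
  cat("# alpha = ", attr(x, "alpha"),
      ", min_support = ", attr(x, "min_support"),
      ", max_terms = ", attr(x, "max_terms"), "\n", sep = "")
  NextMethod()
}

#' Tidy a rule set into a plain tibble
#'
#' @param x A `fall_ruleset`.
#' @param ... Unused.
#' @return A tibble with one row per selected rule.
#' @export
tidy.fall_ruleset <- function(x, ...) {
  out <- as.data.frame(x)
  attributes(out) <- attributes(out)[c("names", "row.names", "class")]
  tibble::as_tibble(out)
}

#' One-row summary of a rule set
#'
#' @param x A `fall_ruleset`.
#' @param ... Unused.
#' @return A tibble with columns `n_rules`, `alpha`, `min_support`,
#'   `max_terms`, `n_positive`, `n_negative`, `min_p`, `median_support`.
#' @export
glance.fall_ruleset <- function(x, ...) {
  prov <- attr(x, "provenance")
  tibble::tibble(
    n_rules = nrow(x),
    alpha = attr(x, "alpha"),
    min_support = attr(x, "min_support"),
    max_terms = attr(x, "max_terms"),
    n_positive = as.integer(prov$n_positive %||% NA),
    n_negative = as.integer(prov$n_negative %||% NA),
    min_p = if (nrow(x) > 0) min(x$selected_p) else NA_real_,
    median_support = if (nrow(x) > 0) stats::median(x$a) else NA_real_)
}
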