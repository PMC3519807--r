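#' Category decision rules
#'
#' A category decision rule is a small set of lemma terms organised into one
#' or two groups. Terms inside a group are joined by `"+"` and must occur in
#' a direct dependency relation (head and dependent, direction-insensitive)
#' within one sentence. Groups are joined by `"->"`, read as causal or
#' temporal precedence and operationalised as strict document order: some
#' match of the left group must precede some match of the right group, by
#' sentence index then token index, cross-sentence matches allowed.
#'
#' Rules are written as strings, e.g. `"sasaeru+nai -> tentoh"` (a failed
#' attempt to support a patient, followed by a fall) or
#' `"bed -> zuri+ochiru"` (a bed mentioned before a slip-and-fall). A term
#' may carry an optional part-of-speech constraint as `lemma/POS`.
#'
#' @name decision-rules
NULL

# rule string -> list of groups; each group a tibble(lemma, pos)
parse_rule <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1)
  groups <- strsplit(rule, "->", fixed = TRUE)[[1]]
  groups <- trimws(groups)
  if (length(groups) < 1 || any(!nzchar(groups))) {
    stop("malformed rule: '", rule, "'", call. = FALSE)
  }
  parsed <- lapply(groups, parse_group)
  total <- sum(vapply(parsed, nrow, 0L))
  if (total < 2) {
    stop("a rule needs at least two terms joined by '+' or '->': '",
         rule, "'", call. = FALSE)
  }
  if (length(parsed) > 2) {
    stop("rule '", rule, "' has more than two '->' groups", call. = FALSE)
  }
  parsed
}

# one "+"-joined group string -> tibble(lemma, pos)
parse_group <- function(g) {
  terms <- trimws(strsplit(g, "+", fixed = TRUE)[[1]])
  if (length(terms) == 0 || any(!nzchar(terms))) {
    stop("malformed rule group: '", g, "'", call. = FALSE)
  }
  if (length(terms) > 2) {
    stop("rule group '", g, "' has more than two terms", call. = FALSE)
  }
  parts <- strsplit(terms, "/", fixed = TRUE)
  tibble::tibble(
    lemma = vapply(parts, `[`, "", 1),
    pos = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                 ""))
}

format_term <- function(lemma, pos) {
  ifelse(is.na(pos), lemma, paste0(lemma, "/", pos))
}

# canonical string form: groups joined by " -> ", terms by "+"
format_rule <- function(parsed) {
  paste(vapply(parsed, function(g) paste(format_term(g$lemma, g$pos),
                                         collapse = "+"), ""),
        collapse = " -> ")
}

#' Number of terms in a rule
#' @param rule Character vector of rule strings.
#' @return Integer vector.
#' @export
rule_terms <- function(rule) {
  vapply(rule, function(r) sum(vapply(parse_rule(r), nrow, 0L)), 0L,
         USE.NAMES = FALSE)
}

#' Lemmas named by a rule
#' @param rule A single rule string.
#' @return Character vector of the rule's lemmas, in rule order.
#' @export
rule_lemmas <- function(rule) {
  unlist(lapply(parse_rule(rule), function(g) g$lemma), use.names = FALSE)
}

term_ok <- function(tok, lemma, pos) {
  tok$lemma == lemma & (is.na(pos) | (!is.na(tok$pos) & tok$pos == pos))
}

#' Match one rule group against one sentence
#'
#' For a single-term group, the match positions are the token indices whose
#' lemma (and part of speech, if constrained) equal the term. For a
#' two-term group, a match is a pair of tokens, one matching each term,
#' that are directly linked in the dependency forest (either direction);
#' the reported position is the smaller token index of the pair.
#'
#' @param sentence Token rows of one sentence (a data frame with
#'   `token_index`, `lemma`, `pos`, `head_index`).
#' @param group A group string such as `"sasaeru+nai"` or `"tentoh"`.
#' @return Sorted integer vector of match positions (possibly empty).
#' @examples
#' s <- tibble::tibble(token_index = 1:2, lemma = c("sasaeru", "nai"),
#'                     pos = "X", head_index = c(0L, 1L))
#' match_group(s, "sasaeru+nai")
#' @export
match_group <- function(sentence, group) {
  g <- if (is.character(group)) parse_group(group) else group
  sentence <- tibble::as_tibble(sentence)
  if (nrow(sentence) == 0) return(integer(0))
  if (nrow(g) == 1) {
    hits <- sentence$token_index[term_ok(sentence, g$lemma[1], g$pos[1])]
    return(sort(unique(hits)))
  }
  # two terms: direct dependency link, direction-insensitive
  dep <- sentence[sentence$head_index > 0L, ]
  if (nrow(dep) == 0) return(integer(0))
  head_tok <- sentence[match(dep$head_index, sentence$token_index), ]
  fwd <- term_ok(dep, g$lemma[1], g$pos[1]) & term_ok(head_tok, g$lemma[2], g$pos[2])
  rev <- term_ok(dep, g$lemma[2], g$pos[2]) & term_ok(head_tok, g$lemma[1], g$pos[1])
  hit <- fwd | rev
  sort(unique(pmin(dep$token_index[hit], dep$head_index[hit])))
}

#' Match a decision rule against one document
#'
#' A rule matches when every group matches somewhere in the document and,
#' for consecutive groups `G1 -> G2`, some match of `G1` strictly precedes
#' some match of `G2` in document order (sentence index, then token index).
#' Matches of the two groups may fall in different sentences.
#'
#' @param document Token rows of one document (a `fall_corpus` filtered to
#'   a single `doc_id`, or any data frame with the token columns).
#' @param rule A rule string.
#' @param trace If `TRUE`, attach the matched positions of each group as the
#'   `"trace"` attribute of the result.
#' @return Logical scalar.
#' @export
match_rule <- function(document, rule, trace = FALSE) {
  parsed <- parse_rule(rule)
  document <- tibble::as_tibble(document)
  if (nrow(document) == 0) return(FALSE)
  if (length(unique(document$doc_id)) > 1) {
    stop("match_rule() expects a single document; got ",
         length(unique(document$doc_id)), " doc_ids", call. = FALSE)
  }
  positions <- lapply(parsed, function(g) {
    hits <- lapply(split(document, document$sentence_index), function(sent) {
      p <- match_group(sent, g)
      if (length(p) == 0) return(NULL)
      cbind(sentence = sent$sentence_index[1], token = p)
    })
    do.call(rbind, hits)
  })
  if (any(vapply(positions, is.null, TRUE))) return(FALSE)
  keys <- lapply(positions, function(m) sort(m[, "sentence"] * 1e6 + m[, "token"]))
  ok <- TRUE
  if (length(keys) == 2) ok <- min(keys[[1]]) < max(keys[[2]])
  if (trace && ok) {
    res <- ok
    attr(res, "trace") <- positions
    return(res)
  }
  ok
}

## ---- vectorised matching machinery -----------------------------------------
## A corpus index holds, per document, the first/last document-order position
## of every lemma (table L) and of every dependency-linked lemma pair
## (table P, pair stored with sorted lemmas, position = min token index of
## the pair). Positions are encoded as sentence_index * 1e6 + token_index,
## which is order-isomorphic to (sentence, token) for sentences shorter than
## a million tokens. Every rule shape used here reduces to existence tests
## of the form min(left positions) < max(right positions), so first/last
## positions are sufficient statistics for matching.

corpus_index <- function(corpus) {
  tok <- tibble::as_tibble(corpus)
  docs <- corpus_docs(corpus)
  if (nrow(tok) == 0) {
    empty_L <- tibble::tibble(doc_id = character(), lemma = character(),
                              n_occ = integer(), first_pos = double(),
                              last_pos = double())
    empty_P <- tibble::tibble(doc_id = character(), u = character(),
                              v = character(), first_pos = double(),
                              last_pos = double())
    return(list(L = empty_L, P = empty_P, docs = docs))
  }
  tok$pos_key <- tok$sentence_index * 1e6 + tok$token_index
  L <- tok |>
    dplyr::group_by(.data$doc_id, .data$lemma) |>
    dplyr::summarise(n_occ = dplyr::n(), first_pos = min(.data$pos_key),
                     last_pos = max(.data$pos_key), .groups = "drop")
  dep <- tok[tok$head_index > 0L, ]
  if (nrow(dep) > 0) {
    key <- paste(dep$doc_id, dep$sentence_index, dep$head_index)
    tok_key <- paste(tok$doc_id, tok$sentence_index, tok$token_index)
    head_row <- match(key, tok_key)
    P <- tibble::tibble(
      doc_id = dep$doc_id,
      u = pmin(dep$lemma, tok$lemma[head_row]),
      v = pmax(dep$lemma, tok$lemma[head_row]),
      pos_key = dep$sentence_index * 1e6 + pmin(dep$token_index, dep$head_index)) |>
      dplyr::group_by(.data$doc_id, .data$u, .data$v) |>
      dplyr::summarise(first_pos = min(.data$pos_key),
                       last_pos = max(.data$pos_key), .groups = "drop")
  } else {
    P <- tibble::tibble(doc_id = character(), u = character(), v = character(),
                        first_pos = double(), last_pos = double())
  }
  list(L = L, P = P, docs = docs)
}

# TRUE when a rule has any part-of-speech-constrained term (index path
# tracks lemmas only; such rules take the per-document matcher)
rule_has_pos <- function(parsed) {
  any(vapply(parsed, function(g) any(!is.na(g$pos)), TRUE))
}

# matches of one (lemma-only) group across all indexed documents:
# tibble(doc_id, first_pos, last_pos)
group_matches_index <- function(index, group) {
  if (nrow(group) == 1) {
    hit <- index$L[index$L$lemma == group$lemma[1], ]
    return(hit[, c("doc_id", "first_pos", "last_pos")])
  }
  u <- min(group$lemma); v <- max(group$lemma)
  hit <- index$P[index$P$u == u & index$P$v == v, ]
  hit[, c("doc_id", "first_pos", "last_pos")]
}

# doc_ids matching each rule, via the index (lemma-only rules)
matched_docs_index <- function(index, rule) {
  parsed <- parse_rule(rule)
  gm <- lapply(parsed, group_matches_index, index = index)
  if (length(gm) == 1) return(gm[[1]]$doc_id)
  joined <- dplyr::inner_join(gm[[1]], gm[[2]], by = "doc_id",
                              suffix = c("_l", "_r"))
  joined$doc_id[joined$first_pos_l < joined$last_pos_r]
}

# (rule, doc_id) pairs for every rule matching every document, computed by
# shape-grouped joins against the corpus index. Rules with part-of-speech
# constraints fall back to the per-document matcher.
matched_pairs <- function(corpus, rules, index = NULL) {
  rules <- unique(rules)
  empty <- tibble::tibble(rule = character(), doc_id = character())
  if (length(rules) == 0) return(empty)
  if (is.null(index)) index <- corpus_index(corpus)
  parsed_all <- lapply(rules, parse_rule)
  needs_pos <- vapply(parsed_all, rule_has_pos, TRUE)
  shape <- vapply(parsed_all, function(p) {
    paste(vapply(p, nrow, 0L), collapse = "_")
  }, "")
  L <- index$L
  P <- index$P
  out <- list(empty)

  lem <- function(idx, i, j) {
    vapply(idx, function(p) parsed_all[[p]][[i]]$lemma[j], "")
  }
  for (sh in unique(shape[!needs_pos])) {
    idx <- which(shape == sh & !needs_pos)
    r <- rules[idx]
    hits <- switch(sh,
      "2" = {
        cand <- tibble::tibble(rule = r,
                               u = pmin(lem(idx, 1, 1), lem(idx, 1, 2)),
                               v = pmax(lem(idx, 1, 1), lem(idx, 1, 2)))
        dplyr::inner_join(cand, P, by = c("u", "v"),
                          relationship = "many-to-many")
      },
      "1_1" = {
        cand <- tibble::tibble(rule = r, a = lem(idx, 1, 1), b = lem(idx, 2, 1))
        dplyr::inner_join(cand, L, by = c(a = "lemma"),
                          relationship = "many-to-many") |>
          dplyr::inner_join(L, by = c("doc_id", b = "lemma"),
                            suffix = c("_l", "_r"),
                            relationship = "many-to-many") |>
          dplyr::filter(.data$first_pos_l < .data$last_pos_r)
      },
      "2_1" = {
        cand <- tibble::tibble(rule = r,
                               u = pmin(lem(idx, 1, 1), lem(idx, 1, 2)),
                               v = pmax(lem(idx, 1, 1), lem(idx, 1, 2)),
                               b = lem(idx, 2, 1))
        dplyr::inner_join(cand, P, by = c("u", "v"),
                          relationship = "many-to-many") |>
          dplyr::inner_join(L, by = c("doc_id", b = "lemma"),
                            suffix = c("_l", "_r"),
                            relationship = "many-to-many") |>
          dplyr::filter(.data$first_pos_l < .data$last_pos_r)
      },
      "1_2" = {
        cand <- tibble::tibble(rule = r, a = lem(idx, 1, 1),
                               u = pmin(lem(idx, 2, 1), lem(idx, 2, 2)),
                               v = pmax(lem(idx, 2, 1), lem(idx, 2, 2)))
        dplyr::inner_join(cand, L, by = c(a = "lemma"),
                          relationship = "many-to-many") |>
          dplyr::inner_join(P, by = c("doc_id", "u", "v"),
                            suffix = c("_l", "_r"),
                            relationship = "many-to-many") |>
          dplyr::filter(.data$first_pos_l < .data$last_pos_r)
      },
      stop("unsupported rule shape: ", sh, call. = FALSE))
    out[[length(out) + 1L]] <- hits[, c("rule", "doc_id")]
  }
  if (any(needs_pos)) {
    tok <- tibble::as_tibble(corpus)
    by_doc <- split(tok, tok$doc_id)
    for (i in which(needs_pos)) {
      hit <- vapply(by_doc, match_rule, TRUE, rule = rules[[i]])
      if (any(hit)) {
        out[[length(out) + 1L]] <-
          tibble::tibble(rule = rules[[i]], doc_id = names(by_doc)[hit])
      }
    }
  }
  dplyr::distinct(dplyr::bind_rows(out))
}
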