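#' Parsed-corpus tibbles
#'
#' A parsed corpus is a tibble with one row per morpheme and columns
#' `doc_id`, `label`, `source`, `sentence_index`, `token_index`, `surface`,
#' `lemma`, `pos` and `head_index`. Token and sentence indices are 1-based;
#' `head_index` points at the token's dependency head within the same
#' sentence, with `0` marking a root. Rule matching operates on `lemma`
#' (the normalized base form), never on `surface`.
#'
#' Document order and per-document metadata (including documents that happen
#' to contain no tokens) are kept in the `docs` attribute, a tibble with
#' columns `doc_id`, `label`, `source`. `label` is `"positive"`,
#' `"negative"` or `NA` (unlabeled).
#'
#' @param tokens A data frame with the token columns listed above.
#' @param docs Optional per-document metadata tibble (`doc_id`, `label`,
#'   `source`). Defaults to the distinct documents of `tokens`, in order of
#'   first appearance.
#' @param metadata Optional named list of free-form corpus metadata
#'   (e.g. collection period).
#' @return A `fall_corpus` tibble.
#' @examples
#' naive_parse("patient slipped from bed. nurse found patient on floor.",
#'             doc_id = "n1", label = "positive")
#' @export
fall_corpus <- function(tokens, docs = NULL, metadata = list()) {
  tokens <- tibble::as_tibble(tokens)
  needed <- c("doc_id", "sentence_index", "token_index", "surface", "lemma",
              "pos", "head_index")
  missing <- setdiff(needed, names(tokens))
  if (length(missing) > 0) {
    stop("corpus tokens lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"label" %in% names(tokens)) tokens$label <- NA_character_
  if (!"source" %in% names(tokens)) tokens$source <- NA_character_
  tokens <- tokens[, c("doc_id", "label", "source", "sentence_index",
                       "token_index", "surface", "lemma", "pos", "head_index")]
  tokens$doc_id <- as.character(tokens$doc_id)
  tokens$sentence_index <- as.integer(tokens$sentence_index)
  tokens$token_index <- as.integer(tokens$token_index)
  tokens$head_index <- as.integer(tokens$head_index)
  if (is.null(docs)) {
    docs <- dplyr::distinct(tokens, .data$doc_id, .data$label, .data$source)
  }
  docs <- tibble::as_tibble(docs)
  if (!"label" %in% names(docs)) docs$label <- NA_character_
  if (!"source" %in% names(docs)) docs$source <- NA_character_
  out <- tokens
  attr(out, "docs") <- docs[, c("doc_id", "label", "source")]
  attr(out, "metadata") <- metadata
  class(out) <- c("fall_corpus", class(tibble::tibble()))
  validate_corpus(out)
  out
}

#' Per-document metadata of a corpus
#'
#' @param corpus A `fall_corpus`.
#' @return A tibble with columns `doc_id`, `label`, `source`, one row per
#'   document in corpus order (documents without tokens included).
#' @export
corpus_docs <- function(corpus) {
  docs <- attr(corpus, "docs")
  if (is.null(docs)) {
    docs <- dplyr::distinct(tibble::as_tibble(corpus),
                            .data$doc_id, .data$label, .data$source)
  }
  docs
}

#' Validate parsed-corpus invariants
#'
#' Checks, per sentence, that token indices are exactly `1..n`, that every
#' `head_index` lies in `0..n` and differs from the token's own index, and
#' that the head relation is a forest (no cycles); per document, that
#' sentence indices are exactly `1..m`; and that `doc_id` is unique in the
#' document table. Errors name the offending document.
#'
#' @param corpus A `fall_corpus` (or plain data frame with the same columns).
#' @return `corpus`, invisibly.
#' @export
validate_corpus <- function(corpus) {
  docs <- corpus_docs(corpus)
  if (anyDuplicated(docs$doc_id) > 0) {
    stop("duplicate doc_id in corpus: ",
         paste(unique(docs$doc_id[duplicated(docs$doc_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_label <- setdiff(unique(docs$label), c("positive", "negative", NA))
  if (length(bad_label) > 0) {
    stop("invalid document label(s): ", paste(bad_label, collapse = ", "),
         call. = FALSE)
  }
  tok <- tibble::as_tibble(corpus)
  if (nrow(tok) == 0) return(invisible(corpus))
  extra <- setdiff(unique(tok$doc_id), docs$doc_id)
  if (length(extra) > 0) {
    stop("tokens reference doc_id absent from document table: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  split_doc <- split(tok, tok$doc_id)
  for (doc in split_doc) {
    id <- doc$doc_id[1]
    sents <- sort(unique(doc$sentence_index))
    if (!identical(sents, seq_along(sents))) {
      stop("document '", id, "': sentence_index values are not 1..m",
           call. = FALSE)
    }
    for (sent in split(doc, doc$sentence_index)) {
      n <- nrow(sent)
      ord <- order(sent$token_index)
      sent <- sent[ord, ]
      if (!identical(sent$token_index, seq_len(n))) {
        stop("document '", id, "', sentence ", sent$sentence_index[1],
             ": token_index values are not 1..n", call. = FALSE)
      }
      h <- sent$head_index
      if (any(h < 0L | h > n)) {
        stop("document '", id, "', sentence ", sent$sentence_index[1],
             ": head_index out of range 0..", n, call. = FALSE)
      }
      if (any(h == sent$token_index)) {
        stop("document '", id, "', sentence ", sent$sentence_index[1],
             ": token is its own head", call. = FALSE)
      }
      if (has_head_cycle(h)) {
        stop("document '", id, "', sentence ", sent$sentence_index[1],
             ": dependency heads form a cycle", call. = FALSE)
      }
    }
  }
  invisible(corpus)
}

# TRUE when following head pointers from some token never reaches root 0
has_head_cycle <- function(heads) {
  n <- length(heads)
  state <- integer(n)  # 0 unseen, 1 on current path, 2 done
  for (start in seq_len(n)) {
    v <- start
    path <- integer(0)
    while (v != 0L && state[v] == 0L) {
      state[v] <- 1L
      path <- c(path, v)
      v <- heads[v]
    }
    if (v != 0L && state[v] == 1L) return(TRUE)
    state[path] <- 2L
  }
  FALSE
}

#' @export
print.fall_corpus <- function(x, ...) {
  docs <- corpus_docs(x)
  cat("# A parsed corpus: ", nrow(docs), " document(s), ",
      nrow(x), " token(s)\n", sep = "")
  NextMethod()
}

# keep class + attributes across dplyr verbs that return compatible frames
restore_corpus_attrs <- function(out, template) {
  attr(out, "docs") <- attr(template, "docs")
  attr(out, "metadata") <- attr(template, "metadata")
  class(out) <- class(template)
  out
}

#' Read a parsed corpus from its tabular exchange format
#'
#' The on-disk dialect is CoNLL-U-like TSV: per document a comment line
#' `# doc_id = <id>`, optionally followed by `# label = positive|negative`
#' and `# source = <name>`; token lines with five tab-separated fields
#' `token_index`, `surface`, `lemma`, `pos`, `head_index`; one blank line
#' between sentences; two blank lines between documents. File-level
#' metadata may precede the first document as `# meta <key> = <value>`
#' lines. Files are UTF-8.
#'
#' @param path Path to a corpus file.
#' @return A `fall_corpus`.
#' @export
read_parsed_corpus <- function(path) {
  if (!file.exists(path)) stop("no such corpus file: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  meta <- list()
  doc_rows <- list()
  tok_rows <- list()
  cur_doc <- NULL
  cur_label <- NA_character_
  cur_source <- NA_character_
  sent_idx <- 0L
  in_sentence <- FALSE

  flush_doc <- function() {
    if (!is.null(cur_doc)) {
      doc_rows[[length(doc_rows) + 1L]] <<-
        tibble::tibble(doc_id = cur_doc, label = cur_label, source = cur_source)
    }
  }
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (grepl("^#", line)) {
      m <- regmatches(line, regexec("^#\\s*meta\\s+([^=]+?)\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 3) { meta[[m[2]]] <- m[3]; next }
      m <- regmatches(line, regexec("^#\\s*doc_id\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 2) {
        flush_doc()
        cur_doc <- m[2]; cur_label <- NA_character_; cur_source <- NA_character_
        sent_idx <- 0L; in_sentence <- FALSE
        next
      }
      m <- regmatches(line, regexec("^#\\s*label\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 2) { cur_label <- m[2]; next }
      m <- regmatches(line, regexec("^#\\s*source\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 2) { cur_source <- m[2]; next }
      next  # other comments ignored
    }
    if (!nzchar(trimws(line))) { in_sentence <- FALSE; next }
    if (is.null(cur_doc)) {
      stop("line ", i, ": token line before any '# doc_id =' comment",
           call. = FALSE)
    }
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 5 ||
        is.na(suppressWarnings(as.integer(fields[1]))) ||
        is.na(suppressWarnings(as.integer(fields[5])))) {
      stop("line ", i, ": malformed token line (expected 5 tab-separated ",
           "fields: token_index, surface, lemma, pos, head_index)",
           call. = FALSE)
    }
    if (!in_sentence) { sent_idx <- sent_idx + 1L; in_sentence <- TRUE }
    tok_rows[[length(tok_rows) + 1L]] <- tibble::tibble(
      doc_id = cur_doc, label = cur_label, source = cur_source,
      sentence_index = sent_idx,
      token_index = as.integer(fields[1]),
      surface = fields[2], lemma = fields[3], pos = fields[4],
      head_index = as.integer(fields[5]))
  }
  flush_doc()
  docs <- if (length(doc_rows) > 0) dplyr::bind_rows(doc_rows) else
    tibble::tibble(doc_id = character(), label = character(), source = character())
  tokens <- if (length(tok_rows) > 0) dplyr::bind_rows(tok_rows) else
    tibble::tibble(doc_id = character(), label = character(),
                   source = character(), sentence_index = integer(),
                   token_index = integer(), surface = character(),
                   lemma = character(), pos = character(),
                   head_index = integer())
  fall_corpus(tokens, docs = docs, metadata = meta)
}

#' Write a parsed corpus to its tabular exchange format
#'
#' Inverse of [read_parsed_corpus()]: `read_parsed_corpus(write_parsed_corpus(x, f))`
#' reproduces `x` exactly (tokens, document metadata and corpus metadata).
#'
#' @param corpus A `fall_corpus`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_parsed_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  docs <- corpus_docs(corpus)
  tok <- tibble::as_tibble(corpus)
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("# fallnlp parsed corpus", con)
  meta <- attr(corpus, "metadata")
  for (key in names(meta)) {
    writeLines(sprintf("# meta %s = %s", key, meta[[key]]), con)
  }
  first <- TRUE
  for (k in seq_len(nrow(docs))) {
    if (!first) writeLines(c("", ""), con)
    first <- FALSE
    writeLines(sprintf("# doc_id = %s", docs$doc_id[k]), con)
    if (!is.na(docs$label[k])) {
      writeLines(sprintf("# label = %s", docs$label[k]), con)
    }
    if (!is.na(docs$source[k])) {
      writeLines(sprintf("# source = %s", docs$source[k]), con)
    }
    dtok <- tok[tok$doc_id == docs$doc_id[k], ]
    if (nrow(dtok) == 0) next
    dtok <- dtok[order(dtok$sentence_index, dtok$token_index), ]
    for (s in unique(dtok$sentence_index)) {
      if (s > 1L) writeLines("", con)
      st <- dtok[dtok$sentence_index == s, ]
      writeLines(sprintf("%d\t%s\t%s\t%s\t%d", st$token_index, st$surface,
                         st$lemma, st$pos, st$head_index), con)
    }
  }
  invisible(path)
}

#' Whitespace fallback tokenizer
#'
#' A deliberately naive front-end for synthetic or already-romanized text:
#' sentences split on terminal punctuation (`. ! ?` and their fullwidth
#' forms), tokens split on whitespace, `lemma` the lowercased surface,
#' `pos` fixed to `"X"`, and a flat dependency chain in which each token's
#' head is the following token and the last token of a sentence is the
#' root. Real morphological analysis and dependency parsing are expected to
#' happen upstream, with the result supplied via [read_parsed_corpus()].
#'
#' @param text Character scalar of raw text (may be empty).
#' @param doc_id Document identifier.
#' @param label Optional `"positive"`/`"negative"` label.
#' @param source Optional source name.
#' @return A single-document `fall_corpus` (zero rows for empty text).
#' @export
naive_parse <- function(text, doc_id = "doc1", label = NULL, source = NULL) {
  label <- if (is.null(label)) NA_character_ else as.character(label)
  source <- if (is.null(source)) NA_character_ else as.character(source)
  docs <- tibble::tibble(doc_id = doc_id, label = label, source = source)
  sentences <- strsplit(text, "[.!?。！？]+")[[1]]
  sentences <- trimws(sentences)
  sentences <- sentences[nzchar(sentences)]
  rows <- purrr::imap(sentences, function(s, i) {
    toks <- strsplit(s, "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    n <- length(toks)
    if (n == 0) return(NULL)
    tibble::tibble(doc_id = doc_id, label = label, source = source,
                   sentence_index = as.integer(i),
                   token_index = seq_len(n), surface = toks,
                   lemma = tolower(toks), pos = "X",
                   head_index = c(seq_len(n)[-1], 0L))
  })
  tokens <- dplyr::bind_rows(rows)
  if (nrow(docs) > 0 && nrow(tokens) == 0) {
    tokens <- tibble::tibble(doc_id = character(), label = character(),
                             source = character(), sentence_index = integer(),
                             token_index = integer(), surface = character(),
                             lemma = character(), pos = character(),
                             head_index = integer())
  }
  # drop gaps left by empty sentences
  if (nrow(tokens) > 0) {
    tokens$sentence_index <- match(tokens$sentence_index,
                                   sort(unique(tokens$sentence_index)))
  }
  fall_corpus(tokens, docs = docs)
}
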