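# Independent brute-force oracles used across the suite. These deliberately
# share no code with the package internals: plain loops over token tuples,
# closed-form hypergeometric sums via choose(), and full enumeration of
# rank splits.

# all match positions of one rule group in one document, by exhaustive
# token(-pair) enumeration; positions encoded as sentence*1e6 + token
brute_group_positions <- function(document, group) {
  pos <- c()
  for (s in unique(document$sentence_index)) {
    sent <- document[document$sentence_index == s, ]
    sent <- sent[order(sent$token_index), ]
    n <- nrow(sent)
    if (nrow(group) == 1) {
      for (i in seq_len(n)) {
        if (sent$lemma[i] == group$lemma[1] &&
            (is.na(group$pos[1]) || sent$pos[i] == group$pos[1])) {
          pos <- c(pos, s * 1e6 + sent$token_index[i])
        }
      }
    } else {
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (i == j) next
        linked <- sent$head_index[i] == sent$token_index[j] ||
          sent$head_index[j] == sent$token_index[i]
        if (!linked) next
        ok1 <- sent$lemma[i] == group$lemma[1] &&
          (is.na(group$pos[1]) || sent$pos[i] == group$pos[1])
        ok2 <- sent$lemma[j] == group$lemma[2] &&
          (is.na(group$pos[2]) || sent$pos[j] == group$pos[2])
        if (ok1 && ok2) {
          pos <- c(pos, s * 1e6 + min(sent$token_index[i], sent$token_index[j]))
        }
      }
    }
  }
  sort(unique(pos))
}

# exhaustive-tuple rule matcher: every group must match, and some match of
# the left group must strictly precede some match of the right group
brute_match_rule <- function(document, rule) {
  groups <- fallnlp:::parse_rule(rule)
  if (nrow(document) == 0) return(FALSE)
  pos <- lapply(groups, brute_group_positions, document = document)
  if (any(vapply(pos, length, 0L) == 0)) return(FALSE)
  if (length(pos) == 1) return(TRUE)
  for (p1 in pos[[1]]) for (p2 in pos[[2]]) if (p1 < p2) return(TRUE)
  FALSE
}

# two-sided Fisher p by explicit hypergeometric enumeration with choose()
brute_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  if (k == 0 || b + d == 0) return(1)
  xs <- max(0, k - n):min(k, m)
  probs <- choose(m, xs) * choose(n, k - xs) / choose(m + n, k)
  p0 <- choose(m, a) * choose(n, k - a) / choose(m + n, k)
  min(1, sum(probs[probs <= p0 * (1 + 1e-7)]))
}

# two-sided exact Wilcoxon p by full enumeration of rank splits (tie-free)
brute_wilcoxon_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  ranks <- rank(c(x, y))
  u_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  us <- colSums(matrix(as.numeric(splits), nrow = nx)) - nx * (nx + 1) / 2
  pl <- mean(us <= u_obs)
  pu <- mean(us >= u_obs)
  min(1, 2 * min(pl, pu))
}

# sort-and-interpolate percentile oracle (linear interpolation, "type 7")
brute_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# small random corpus, independent of the package's simulator: heads point
# at strictly later tokens (or root), which is acyclic by construction
random_corpus <- function(n_docs, vocab = letters[1:8], max_sent = 3,
                          max_len = 7, labels = NA_character_) {
  rows <- list()
  for (k in seq_len(n_docs)) {
    m <- sample(max_sent, 1)
    for (s in seq_len(m)) {
      n <- sample(2:max_len, 1)
      heads <- vapply(seq_len(n), function(i) {
        if (i == n) 0L else sample(c(0L, (i + 1):n), 1)
      }, 0L)
      lem <- sample(vocab, n, replace = TRUE)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        doc_id = sprintf("rd%03d", k), label = labels[1],
        source = NA_character_, sentence_index = s, token_index = seq_len(n),
        surface = toupper(lem), lemma = lem,
        pos = sample(c("NOUN", "VERB"), n, replace = TRUE),
        head_index = heads)
    }
  }
  fall_corpus(dplyr::bind_rows(rows))
}

# random syntactically valid rule over a vocabulary
random_rule <- function(vocab) {
  shape <- sample(c("pair", "prec", "pair_prec", "prec_pair"), 1)
  t <- sample(vocab, 3)
  switch(shape,
         pair = paste0(t[1], "+", t[2]),
         prec = paste(t[1], "->", t[2]),
         pair_prec = paste(paste0(t[1], "+", t[2]), "->", t[3]),
         prec_pair = paste(t[1], "->", paste0(t[2], "+", t[3])))
}
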