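#' Round half-up at a fixed number of decimals
#'
#' Base `round()` rounds half-to-even; published clinical tables round half
#' away from zero, so exact reproduction of printed figures needs an
#' explicit half-up rule.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' Cross-classify predicted flags against gold labels
#'
#' @param predicted A data frame with columns `doc_id` and `flag` (logical),
#'   e.g. the output of [classify()].
#' @param gold A data frame with columns `doc_id` and `label`
#'   (`"positive"`/`"negative"`, fully labeled), or a `fall_corpus` whose
#'   document table carries labels.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`;
#'   `tp+fp+fn+tn` equals the number of documents.
#' @export
build_contingency <- function(predicted, gold) {
  if (inherits(gold, "fall_corpus")) gold <- corpus_docs(gold)
  predicted <- tibble::as_tibble(predicted)
  gold <- tibble::as_tibble(gold)
  for (nm in c("doc_id", "flag")) {
    if (!nm %in% names(predicted)) {
      stop("`predicted` lacks column ", nm, call. = FALSE)
    }
  }
  for (nm in c("doc_id", "label")) {
    if (!nm %in% names(gold)) stop("`gold` lacks column ", nm, call. = FALSE)
  }
  if (!setequal(predicted$doc_id, gold$doc_id) ||
      anyDuplicated(predicted$doc_id) || anyDuplicated(gold$doc_id)) {
    stop("predicted and gold document identity sets differ", call. = FALSE)
  }
  if (any(!gold$label %in% c("positive", "negative"))) {
    stop("gold labels must all be 'positive' or 'negative'", call. = FALSE)
  }
  joined <- dplyr::inner_join(predicted[, c("doc_id", "flag")],
                              gold[, c("doc_id", "label")], by = "doc_id")
  tibble::tibble(
    tp = sum(joined$flag & joined$label == "positive"),
    fp = sum(joined$flag & joined$label == "negative"),
    fn = sum(!joined$flag & joined$label == "positive"),
    tn = sum(!joined$flag & joined$label == "negative"))
}

#' Detection metrics from a contingency table
#'
#' Computes sensitivity (recall) `tp/(tp+fn)`, positive predictive value
#' (precision) `tp/(tp+fp)`, specificity `tn/(tn+fp)` and the F-measure
#' (harmonic mean of PPV and sensitivity). A metric with a zero denominator
#' is undefined and reported as `NA`, never silently coerced to 0 or 1.
#'
#' Reported values follow the rounding convention of published adverse-event
#' tables: proportions are first expressed at per-mille precision (the
#' "86.5%" style of running text), then rounded half-up to `decimals`
#' places. With the default `decimals = 2` this reproduces printed
#' two-decimal figures exactly, including the boundary case
#' 224/259 = 0.8649 -> 86.5% -> 0.87.
#'
#' @param table A data frame with columns `tp`, `fp`, `fn`, `tn`
#'   (vectorized over rows; extra columns such as `source` are kept).
#' @param decimals Decimal places of the reported metrics.
#' @return `table` with columns `sensitivity`, `ppv`, `specificity`,
#'   `f_measure` appended.
#' @examples
#' compute_metrics(tibble::tibble(tp = 224, fp = 52, fn = 35, tn = 2184))
#' @export
compute_metrics <- function(table, decimals = 2) {
  table <- tibble::as_tibble(table)
  for (nm in c("tp", "fp", "fn", "tn")) {
    if (!nm %in% names(table)) stop("`table` lacks column ", nm, call. = FALSE)
    if (any(table[[nm]] < 0)) stop("counts must be non-negative", call. = FALSE)
  }
  report <- function(x) {
    if (decimals < 3) x <- round_half_up(x, 3)
    round_half_up(x, decimals)
  }
  ratio <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  sens <- ratio(table$tp, table$tp + table$fn)
  ppv <- ratio(table$tp, table$tp + table$fp)
  spec <- ratio(table$tn, table$tn + table$fp)
  f <- ifelse(!is.na(sens) & !is.na(ppv) & (sens + ppv) > 0,
              2 * ppv * sens / (ppv + sens), NA_real_)
  table$sensitivity <- report(sens)
  table$ppv <- report(ppv)
  table$specificity <- report(spec)
  table$f_measure <- report(f)
  table
}

#' Data-containing rate of a document source
#'
#' The percentage of true events (per the chart-review gold standard) that
#' were recorded at all in a given document source, e.g. 52 of 80 fall
#' events in incident reports = 65.0%.
#'
#' @param n_recorded Number of true events recorded in the source.
#' @param n_true Total number of true events; must satisfy
#'   `0 <= n_recorded <= n_true`.
#' @return Percentage, rounded half-up to one decimal; `NA` when
#'   `n_true == 0`.
#' @examples
#' data_containing_rate(52, 80)
#' @export
data_containing_rate <- function(n_recorded, n_true) {
  if (any(n_recorded < 0 | (n_true > 0 & n_recorded > n_true))) {
    stop("need 0 <= n_recorded <= n_true", call. = FALSE)
  }
  ifelse(n_true > 0, round_half_up(100 * n_recorded / n_true, 1), NA_real_)
}

#' Fall rate per 1,000 patient-days
#'
#' @param n_falls Number of fall events.
#' @param patient_days Patient-days over the same period; must be positive.
#' @return Falls per 1,000 patient-days, rounded half-up to two decimals;
#'   `NA` when `patient_days == 0`.
#' @examples
#' fall_rate(80, 22401)
#' @export
fall_rate <- function(n_falls, patient_days) {
  if (any(n_falls < 0 | patient_days < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  ifelse(patient_days > 0, round_half_up(1000 * n_falls / patient_days, 2),
         NA_real_)
}
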