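#' Fall-event streams
#'
#' A fall-event stream is a tibble with one row per adverse event:
#' `event_id`, `occurrence_time` (POSIXct, UTC), `severity` (ordered
#' factor `none < mild < moderate < severe`, the WHO patient-safety injury
#' grading), and per document source a pair of columns
#' `recorded_<source>` (logical: was the event documented there) and
#' `submitted_<source>` (POSIXct submission time to the hospital
#' information system, `NA` where not recorded). Submission never precedes
#' occurrence.
#'
#' @param events A data frame with the columns above.
#' @return A validated event tibble.
#' @export
fall_events <- function(events) {
  events <- tibble::as_tibble(events)
  for (nm in c("event_id", "occurrence_time", "severity")) {
    if (!nm %in% names(events)) {
      stop("event stream lacks column ", nm, call. = FALSE)
    }
  }
  events$severity <- factor(as.character(events$severity),
                            levels = severity_levels(), ordered = TRUE)
  if (anyNA(events$severity)) {
    stop("severity values must be one of: ",
         paste(severity_levels(), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(events$event_id) > 0) {
    stop("duplicate event_id in event stream", call. = FALSE)
  }
  for (src in event_sources(events)) {
    rec <- events[[paste0("recorded_", src)]]
    sub <- events[[paste0("submitted_", src)]]
    if (is.null(sub)) {
      stop("source '", src, "' has recorded_ but no submitted_ column",
           call. = FALSE)
    }
    if (any(rec & is.na(sub))) {
      stop("source '", src, "': recorded events must carry a submission time",
           call. = FALSE)
    }
    if (any(!rec & !is.na(sub))) {
      stop("source '", src, "': submission time present for unrecorded event",
           call. = FALSE)
    }
    if (any(rec & sub < events$occurrence_time, na.rm = TRUE)) {
      stop("source '", src, "': submission precedes event occurrence",
           call. = FALSE)
    }
  }
  events
}

severity_levels <- function() c("none", "mild", "moderate", "severe")

#' Source names present in an event stream
#' @param events An event tibble.
#' @return Character vector of source names (from `recorded_*` columns).
#' @export
event_sources <- function(events) {
  sub("^recorded_", "", grep("^recorded_", names(events), value = TRUE))
}

#' Submission lag in minutes
#'
#' Minutes between event occurrence and submission of the documenting
#' record to the hospital information system, for one source.
#'
#' @param events An event tibble; every row must be recorded in `source`
#'   (filter first, e.g. `dplyr::filter(events, recorded_incident_report)`).
#' @param source Source name, e.g. `"incident_report"`.
#' @return A tibble with columns `event_id` and `lag_minutes`.
#' @export
lag_minutes <- function(events, source) {
  rec_col <- paste0("recorded_", source)
  sub_col <- paste0("submitted_", source)
  if (!rec_col %in% names(events)) {
    stop("unknown source '", source, "'", call. = FALSE)
  }
  if (any(!events[[rec_col]])) {
    bad <- events$event_id[!events[[rec_col]]]
    stop("event(s) not recorded in source '", source, "': ",
         paste(utils::head(bad, 3), collapse = ", "),
         if (length(bad) > 3) ", ..." else "", call. = FALSE)
  }
  tibble::tibble(
    event_id = events$event_id,
    lag_minutes = as.numeric(difftime(events[[sub_col]],
                                      events$occurrence_time,
                                      units = "mins")))
}

#' Median and quartiles of submission lags
#'
#' Quantiles use linear interpolation between order statistics
#' (`stats::quantile()` type 7), the convention under which lag
#' distributions are reported as median (25th, 75th percentile).
#'
#' @param lags Numeric vector of lag minutes (non-empty).
#' @return A one-row tibble with columns `n`, `q25`, `median`, `q75`.
#' @examples
#' summarize_lags(c(10, 20, 30))
#' @export
summarize_lags <- function(lags) {
  if (is.data.frame(lags)) lags <- lags$lag_minutes
  if (length(lags) == 0 || anyNA(lags)) {
    stop("lags must be a non-empty numeric vector without NA", call. = FALSE)
  }
  q <- stats::quantile(lags, probs = c(0.25, 0.5, 0.75), type = 7,
                       names = FALSE)
  tibble::tibble(n = length(lags), q25 = q[1], median = q[2], q75 = q[3])
}

#' Wilcoxon rank-sum comparison of two lag samples
#'
#' Two-sided Wilcoxon (Mann-Whitney) rank-sum test. With combined sample
#' size at most 20 and no ties the exact null distribution of the rank sum
#' is used; otherwise the normal approximation with tie-corrected variance
#' and 0.5 continuity correction.
#'
#' @param x,y Non-empty numeric vectors of lag minutes.
#' @return A one-row tibble with columns `n_x`, `n_y`, `statistic`
#'   (Mann-Whitney U of `x`), `p_value` and `method` (`"exact"` or
#'   `"normal_approx"`).
#' @examples
#' compare_lags(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_lags <- function(x, y) {
  if (is.data.frame(x)) x <- x$lag_minutes
  if (is.data.frame(y)) y <- y$lag_minutes
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 20) && !has_ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  tibble::tibble(n_x = length(x), n_y = length(y),
                 statistic = unname(ht$statistic),
                 p_value = min(1, ht$p.value),
                 method = if (exact) "exact" else "normal_approx")
}

#' Compare injury-severity distributions between two detection methods
#'
#' Tests the 2xK table of severity counts with the chi-square test (no
#' continuity correction); for 2x2 tables with any expected cell below 5
#' the Fisher exact test is substituted. Categories may first be collapsed
#' into contiguous groups of the severity ordering
#' `none < mild < moderate < severe` (e.g. mild vs moderate+severe).
#'
#' @param counts_a,counts_b Named numeric vectors of event counts per
#'   severity category (names from the severity levels).
#' @param collapse Optional named list of character vectors defining
#'   contiguous category groups, e.g.
#'   `list(mild = "mild", worse = c("moderate", "severe"))`.
#' @return A one-row tibble with columns `method`, `statistic`, `df`,
#'   `p_value`.
#' @examples
#' compare_severity(c(mild = 480, moderate = 6, severe = 7),
#'                  c(mild = 44, moderate = 5, severe = 8),
#'                  collapse = list(mild = "mild",
#'                                  worse = c("moderate", "severe")))
#' @export
compare_severity <- function(counts_a, counts_b, collapse = NULL) {
  lev <- severity_levels()
  check <- function(counts, who) {
    if (is.null(names(counts)) || any(!names(counts) %in% lev)) {
      stop(who, " must be named with severity categories (",
           paste(lev, collapse = ", "), ")", call. = FALSE)
    }
    counts
  }
  counts_a <- check(counts_a, "counts_a")
  counts_b <- check(counts_b, "counts_b")
  cats <- intersect(lev, union(names(counts_a), names(counts_b)))
  full_a <- stats::setNames(rep(0, length(cats)), cats)
  full_b <- full_a
  full_a[names(counts_a)] <- counts_a
  full_b[names(counts_b)] <- counts_b
  if (!is.null(collapse)) {
    used <- unlist(collapse, use.names = FALSE)
    if (anyDuplicated(used) > 0 || any(!cats %in% used)) {
      stop("collapse groups must partition the observed categories",
           call. = FALSE)
    }
    for (grp in collapse) {
      pos <- sort(match(grp, lev))
      if (anyNA(pos) || (length(pos) > 1 && any(diff(pos) != 1))) {
        stop("collapse groups must be contiguous in the severity ordering",
             call. = FALSE)
      }
    }
    full_a <- vapply(collapse, function(g) sum(full_a[g], na.rm = TRUE), 0)
    full_b <- vapply(collapse, function(g) sum(full_b[g], na.rm = TRUE), 0)
  }
  keep <- (full_a + full_b) > 0
  full_a <- full_a[keep]; full_b <- full_b[keep]
  if (length(full_a) < 2) {
    stop("need at least two non-empty severity categories after collapsing",
         call. = FALSE)
  }
  tab <- rbind(a = full_a, b = full_b)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("severity table has a zero margin", call. = FALSE)
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (ncol(tab) == 2 && any(expected < 5)) {
    ht <- stats::fisher.test(tab)
    return(tibble::tibble(method = "fisher_exact", statistic = NA_real_,
                          df = NA_real_, p_value = ht$p.value))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(method = "chi_square", statistic = unname(ht$statistic),
                 df = unname(ht$parameter), p_value = ht$p.value)
}

#' Overlap of two detection sources
#'
#' Partitions events recorded in at least one of two sources into those
#' found only by the first, only by the second, and by both.
#'
#' @param events An event tibble.
#' @param source_a,source_b Source names.
#' @return A one-row tibble with columns `only_a`, `only_b`, `both`,
#'   `total_a` (`only_a + both`), `total_b` (`only_b + both`).
#' @export
source_overlap <- function(events, source_a, source_b) {
  for (src in c(source_a, source_b)) {
    if (!paste0("recorded_", src) %in% names(events)) {
      stop("unknown source '", src, "'", call. = FALSE)
    }
  }
  in_a <- events[[paste0("recorded_", source_a)]]
  in_b <- events[[paste0("recorded_", source_b)]]
  only_a <- sum(in_a & !in_b)
  only_b <- sum(!in_a & in_b)
  both <- sum(in_a & in_b)
  tibble::tibble(only_a = only_a, only_b = only_b, both = both,
                 total_a = only_a + both, total_b = only_b + both)
}

#' Detection gain from adding a second source
#'
#' The percentage increase in detected events when source B is added to
#' source A: `100 * only_b / (only_a + both)`.
#'
#' @param only_a Events found only by source A, or a data frame with
#'   columns `only_a`, `only_b`, `both` (e.g. from [source_overlap()]).
#' @param only_b,both Counts (ignored when `only_a` is a data frame).
#' @return Percentage gain, rounded half-up to one decimal; `NA` when
#'   source A detected nothing.
#' @examples
#' detection_gain(451, 15, 42)
#' @export
detection_gain <- function(only_a, only_b = NULL, both = NULL) {
  if (is.data.frame(only_a)) {
    df <- only_a
    only_a <- df$only_a; only_b <- df$only_b; both <- df$both
  }
  denom <- only_a + both
  ifelse(denom > 0, round_half_up(100 * only_b / denom, 1), NA_real_)
}

#' Read a fall-event stream from TSV
#'
#' Columns: `event_id`, `occurrence_time`, `severity`, then per source
#' `recorded_<source>` (0/1) and `submitted_<source>` (ISO 8601 timestamp
#' or empty). Leading `#` comment lines are ignored. Timestamps are UTC.
#'
#' @param path Path to an events file.
#' @return A validated event tibble.
#' @export
read_event_stream <- function(path) {
  if (!file.exists(path)) stop("no such events file: ", path, call. = FALSE)
  raw <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    stop("empty events file: ", path, call. = FALSE)
  }
  parse_time <- function(x) {
    out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%S")
    bad <- nzchar(x) & is.na(out)
    out[bad] <- as.POSIXct(x[bad], tz = "UTC")
    out
  }
  out <- tibble::tibble(event_id = raw$event_id,
                        occurrence_time = parse_time(raw$occurrence_time),
                        severity = raw$severity)
  for (src in sub("^recorded_", "", grep("^recorded_", names(raw),
                                         value = TRUE))) {
    out[[paste0("recorded_", src)]] <-
      as.integer(raw[[paste0("recorded_", src)]]) == 1L
    out[[paste0("submitted_", src)]] <-
      parse_time(raw[[paste0("submitted_", src)]])
  }
  fall_events(out)
}

#' Write a fall-event stream to TSV
#'
#' Inverse of [read_event_stream()]; timestamps are written as ISO 8601
#' UTC with whole-second precision.
#'
#' @param events An event tibble.
#' @param path Output path.
#' @param header Optional character vector of leading `#` comment lines.
#' @return `path`, invisibly.
#' @export
write_event_stream <- function(events, path, header = NULL) {
  events <- fall_events(events)
  fmt_time <- function(x) {
    ifelse(is.na(x), "", format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC"))
  }
  out <- data.frame(event_id = events$event_id,
                    occurrence_time = fmt_time(events$occurrence_time),
                    severity = as.character(events$severity),
                    check.names = FALSE, stringsAsFactors = FALSE)
  for (src in event_sources(events)) {
    out[[paste0("recorded_", src)]] <-
      as.integer(events[[paste0("recorded_", src)]])
    out[[paste0("submitted_", src)]] <-
      fmt_time(events[[paste0("submitted_", src)]])
  }
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  if (!is.null(header)) writeLines(header, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
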