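# Post-simulation analytics: score distribution summaries, quartile
# categories, baseline-vs-deliberate patient flow, static matchability
# profiles and hard-to-match detection.

# Resolve "A"/"B"/.../"DQB1" or "sum5" to a Match-List column name.
.score_column <- function(locus_or_sum) {
  if (identical(locus_or_sum, "sum5")) return("sum5")
  loc <- match.arg(locus_or_sum, .LOCI)
  paste0("score_", loc)
}

#' Summary of a match score distribution
#'
#' Median (lower-middle convention for even counts, so integer scores stay
#' integer), range, and the zero-score fraction — the quantities the score
#' distribution figures report.
#'
#' @param matches Non-empty Match-List data frame.
#' @param locus_or_sum One of `"A"`, `"B"`, `"C"`, `"DRB1"`, `"DQB1"`, or
#'   `"sum5"`.
#' @return List with `median`, `min`, `max`, `zero_probability`, `n`.
#' @export
summarize_scores <- function(matches, locus_or_sum = "sum5") {
  x <- matches[[.score_column(locus_or_sum)]]
  if (is.null(x) || !length(x)) stop("empty match list")
  list(median = median_low(x), min = min(x), max = max(x),
       zero_probability = mean(x == 0), n = length(x))
}

#' Quartile score categories from a baseline score distribution
#'
#' Splits scores at the empirical 25/50/75 percentiles (type-1, i.e. order
#' statistics) into four categories Q1-Q4 using closed-right intervals:
#' Q1 = [0, q25], Q2 = (q25, q50], Q3 = (q50, q75], Q4 = (q75, Inf). With
#' integer scores this reproduces printed conventions such as
#' "Q1 = 0-7, Q2 = 8-13, Q3 = 14-20, Q4 = >= 21". Degenerate distributions
#' collapse duplicate edges with a warning.
#'
#' @param scores Numeric vector of baseline match scores (>= 4 values).
#' @return Object of class `score_quartiles`: data frame `label`, `lower`,
#'   `upper` (inclusive integer bounds for display) with attribute `edges`
#'   (the percentile cutpoints used by [assign_quartile()]).
#' @export
quartile_categories <- function(scores) {
  if (length(scores) < 4L) stop("need at least 4 scores")
  if (any(scores < 0)) stop("scores must be non-negative")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), type = 1, names = FALSE)
  edges <- unique(q[q < max(scores)])  # a trailing empty category is dropped
  if (length(edges) < 3L) {
    warning("degenerate score distribution: quartile edges collapse (",
            length(edges) + 1L, " categories kept)")
  }
  labels <- paste0("Q", seq_len(length(edges) + 1L))
  out <- data.frame(
    label = labels,
    lower = c(0, edges + 1),
    upper = c(edges, Inf),
    stringsAsFactors = FALSE
  )
  structure(out, class = c("score_quartiles", "data.frame"), edges = edges)
}

#' Assign scores to quartile categories
#'
#' @param x Numeric scores.
#' @param categories A `score_quartiles` from [quartile_categories()].
#' @return Factor with the category labels.
#' @export
assign_quartile <- function(x, categories) {
  edges <- attr(categories, "edges")
  cut(x, breaks = c(-Inf, edges, Inf), labels = categories$label,
      right = TRUE)
}

#' Patient-flow table between baseline and deliberate allocation
#'
#' Tracks every candidate who entered either simulation of a paired run
#' (identical streams). Each patient gets a baseline category — the
#' quartile of their baseline match score, or `Waiting` if they were still
#' on the list — and a deliberate category using the *same* baseline
#' quartile edges, and the flows are tabulated.
#'
#' @param paired A `paired_result` from [run_base_and_deliberate_paired()],
#'   with the base-case run first.
#' @param locus_or_sum Score column to categorise (default `"sum5"`).
#' @param categories Optional pre-computed `score_quartiles`; default
#'   derives them from the baseline matches.
#' @return Object of class `flow_table`: `counts` (baseline x deliberate
#'   matrix including `Waiting`), `categories`, `n` tracked patients. Row
#'   and column totals each sum to `n`.
#' @export
patient_flow <- function(paired, locus_or_sum = "sum5", categories = NULL) {
  stopifnot(inherits(paired, "paired_result"))
  res <- paired$results
  if (length(res) != 2L) stop("paired result must hold exactly two runs")
  b <- res[[1L]]; d <- res[[2L]]
  if (!identical(b$config$stream_id, d$config$stream_id)) {
    stop("runs were not produced from identical streams")
  }
  col <- .score_column(locus_or_sum)
  ids_b <- c(b$matches$recipient_id, b$final_waitlist$id)
  ids_d <- c(d$matches$recipient_id, d$final_waitlist$id)
  tracked <- sort(union(ids_b, ids_d))
  if (!setequal(ids_b, ids_d)) {
    stop("runs track different candidate sets; streams mismatch")
  }
  categories <- categories %||% quartile_categories(b$matches[[col]])
  levs <- c(categories$label, "Waiting")

  cat_of <- function(run) {
    m <- match(tracked, run$matches$recipient_id)
    lab <- rep("Waiting", length(tracked))
    hit <- !is.na(m)
    lab[hit] <- as.character(assign_quartile(run$matches[[col]][m[hit]],
                                             categories))
    factor(lab, levels = levs)
  }
  counts <- table(baseline = cat_of(b), deliberate = cat_of(d))
  structure(list(counts = counts, categories = categories,
                 n = length(tracked)),
            class = "flow_table")
}

#' @export
print.flow_table <- function(x, ...) {
  cat(sprintf("patient flow over %d tracked patients:\n", x$n))
  print(x$counts)
  invisible(x)
}

#' Flow table in long form
#'
#' @param flow A `flow_table`.
#' @return Data frame `baseline_cat`, `deliberate_cat`, `count`.
#' @export
flow_to_long <- function(flow) {
  df <- as.data.frame(flow$counts, stringsAsFactors = FALSE)
  names(df) <- c("baseline_cat", "deliberate_cat", "count")
  df
}

#' Static per-patient score profile against all ABO-identical donors
#'
#' Scores every patient against every ABO-identical donor irrespective of
#' any allocation, summarising each patient's attainable score
#' distribution. Patients with no ABO-identical donor are flagged
#' unscorable.
#'
#' @param patients,donors Person tables (rows with `abo` and genotype
#'   information understood by the scorer).
#' @param scorer Scorer object.
#' @param locus_or_sum Score column (default `"sum5"`).
#' @return Object of class `score_profile`: data frame `id`, `abo`,
#'   `n_donors`, `median`, `q25`, `q75`, `unscorable`, with the full
#'   patient x donor score matrix as attribute `scores` (NA where ABO
#'   differs).
#' @export
static_score_profile <- function(patients, donors, scorer,
                                 locus_or_sum = "sum5") {
  col <- .score_column(locus_or_sum)
  np <- nrow(patients); ndn <- nrow(donors)
  vals <- matrix(NA_real_, np, ndn,
                 dimnames = list(patients$id, donors$id))
  for (j in seq_len(ndn)) {
    sv <- score_waitlist(scorer, donors[j, , drop = FALSE], patients)
    v <- sv[[col]]
    v[patients$abo != donors$abo[j]] <- NA
    vals[, j] <- v
  }
  stats_of <- function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(NA_real_, NA_real_, NA_real_, 0))
    c(median_low(v),
      stats::quantile(v, 0.25, type = 1, names = FALSE),
      stats::quantile(v, 0.75, type = 1, names = FALSE),
      length(v))
  }
  st <- t(apply(vals, 1L, stats_of))
  out <- data.frame(id = patients$id, abo = patients$abo,
                    n_donors = as.integer(st[, 4L]),
                    median = st[, 1L], q25 = st[, 2L], q75 = st[, 3L],
                    unscorable = st[, 4L] == 0,
                    stringsAsFactors = FALSE)
  structure(out, class = c("score_profile", "data.frame"), scores = vals)
}

#' Flag hard-to-match patients from a static score profile
#'
#' Orders scorable patients by ascending median score, smooths the median
#' curve with a centred moving average (window truncated at the edges),
#' takes first differences of the smoothed series, and flags patients whose
#' difference exceeds `rel_threshold` times the maximum median — the steep
#' right tail of the ordered median curve. The threshold is relative, so
#' rescaling all scores leaves the flagged set unchanged.
#'
#' @param profiles A `score_profile` from [static_score_profile()].
#' @param window_halfwidth Half-width of the smoothing window (default 5,
#'   i.e. +-5 patients).
#' @param rel_threshold Flagging threshold as a fraction of the maximum
#'   median score (default 0.002, i.e. 0.2%).
#' @return Object of class `hard_to_match_report`: data frame `id`,
#'   `median`, `smoothed`, `diff`, `flagged` (in ascending median order)
#'   with attributes `threshold` (absolute), `rel_threshold`,
#'   `window_halfwidth`, `n_unscorable`.
#' @export
flag_hard_to_match <- function(profiles, window_halfwidth = 5,
                               rel_threshold = 0.002) {
  assert_scalar_count(window_halfwidth, "window_halfwidth", min = 1)
  if (rel_threshold <= 0) stop("`rel_threshold` must be positive")
  df <- profiles[!profiles$unscorable, , drop = FALSE]
  n <- nrow(df)
  if (n < 2L) stop("need at least 2 scorable patients")
  if (n < 2L * window_halfwidth + 1L) {
    warning("fewer patients than the smoothing window; window truncated")
  }
  ord <- order(df$median, df$id)
  df <- df[ord, , drop = FALSE]
  smoothed <- smooth_truncated(df$median, window_halfwidth)
  diffs <- c(0, diff(smoothed))
  thr <- rel_threshold * max(df$median)
  out <- data.frame(id = df$id, median = df$median, smoothed = smoothed,
                    diff = diffs, flagged = diffs > thr,
                    stringsAsFactors = FALSE)
  structure(out, class = c("hard_to_match_report", "data.frame"),
            threshold = thr, rel_threshold = rel_threshold,
            window_halfwidth = window_halfwidth,
            n_unscorable = sum(profiles$unscorable))
}
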