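# Scenario grid execution and replicate-level aggregation.

#' Scenario grid configuration
#'
#' The default grid spans the waitlist sizes named in the study design
#' (provincial 100-800, the 290 benchmark, the ~2,000 national list, the
#' 2,286 national replicate and the 2,500 ceiling) crossed with
#' candidate-to-donor ratios from 2 to 4 (2.6 being the national value).
#'
#' @param waitlist_sizes Integer vector of waitlist sizes (all >= 2).
#' @param ratios Numeric vector of candidate-to-donor ratios in [1, Inf).
#' @param strategies List of [strategy()] objects.
#' @param replicates Replicates per cell (>= 1; default 10).
#' @param master_seed Integer master seed; per-cell stream seeds are
#'   derived from it deterministically (see [run_grid()]).
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(waitlist_sizes = c(100, 200, 290, 400, 800,
                                               1600, 2000, 2286, 2500),
                            ratios = c(2, 2.6, 3, 4),
                            strategies = list(strategy("base_case"),
                                              strategy("deliberate")),
                            replicates = 10, master_seed = 1) {
  if (!length(waitlist_sizes) || any(waitlist_sizes < 2) ||
      any(waitlist_sizes != floor(waitlist_sizes))) {
    stop("`waitlist_sizes` must be integers >= 2")
  }
  if (!length(ratios) || any(ratios < 1)) stop("`ratios` must be >= 1")
  assert_scalar_count(replicates, "replicates", min = 1)
  if (!length(strategies) ||
      !all(vapply(strategies, inherits, logical(1), "strategy"))) {
    stop("`strategies` must be a list of strategy objects")
  }
  structure(list(waitlist_sizes = as.integer(waitlist_sizes),
                 ratios = as.numeric(ratios), strategies = strategies,
                 replicates = as.integer(replicates),
                 master_seed = as.integer(master_seed)),
            class = "scenario_config")
}

# Stream seed for one grid cell. Strategy is deliberately excluded so that
# strategies are paired on identical streams within a (W, ratio, replicate)
# cell; cells differing in W, ratio or replicate never share streams, and
# adding grid cells never perturbs existing ones.
cell_stream_seed <- function(master_seed, W, ratio, replicate) {
  seed_from_key(sprintf("stream|%d|%d|%.10g|%d",
                        master_seed, W, ratio, replicate))
}

#' Run the full scenario grid
#'
#' One simulation per (waitlist size, ratio, strategy, replicate). Stream
#' seeds are derived per (W, ratio, replicate) from the master seed via a
#' string hash, so different strategies in a cell run on identical streams
#' while disjoint cells share none.
#'
#' @param config A [scenario_config()].
#' @param pool A `haplotype_pool`.
#' @param scorer Scorer object.
#' @param abo_freqs ABO probabilities.
#' @param progress Print one line per cell.
#' @return Object of class `grid_results`: `results` (named list of
#'   `sim_result`), `index` (data frame with `W`, `ratio`, `strategy`,
#'   `replicate`, `stream_seed`, `key`), and the `config`.
#' @export
run_grid <- function(config, pool, scorer, abo_freqs = default_abo_freqs(),
                     progress = FALSE) {
  stopifnot(inherits(config, "scenario_config"))
  results <- list()
  idx <- list()
  for (W in config$waitlist_sizes) {
    for (r in config$ratios) {
      for (rep_i in seq_len(config$replicates)) {
        sseed <- cell_stream_seed(config$master_seed, W, r, rep_i)
        streams <- generate_streams(pool, abo_freqs, W, r, seed = sseed)
        for (s in config$strategies) {
          lab <- strategy_label(s)
          key <- sprintf("W%d_r%g_%s_rep%d", W, r, lab, rep_i)
          if (progress) message("running ", key)
          results[[key]] <- run_replicate(streams, s, scorer)
          idx[[key]] <- data.frame(W = W, ratio = r, strategy = lab,
                                   replicate = rep_i, stream_seed = sseed,
                                   key = key, stringsAsFactors = FALSE)
        }
      }
    }
  }
  structure(list(results = results,
                 index = do.call(rbind, c(idx, make.row.names = FALSE)),
                 config = config),
            class = "grid_results")
}

#' Cumulative probability of a match score below a threshold
#'
#' @param matches Match-List data frame (non-empty).
#' @param threshold Score threshold.
#' @param mode `"strict_less"` (score < threshold) or `"less_equal"`.
#' @param column Score column to threshold (default the strategy objective).
#' @return Fraction in [0, 1].
#' @examples
#' m <- data.frame(objective_score = c(3, 9, 40))
#' cumulative_probability(m, 9, "strict_less")  # 1/3
#' @export
cumulative_probability <- function(matches, threshold,
                                   mode = c("strict_less", "less_equal"),
                                   column = "objective_score") {
  mode <- match.arg(mode)
  x <- matches[[column]]
  if (is.null(x) || !length(x)) {
    stop("cumulative probability is undefined for an empty match list")
  }
  if (mode == "strict_less") mean(x < threshold) else mean(x <= threshold)
}

#' Aggregate replicate-level curves over the grid
#'
#' For every (strategy, ratio, waitlist size) cell, computes the
#' per-replicate cumulative probabilities at the requested thresholds
#' and/or the four stratum frequencies, then the mean and standard
#' deviation across replicates (the published error-bar convention).
#'
#' @param grid A `grid_results` from [run_grid()].
#' @param thresholds Numeric thresholds (optional).
#' @param strata Also tabulate the four risk-stratum frequencies of `sum5`.
#' @param mode Threshold comparison mode (see [cumulative_probability()]).
#' @param column Score column for thresholds.
#' @return Data frame: `strategy`, `ratio`, `W`, `metric`, `mean`, `sd`,
#'   `n_replicates`. Stratum frequencies at one cell sum to 1.
#' @export
aggregate_curves <- function(grid, thresholds = NULL, strata = FALSE,
                             mode = "strict_less",
                             column = "objective_score") {
  stopifnot(inherits(grid, "grid_results"))
  if (is.null(thresholds) && !strata) {
    stop("request at least one of `thresholds` or `strata`")
  }
  ix <- grid$index
  cells <- unique(ix[c("strategy", "ratio", "W")])
  out <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- ix$strategy == cells$strategy[i] & ix$ratio == cells$ratio[i] &
      ix$W == cells$W[i]
    keys <- ix$key[sel]
    if (!length(keys)) next
    reps <- lapply(keys, function(k) grid$results[[k]]$matches)
    vals <- list()
    for (th in thresholds) {
      p <- vapply(reps, cumulative_probability, numeric(1),
                  threshold = th, mode = mode, column = column)
      vals[[paste0(if (mode == "strict_less") "<" else "<=", th)]] <- p
    }
    if (strata) {
      labs <- levels(classify_stratum(0))
      freq <- vapply(reps, function(m) {
        as.numeric(table(m$stratum) / nrow(m))
      }, numeric(length(labs)))
      freq <- matrix(freq, nrow = length(labs), dimnames = list(labs, NULL))
      for (lab in labs) vals[[paste0("stratum_", lab)]] <- freq[lab, ]
    }
    for (metric in names(vals)) {
      out[[length(out) + 1L]] <- data.frame(
        strategy = cells$strategy[i], ratio = cells$ratio[i], W = cells$W[i],
        metric = metric, mean = mean(vals[[metric]]), sd = sd0(vals[[metric]]),
        n_replicates = length(keys), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Saturation (plateau onset) of a probability curve
#'
#' Operationalises the curve "inflection point" as the smallest x from
#' which every subsequent step of the mean curve changes by less than
#' `tolerance` times the curve's range. A curve that never settles returns
#' the largest x flagged `saturated = FALSE`; a constant curve saturates at
#' its first point.
#'
#' @param curve Data frame with columns `x` (or `W`) and `mean`, >= 3 rows.
#' @param tolerance Fraction of the curve range (default 0.01).
#' @return List with `x`, `index`, `saturated`.
#' @export
saturation_point <- function(curve, tolerance = 0.01) {
  xcol <- if (!is.null(curve$x)) "x" else "W"
  if (is.null(curve[[xcol]]) || is.null(curve$mean)) {
    stop("`curve` needs columns x (or W) and mean")
  }
  curve <- curve[order(curve[[xcol]]), , drop = FALSE]
  n <- nrow(curve)
  if (n < 3L) stop("need at least 3 curve points")
  y <- curve$mean
  rng <- diff(range(y))
  if (rng == 0) {
    return(list(x = curve[[xcol]][1L], index = 1L, saturated = TRUE))
  }
  steps <- abs(diff(y))
  for (i in seq_len(n - 1L)) {
    if (all(steps[i:(n - 1L)] < tolerance * rng)) {
      return(list(x = curve[[xcol]][i], index = i, saturated = TRUE))
    }
  }
  list(x = curve[[xcol]][n], index = n, saturated = FALSE)
}
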