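# Greedy allocation engine: one replicate of ABO-identical kidney
# allocation over a constant-size waitlist.

#' Define an allocation strategy
#'
#' `base_case` ranks eligible candidates by waiting time only (arrival
#' index), approximating current queue-based practice; scores are computed
#' for the match record but never used for ranking. `deliberate` gives each
#' kidney to the eligible candidate with the lowest mismatch score summed
#' over `loci`, waiting time breaking ties.
#'
#' @param mode `"base_case"` or `"deliberate"`.
#' @param loci Objective loci, a subset of [hla_loci()]; default all five
#'   (the "5LOCI" / PIRCHE-sum objective). For `base_case` the loci only
#'   define the reported `objective_score`.
#' @return An object of class `strategy`.
#' @export
strategy <- function(mode = c("base_case", "deliberate"), loci = hla_loci()) {
  mode <- match.arg(mode)
  loci <- unique(as.character(loci))
  if (!length(loci) || !all(loci %in% .LOCI)) {
    stop("`loci` must be a non-empty subset of ", paste(.LOCI, collapse = ", "))
  }
  loci <- .LOCI[.LOCI %in% loci]
  structure(list(mode = mode, loci = loci), class = "strategy")
}

#' @export
print.strategy <- function(x, ...) {
  cat(sprintf("strategy: %s (%s)\n", x$mode, strategy_label(x)))
  invisible(x)
}

#' Short label for a strategy
#'
#' @param s A `strategy`.
#' @return E.g. `"base_case"`, `"deliberate_5LOCI"`, `"deliberate_DRB1"`.
#' @export
strategy_label <- function(s) {
  tag <- if (length(s$loci) == 5L) "5LOCI" else paste(s$loci, collapse = "+")
  if (s$mode == "base_case") "base_case" else paste0("deliberate_", tag)
}

#' Select the recipient for one kidney offer
#'
#' Eligibility is ABO identity. Under `deliberate`, the eligible candidate
#' with the minimum objective score wins, ties broken by smallest arrival
#' index (longest waiting), then by candidate id for full determinism.
#' Under `base_case`, the longest-waiting eligible candidate wins.
#'
#' @param waitlist Candidate data frame (rows ordered arbitrarily; arrival
#'   indices must be distinct).
#' @param donor Donor person or table row.
#' @param strategy A [strategy()].
#' @param scorer Scorer object (unused for `base_case` ranking).
#' @return The selected candidate row (one-row data frame), or `NULL` if no
#'   ABO-identical candidate exists.
#' @export
select_recipient <- function(waitlist, donor, strategy, scorer = NULL) {
  dabo <- if (is.data.frame(donor)) donor$abo[1] else donor$abo
  elig <- waitlist[waitlist$abo == dabo, , drop = FALSE]
  if (nrow(elig) == 0L) return(NULL)
  if (strategy$mode == "base_case") {
    return(elig[which.min(elig$arrival_index), , drop = FALSE])
  }
  sv <- score_waitlist(scorer, donor, elig)
  obj <- rowSums(sv[, paste0("score_", strategy$loci), drop = FALSE])
  elig[order(obj, elig$arrival_index, elig$id)[1L], , drop = FALSE]
}

#' Run one allocation replicate
#'
#' Processes the donor stream in order. Each donor offers two kidneys
#' sequentially against the shrinking waitlist (so the second-lowest score
#' can win kidney two); every offer is accepted. After both kidneys, two
#' replenishment candidates join the bottom of the waitlist, keeping its
#' size constant — asserted after every donor cycle. A kidney with no
#' ABO-identical candidate is recorded as unallocated and the simulation
#' proceeds; each such kidney leaves one extra candidate on the list, so
#' the asserted size is `W` plus the unallocated-kidney count so far.
#'
#' @param streams A `cohort_streams` object from [generate_streams()] (all
#'   randomness lives there; this function is deterministic).
#' @param strategy A [strategy()].
#' @param scorer Scorer object.
#' @param verbose Emit one log line per donor cycle.
#' @return An object of class `sim_result`: `matches` (the Match-List:
#'   `donor_id`, `recipient_id`, `donor_seq`, `score_A ... score_DQB1`,
#'   `sum5`, `objective_score`, `stratum`, `recipient_arrival_index`),
#'   `final_waitlist`, `unallocated` (donor_id, reason), and a `config`
#'   echo. Matches plus unallocated kidneys always total twice the number
#'   of donors, and no recipient appears twice.
#' @export
run_replicate <- function(streams, strategy, scorer, verbose = FALSE) {
  stopifnot(inherits(streams, "cohort_streams"), inherits(strategy, "strategy"))
  cand <- streams$candidates
  donors <- streams$donors
  W <- streams$waitlist_size
  nd <- nrow(donors)
  if (nrow(cand) < W + 2L * nd) stop("candidate stream exhausted")
  deliberate <- strategy$mode == "deliberate"
  obj_cols <- paste0("score_", strategy$loci)
  score_cols <- paste0("score_", .LOCI)

  wl <- seq_len(W)
  ptr <- W
  nmax <- 2L * nd
  m_donor <- character(nmax); m_recip <- character(nmax)
  m_seq <- integer(nmax); m_arr <- integer(nmax)
  m_scores <- matrix(0L, nmax, 6L,
                     dimnames = list(NULL, c(score_cols, "sum5")))
  m_obj <- integer(nmax)
  n_match <- 0L
  u_donor <- character(0); u_reason <- character(0)

  for (d in seq_len(nd)) {
    drow <- donors[d, , drop = FALSE]
    elig <- wl[cand$abo[wl] == drow$abo]
    sv <- NULL
    obj <- NULL
    if (deliberate && length(elig)) {
      sv <- score_waitlist(scorer, drow, cand[elig, , drop = FALSE])
      obj <- rowSums(sv[, obj_cols, drop = FALSE])
    }
    chosen <- character(0)
    for (kid in 1:2) {
      if (!length(elig)) {
        u_donor <- c(u_donor, drow$id)
        u_reason <- c(u_reason, "no_abo_identical_candidate")
        next
      }
      if (deliberate) {
        pos <- order(obj, cand$arrival_index[elig], cand$id[elig])[1L]
        svec <- unlist(sv[pos, c(score_cols, "sum5")])
      } else {
        pos <- which.min(cand$arrival_index[elig])
        sp <- score_pair(scorer, drow, cand[elig[pos], , drop = FALSE])
        svec <- c(sp[.LOCI], sp[["sum5"]])
      }
      ci <- elig[pos]
      n_match <- n_match + 1L
      m_donor[n_match] <- drow$id
      m_recip[n_match] <- cand$id[ci]
      m_seq[n_match] <- d
      m_arr[n_match] <- cand$arrival_index[ci]
      m_scores[n_match, ] <- as.integer(svec)
      m_obj[n_match] <- sum(as.integer(svec)[match(strategy$loci, .LOCI)])
      chosen <- c(chosen, cand$id[ci])
      wl <- wl[wl != ci]
      elig <- elig[-pos]
      if (deliberate) {
        sv <- sv[-pos, , drop = FALSE]
        obj <- obj[-pos]
      }
    }
    wl <- c(wl, ptr + 1:2)
    ptr <- ptr + 2L
    # Two candidates always enter per donor; the waitlist stays at W except
    # that each unallocatable kidney leaves one extra candidate waiting.
    if (length(wl) != W + length(u_donor)) {
      stop("waitlist size invariant violated")
    }
    if (verbose) {
      message(sprintf("donor %s (%s): eligible=%d, matched=[%s]",
                      drow$id, drow$abo, length(elig) + length(chosen),
                      paste(chosen, collapse = ", ")))
    }
  }

  matches <- data.frame(
    donor_id = m_donor[seq_len(n_match)],
    recipient_id = m_recip[seq_len(n_match)],
    donor_seq = m_seq[seq_len(n_match)],
    stringsAsFactors = FALSE
  )
  matches <- cbind(matches,
                   as.data.frame(m_scores[seq_len(n_match), , drop = FALSE]))
  matches$objective_score <- m_obj[seq_len(n_match)]
  matches$stratum <- classify_stratum(matches$sum5)
  matches$recipient_arrival_index <- m_arr[seq_len(n_match)]

  unallocated <- data.frame(donor_id = u_donor, reason = u_reason,
                            stringsAsFactors = FALSE)
  if (nrow(matches) + nrow(unallocated) != 2L * nd) {
    stop("kidney conservation invariant violated")
  }
  if (anyDuplicated(matches$recipient_id)) {
    stop("a recipient was transplanted twice")
  }

  structure(
    list(matches = matches,
         final_waitlist = cand[wl, , drop = FALSE],
         unallocated = unallocated,
         config = list(strategy = strategy,
                       strategy_label = strategy_label(strategy),
                       waitlist_size = W, ratio = streams$ratio,
                       n_donors = nd, seed = streams$seed,
                       stream_id = streams$stream_id)),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim result [%s]: W=%d, %d donors, %d matches, %d unallocated kidneys\n",
              x$config$strategy_label, x$config$waitlist_size,
              x$config$n_donors, nrow(x$matches), nrow(x$unallocated)))
  invisible(x)
}

#' Run base-case and deliberate allocation on identical streams
#'
#' Both runs consume the same streams object, so the donor and candidate
#' orders are identical and only the selection logic differs — the paired
#' design behind the patient-flow analysis.
#'
#' @param streams A `cohort_streams`.
#' @param strategies List of two [strategy()] objects; default base-case
#'   and deliberate five-locus.
#' @param scorer Scorer object.
#' @return Object of class `paired_result`: list with `results` (named by
#'   strategy label, or `run1`/`run2` when the labels coincide) and
#'   `stream_id`.
#' @export
run_base_and_deliberate_paired <- function(streams,
                                           strategies = list(
                                             strategy("base_case"),
                                             strategy("deliberate")),
                                           scorer) {
  stopifnot(length(strategies) == 2L)
  res <- lapply(strategies, function(s) run_replicate(streams, s, scorer))
  labs <- vapply(strategies, strategy_label, character(1))
  if (anyDuplicated(labs)) labs <- paste0("run", seq_along(labs))
  names(res) <- labs
  structure(list(results = res, stream_id = streams$stream_id),
            class = "paired_result")
}
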