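test_that("score summaries use the lower-middle median and zero fraction", {
  m <- data.frame(sum5 = c(0, 0, 5))
  s <- summarize_scores(m)
  expect_equal(s$median, 0)
  expect_equal(s$zero_probability, 2 / 3)
  expect_equal(summarize_scores(data.frame(sum5 = c(1, 2, 3, 4)))$median, 2)
  expect_equal(summarize_scores(data.frame(score_DRB1 = c(7, 3, 9)),
                                "DRB1")$median, 7)
  expect_error(summarize_scores(data.frame(sum5 = numeric(0))), "empty")
})

test_that("quartile categories reproduce printed integer conventions", {
  # uniform 0..99: category lower bounds at 25/50/75
  qq <- quartile_categories(0:99)
  expect_equal(qq$lower, c(0, 25, 50, 75))
  # multiset with order-statistic quartiles 7/13/20 reproduces the
  # published DRB1 convention Q1=0-7, Q2=8-13, Q3=14-20, Q4=>=21
  x <- c(rep(7, 25), rep(13, 25), rep(20, 25), rep(30, 25))
  qp <- quartile_categories(x)
  expect_equal(qp$label, paste0("Q", 1:4))
  expect_equal(qp$lower, c(0, 8, 14, 21))
  expect_equal(qp$upper, c(7, 13, 20, Inf))
  f <- assign_quartile(c(0, 7, 8, 13, 14, 20, 21, 100), qp)
  expect_equal(as.character(f), c("Q1", "Q1", "Q2", "Q2", "Q3", "Q3",
                                  "Q4", "Q4"))
  # all scores equal: single category with a warning
  expect_warning(q1 <- quartile_categories(rep(5, 10)), "degenerate")
  expect_equal(nrow(q1), 1L)
})

test_that("patient flow is diagonal for identical runs and conserves patients", {
  pool <- test_pool()
  scorer <- make_scorer(pool, k = 9)
  s <- generate_streams(pool, waitlist_size = 40, ratio = 2, seed = 81)
  same <- run_base_and_deliberate_paired(
    s, list(strategy("base_case"), strategy("base_case")), scorer)
  fl <- patient_flow(same)
  expect_equal(sum(fl$counts), fl$n)
  off_diag <- fl$counts
  diag(off_diag) <- 0
  expect_equal(sum(off_diag), 0)

  pr <- run_base_and_deliberate_paired(s, scorer = scorer)
  fl2 <- patient_flow(pr)
  expect_equal(sum(rowSums(fl2$counts)), fl2$n)
  expect_equal(sum(colSums(fl2$counts)), fl2$n)
  expect_equal(fl2$n, nrow(s$candidates))
  # hand-computed flows from the two match lists
  b <- pr$results[[1]]; d <- pr$results[[2]]
  qq <- quartile_categories(b$matches$sum5)
  ids <- s$candidates$id
  lab <- function(run) {
    i <- match(ids, run$matches$recipient_id)
    out <- ifelse(is.na(i), "Waiting",
                  as.character(assign_quartile(run$matches$sum5[i], qq)))
    factor(out, levels = c(qq$label, "Waiting"))
  }
  expect_equal(unclass(fl2$counts),
               unclass(table(baseline = lab(b), deliberate = lab(d))))
})

test_that("static profiles score patients against ABO-identical donors only", {
  pool <- test_pool()
  scorer <- make_scorer(pool, k = 9)
  s <- generate_streams(pool, waitlist_size = 6, ratio = 3, seed = 91)
  pats <- s$candidates[1:4, ]
  dons <- s$donors
  # donor 1 cloned from patient 1: identical genotype and ABO -> score 0
  clone_cols <- c("abo", "h1", "h2", "drb1_key",
                  as.vector(rbind(paste0(hla_loci(), "_1"),
                                  paste0(hla_loci(), "_2"))))
  for (cc in clone_cols) dons[1, cc] <- pats[1, cc]
  dons$id[1] <- "D_CLONE"
  # patient 4 given an ABO group no donor carries
  pats$abo[4] <- setdiff(c("O", "A", "B", "AB"), dons$abo)[1]
  prof <- static_score_profile(pats, dons, scorer)
  expect_equal(prof$median[1], 0)
  expect_true(prof$unscorable[4])
  expect_equal(prof$n_donors[4], 0L)
  # medians equal brute-force pairwise table
  sc <- attr(prof, "scores")
  for (i in 1:3) {
    expected <- vapply(seq_len(nrow(dons)), function(j) {
      if (dons$abo[j] != pats$abo[i]) return(NA_real_)
      unname(score_pair(scorer, dons[j, ], pats[i, ])[["sum5"]])
    }, numeric(1))
    expect_equal(unname(sc[i, ]), expected)
    if (any(!is.na(expected))) {
      v <- sort(expected[!is.na(expected)])
      expect_equal(prof$median[i], v[[(length(v) + 1) %/% 2]])
    }
  }
})

test_that("hard-to-match flagging detects a constructed heavy tail and nothing else", {
  mk_prof <- function(medians) {
    structure(data.frame(id = sprintf("P%03d", seq_along(medians)),
                         median = medians, unscorable = FALSE,
                         stringsAsFactors = FALSE),
              class = c("score_profile", "data.frame"))
  }
  # flat medians: zero differences, no flags
  expect_equal(sum(flag_hard_to_match(mk_prof(rep(40, 50)))$flagged), 0)
  # gentle linear slope below the relative threshold: no flags
  gentle <- mk_prof(seq(100, 104, length.out = 200))
  expect_equal(sum(flag_hard_to_match(gentle)$flagged), 0)
  # 5% heavy tail: flagged fraction lands in [0.01, 0.10]
  medians <- c(seq(20, 60, length.out = 190), seq(90, 300, length.out = 10))
  rep_t <- flag_hard_to_match(mk_prof(medians))
  frac <- mean(rep_t$flagged)
  expect_gte(frac, 0.01)
  expect_lte(frac, 0.10)
  # flagged set is a suffix of the ordered patients for this monotone tail
  expect_true(all(diff(which(rep_t$flagged)) == 1))
  # relative threshold: doubling all scores doubles the absolute threshold
  # and leaves the flagged set unchanged
  rep_2x <- flag_hard_to_match(mk_prof(2 * medians))
  expect_equal(attr(rep_2x, "threshold"), 2 * attr(rep_t, "threshold"))
  expect_equal(rep_2x$flagged, rep_t$flagged)
  # short series: window truncated with a warning
  expect_warning(flag_hard_to_match(mk_prof(c(1, 2, 30))), "window")
})
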