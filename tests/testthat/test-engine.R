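make_waitlist <- function(abo, arrival, scores = NULL) {
  df <- data.frame(id = sprintf("C%02d", seq_along(abo)), abo = abo,
                   arrival_index = arrival, stringsAsFactors = FALSE)
  df
}

test_that("recipient selection follows score, waiting time, and ABO identity", {
  pool <- test_pool()
  scorer <- make_scorer(pool, k = 9)
  s <- generate_streams(pool, c(O = 1), waitlist_size = 12, ratio = 3,
                        seed = 51)
  donor <- s$donors[1, ]
  wl <- s$candidates[1:12, ]
  # deliberate: minimum five-locus sum wins
  sv <- score_waitlist(scorer, donor, wl)
  sel <- select_recipient(wl, donor, strategy("deliberate"), scorer)
  best <- order(sv$sum5, wl$arrival_index, wl$id)[1]
  expect_equal(sel$id, wl$id[best])
  # base case: longest-waiting (lowest arrival index) wins
  sel_b <- select_recipient(wl, donor, strategy("base_case"), scorer)
  expect_equal(sel_b$id, wl$id[which.min(wl$arrival_index)])
  # scores 5 vs 3 -> the score-3 candidate; tie -> smaller arrival index
  fake <- structure(list(scores = matrix(c(1, 1, 1, 1, 1,
                                           0, 1, 1, 1, 0), 2, 5, byrow = TRUE),
                         key = c(paste(donor$id, wl$id[1], sep = ">"),
                                 paste(donor$id, wl$id[2], sep = ">"))),
                    class = "matrix_scorer")
  two <- wl[1:2, ]
  sel2 <- select_recipient(two, donor, strategy("deliberate"), fake)
  expect_equal(sel2$id, wl$id[2])  # sum 3 beats sum 5
  fake$scores[2, ] <- fake$scores[1, ]
  two$arrival_index <- c(7L, 2L)
  sel3 <- select_recipient(two, donor, strategy("deliberate"), fake)
  expect_equal(sel3$id, wl$id[2])  # identical scores, arrival 2 beats 7
  # ABO identity: AB donor, all-O waitlist -> nobody
  donor_ab <- donor
  donor_ab$abo <- "AB"
  expect_null(select_recipient(wl, donor_ab, strategy("deliberate"), scorer))
})

test_that("one-donor replicate matches brute force over a tiny waitlist", {
  pool <- test_pool()
  scorer <- make_scorer(pool, k = 9)
  s <- generate_streams(pool, c(O = 1), waitlist_size = 4, ratio = 4,
                        seed = 61)
  expect_equal(s$n_donors, 1L)
  res <- run_replicate(s, strategy("deliberate", "DRB1"), scorer)
  expect_equal(nrow(res$matches), 2L)
  # brute force: the two lowest-DRB1-score candidates, in order
  d <- s$donors[1, ]
  sc <- vapply(1:4, function(i) {
    unname(score_pair(scorer, d, s$candidates[i, ])[["DRB1"]])
  }, numeric(1))
  ord <- order(sc, s$candidates$arrival_index[1:4])
  expect_equal(res$matches$recipient_id, s$candidates$id[ord[1:2]])
  expect_equal(res$matches$objective_score, sc[ord[1:2]])
})

test_that("zero donors leave the waitlist untouched", {
  pool <- test_pool()
  scorer <- make_scorer(pool, k = 9)
  s <- generate_streams(pool, waitlist_size = 10, ratio = 2, seed = 62)
  s$donors <- s$donors[0, ]
  res <- run_replicate(s, strategy("base_case"), scorer)
  expect_equal(nrow(res$matches), 0L)
  expect_equal(res$final_waitlist$id, s$candidates$id[1:10])
})

test_that("kidney conservation and single-transplant invariants hold under ABO scarcity", {
  pool <- test_pool()
  scorer <- make_scorer(pool, k = 9)
  # AB donors are common but AB candidates rare: unallocated kidneys occur
  freqs <- c(O = 0.60, A = 0.15, B = 0.05, AB = 0.20)
  s <- generate_streams(pool, freqs, waitlist_size = 12, ratio = 3, seed = 63)
  res <- run_replicate(s, strategy("deliberate"), scorer)
  expect_equal(nrow(res$matches) + nrow(res$unallocated), 2L * s$n_donors)
  expect_equal(anyDuplicated(res$matches$recipient_id), 0L)
  if (nrow(res$unallocated)) {
    expect_true(all(res$unallocated$reason == "no_abo_identical_candidate"))
  }
  # Match-List fields are internally consistent
  m <- res$matches
  expect_equal(m$sum5, rowSums(m[paste0("score_", hla_loci())]))
  expect_equal(m$objective_score, m$sum5)  # 5LOCI objective
  expect_equal(as.character(m$stratum), as.character(classify_stratum(m$sum5)))
})

test_that("engine equals exhaustive per-kidney minimum search on small instances", {
  n_checked <- 0
  for (i in 1:60) {
    withr::with_seed(7000 + i, {
      pool <- build_haplotype_pool(sample(3:6, 1), 4, 0.5, seed = 7000 + i,
                                   n_alleles_per_locus = 3, seq_length = 12)
      W <- sample(2:6, 1)
      ratio <- W / sample(1:2, 1)
      abo <- sample(list(c(O = 1), c(O = 0.7, A = 0.3)), 1)[[1]]
      k <- 4
      pres <- make_hash_presenter(runif(1, 0.3, 1))
      mode <- sample(c("deliberate", "deliberate", "base_case"), 1)
      loci <- if (runif(1) < 0.5) hla_loci() else
        sample(hla_loci(), sample(1:3, 1))
      strat <- strategy(mode, loci)
      s <- generate_streams(pool, abo, waitlist_size = W, ratio = ratio,
                            seed = 7100 + i)
      scorer <- make_scorer(pool, k = k, presenter = pres)
      res <- run_replicate(s, strat, scorer)
      expected <- oracle_run(s, strat, pool, k, pres)
      got <- res$matches[c("donor_id", "recipient_id")]
      if (is.null(expected)) {
        expect_equal(nrow(got), 0L)
      } else {
        expect_equal(got, expected, info = paste("instance", i))
      }
      n_checked <- n_checked + 1
    })
  }
  expect_equal(n_checked, 60)
})

test_that("paired runs consume identical streams and deliberate matching dominates", {
  pool <- test_pool()
  scorer <- make_scorer(pool, k = 9)
  s <- generate_streams(pool, waitlist_size = 200, ratio = 3, seed = 71)
  pr <- run_base_and_deliberate_paired(s, scorer = scorer)
  expect_named(pr$results, c("base_case", "deliberate_5LOCI"))
  expect_equal(pr$results[[1]]$config$stream_id,
               pr$results[[2]]$config$stream_id)
  expect_equal(unique(pr$results[[1]]$matches$donor_id),
               unique(pr$results[[2]]$matches$donor_id))
  # same strategy twice: identical match lists
  pr2 <- run_base_and_deliberate_paired(
    s, list(strategy("base_case"), strategy("base_case")), scorer)
  expect_identical(pr2$results$run1$matches, pr2$results$run2$matches)
  # deliberate mean objective never exceeds base case (3 seeds)
  for (seed in 72:74) {
    ss <- generate_streams(pool, waitlist_size = 200, ratio = 3, seed = seed)
    pp <- run_base_and_deliberate_paired(ss, scorer = scorer)
    expect_lte(mean(pp$results$deliberate_5LOCI$matches$objective_score),
               mean(pp$results$base_case$matches$objective_score))
  }
})
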