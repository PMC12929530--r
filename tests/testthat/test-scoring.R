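test_that("peptide derivation enumerates and deduplicates k-mers", {
  expect_setequal(derive_peptides("ABCDE", 5), "ABCDE")
  expect_setequal(derive_peptides("ABCDE", 3), c("ABC", "BCD", "CDE"))
  expect_setequal(derive_peptides("AAAA", 2), "AA")
  expect_error(derive_peptides("ABC", 4), "shorter")
})

test_that("strata follow the published cutpoints and partition the integers", {
  expect_equal(as.character(classify_stratum(c(0, 8))), c("low", "low"))
  expect_equal(as.character(classify_stratum(c(9, 34))),
               c("elevated", "elevated"))
  expect_equal(as.character(classify_stratum(c(35, 89))),
               c("intermediate", "intermediate"))
  expect_equal(as.character(classify_stratum(c(90, 5000))), c("high", "high"))
  # every non-negative integer lands in exactly one stratum
  expect_false(anyNA(classify_stratum(0:500)))
  expect_error(classify_stratum(-1), "non-negative")
})

test_that("locus score matches hand-enumerable toy cases", {
  seqs <- lapply(hla_loci(), function(loc) c("AAAAAAAAAA", "AAAACAAAAA"))
  names(seqs) <- hla_loci()
  pool <- toy_pool(seqs)
  all_in <- make_scorer(pool, k = 9, presenter = make_constant_presenter(TRUE))
  homozygote <- function(which_allele) {
    structure(stats::setNames(lapply(hla_loci(), function(l) {
      rep(sprintf("%s*%02d", l, which_allele), 2)
    }), hla_loci()), class = "hla_genotype")
  }
  donor <- homozygote(2)
  recip <- homozygote(1)
  # donor sequence AAAACAAAAA has 9-mers {AAAACAAAA, AAACAAAAA}; both are
  # non-self against the all-A recipient peptidome
  expect_equal(locus_score(all_in, donor, recip, "A"), 2L)
  none <- make_scorer(pool, k = 9, presenter = make_constant_presenter(FALSE))
  expect_equal(locus_score(none, donor, recip, "A"), 0L)
  # identical genotypes score zero everywhere
  for (loc in hla_loci()) {
    expect_equal(locus_score(all_in, recip, recip, loc), 0L)
  }
})

test_that("self score is zero for random genotypes", {
  scorer <- make_scorer(test_pool(), k = 9)
  withr::with_seed(11, {
    for (i in 1:250) {
      g <- random_genotype(test_pool())
      sv <- score_pair(scorer, g, g)
      expect_true(all(sv == 0L))
    }
  })
})

test_that("replacing a donor allele by a recipient allele never raises a score", {
  scorer <- make_scorer(test_pool(), k = 9)
  withr::with_seed(12, {
    for (i in 1:250) {
      dg <- random_genotype(test_pool())
      rg <- random_genotype(test_pool())
      before <- score_pair(scorer, dg, rg, use_cache = FALSE)
      loc <- sample(hla_loci(), 1)
      slot <- sample(1:2, 1)
      dg2 <- dg
      dg2[[loc]][slot] <- rg[[loc]][sample(1:2, 1)]
      after <- score_pair(scorer, dg2, rg, use_cache = FALSE)
      expect_true(all(after[hla_loci()] <= before[hla_loci()]))
    }
  })
})

test_that("locus scores equal brute-force k-mer set-difference enumeration", {
  for (i in 1:50) {
    pool <- random_toy_pool(seed = 3000 + i,
                            n_alleles = sample(2:4, 1), len = 14)
    k <- sample(3:5, 1)
    pres <- make_hash_presenter(runif(1, 0.3, 1))
    scorer <- make_scorer(pool, k = k, presenter = pres)
    dg <- random_genotype(pool, seed = 100 + i)
    rg <- random_genotype(pool, seed = 200 + i)
    for (loc in hla_loci()) {
      expect_equal(locus_score(scorer, dg, rg, loc),
                   oracle_locus_score(pool, dg, rg, loc, k, pres),
                   info = sprintf("pool %d locus %s", i, loc))
    }
  }
})

test_that("score_pair sums loci, caches consistently, and matches cache-free recomputation", {
  scorer <- make_scorer(test_pool(), k = 9)
  withr::with_seed(21, {
    for (i in 1:20) {
      dg <- random_genotype(test_pool())
      rg <- random_genotype(test_pool())
      cached1 <- score_pair(scorer, dg, rg)
      cached2 <- score_pair(scorer, dg, rg)
      fresh <- score_pair(scorer, dg, rg, use_cache = FALSE)
      expect_identical(cached1, cached2)
      expect_equal(cached1, fresh)
      expect_equal(unname(cached1[["sum5"]]), sum(cached1[hla_loci()]))
    }
  })
})

test_that("vectorised waitlist scoring equals pairwise scoring on both representations", {
  pool <- test_pool()
  scorer <- make_scorer(pool, k = 9)
  s <- generate_streams(pool, waitlist_size = 30, ratio = 3, seed = 31)
  donor <- s$donors[1, ]
  cand <- s$candidates[1:30, ]
  sv <- score_waitlist(scorer, donor, cand)
  expect_equal(nrow(sv), 30)
  # allele-column path (no haplotype indices) must agree exactly
  cand_noh <- cand[, setdiff(names(cand), c("h1", "h2"))]
  expect_equal(score_waitlist(scorer, donor, cand_noh), sv)
  for (i in seq_len(nrow(cand))) {
    sp <- score_pair(scorer, donor, cand[i, ], use_cache = FALSE)
    expect_equal(unlist(sv[i, ]), stats::setNames(
      sp, c(paste0("score_", hla_loci()), "sum5")),
      info = paste("candidate", i))
  }
})

test_that("presenter acceptance rate is calibrated", {
  rate <- 0.16
  pres <- make_hash_presenter(rate)
  drb <- test_pool()$alleles$allele[test_pool()$alleles$locus == "DRB1"]
  withr::with_seed(41, {
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    hits <- 0L; total <- 0L
    for (b in 1:100) {
      peps <- vapply(1:100, function(i) {
        paste(sample(aa, 9, replace = TRUE), collapse = "")
      }, character(1))
      pair <- sample(drb, 2, replace = TRUE)
      hits <- hits + sum(pres$accepts(peps, pair))
      total <- total + 100L
    }
  })
  se <- sqrt(rate * (1 - rate) / total)
  expect_lt(abs(hits / total - rate), 3 * se)
  expect_error(make_hash_presenter(0), "acceptance_rate")
  expect_error(make_hash_presenter(1.5), "acceptance_rate")
})

test_that("score matrix loads, recomputes sums, and round-trips the surrogate", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "donor_id\trecipient_id\tscore_A\tscore_B\tscore_C\tscore_DRB1\tscore_DQB1",
    "d1\tr1\t15\t14\t13\t14\t20"), tf)
  ms <- load_score_matrix(tf)
  sv <- score_pair(ms, list(id = "d1"), list(id = "r1"))
  expect_equal(unname(sv[["sum5"]]), 76)
  expect_error(score_pair(ms, list(id = "d1"), list(id = "r9")),
               "not in score matrix")
  writeLines(c(
    "donor_id\trecipient_id\tscore_A\tscore_B\tscore_C\tscore_DRB1\tscore_DQB1",
    "d1\tr1\t-1\t14\t13\t14\t20"), tf)
  expect_error(load_score_matrix(tf), "non-negative integers")

  # write-then-load reproduces surrogate scores exactly
  pool <- test_pool()
  scorer <- make_scorer(pool, k = 9)
  s <- generate_streams(pool, waitlist_size = 12, ratio = 3, seed = 5)
  tf2 <- withr::local_tempfile(fileext = ".tsv")
  write_score_matrix(scorer, s$donors, s$candidates, tf2)
  ms2 <- load_score_matrix(tf2)
  for (d in 1:2) {
    expect_equal(score_waitlist(ms2, s$donors[d, ], s$candidates),
                 score_waitlist(scorer, s$donors[d, ], s$candidates))
  }
})
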