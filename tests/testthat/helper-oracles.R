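# Independent oracles and tiny fixtures. Everything here works on raw
# strings and explicit loops, deliberately sharing no code with the
# package's indexed scoring tables or the allocation engine.

oracle_peptides <- function(seq, k) {
  n <- nchar(seq)
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

# Brute-force per-locus mismatch score: materialise donor k-mers and the
# recipient's full self k-mer set, take the set difference, apply the
# presenter in the recipient's DRB1 context.
oracle_locus_score <- function(pool, donor_g, recip_g, locus, k, presenter) {
  seq_of <- function(a) pool$alleles$sequence[match(a, pool$alleles$allele)]
  dk <- unique(unlist(lapply(seq_of(donor_g[[locus]]), oracle_peptides, k)))
  self <- unique(unlist(lapply(seq_of(unlist(recip_g)), oracle_peptides, k)))
  nonself <- setdiff(dk, self)
  if (!length(nonself)) return(0L)
  sum(presenter$accepts(nonself, recip_g$DRB1))
}

oracle_score_vector <- function(pool, donor_g, recip_g, k, presenter) {
  sc <- vapply(hla_loci(), function(loc) {
    oracle_locus_score(pool, donor_g, recip_g, loc, k, presenter)
  }, integer(1))
  c(sc, sum5 = sum(sc))
}

# Exhaustive per-kidney greedy search over a streams object: for every
# donor and kidney, enumerate every waitlisted candidate, score it by the
# brute-force oracle, and pick the minimum (waiting time, then id, breaking
# ties). Mirrors the allocation rules with plain loops and no caching.
oracle_run <- function(streams, strat, pool, k, presenter) {
  cand <- streams$candidates
  W <- streams$waitlist_size
  wl <- seq_len(W)
  ptr <- W
  picks <- list()
  for (d in seq_len(nrow(streams$donors))) {
    drow <- streams$donors[d, ]
    for (kid in 1:2) {
      elig <- wl[cand$abo[wl] == drow$abo]
      if (!length(elig)) next
      if (strat$mode == "base_case") {
        best <- elig[which.min(cand$arrival_index[elig])]
      } else {
        dg <- as_genotype(drow)
        obj <- vapply(elig, function(ci) {
          rg <- as_genotype(cand[ci, ])
          sum(vapply(strat$loci, function(loc) {
            oracle_locus_score(pool, dg, rg, loc, k, presenter)
          }, integer(1)))
        }, integer(1))
        best <- elig[order(obj, cand$arrival_index[elig], cand$id[elig])[1]]
      }
      picks[[length(picks) + 1L]] <- data.frame(
        donor_id = drow$id, recipient_id = cand$id[best],
        stringsAsFactors = FALSE)
      wl <- wl[wl != best]
    }
    wl <- c(wl, ptr + 1:2)
    ptr <- ptr + 2L
  }
  if (!length(picks)) return(NULL)
  do.call(rbind, c(picks, make.row.names = FALSE))
}

# Pool with explicitly given sequences: one allele per entry of
# seqs_by_locus[[locus]], haplotype i carrying allele i at every locus.
toy_pool <- function(seqs_by_locus) {
  loci <- hla_loci()
  n <- length(seqs_by_locus[[1]])
  alleles <- do.call(rbind, lapply(loci, function(loc) {
    data.frame(allele = sprintf("%s*%02d", loc, seq_len(n)), locus = loc,
               sequence = seqs_by_locus[[loc]], stringsAsFactors = FALSE)
  }))
  hap <- vapply(loci, function(loc) sprintf("%s*%02d", loc, seq_len(n)),
                character(n))
  hap <- matrix(hap, nrow = n, dimnames = list(NULL, loci))
  new_haplotype_pool(hap, rep(1 / n, n), alleles)
}

# Random small pool for oracle comparisons: few alleles, short sequences
# over a reduced alphabet so self/non-self collisions actually occur.
random_toy_pool <- function(seed, n_alleles = 3, len = 14,
                            alphabet = c("A", "C", "G")) {
  withr::with_seed(seed, {
    seqs <- lapply(hla_loci(), function(loc) {
      repeat {
        s <- vapply(seq_len(n_alleles), function(i) {
          paste(sample(alphabet, len, replace = TRUE), collapse = "")
        }, character(1))
        if (!anyDuplicated(s)) return(s)
      }
    })
    names(seqs) <- hla_loci()
    toy_pool(seqs)
  })
}

random_genotype <- function(pool, seed = NULL) {
  draw <- function() as_genotype(sample_person(pool, c(O = 1), "candidate"))
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Shared mid-size pool for tests that don't depend on its details.
test_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) pool <<- build_haplotype_pool(20, 18, 0.3, seed = 99,
                                                     seq_length = 40)
    pool
  }
})
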