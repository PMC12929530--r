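# Synthetic haplotype pool and cohort generation.

.LOCI <- c("A", "B", "C", "DRB1", "DQB1")
.AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
.ABO <- c("O", "A", "B", "AB")

#' The five HLA loci scored by the simulation
#'
#' @return Character vector `c("A", "B", "C", "DRB1", "DQB1")`.
#' @export
hla_loci <- function() .LOCI

#' Default ABO blood-group frequencies
#'
#' Approximate Canadian population distribution, used when sampling donors
#' and candidates. Allocation is ABO-identical, so these frequencies control
#' how large each donor's eligible sub-waitlist is.
#'
#' @return Named numeric vector over O, A, B, AB summing to 1.
#' @export
default_abo_freqs <- function() {
  c(O = 0.46, A = 0.42, B = 0.09, AB = 0.03)
}

#' Construct a haplotype pool from explicit tables
#'
#' Low-level constructor for users who already have haplotypes, frequencies
#' and allele sequences (e.g. round-tripped through [read_pool()] or built
#' from a real cohort table). Validates the pool invariants.
#'
#' @param haplotypes Character matrix, one row per haplotype, columns named
#'   `A, B, C, DRB1, DQB1`, entries are allele identifiers.
#' @param frequencies Numeric vector of haplotype probabilities (one per
#'   row), non-negative, summing to 1 within 1e-9.
#' @param alleles Data frame with columns `allele`, `locus`, `sequence`
#'   giving exactly one protein sequence per allele identifier; all
#'   sequences at one locus must have equal length.
#' @param params Optional list of generator parameters (kept for the
#'   manifest; not interpreted).
#' @return An object of class `haplotype_pool`.
#' @export
new_haplotype_pool <- function(haplotypes, frequencies, alleles,
                               params = list()) {
  haplotypes <- as.matrix(haplotypes)
  if (!identical(colnames(haplotypes), .LOCI)) {
    stop("haplotype columns must be exactly ", paste(.LOCI, collapse = ", "))
  }
  if (nrow(haplotypes) != length(frequencies)) {
    stop("one frequency per haplotype required")
  }
  if (any(frequencies < 0) || abs(sum(frequencies) - 1) > 1e-9) {
    stop("frequencies must be non-negative and sum to 1 (within 1e-9)")
  }
  alleles <- as.data.frame(alleles, stringsAsFactors = FALSE)
  if (!all(c("allele", "locus", "sequence") %in% names(alleles))) {
    stop("alleles table needs columns allele, locus, sequence")
  }
  if (anyDuplicated(alleles$allele)) {
    stop("every allele identifier must have exactly one sequence")
  }
  used <- unique(as.vector(haplotypes))
  missing <- setdiff(used, alleles$allele)
  if (length(missing)) {
    stop("alleles without sequence: ", paste(missing, collapse = ", "))
  }
  for (loc in .LOCI) {
    len <- nchar(alleles$sequence[alleles$locus == loc])
    if (length(unique(len)) > 1L) {
      stop("sequences at locus ", loc, " must have equal length")
    }
  }
  if (is.null(rownames(haplotypes))) {
    rownames(haplotypes) <- sprintf("H%03d", seq_len(nrow(haplotypes)))
  }
  structure(
    list(haplotypes = haplotypes, frequencies = frequencies,
         alleles = alleles, params = params),
    class = "haplotype_pool"
  )
}

#' Generate a synthetic HLA haplotype pool
#'
#' Builds a pool of five-locus haplotypes with a skewed (few common, many
#' rare) frequency profile drawn from a symmetric Dirichlet distribution,
#' plus synthetic protein sequences for every allele. Sequences at a locus
#' share a random backbone and differ only at designated polymorphic
#' positions, so distinct alleles always yield non-self peptides while
#' alleles still share most of their peptidome, mimicking the structure that
#' drives molecular mismatch counts.
#'
#' @param n_haplotypes Number of haplotypes (>= 2).
#' @param n_polymorphic_sites Number of polymorphic sequence positions per
#'   locus.
#' @param concentration Symmetric Dirichlet concentration for the haplotype
#'   frequencies; values < 1 give the long rare tail typical of HLA.
#' @param seed Integer seed; identical seeds reproduce identical pools.
#' @param n_alleles_per_locus Distinct alleles per locus; default
#'   `max(3, ceiling(n_haplotypes / 3))`.
#' @param seq_length Protein sequence length per locus (all loci equal).
#' @param n_site_variants Residue alphabet size at each polymorphic site;
#'   small values make allele pairs share residues more often.
#' @return A `haplotype_pool` (frequencies sorted descending).
#' @examples
#' pool <- build_haplotype_pool(10, 12, 0.3, seed = 1)
#' sum(pool$frequencies)
#' @export
build_haplotype_pool <- function(n_haplotypes, n_polymorphic_sites,
                                 concentration, seed,
                                 n_alleles_per_locus = NULL,
                                 seq_length = 72L,
                                 n_site_variants = 4L) {
  assert_scalar_count(n_haplotypes, "n_haplotypes", min = 2)
  assert_scalar_count(n_polymorphic_sites, "n_polymorphic_sites", min = 1)
  assert_scalar_count(seq_length, "seq_length", min = 2)
  assert_scalar_count(n_site_variants, "n_site_variants", min = 2)
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      concentration <= 0) {
    stop("`concentration` must be a single positive number")
  }
  if (n_polymorphic_sites > seq_length) {
    stop("`n_polymorphic_sites` cannot exceed `seq_length`")
  }
  n_alleles_per_locus <- n_alleles_per_locus %||%
    max(3L, ceiling(n_haplotypes / 3))
  assert_scalar_count(n_alleles_per_locus, "n_alleles_per_locus", min = 2)

  withr::with_seed(seed, {
    allele_tabs <- lapply(.LOCI, function(loc) {
      backbone <- sample(.AA, seq_length, replace = TRUE)
      sites <- sort(sample.int(seq_length, n_polymorphic_sites))
      variants <- lapply(seq_along(sites),
                         function(i) sample(.AA, n_site_variants))
      draw_seq <- function() {
        s <- backbone
        s[sites] <- vapply(variants, function(v) sample(v, 1L), character(1))
        paste(s, collapse = "")
      }
      seqs <- vapply(seq_len(n_alleles_per_locus), function(i) draw_seq(),
                     character(1))
      # enforce distinct alleles (collisions are vanishingly rare but would
      # break the "distinct alleles yield non-self peptides" contract)
      while (anyDuplicated(seqs)) {
        dup <- which(duplicated(seqs))
        seqs[dup] <- vapply(dup, function(i) draw_seq(), character(1))
      }
      data.frame(allele = sprintf("%s*%02d", loc, seq_len(n_alleles_per_locus)),
                 locus = loc, sequence = seqs, stringsAsFactors = FALSE)
    })
    alleles <- do.call(rbind, allele_tabs)

    haplotypes <- vapply(.LOCI, function(loc) {
      ids <- alleles$allele[alleles$locus == loc]
      sample(ids, n_haplotypes, replace = TRUE)
    }, character(n_haplotypes))
    haplotypes <- matrix(haplotypes, nrow = n_haplotypes,
                         dimnames = list(sprintf("H%03d", seq_len(n_haplotypes)),
                                         .LOCI))

    g <- stats::rgamma(n_haplotypes, shape = concentration, rate = 1)
    freqs <- sort(g / sum(g), decreasing = TRUE)

    new_haplotype_pool(haplotypes, freqs, alleles, params = list(
      n_haplotypes = n_haplotypes,
      n_polymorphic_sites = n_polymorphic_sites,
      concentration = concentration,
      seed = seed,
      n_alleles_per_locus = n_alleles_per_locus,
      seq_length = seq_length,
      n_site_variants = n_site_variants
    ))
  })
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat(sprintf("haplotype pool: %d haplotypes, %d alleles over %d loci, top frequency %.3f\n",
              nrow(x$haplotypes), nrow(x$alleles), length(.LOCI),
              max(x$frequencies)))
  invisible(x)
}

# Genotype at the five loci from two haplotype row indices.
genotype_from_haps <- function(pool, h1, h2) {
  g <- lapply(.LOCI, function(loc) c(pool$haplotypes[h1, loc],
                                     pool$haplotypes[h2, loc]))
  names(g) <- .LOCI
  structure(g, class = "hla_genotype")
}

#' Coerce a person, table row, or list to an HLA genotype
#'
#' Accepts an `hla_genotype`, a person created by [sample_person()], or a
#' one-row data frame / list carrying allele columns `A_1, A_2, ...,
#' DQB1_1, DQB1_2` (the cohort table layout).
#'
#' @param x Object to coerce.
#' @return An `hla_genotype`: named list of unordered allele pairs.
#' @export
as_genotype <- function(x) {
  if (inherits(x, "hla_genotype")) return(x)
  if (is.list(x) && !is.null(x$genotype) && inherits(x$genotype, "hla_genotype")) {
    return(x$genotype)
  }
  cols <- as.vector(rbind(paste0(.LOCI, "_1"), paste0(.LOCI, "_2")))
  if (is.data.frame(x)) x <- as.list(x[1, , drop = FALSE])
  if (is.list(x) && all(cols %in% names(x))) {
    g <- lapply(.LOCI, function(loc) {
      c(as.character(x[[paste0(loc, "_1")]]), as.character(x[[paste0(loc, "_2")]]))
    })
    names(g) <- .LOCI
    return(structure(g, class = "hla_genotype"))
  }
  stop("cannot interpret object as an HLA genotype")
}

# Canonical cache key: allele pair per locus, sorted within locus.
geno_key <- function(g) {
  paste(vapply(g, function(a) paste(sort(a), collapse = "/"), character(1)),
        collapse = ";")
}

#' Sample one candidate or donor from a haplotype pool
#'
#' The genotype is formed from two haplotypes drawn independently with the
#' pool frequencies (Hardy-Weinberg at the haplotype level); the ABO group
#' is drawn independently. Uses the current RNG state; seed at the caller.
#'
#' @param pool A `haplotype_pool`.
#' @param abo_freqs Named probability vector over O/A/B/AB summing to 1.
#' @param role `"candidate"` or `"donor"`.
#' @param id Optional identifier string.
#' @param arrival_index Waitlist arrival index for candidates (lower =
#'   longer waiting).
#' @return A list of class `candidate` or `donor` with fields `id`, `abo`,
#'   `haplotypes` (row indices), `genotype`, and `arrival_index` or
#'   `kidneys = 2` respectively.
#' @export
sample_person <- function(pool, abo_freqs = default_abo_freqs(),
                          role = c("candidate", "donor"), id = NULL,
                          arrival_index = NA_integer_) {
  role <- match.arg(role)
  if (!inherits(pool, "haplotype_pool") || nrow(pool$haplotypes) == 0L) {
    stop("`pool` must be a non-empty haplotype_pool")
  }
  if (abs(sum(abo_freqs) - 1) > 1e-9) stop("`abo_freqs` must sum to 1")
  n <- nrow(pool$haplotypes)
  h <- sample.int(n, 2L, replace = TRUE, prob = pool$frequencies)
  abo <- sample(names(abo_freqs), 1L, prob = abo_freqs)
  out <- list(id = id %||% paste0(toupper(substr(role, 1, 1)), "?"),
              abo = abo, haplotypes = h,
              genotype = genotype_from_haps(pool, h[1], h[2]))
  if (role == "candidate") {
    out$arrival_index <- arrival_index
  } else {
    out$kidneys <- 2L
  }
  structure(out, class = role)
}

# Person table used by the engine: ids, ABO, haplotype indices, the ten
# allele columns, and the canonical DRB1 pair key used by the presenter.
.person_table <- function(pool, ids, abo, h1, h2, arrival_index = NULL) {
  df <- data.frame(id = ids, abo = abo, h1 = h1, h2 = h2,
                   stringsAsFactors = FALSE)
  for (loc in .LOCI) {
    df[[paste0(loc, "_1")]] <- unname(pool$haplotypes[h1, loc])
    df[[paste0(loc, "_2")]] <- unname(pool$haplotypes[h2, loc])
  }
  df$drb1_key <- paste(pmin(df$DRB1_1, df$DRB1_2),
                       pmax(df$DRB1_1, df$DRB1_2), sep = "|")
  if (!is.null(arrival_index)) df$arrival_index <- arrival_index
  df
}

#' Generate paired donor and candidate streams for one replicate
#'
#' Produces the three inputs of one allocation replicate: an initial
#' waitlist of `waitlist_size` candidates (arrival indices `0 ..
#' waitlist_size - 1`), a donor stream of `floor(waitlist_size / ratio)`
#' donors (two kidneys each), and a replenishment stream of exactly two
#' candidates per donor whose arrival indices continue the initial
#' sequence. All randomness is consumed here; running the engine on a
#' streams object is fully deterministic, which is what makes paired
#' base-case/deliberate comparisons exact.
#'
#' @param pool A `haplotype_pool`.
#' @param abo_freqs ABO probabilities (see [default_abo_freqs()]).
#' @param waitlist_size Constant waitlist size W (>= 2).
#' @param ratio Candidate-to-donor ratio (>= 1); national Canadian value is
#'   about 2.6, the figure-level analyses use 3.
#' @param seed Integer seed for the whole replicate stream.
#' @return An object of class `cohort_streams`: `candidates` (initial W
#'   rows followed by the replenishment stream), `donors`, `waitlist_size`,
#'   `ratio`, `n_donors`, `seed`, `stream_id`.
#' @examples
#' pool <- build_haplotype_pool(8, 10, 0.3, seed = 2)
#' s <- generate_streams(pool, waitlist_size = 100, ratio = 3, seed = 7)
#' s$n_donors  # floor(100 / 3) = 33
#' @export
generate_streams <- function(pool, abo_freqs = default_abo_freqs(),
                             waitlist_size, ratio, seed) {
  assert_scalar_count(waitlist_size, "waitlist_size", min = 2)
  if (!is.numeric(ratio) || length(ratio) != 1L || ratio < 1) {
    stop("`ratio` must be a single number >= 1")
  }
  if (abs(sum(abo_freqs) - 1) > 1e-9) stop("`abo_freqs` must sum to 1")
  W <- as.integer(waitlist_size)
  n_donors <- as.integer(floor(W / ratio))
  if (n_donors < 1L) stop("ratio too large: no donors for this waitlist size")
  n_cand <- W + 2L * n_donors
  nh <- nrow(pool$haplotypes)

  withr::with_seed(seed, {
    c_h1 <- sample.int(nh, n_cand, replace = TRUE, prob = pool$frequencies)
    c_h2 <- sample.int(nh, n_cand, replace = TRUE, prob = pool$frequencies)
    c_abo <- sample(names(abo_freqs), n_cand, replace = TRUE, prob = abo_freqs)
    d_h1 <- sample.int(nh, n_donors, replace = TRUE, prob = pool$frequencies)
    d_h2 <- sample.int(nh, n_donors, replace = TRUE, prob = pool$frequencies)
    d_abo <- sample(names(abo_freqs), n_donors, replace = TRUE,
                    prob = abo_freqs)
  })

  candidates <- .person_table(pool, sprintf("C%05d", seq_len(n_cand)),
                              c_abo, c_h1, c_h2,
                              arrival_index = seq_len(n_cand) - 1L)
  donors <- .person_table(pool, sprintf("D%04d", seq_len(n_donors)),
                          d_abo, d_h1, d_h2)
  donors$kidneys <- 2L

  structure(
    list(candidates = candidates, donors = donors, waitlist_size = W,
         ratio = ratio, n_donors = n_donors, seed = seed,
         stream_id = sprintf("s%010.0f", str_hash(paste(
           seed, W, ratio, n_cand, paste(c_h1[1:min(20, n_cand)], collapse = ","),
           sep = "|")))),
    class = "cohort_streams"
  )
}

#' @export
print.cohort_streams <- function(x, ...) {
  cat(sprintf("cohort streams: W=%d, ratio=%g, %d donors, %d candidates (stream %s)\n",
              x$waitlist_size, x$ratio, x$n_donors, nrow(x$candidates),
              x$stream_id))
  invisible(x)
}
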