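# Tabular interchange: everything is header-carrying UTF-8 TSV so outputs
# diff cleanly and round-trip without loss.

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

.allele_cols <- function() as.vector(rbind(paste0(.LOCI, "_1"),
                                           paste0(.LOCI, "_2")))

#' Write a combined donor/candidate cohort table
#'
#' Columns: `id`, `role`, `abo`, `arrival_index` (empty for donors), and
#' the ten allele columns `A_1 ... DQB1_2`.
#'
#' @param candidates,donors Person tables (from [generate_streams()] or
#'   [read_cohort_tsv()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_tsv <- function(candidates, donors, path) {
  ac <- .allele_cols()
  cc <- candidates[, c("id", "abo", ac)]
  cc$role <- "candidate"
  cc$arrival_index <- candidates$arrival_index
  dd <- donors[, c("id", "abo", ac)]
  dd$role <- "donor"
  dd$arrival_index <- NA_integer_
  out <- rbind(cc, dd)[, c("id", "role", "abo", "arrival_index", ac)]
  .write_tsv(out, path)
}

#' Read a cohort table written by [write_cohort_tsv()]
#'
#' Validates the header, roles, ABO groups and arrival indices; parse
#' errors report the offending line number.
#'
#' @param path Cohort TSV path.
#' @return List with `candidates` and `donors` data frames (allele-column
#'   representation; scoreable by any scorer built over a pool containing
#'   the alleles).
#' @export
read_cohort_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "role", "abo", "arrival_index", .allele_cols())
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("cohort parse error: missing columns ", paste(miss, collapse = ", "))
  }
  bad <- which(!tab$role %in% c("candidate", "donor"))
  if (length(bad)) {
    stop(sprintf("cohort parse error at line %d: unknown role '%s'",
                 bad[1] + 1L, tab$role[bad[1]]))
  }
  bad <- which(!tab$abo %in% .ABO)
  if (length(bad)) {
    stop(sprintf("cohort parse error at line %d: unknown ABO group '%s'",
                 bad[1] + 1L, tab$abo[bad[1]]))
  }
  tab$arrival_index <- suppressWarnings(as.integer(tab$arrival_index))
  cand <- tab[tab$role == "candidate", , drop = FALSE]
  bad <- which(is.na(cand$arrival_index))
  if (length(bad)) {
    stop(sprintf("cohort parse error at line %d: bad arrival_index",
                 which(tab$role == "candidate")[bad[1]] + 1L))
  }
  if (anyDuplicated(cand$arrival_index)) {
    stop("cohort parse error: duplicate arrival_index among candidates")
  }
  cand$drb1_key <- paste(pmin(cand$DRB1_1, cand$DRB1_2),
                         pmax(cand$DRB1_1, cand$DRB1_2), sep = "|")
  don <- tab[tab$role == "donor", , drop = FALSE]
  don$arrival_index <- NULL
  don$kidneys <- 2L
  rownames(cand) <- rownames(don) <- NULL
  list(candidates = cand, donors = don)
}

#' Serialise a haplotype pool to two TSV tables
#'
#' Writes `<stem>_alleles.tsv` (`allele`, `locus`, `sequence`) and
#' `<stem>_haplotypes.tsv` (`haplotype_id`, the five allele columns,
#' `frequency`, full precision).
#'
#' @param pool A `haplotype_pool`.
#' @param stem Path stem for the two files.
#' @return Character vector of the two paths, invisibly.
#' @export
write_pool <- function(pool, stem) {
  pa <- paste0(stem, "_alleles.tsv")
  ph <- paste0(stem, "_haplotypes.tsv")
  .write_tsv(pool$alleles, pa)
  hdf <- data.frame(haplotype_id = rownames(pool$haplotypes),
                    pool$haplotypes,
                    frequency = format(pool$frequencies, digits = 17,
                                       scientific = TRUE, trim = TRUE),
                    stringsAsFactors = FALSE)
  .write_tsv(hdf, ph)
  invisible(c(pa, ph))
}

#' Read a haplotype pool written by [write_pool()]
#'
#' @param stem Path stem used at write time.
#' @return A `haplotype_pool` equal (up to frequency rounding at 1e-15) to
#'   the one written.
#' @export
read_pool <- function(stem) {
  alleles <- utils::read.delim(paste0(stem, "_alleles.tsv"),
                               stringsAsFactors = FALSE)
  hdf <- utils::read.delim(paste0(stem, "_haplotypes.tsv"),
                           stringsAsFactors = FALSE,
                           colClasses = c(frequency = "character"))
  hap <- as.matrix(hdf[, .LOCI])
  rownames(hap) <- hdf$haplotype_id
  freq <- as.numeric(hdf$frequency)
  freq <- freq / sum(freq)  # absorb decimal-representation rounding
  new_haplotype_pool(hap, freq, alleles)
}

#' Write a Match-List table
#'
#' @param result A `sim_result`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_match_list <- function(result, path) {
  .write_tsv(result$matches, path)
}

#' Read a Match-List table
#'
#' @param path Match-List TSV path.
#' @return Data frame with `stratum` restored as a factor.
#' @export
read_match_list <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  m$stratum <- factor(m$stratum, levels = levels(classify_stratum(0)))
  m
}

#' Write aggregated curves
#'
#' @param curves Data frame from [aggregate_curves()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_curves <- function(curves, path) .write_tsv(curves, path)

#' Read a scenario configuration file
#'
#' YAML with up to four blocks: `cohort` (`n_haplotypes`,
#' `n_polymorphic_sites`, `concentration`, optional `n_alleles_per_locus`,
#' `seq_length`, `abo_freqs`), `scorer` (`k`, `acceptance_rate`), `grid`
#' (`waitlist_sizes`, `ratios`, `strategies` as mode/loci pairs,
#' `replicates`, `master_seed`), `output` (`dir`). Unknown or missing keys
#' are rejected by name.
#'
#' @param path YAML file path.
#' @return List with `cohort`, `scorer`, `config` (a [scenario_config()])
#'   and `output`.
#' @export
read_scenario_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- c("cohort", "scorer", "grid", "output")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  check_block <- function(block, name, required, optional = character(0)) {
    if (is.null(block)) stop("missing config block: ", name)
    unknown <- setdiff(names(block), c(required, optional))
    if (length(unknown)) {
      stop(sprintf("unknown keys in `%s`: %s", name,
                   paste(unknown, collapse = ", ")))
    }
    miss <- setdiff(required, names(block))
    if (length(miss)) {
      stop(sprintf("missing required keys in `%s`: %s", name,
                   paste(miss, collapse = ", ")))
    }
    block
  }
  cohort <- check_block(cfg$cohort, "cohort",
                        c("n_haplotypes", "n_polymorphic_sites",
                          "concentration", "seed"),
                        c("n_alleles_per_locus", "seq_length",
                          "n_site_variants", "abo_freqs"))
  scorer <- check_block(cfg$scorer %||% list(), "scorer", character(0),
                        c("k", "acceptance_rate"))
  grid <- check_block(cfg$grid, "grid", c("master_seed"),
                      c("waitlist_sizes", "ratios", "strategies",
                        "replicates"))
  strategies <- if (is.null(grid$strategies)) {
    list(strategy("base_case"), strategy("deliberate"))
  } else {
    lapply(grid$strategies, function(s) {
      strategy(s$mode, s$loci %||% hla_loci())
    })
  }
  defaults <- scenario_config()
  config <- scenario_config(
    waitlist_sizes = grid$waitlist_sizes %||% defaults$waitlist_sizes,
    ratios = grid$ratios %||% defaults$ratios,
    strategies = strategies,
    replicates = grid$replicates %||% defaults$replicates,
    master_seed = grid$master_seed
  )
  list(cohort = cohort, scorer = scorer, config = config,
       output = cfg$output %||% list(dir = "results"))
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run exactly: package version,
#' the configuration echo, the master and derived seeds, and the output
#' file inventory, plus wall-clock metadata.
#'
#' @param path Output JSON path.
#' @param config Configuration echo (any JSON-serialisable list).
#' @param seeds Named list/vector of seeds used.
#' @param files Character vector of produced files.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seeds, files) {
  manifest <- list(
    package = "allocsim",
    version = as.character(utils::packageVersion("allocsim")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config,
    seeds = seeds,
    files = as.character(files)
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
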