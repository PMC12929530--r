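#!/usr/bin/env Rscript
# National-scale paired simulation: base-case (waiting-time) allocation
# versus deliberate five-locus minimisation on identical donor/candidate
# streams. Writes both Match-Lists and a per-locus score-distribution
# summary (median, range, zero-score fraction) for each scenario.

suppressPackageStartupMessages(library(allocsim))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

POOL_SEED <- 1L
STREAM_SEED <- 101L

pool <- build_haplotype_pool(50, 30, 0.3, seed = POOL_SEED)
scorer <- make_scorer(pool)
streams <- generate_streams(pool, waitlist_size = 2286, ratio = 3,
                            seed = STREAM_SEED)

paired <- run_base_and_deliberate_paired(streams, scorer = scorer)

rows <- list()
for (lab in names(paired$results)) {
  res <- paired$results[[lab]]
  write_match_list(res, file.path(out_dir, paste0("matchlist_", lab, ".tsv")))
  for (what in c(hla_loci(), "sum5")) {
    s <- summarize_scores(res$matches, what)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = lab, score = what, median = s$median, min = s$min,
      max = s$max, zero_probability = s$zero_probability, n = s$n)
  }
}
summary_tab <- do.call(rbind, c(rows, make.row.names = FALSE))
write_curves(summary_tab, file.path(out_dir, "score_distributions.tsv"))

write_manifest(file.path(out_dir, "manifest_national.json"),
               config = list(waitlist_size = 2286, ratio = 3,
                             strategies = names(paired$results)),
               seeds = list(pool = POOL_SEED, stream = STREAM_SEED),
               files = file.path(out_dir, c(
                 paste0("matchlist_", names(paired$results), ".tsv"),
                 "score_distributions.tsv")))

cat("\nScore distributions over", nrow(paired$results[[1]]$matches),
    "match pairs (identical streams):\n")
print(summary_tab, row.names = FALSE)
for (lab in names(paired$results)) {
  f <- table(paired$results[[lab]]$matches$stratum) /
    nrow(paired$results[[lab]]$matches)
  cat(sprintf("%s stratum frequencies: %s\n", lab,
              paste(names(f), sprintf("%.3f", f), collapse = ", ")))
}
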