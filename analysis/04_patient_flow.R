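#!/usr/bin/env Rscript
# Patient-flow accounting: who gains and who loses when allocation switches
# from waiting-time order to deliberate score minimisation? Pairs of
# simulations on identical streams, deliberately matching at DRB1 only, at
# DQB1 only, and at all five loci; flows are tabulated between baseline
# score quartiles (plus Waiting) and the same categories after deliberate
# matching.

suppressPackageStartupMessages(library(allocsim))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

POOL_SEED <- 1L
STREAM_SEED <- 101L

pool <- build_haplotype_pool(50, 30, 0.3, seed = POOL_SEED)
scorer <- make_scorer(pool)
streams <- generate_streams(pool, waitlist_size = 2286, ratio = 3,
                            seed = STREAM_SEED)

targets <- list(DRB1 = "DRB1", DQB1 = "DQB1", sum5 = hla_loci())
files <- character(0)
for (nm in names(targets)) {
  paired <- run_base_and_deliberate_paired(
    streams, list(strategy("base_case"),
                  strategy("deliberate", targets[[nm]])), scorer)
  fl <- patient_flow(paired, locus_or_sum = if (nm == "sum5") "sum5" else nm)
  f <- file.path(out_dir, paste0("patient_flow_", nm, ".tsv"))
  write_curves(flow_to_long(fl), f)
  files <- c(files, f)

  cat(sprintf("\n== deliberate matching at %s (n = %d tracked patients) ==\n",
              nm, fl$n))
  print(fl$counts)
  q4 <- fl$counts[nrow(fl$counts) - 1L, ]  # highest baseline quartile
  cat(sprintf("baseline Q4 patients: %d; of these %d end up Waiting and %d in Q1 under deliberate matching\n",
              sum(q4), q4[["Waiting"]], q4[["Q1"]]))
}

write_manifest(file.path(out_dir, "manifest_flow.json"),
               config = list(waitlist_size = 2286, ratio = 3,
                             objectives = names(targets)),
               seeds = list(pool = POOL_SEED, stream = STREAM_SEED),
               files = files)
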