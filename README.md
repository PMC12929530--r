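# allocsim

Simulation toolkit for a feasibility question in kidney transplantation:
if deceased-donor kidneys were deliberately steered to the ABO-identical
candidate with the **lowest molecular mismatch score**, instead of to the
longest-waiting one, how compatible could transplants become — and how does
the answer depend on waitlist size and donor supply?

The package is aimed at transplant immunogenetics and allocation-policy
researchers. It provides:

* a **synthetic cohort generator** — five-locus HLA haplotype pools with a
  skewed (few common, many rare) Dirichlet frequency profile, synthetic
  allele sequences (shared backbone + polymorphic sites), and ABO groups,
  so every downstream stage is testable without clinical data;
* a **pluggable mismatch scorer** — the per-locus score of a donor
  *d* and recipient *r* is

  `S_L(d, r) = #{ p in kmers_k(d_L) : p not in self_k(r), presented(p | r_DRB1) }`

  the number of unique k-mers (k = 9) from the donor's two alleles at locus
  *L* ∈ {A, B, C, DRB1, DQB1} that occur nowhere in the recipient's own ten
  allele sequences (self-peptidome subtraction) and are accepted by a
  presentation model in the context of the recipient's DRB1 pair; the
  five-locus sum `sum5 = Σ_L S_L` is classified into the usual clinical
  risk strata low [0,9), elevated [9,35), intermediate [35,90), high [90,∞).
  The default presenter is a deterministic keyed-hash surrogate with a
  calibrated acceptance rate; precomputed real scores can be loaded from
  TSV instead (`load_score_matrix()`);
* a **greedy allocation engine** — donors arrive in sequence, each offering
  two kidneys to ABO-identical candidates (lowest score wins under
  deliberate matching, waiting time under the base case and for ties), with
  two replenishment candidates entering per donor so the waitlist size
  stays constant;
* a **scenario runner and analytics** — waitlist-size × ratio grids with
  replicate means/SDs, cumulative probability and stratum curves with
  plateau detection, baseline-vs-deliberate patient-flow tables, and
  hard-to-match candidate detection from static score profiles.

## Worked example

```r
library(allocsim)

pool    <- build_haplotype_pool(n_haplotypes = 50, n_polymorphic_sites = 30,
                                concentration = 0.3, seed = 1)
scorer  <- make_scorer(pool)   # k = 9, calibrated surrogate presenter
streams <- generate_streams(pool, waitlist_size = 400, ratio = 3, seed = 7)

paired <- run_base_and_deliberate_paired(streams, scorer = scorer)
str(summarize_scores(paired$results$base_case$matches))
#> List of 5
#>  $ median          : int 77
#>  $ min             : int 0
#>  $ max             : int 112
#>  $ zero_probability: num 0.0451
#>  $ n               : int 266
str(summarize_scores(paired$results$deliberate_5LOCI$matches))
#> List of 5
#>  $ median          : int 15
#>  $ min             : int 0
#>  $ max             : int 62
#>  $ zero_probability: num 0.451
#>  $ n               : int 266
table(paired$results$base_case$matches$stratum)
#>          low     elevated intermediate         high
#>           12            9          169           76
table(paired$results$deliberate_5LOCI$matches$stratum)
#>          low     elevated intermediate         high
#>          120          104           42            0
```

A waitlist of 400 with ratio 3 yields 133 donors = 266 kidneys; both runs
consume identical donor/candidate streams. Under waiting-time allocation the
median five-locus mismatch sum is 77 and 29% of transplants fall in the
high-risk stratum (≥ 90); deliberately minimising the five-locus sum drops
the median to 15, multiplies the zero-score probability tenfold, and empties
the high-risk stratum — the central feasibility result, which strengthens
with larger waitlists (see `analysis/03_waitlist_curves.R`).

## Analysis workflow

The numbered scripts under `analysis/` run the full study on the default
synthetic population and write TSV tables (plus optional figures) under
`results/`:

1. `01_build_cohort.R` — pool + national-scale cohort tables;
2. `02_national_matching.R` — paired base-case vs deliberate run at
   W = 2,286, ratio 3 (762 donors, 1,524 kidneys); per-locus score
   distribution summaries;
3. `03_waitlist_curves.R` — grid over waitlist sizes 100–2,500 at ratio 3,
   stratum/threshold curves with replicate SDs and saturation points;
4. `04_patient_flow.R` — who gains and loses when the objective switches,
   matching at DRB1, DQB1, or all five loci;
5. `05_hard_to_match.R` — 1,150 × 261 static score profile and the flagged
   steep tail of the ordered median curve.

Each script prints its headline findings and writes a JSON manifest with
the seeds needed to reproduce its outputs exactly.

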