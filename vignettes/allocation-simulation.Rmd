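---
title: "Simulating molecular mismatch-guided kidney allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating molecular mismatch-guided kidney allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Deceased-donor kidneys are usually allocated by waiting time within ABO
blood-group identity; HLA compatibility plays little role in the ranking.
Molecular mismatch scores — counts of donor-derived peptides a recipient's
immune system can recognise as foreign — predict de novo donor-specific
antibody formation and graft outcomes, which raises a feasibility question:
if each kidney instead went to the ABO-identical candidate with the *lowest*
mismatch score, how compatible could transplants become, and how does that
depend on the size of the waitlist relative to the donor supply?

`allocsim` answers this with a discrete allocation simulation over synthetic
cohorts. Every stage is a tested package function; the numbered scripts under
`analysis/` are thin drivers that run the stages and write TSV tables under
`results/`.

## The allocation model

One replicate processes a donor stream against a waitlist of constant size
$W$:

* **Eligibility** is ABO identity (never mere compatibility), protecting
  blood-group O candidates.
* Each donor provides **two kidneys**, offered sequentially against the
  shrinking waitlist, and every offer is accepted.
* **Base-case** ranking is waiting time only (lowest arrival index), the
  queue-based status quo. **Deliberate** ranking gives each kidney to the
  eligible candidate minimising the mismatch score summed over a chosen
  locus set (one locus, a subset, or all five — the "5LOCI" objective);
  waiting time breaks score ties, candidate id breaks any residue (arrival
  indices are unique, so this last rule is only a determinism guarantee).
* After both kidneys, **two replenishment candidates** join the bottom of
  the list, so the waitlist size is constant whenever every kidney finds a
  recipient. A kidney with no ABO-identical candidate is recorded as
  unallocated and the run proceeds; each such kidney leaves one extra
  candidate waiting, and the engine asserts
  `waitlist size == W + unallocated kidneys` after every donor cycle.
* Calendar time is not modelled; the donor sequence is the clock. No
  sensitisation, paediatric priority, offer decline, or logistics are
  simulated — the design isolates the waitlist-size effect.

Paired comparisons (`run_base_and_deliberate_paired()`) run two strategies
on a single pre-generated stream object. All randomness is consumed when the
stream is generated, so the two runs see byte-identical donor and candidate
orders and differ only in selection logic.

## The mismatch score

The scorer is peptide-based, mirroring how indirect-recognition epitope
counts are constructed:

1. every allele sequence is decomposed into its unique 9-mers (`k` is
   configurable; 9 is the canonical class-II core length);
2. the donor's two alleles at the scored locus contribute their k-mer
   union;
3. k-mers occurring anywhere in the recipient's **own ten allele
   sequences across all five loci** are removed (self-peptidome
   subtraction — "non-self" is defined against the whole HLA complement,
   not just the scored locus);
4. the surviving peptides are filtered by a **presenter model** in the
   context of the recipient's DRB1 allele pair, and the score is the count
   of unique accepted peptides. The five-locus sum (`sum5`) adds the locus
   scores.

Real presentation predictors are neural-network binding models tied to
curated allele databases. The shipped surrogate replaces that step with a
deterministic keyed-hash decision on (peptide, DRB1 pair): a pure function
of its string inputs that accepts a calibrated fraction
(`default_acceptance_rate()`, 0.16) of queries. This keeps the scorer
seed-free, dependency-free and exactly reproducible, while preserving the
structural properties that matter for allocation: identical genotypes score
zero, moving a donor allele toward the recipient never raises a score, and
scores scale with the number of polymorphic differences. Users with real
per-pair scores can bypass the surrogate entirely via
`load_score_matrix()`; the five-locus sum is always recomputed, never read.

Summed scores are classified into the four clinical risk strata in common
use: low $[0,9)$, elevated $[9,35)$, intermediate $[35,90)$, high
$[90,\infty)$.

## The synthetic cohort generator

`build_haplotype_pool()` emulates the statistical structure of a real
transplant population without any external data:

* **Haplotype frequencies** are symmetric-Dirichlet draws (concentration
  0.3), sorted descending: a few common haplotypes and a long rare tail,
  the profile HLA shows in practice and the source of a hard-to-match tail.
* **Sequences** at a locus share a random backbone and differ only at a
  designated set of polymorphic positions (30 per locus by default, four
  possible residues per site), so distinct alleles always differ by
  non-self peptides while sharing most of their peptidome.
* **Genotypes** are two independent haplotype draws (Hardy–Weinberg at the
  haplotype level) — the simplest model consistent with resampling
  candidates from a population distribution; linkage disequilibrium beyond
  the haplotype structure itself is not modelled.
* **ABO groups** default to an approximate Canadian distribution
  (O 0.46, A 0.42, B 0.09, AB 0.03), configurable.

The default study conditions are a pool of 50 haplotypes with
`n_alleles_per_locus = 17` (a third of the haplotype count), sequence length
72, `k = 9` and acceptance rate 0.16. These were calibrated once so that
**base-case** allocation at the national scale (waitlist 2,286,
candidate-to-donor ratio 3) reproduces the published shape of the score
distributions: per-locus medians of 13–15 (published range 13–20), a
five-locus sum median of 76–77 (published 78), and per-locus zero-score
fractions of 5–8% (published < 8%).

What the generator does **not** reproduce: real allele sequences, real
haplotype linkage, population substructure, and — importantly — the true
genotype diversity of a large human cohort. With 50 haplotypes, exact or
near-exact genotype coincidences are far more common than in reality, so
under *deliberate* matching the zero-score fractions are much higher than a
real cohort would show. Deliberate-scenario results should therefore be read
as directions and orderings (deliberate dominates base-case; low-score
probability grows with waitlist size; the high stratum empties), not as
calibrated magnitudes. Passing tests demonstrate the engine's correctness
and these qualitative claims, not point predictions for any real program.

## Scenario grids and aggregation

`run_grid()` crosses waitlist sizes (default
100–2,500, covering provincial through national scales) with ratios
(default 2, 2.6, 3, 4), strategies and replicates. Per-cell stream seeds
derive from the master seed by hashing `(W, ratio, replicate)` — the
strategy is deliberately excluded so strategies are paired on identical
streams, and adding cells never perturbs existing ones. Curves report the
mean and standard deviation **across replicates** of cumulative
probabilities or stratum frequencies (`aggregate_curves()`), the error-bar
convention of repeated-simulation studies. `saturation_point()`
operationalises a curve's "inflection point" as plateau onset: the smallest
waitlist size from which every subsequent step changes by less than 1% (by
default) of the curve's range; a curve that never settles returns the
largest size with `saturated = FALSE`.

## Analytics conventions

* **Medians** are lower-middle order statistics (for even counts, the lower
  of the two central values), keeping integer scores integer.
* **Quartile categories** for the patient-flow analysis cut baseline match
  scores at type-1 (order-statistic) 25/50/75 percentiles into
  closed-right intervals, so integer score multisets reproduce printed
  conventions like "Q1 = 0–7, Q2 = 8–13, Q3 = 14–20, Q4 ≥ 21"; a trailing
  empty category is dropped and fully degenerate distributions collapse
  with a warning. Patients untransplanted at the end of a run form the
  `Waiting` category; flows between baseline and deliberate categories are
  tabulated over every candidate who entered the (identical) streams.
* **Hard-to-match detection** orders patients by their median score
  against all ABO-identical donors, smooths the median curve with a ±5
  centred moving average (window truncated at the edges — there is no data
  to pad with), takes first differences of the smoothed series as a
  discrete slope, and flags differences above 0.2% of the maximum median.
  The threshold is relative, so rescaling all scores leaves the flagged set
  unchanged. Patients with no ABO-identical donor are reported unscorable
  and excluded.

## Problem sizes used in the shipped analyses and tests

The analysis scripts run the national replicate (W = 2,286, ratio 3, 762
donors) for distribution and flow analyses, a 1,150 × 261 static
matchability profile, and the waitlist grid at ratio 3 with 3 replicates —
enough for stable means with an SD estimate while keeping each script in
the minutes range. The test suite exercises the same engine on small
instances against brute-force oracles (exhaustive per-kidney search,
string-level k-mer enumeration) and runs the study-level property checks at
W = 500 (10 paired replicates) and the full size grid at 2 replicates.
Replicate counts are a precision choice, not a model parameter: means are
stable well below 10 replicates for every property asserted.

## Known limitations

* The surrogate presenter is unweighted (no binding-promiscuity ranking)
  and its scores are not comparable in magnitude to any proprietary
  predictor's output; only score *structure* is preserved.
* Synthetic diversity understates real cohort diversity (see above).
* The one-year, constant-waitlist horizon underrepresents candidates who
  wait across many cycles; hard-to-match estimates from allocation runs
  are therefore complemented by the static (allocation-free) profile.
* Base-case ranking ignores the practice of using HLA to break ties among
  equally ranked candidates: with unique arrival indices such ties cannot
  occur in the model.
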