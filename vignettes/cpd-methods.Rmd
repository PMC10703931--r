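---
title: "Methods: enriching and analysing consumer purchase data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: enriching and analysing consumer purchase data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpdenrich)
```

## The problem

A digital receipt line carries an item number, a terse free-text name
("apples 6-pack"), a price, a quantity and a timestamp. To use consumer
purchase data (CPD) for exposure assessment, each purchased product must
be linked to structured product information — nutrients, ingredients,
chemical risk — held in external databases, and the resulting individual
purchase profiles must be understood as *estimates* whose quality depends
on how many of a person's retailers actually contribute data. `cpdenrich`
implements both halves: the enrichment pipeline and the coverage
analysis, plus a synthetic cohort with known ground truth to validate
them.

## Enrichment pipeline

Unique products are identified by the raw *(item number, item name)*
pair: the same short code can be reused by different retailers for
different supplier-internal articles, while a printed name alone is not
unique either.

**Item-number gate.** Non-digits are stripped. Strings with fewer than 3
or more than 14 digits are excluded from barcode handling (flag
`excluded_item_number`); their names can still be matched generically.
Digit counts 8, 12, 13 and 14 are GTIN candidates: 8- and 12-digit codes
are left-padded with zeros to 13 digits, and a 14-digit code must begin
with a zero, which is dropped. Candidates are validated by the GTIN
mod-10 check digit (alternating weights 1, 3 from the left over the first
twelve digits, check digit the complement of the weighted sum modulo 10).
A failing check digit does not discard the row: receipts legitimately
contain supplier-generated internal codes, so such codes — together with
digit counts 3–7 and 9–11 — are kept as internal codes eligible only for
name matching.

**Specific (barcode) matching.** Valid GTINs are looked up in up to three
barcode-keyed databases with priority *GS1-like > chemical-risk-like >
crowd-sourced-like*. The highest-priority hit labels the match; the other
hits merge in secondary annotations (ingredients, risk score, nutrients
missing from the primary source). Matched products are additionally
assigned a generic category by scoring their *database* product name, so
that a brand-level and a category-average nutrient value coexist for the
concordance analysis.

**Name preprocessing.** Names are lower-cased; unit expressions (weight,
volume, pack count), organic markers and origin words are parsed into
structured attributes and removed; configurable abbreviations are
expanded and stopwords dropped; bare numbers are discarded. Token order
is preserved, and the space-joined token string is what the patterns see.
An empty result is allowed and simply cannot match.

**Regex scoring.** The generic database carries six regular-expression
columns per mutually exclusive category: brand, product type, specific
descriptor, broad/generic descriptor, flavor, and fat content. Patterns
are anchored with word boundaries, so "partial word matching" means token
matching, not substring matching. The score of a category is the weighted
sum of its pattern hits with default weights type 4, specific 3, brand 2,
generic 1, flavor 1, fat 1. The weights are deliberately simple and
fully configurable (`enrich_config()`): a type hit alone (4) reaches the
default acceptance threshold, a fat or flavor hit breaks ties between
sibling categories (5 vs 4), and a broad descriptor alone (1) never
suffices.

**Thresholds and flags.** The best candidate is accepted iff its score is
at least `min_score` (default 4). A winning margin below `min_margin`
(default 1) keeps the match but flags it `ambiguous`; a win carried by
generic-descriptor evidence only is flagged `greedy`; a best score below
threshold leaves the product `unmatched` (`below_threshold`). Ties in
score are broken lexicographically by category id, so ranking is
deterministic. All flagged products are exported by
`export_review_queue()` sorted by purchase volume, mirroring an
iterative manual-review workflow in which word stems are refined
highest-impact first. The flag semantics follow the operational reading
that an ambiguous winner is *kept and queued* rather than dropped:
review, not rejection, is the remedy for ambiguity.

## Nutrient concordance

For every product with both an accepted generic category and a branded
(GS1-like) record, and for each nutrient reported by both sources per
100 g, the package computes the modified relative difference
`|a − b| / max(a, b)`. It is symmetric, scale-invariant and bounded in
[0, 1]; `d(0, b) = 1` for `b > 0`, and `d(0, 0) = 0` by convention
(identical values should never register a difference; the zero case is
otherwise undefined). Non-food custom categories are excluded — a
category-average nutrient of 0 for, say, detergent is a schema
placeholder, not information. Summaries are cumulative distributions
(per unique product, or weighted by purchase volume) and per-category
medians. No serving-size reconciliation is attempted: both sides are
per 100 g by construction.

## Retailer-coverage analysis

Let `p_g` be the proportion of a participant's purchases falling in food
product group `g` (of the top-*K* groups cohort-wide, default K = 20),
where purchases are weighted by units bought (`quantity`; line-count and
spend weighting are options). For a retailer subset `S`, `p_g(S)` uses
only lines from retailers in `S`, with the participant's *total* lines in
`S` as denominator. Reported are the percentage-point difference
`100·(p_g(S) − p_g)` and the relative difference
`100·(p_g(S) − p_g)/p_g` (undefined when `p_g = 0`; exactly −100% when a
group present in full data is absent from the subset). Default subsets
are the ten largest retailers individually and every cumulative prefix of
the ranking by total purchases — the natural reading of "cumulatively
combined". Both profiles run through the identical code path, so the
full-set subset yields exact binary zeros, not floating-point residue.

Participants with zero purchases inside a subset are flagged
(`zero_subset_flag`), retained in the output, and excluded from
dispersion and percentile pooling — they carry no profile to compare.
Percentile summaries pool relative differences over participant × group
cells (dropping `p_g = 0` cells) and use linear interpolation
(`stats::quantile`, type 7). Dispersion is the SD across participants of
the percentage-point differences, per group and pooled.

## The synthetic cohort

The generator (`cohort_config()` + `generate_cohort()`) produces a
catalog, databases and receipt streams with known truth. What it
emulates, and the defaults chosen:

* **Scale.** 200 participants, 34 retailers, 24 months, 2000 products —
  the per-stage problem sizes used throughout the package's own test
  runs. Generation is vectorized; a cohort of this size is a few hundred
  thousand lines.
* **Product popularity.** Zipf weights `rank^(−s)` with `s = 1.1`, the
  classic skew regime for purchase frequencies; the share of lines from
  the top-N products rises with `s` (a tested property).
* **Shopping intensity.** 8.4 receipts per active participant-month and
  on average ~9.8 lines per receipt, typical of a grocery-dominated
  receipt stream; a participant-month is entirely inactive with
  probability 0.1 (card churn, holidays).
* **Preferences and loyalty.** Per-participant Dirichlet draws: group
  preferences over 20 food groups (plus tobacco-like, cleaning, dental
  non-food groups at lower base weight) and retailer loyalty over the 34
  retailers (concentration 0.5, giving realistic many-but-skewed retailer
  use). At extreme concentrations the gamma draws may underflow; an
  all-zero row degenerates to a one-hot vector, which is the
  distributional limit.
* **Assortments.** Each retailer carries a popularity-weighted 80% of the
  catalog; the tobacco-like group is carried by only ~30% of retailers.
  This reproduces the misclassification mechanism where a single-retailer
  view shows an apparent non-user of a product group sold elsewhere.
* **Database coverage.** Each specific database holds a
  popularity-weighted random fraction of the catalog (defaults 0.5 / 0.2
  / 0.3), so volume-weighted match coverage exceeds unique-product
  coverage. Brand-level nutrients are the category average times
  log-normal noise `exp(N(0, σ))` with σ = 0.39: the median modified
  relative difference of such a pair is `1 − exp(−0.6745·σ) ≈ 0.23`,
  the concordance level reported for real generic-vs-branded energy
  comparisons. The crowd-sourced database loses each nutrient with
  probability 0.2.
* **Receipt names.** A retailer prints one fixed display name per
  product, corrupted with probability 0.1 by one of: vowel-dropping
  abbreviation, truncation to 20 characters, junk-token injection, case
  mangling. Corruption is per (product, retailer) rather than per line —
  receipts are machine-printed, so a given retailer misprints a product
  *consistently*; per-line corruption would also make unique-product
  identity meaningless. 20% of products print a supplier-internal code
  instead of their GTIN and are reachable only by name.

One global seed drives the catalog, database and receipt stages through
fixed offsets, so regenerating receipts under a new downstream setting
does not disturb the catalog stream. Identical configurations produce
byte-identical output files.

What the generator does **not** emulate: demographic structure, price
levels beyond a plausible log-normal, household composition, seasonal or
trend dynamics, assortment geography, and real receipt-name vocabulary
(names are built from a synthetic token grammar the generic patterns are
generated from). Passing tests therefore demonstrate algorithmic
correctness and calibration under the stated statistical structure — not
performance on real Danish receipt text, where pattern curation is the
dominant effort.

## Numerical and design choices

* Currency is held internally as integer øre (1/100 DKK); files carry
  DKK with two decimals. Spend summaries are exact and
  order-independent.
* Timestamps are ISO-8601, timezone-naive local purchase time; analyses
  use calendar-month granularity only. Rate denominators count whole
  calendar months from first to last receipt inclusive; inactive months
  are whole months strictly inside that window with no receipts.
* Quartiles and percentiles use linear interpolation (type 7), the R
  default, stated wherever reported.
* Degenerate inputs are explicit: empty purchase tables summarize to
  empty results, an empty comparison set yields an empty CDF, a
  single-participant SD is `NA`, and a name that cleans to nothing is
  simply unmatched.
* The scoring weights and thresholds are not field standards; they are
  package defaults with documented semantics, expected to be tuned per
  deployment through `enrich_config()`.

## Limitations

The regex matcher is intentionally transparent rather than clever: no
embeddings, no fuzzy string distance, no learned ranking. Its accuracy on
real data is bounded by pattern curation, which the review-queue loop is
designed to drive. The coverage analysis treats the all-retailer profile
as the reference; purchases outside all participating retailers remain
invisible by construction. Nutrient concordance compares per-100 g values
only and cannot separate genuine brand deviation from category
misassignment — the evaluation module quantifies the latter on synthetic
truth, where the two are distinguishable.
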