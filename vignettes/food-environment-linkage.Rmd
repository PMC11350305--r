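---
title: "Linking and summarising local and online food environments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking and summarising local and online food environments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodscape)
library(dplyr)
```

## The problem

Online food delivery services detach food access from physical proximity:
an outlet 3 km away — three times the conventional 1 km "local
neighbourhood" radius — can deliver into a suburb and effectively join its
food environment. Surveillance of this *hybrid* food environment needs
two scraped listing sources (a business directory for the physical, local
environment; a delivery platform for the online one), linked record by
record so that an outlet present in both is counted once. `foodscape`
implements the full chain — simulation of the scraped inputs, cleaning,
deterministic record linkage, healthfulness-oriented categorisation, and
geographic summaries — with every rule specified tightly enough to be
property-tested.

## Normalisation rules and their edge cases

Both sources pass through the same scrub: ASCII-fold diacritics, spell
out `&` as "and", lowercase, delete non-alphanumeric characters (no space
is inserted in their place), collapse whitespace. Three choices here were
genuinely open and are fixed as follows:

- **Diacritics** are folded before the alphanumeric filter ("café" →
  "cafe"); otherwise accented names can never match their plain-ASCII
  twins.
- **`&` becomes "and"** before punctuation stripping, since "Fish &
  Chips" and "Fish and Chips" are the same business in different
  listings; deleting `&` silently would leave "fish chips".
- **Numerals are kept** ("7eleven") — only non-alphanumerics are removed.

Because specials are deleted rather than replaced by spaces,
"Brighton-Le-Sands" normalises to `brightonlesands` while "Brighton Le
Sands" normalises to `brighton le sands`: the two spellings of one suburb
remain unequal. This is a deliberate, documented failure mode of this
family of cleaning rules (it mirrors how such pipelines behave on real
listings); the unmatched-outlet audit classifies exactly this pattern as
`suburb_inconsistency` instead of hiding it.

Outlet names additionally lose whole-word occurrences of
shopping-centre/building names, petrol-station brands, suburb names, the
city token, and state tokens — in that order (the order is unstated in
the source rules; centre-before-suburb matters when a centre name
contains a suburb word, and the chosen order is fixed and tested).
Addresses lose embedded suburb/postcode/state tokens and leading
"shop/unit/level/kiosk/suite N" tokens, then split into a leading number
token, street name, and a trailing street type drawn from a closed
vocabulary with an abbreviation map ("st" → "street", "rd" → "road") —
the vocabulary is configuration because listing sources never define it.

Missing-field imputation runs after statistics are computed over the
*combined* dataset: a missing suburb with a known postcode takes the
modal suburb for that postcode (ties broken lexicographically, so the
result is deterministic); both missing become `"empty"`/`"0000"`; a
missing street number becomes the sentinel `"12345"`. A postcode that is
present but unseen in the statistics keeps its value with suburb
`"empty"`. Symmetrically, a missing postcode with a known suburb takes
the suburb's modal postcode; this is the one place the rules are extended
beyond their source, and it can only fire when the suburb was observed
with some postcode. Every normalisation operation is idempotent
(property-tested under fuzzing) and never touches `source` or
`source_id`.

## The matching cascade

Matching proceeds through fifteen ordered steps, each looser than the
last, with matched rows leaving both pools between steps; the recorded
step is therefore the first step whose criteria a pair satisfies.

| steps | criteria |
|-------|----------|
| 1–9   | exact name equality plus progressively fewer address fields |
| 10–11 | address-field equality, name ratio ≥ 83 |
| 12–15 | one address field, plus dual name *and* address thresholds |
| final | dual name *and* address thresholds only |

Two similarity scales are used side by side, as is conventional in this
kind of listing linkage: a Jaro similarity on [0, 1] and a normalised
Levenshtein ratio on [0, 100], defined as `100 * (1 − d / max(|a|, |b|))`.
Equal strings score (1, 100); an empty string against a non-empty one
scores (0, 0); two empty strings count as equal. The 83 threshold is
evaluated on the ratio scale (it is quoted as a percentage alongside the
0–100 scale); the dual thresholds default to Jaro ≥ 0.90 and ratio ≥ 90
applied to *both* the name and the reassembled
`number street-name street-type` address string.

Three aspects of the cascade are under-determined by its narrative
description and are fixed here as design choices:

1. **One-to-one greedy matching.** Nothing says matching is one-to-one,
   but matched-count semantics imply each outlet pairs once. Within a
   step, candidate pairs are taken in stable order of (online id, name
   ratio descending, local id) and accepted when both sides are free.
   This makes the match *set* invariant to input row order
   (property-tested), and ties between equally eligible locals resolve
   first by higher name similarity, then by id.
2. **Placement of the dual-threshold similarity pass.** It is run once,
   after step 15, as a final pass over the remaining pools (the narrative
   lists it after the step table).
3. **Steps 12–15 are similarity-constrained.** Read literally, "same
   postcode" alone would match nearly everything; the steps therefore
   additionally require the dual name+address thresholds. Without this, a
   one-to-one greedy pass over same-postcode pairs would produce absurd
   matches dominated by id order.

The implementation is verified against a brute-force oracle — an
independent matcher that tests every (online, local) pair against every
step in order using matrix comparisons, `utils::adist`, and a pure-R
Jaro — on synthetic instances up to ~500 outlets per side, and against
truth maps on zero-noise data (precision = recall = 1 with every pair at
step 1).

## Categorisation

A *franchise* is a brand with strictly more than 10 distinct physical
locations (distinct number/street/suburb triples) across both datasets,
matched pairs counted once — deliberately more inclusive than the
20-location menu-labelling definition so that incomplete listings do not
demote a true franchise. The boundary is strict: 11 locations qualify, 10
do not (boundary-tested both ways).

Non-franchise outlets are scored against a descriptor lexicon: every
descriptor carries a base weight of 2 toward its mapped category,
prominent generic tags are up-weighted to 4 ("fast food") and niche tags
down-weighted to 1 ("japanese set item"), and multi-category descriptors
("grocer", "hotel", "restaurant") contribute to each mapped category. The
outlet takes the category with the highest cumulative score. Ties go to
the category that is *rarer* in the global frequency table — a deliberate
counterweight to the dominance of restaurants/cafes — and the frequency
table is computed once from the outlets with a unique maximal score (a
provisional pass), then frozen; the source rules do not say when
frequencies are measured, and freezing makes assignment order-free. A
residual tie falls back to the fixed category order of
`main_categories()`. The shipped lexicon contains every mapping the
source rules state explicitly plus the descriptors the synthetic
generator emits; real deployments extend it via configuration, since the
full multi-hundred-descriptor inventory of any particular platform is
not reproducible here.

Matched local outlets inherit their online twin's category
(`assignment_source = "transferred"`); franchise brands are subtyped by
lexicon lookup with a keyword-precedence fallback (dessert, then bakery,
then juice, then healthy, else unhealthy). Self-reported descriptors can
be misleading (a fried-chicken chain may tag itself "Healthy"); no
correction is attempted, and the keyword precedence at least prevents a
dessert chain's stray "healthy" tag from flipping its subtype.

## Environments and summary statistics

The local view of a unit (postcode or region) holds outlets physically
located there; the online view holds unique platform outlets able to
deliver there (membership follows the delivery rows, not physical
location); the hybrid view is their union with matched pairs collapsed
onto the local id. Outlets with imputed postcode `"0000"` live in a
reserved `"unknown"` unit rather than being dropped, so per-scope totals
are conserved. Note the two online totals differ by construction: the
per-unit online counts sum to more than the unique platform-outlet total
(delivery duplication), and regional hybrid counts can double-count an
outlet that delivers into several regions, so the state-wide unique
hybrid total (`environment_totals()`) is *not* the sum of regional
hybrid counts; both views are reported.

All printed percentages use **round-half-up** (102.5 → 103, never
banker's rounding): integer percents for the percent-change statistic
`100 × n_hybrid / n_local`, one decimal for category shares. This
convention was validated cell-by-cell against a published regional
summary table of this statistic, which pins it uniquely. Accessibility
(`100 × n_online / n_local`) is exposed at both precisions — one decimal
and integer — because published tables mix the two (83.5 alongside 216);
the renderer chooses. Density per postcode is min-max scaled to [0, 1];
when all postcodes tie, density is defined as 1.

## The synthetic data generator

The generator defines the study conditions under which the pipeline's
properties are tested; it emulates the *structure* of scraped listing
data, not any particular city:

- **Geography**: regions of suburbs on a deterministic planar grid
  (spacing 0.02°, roughly 2 km), consecutive suburb pairs sharing a
  4-digit postcode (so modal-suburb imputation has real work to do),
  each postcode in exactly one region; urban regions carry larger
  populations. Distances use the equirectangular approximation
  `d = R·sqrt(Δφ² + (cos φ̄·Δλ)²)`, R = 6371 km, whose error at suburb
  scales is irrelevant to the pipeline logic and which keeps coverage
  checks reproducible by hand.
- **Universe**: outlets are allocated to regions by population (largest
  remainder); franchise brands are placed first with fixed location
  counts, each brand in distinct suburbs; independent outlets draw a
  true category from a mix dominated by restaurants/cafes (~47%) as
  state-wide directory data are, with descriptors diagnostic of the
  category. Independent names are unique by construction and franchise
  locations never collide on (name, street, suburb), so zero-noise
  linkage has a unique correct answer — the condition under which
  recall = 1 is asserted.
- **Delivery**: platform participation is Bernoulli with urban
  probability 0.6 versus rural 0.1 (the urban skew of delivery
  platforms), and each participant delivers to every suburb whose
  midpoint lies within its radius, drawn uniformly from 1–6 km around
  the ~3 km scale typical of delivery trips. Delivery-suburb lists are
  derived from the radius, never sampled, so row-count oracles are
  exact; an outlet whose radius covers no midpoint still lists its home
  suburb once.
- **Noise**: per-row operators — missing suburbs/postcodes/street
  numbers, centre prefixes ("Shop 12, Westfield, …"), name decoration
  with suburb/city/state tokens, token-boundary punctuation, case
  shuffling — at rates of a few percent each (defaults in
  `noise_config()`), plus non-food and permanently-closed contaminant
  rows injected into the local view at 8% and 5%. Every draw comes from
  a substream keyed by (seed, row index), so outputs are byte-identical
  under a fixed seed and insertion order cannot change noise outcomes.

What the generator does *not* emulate — and hence what green tests do not
certify about real scraped data: genuinely misspelled names, geocoding
errors, multi-word suburb name variants beyond the space/no-space
pattern, outlets listed on several platforms, partial scrapes, and
listing churn between scrape dates. The test-suite problem sizes (a
~500-outlet instance for oracle equivalence, 5 000 outlets for
parameter recovery, 10 000 for participation-rate calibration) were
chosen as the smallest sizes at which the statistical checks have
negligible flake probability (3-standard-error bounds).

## Numerical and degenerate-input conventions

- Similarity of two empty strings is (1, 100); empty versus non-empty is
  (0, 0); `NA` propagates.
- Empty inputs to the cascade yield empty match sets, not errors;
  duplicate ids are a hard error (upstream dedupe was violated).
- A name that is empty after token stripping is kept with
  `name_empty = TRUE` for manual review rather than dropped.
- Postcodes that are not exactly four digits are treated as missing at
  normalisation and surface in the audit as `malformed_field`.
- All randomness is driven by one integer seed; derived substream seeds
  stay below 2³¹.

## Limitations

The pipeline inherits the epistemics of its sources: directory and
platform listings are self-reported, categories are coarse (half of all
outlets land in restaurants/cafes), and a single delivery platform
understates the online environment. The linkage cascade is deterministic
rather than probabilistic (no Fellegi–Sunter model) — by design, since
the method it implements is a stepwise rule cascade — so its error
profile is driven entirely by the normalisation rules, and the audit
report exists precisely to make those residual errors visible.
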