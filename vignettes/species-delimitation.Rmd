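---
title: "Morphometric species delimitation in Kapentagyrus: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric species delimitation in Kapentagyrus: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kapentagyrus)
```

## The problem

Gill monogeneans of *Kapentagyrus* (Dactylogyridae) infect Afrotropical
freshwater clupeids (tribe Pellonulini). The species are morphologically
very similar; what separates them is the morphometrics of the sclerotized
haptor — anchor, bar and hook lengths, and especially the proportions
between the inner and outer anchor roots and between anchor and hook
lengths — together with the host species. This package makes that
delimitation workflow executable: a measurement data model, the published
reference summaries, the dichotomous identification key as a decision tree,
quantitative-parasitology statistics, the multivariate ordination protocol,
and a specimen simulator for end-to-end testing.

## Measurement model and diagnostic features

A specimen carries up to 21 haptoral and 2 genital lengths (µm): five
lengths per anchor (total length, length to notch, inner and outer root
length, point length), branch length and maximum width per transversal bar,
hook pairs I–VII, and the copulatory tube and accessory piece axial
lengths. Missingness is a first-class state — mounted museum material often
lacks measurements (hook pair VII most of all) — and every derived quantity
propagates it; nothing is silently zero-filled.

Diagnostic features are per-specimen ratios (inner/outer root of each
anchor, inner root over hook pair I, dorsal length to notch over hook I,
dorsal bar branch over hook I). The reference tables report the *mean of
per-specimen ratios*, which differs from the ratio of means (e.g. a
printed mean proportion of 3.2 against 16.0/4.9 ≈ 3.27 for the
corresponding mean lengths); the package computes ratios per specimen and
aggregates afterwards, and `check_proportions()` reports where the two
conventions drift apart in the embedded tables. Units are µm throughout;
there is no conversion layer.

## The identification key as a decision tree

`kapentagyrus_key()` builds the 13-couplet key with 14 terminal species
spanning 11 host species. Each lead is a conjunction of atomic conditions
(measurement thresholds, ratio thresholds, the accessory-piece loop side,
one qualitative root-shape character, host membership). Build-time
assertions check the graph: single root, acyclic, all terminals reachable.

Evaluation is three-valued. A condition on a missing operand is *unknown*;
a lead is the Kleene conjunction of its conditions. At a couplet, a lead is
taken when it alone is true, or when its sibling alone is definitively
false (the key is a dichotomy, so a definitively failed lead forces the
other). Otherwise — both true, both false, or unresolvable — both leads are
explored, candidate sets are unioned, and a note records why. Three design
points deserve mention:

* **Boundary ties.** Some couplets split as "< 19 µm" versus "> 19 µm",
  leaving exactly 19 undefined. A value on such a boundary makes both leads
  false: the couplet is undecided, both branches are explored and the tie
  is flagged, rather than inventing a tie-break the key does not state.
* **The qualitative character.** Couplet 1 also asks for "broad inner
  anchor roots", which has no numeric definition. It is an optional boolean
  on the record; when unscored, the quantitative conditions alone decide.
* **Host use.** Two couplets are host-based, so host-aware identification
  is the default; terminal candidates are additionally filtered against the
  hosts each species is recorded from. If that filter would empty the
  candidate set, it is not applied and a note surfaces the conflict — a
  non-empty answer with an explicit warning is more useful to a
  taxonomist than an empty one. A host-free mode treats host couplets as
  undecided.

The key ships in two modes. `strict` routes exactly as printed. The
printed key, however, conflicts with the species descriptions in three
places: couplet 11 sends accessory-piece-right worms to *K. rochetteae*
although the descriptions give that species' loop from the left (and
*K. bisthoveni*'s from the right); the table means of *K. boegeri* put its
dorsal inner root/hook I ratio below 1, on the opposite side of couplet 10
from where the key resolves the species; and *K. chochamandai* ex
*Potamothrissa acutirostris* has a ventral length to notch of 18.5 µm,
conflicting with the "> 19 µm" lead that names it. `annotated` mode routes
identically but emits warnings at those couplets; no silently "corrected"
key is fabricated.

`validate_key()` routes the mean reference specimen of every embedded
profile through the key:

```{r validate}
v <- validate_key()
v[, c("species", "candidates", "own_terminal_recovered")]
attr(v, "exceptions")
```

Eleven of twelve profiles recover their own terminal; the exceptions are
exactly the three documented inconsistencies. *K. hahni* has no published
dorsal-anchor measurements, so couplet 8 cannot be decided for it and its
mean specimen legitimately returns {*K. verbisti*, *K. hahni*} — its own
terminal among them.

## Infection statistics

`summarize_infection()` implements the standard quantitative-parasitology
definitions: prevalence = infected/examined, mean intensity =
worms/infected (undefined when nothing is infected), mean abundance =
worms/examined. Counts are summed exactly and divided once; rounding (half
away from zero, one decimal — the convention under which 11/8 prints as
1.4) is display-only. Worm counts that the source states only as a range
with a printed intensity are stored unresolved: they expose the number of
infected hosts and the printed intensity but refuse a per-host summary
rather than fabricate a vector. Two fixture cells disagree between the
survey table and the infection paragraphs (11 vs 10 hosts at Lake Mweru;
9 vs 8 at Manyanga); the survey table is canonical, and the printed
intensities are unaffected because intensity does not involve the examined
count.

## Multivariate protocol

`prepare_matrix()` assembles the 20-parameter haptoral matrix (hook pair
VII excluded for its missing-data load), drops variables and then
specimens with more than 50 % missing data (threshold configurable), and
mean-imputes residual cells, logging every imputation. The original
protocol does not state how residual missing cells entered its analyses,
nor its NMDS distance; both are explicit configuration here rather than
silent guesses. PCA (`run_pca()`) z-scores columns and eigendecomposes,
with a deterministic sign convention (largest-magnitude loading positive);
"autotransformation" is software-specific, and for same-unit morphometric
lengths column standardization is the sensible reading — a no-transform
switch exists. NMDS (`run_nmds()`) uses Euclidean distance on the
standardized matrix by default (configurable to community-ecology
dissimilarities), multiple seeded random starts, best-stress configuration
returned.

The published first-two-axes variance shares were computed from the raw
per-specimen appendix measurements, which are an optional external input
that is not shipped; with a raw table supplied in the specimen CSV dialect
the same pipeline reproduces that analysis, and the match can only be
approximate because the original imputation details are unstated.

## The specimen simulator

The reference tables publish only (min, mean, max, n) per parameter, so
the generator draws each parameter from a normal truncated to the printed
[min, max], with sd = *f*·(max − min), default *f* = 0.25 — the printed
range then spans roughly four standard deviations, a common reading of a
range report at these sample sizes. Two numerical points:

* **Moment matching.** Plain truncation of a normal centred on the printed
  mean biases the post-truncation mean whenever the mean sits off-centre in
  the range (for one ventral-anchor cell the bias would be ≈ 0.2 µm). The
  generator therefore solves for the pre-truncation location (closed-form
  truncated-normal mean, Gauss–Hermite quadrature over the latent size
  factor, `uniroot`) so that the marginal mean equals the printed mean. A
  printed mean lying exactly on a range bound cannot be matched by any
  finite location; the nearest achievable location is used.
* **Correlation.** A single per-specimen latent size factor shared by all
  length parameters induces allometric correlation ρ (default 0.5 — no
  covariance data are published, so ρ is an explicit knob). Ratios are
  never sampled; operands are sampled and ratios computed, and coverage of
  the printed proportion ranges is reported, not enforced.

Single-value cells reproduce verbatim; parameters without any printed
summary are emitted missing with a warning; missingness (default 5 % per
parameter, 50 % for hook pair VII) is applied after sampling. Because
marginal ranges of length-to-notch/point can overlap an anchor total's
range, independent draws are reconciled by capping those lengths at the
specimen's sampled total, which keeps every value inside its printed range.
Survey simulation is independent per host with zero-truncated Poisson
intensities.

What the simulator does *not* emulate: fixation-method size effects, real
measurement error structure, within-population allometry beyond a single
size factor, or any multimodality. Passing recovery tests on simulated
data therefore shows that the key and the printed ranges are mutually
consistent — not that field identification reaches the same accuracy.

## Recovery assessment and its eligibility rule

`assess_recovery()` simulates specimens per species (no missing data, host
known) and asks how often the key returns the generating species as sole
candidate. A species is *range-recoverable* when every couplet on its
reference path is decided to a unique lead for the whole printed [min,
max] box (`key_recoverable_species()`; printed proportion rows are used
for ratio conditions where available, otherwise the interval implied by the
operand ranges). Seven species are range-recoverable — *K. voreli*,
*K. marispastoris*, *K. parisellei*, *K. pellonulae*, *K. hugei*,
*K. verbisti*, *K. chochamandai* — and achieve ≥ 99 % accuracy at 1000
simulated specimens per species. The rest are exempt with stated reasons:
*K. sefcae*'s ventral length-to-notch range (18.2–33.3) straddles couplet
1's 24 µm threshold; *K. hahni* lacks dorsal-anchor summaries; and
*K. bisthoveni*, *K. boegeri* and *K. rochetteae* sit on the documented
key inconsistencies. Slightly sub-100 % accuracy for the recoverable
ratio-routed species is expected: sampled operands can produce ratios just
outside the printed proportion ranges.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds; identical configurations
give byte-identical outputs. The shipped tests use 1000 simulated
specimens per species for recovery (binomial error < 1 % at the 95 %
bound), 2000 draws for mean-recovery checks, and 30 specimens per species
for ordination separation — sizes at which the asserted stochastic bounds
hold with large margins while the whole suite runs in about a minute.

## Known limitations

* The key engine is generic over couplet lists but only this key ships.
* Shape descriptors beyond the standard length scheme (root angles, blade
  curvature, bulb widths) are not modelled; they are proposed qualitative
  discriminators for which no measurement protocol exists yet.
* Measurement columns for the two Lake Tanganyika congeners are not
  embedded (published elsewhere); they appear in the key only.
* Pooled infection paragraphs that span several museum lots attach to the
  survey rows only where the mapping is one-to-one; the paragraph-level
  records remain available in full.
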