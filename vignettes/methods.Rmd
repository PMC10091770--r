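---
title: "Counting Palaeozoic fish diversity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting Palaeozoic fish diversity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actinodiv)
```

`actinodiv` estimates face-value taxonomic diversity through the
Palaeozoic from literature-compiled occurrence data, together with the
sampling proxies needed to judge how much of that signal is artefact.
This vignette documents the statistical procedure, the package's design
decisions where the methodology is genuinely open, and what the tests do
and do not demonstrate.

## The data model

An *occurrence* is one taxon recorded at one geographic locality in one
dated stratigraphic context. The canonical table carries taxonomy (genus,
epithet, a qualifier in `none/cf/aff/quoted/indet`), geography (locality
name, WGS84 coordinates, country, one of nine present-day regions),
stratigraphy (geological unit, ICS stage, regional substage, optional
numeric age range in Ma), environment (`marine/freshwater/unknown`),
material (`body/scales_only/teeth_only/other`), and the authority and
year in which the species was described.

Cleaning drops records that cannot be confidently assigned to a valid
genus (`indet`) and records represented solely by scales or teeth; both
rules target the classic inflation of fish occurrence data by
unidentifiable fragments. Two deliberate retention choices:

* records qualified `cf`, `aff`, or with a quoted ("waste-basket") genus
  still count toward the named taxon — species tallied under
  '*Elonichthys*'-style genera belong to that genus for counting
  purposes, doubts notwithstanding;
* genus-determinate but species-indeterminate records are retained and
  count toward genus-level richness (they are confidently assigned at
  genus level), while species-level counts use only species-determinate
  binomials.

Locality identity is the exact locality name plus coordinates rounded to
2 decimal degrees (~1 km): literature sources quote coordinates of the
same site with sub-km jitter, and this rounding absorbs it without
merging genuinely distinct sites.

## Time bins

Ages are Ma before present (positive, older = larger). Stage boundary
ages are packaged from the 2021/10 ICS chart and are user-replaceable
CSV; regional substage boundary ages (Chadian … Brigantian, Pendleian,
Arnsbergian, plus substage-level splits of the Emsian and Famennian) are
packaged from standard British/regional usage, since primary sources
rarely print them.

Stage durations in the Devonian–Permian span 2.2–15.8 Myr, and unequal
bins distort richness counts. The packaged composite scheme therefore
re-tiles the Lochkovian–Changhsingian span into 20 intervals of roughly
equal (~9 Myr) length, by merging short stages and splitting long ones at
substage boundaries. Where the published precedent names only examples
(Kasimovian + Gzhelian merged; Visean split into Chadian–Holkerian and
Asbian–Brigantian), the remaining memberships are this package's own
reconstruction under two constraints: every composite duration within
[5, 13] Myr, and splits only at packaged substage boundaries. That
forces substage-level splits of the Emsian (Zlichovian/Dalejan) and
Famennian (informal early/late halves), and end-Permian merges
(Wordian + Capitanian; Wuchiapingian + Changhsingian). The scheme is a
plain CSV (`composite_id, label, member_kind, member_name`) and fully
user-replaceable; `stage_intervals()` provides the identity (one bin per
ICS stage) scheme for sensitivity comparison.

Interval membership for point ages uses half-open spans closed at the
older bound, so a boundary-aged datum belongs to the older interval — a
deterministic tie-break the literature leaves unstated. Age comparisons
carry a 1e-6 Myr tolerance.

## Binning policy

Each record's dated span is resolved in order: substage span, else stage
span, else the numeric `[max_ma, min_ma]` range. The substage wins even
against a conflicting stage name, because regional substages are the
finer, preferred dating (the Arnsbergian case: records labelled
Bashkirian by stage belong in the Serpukhovian by substage).

The default policy, `strict`, assigns a record only when its span lies
inside a single interval; this is the most conservative reading of
"sampled-in-bin" counting. How records resolvable only to a split stage
(a bare "Visean") were handled in prior work is not stated anywhere we
can check, which is precisely why the policy is a switch:
`all_overlapping` and `midpoint` are exposed for sensitivity analysis.
Under `strict` those records sit in the `unassigned` list with a reason,
and assigned + unassigned always equals the table size.

## Sampling proxies and the equal-area grid

Three per-interval effort proxies: unique localities, unique geological
units (verbatim unit names after case/whitespace canonicalisation, with
the formation preferred when a record lists alternatives), and occupied
equal-area grid cells.

The grid is the package's own deterministic construction: latitude bands
of equal angular height (`n_bands = round(πR/spacing)`), each band split
into `round(band-centre circumference / spacing)` equal-longitude cells.
Cell counts per band scale with cos(latitude), so cell areas stay within
a few percent of the global mean (max/min ratio 1.067 at the default
50 km spacing, verified by closed-form spherical areas in the tests).
Design rationale: external discrete-global-grid libraries do not pin
their orientation, so their occupancy statistics are not exactly
reproducible from a paper's text; a deterministic grid is testable and
reproducible, at the cost that grid-cell statistics replicated against
other grid systems carry a tolerance (the acceptance check on the
occupied-cell regression allows ±0.05 in R²). Boundary points resolve to
the lower-index (pole-ward, western) cell. Modern coordinates only — no
palaeorotation.

## Regressions

All fits are simple OLS on raw values: published comparisons report
plain linear regressions of counts, so no transformation is applied by
default (a `log1p` response option exists but is off). The p-value is
the two-sided t test of zero slope (equivalent to the F test here);
R² is the coefficient of determination, equal to squared Pearson r —
the tests verify this identity on 1000 random fits as a cross-check of
the `lm` path. Intervals missing on either side are dropped pairwise and
counted. Zero-variance covariates are an error, not an NA.

The nine-panel suite regresses genus richness on localities, geological
units, grid cells, interval length and sea level, plus
freshwater/marine subsets and Devonian-excluded variants ("Devonian"
means intervals lying entirely older than the 358.9 Ma
Devonian–Carboniferous boundary). Sea level is aggregated to intervals
as the mean of samples within each interval by default; the aggregation
used by prior work is unstated, so a midpoint-interpolation method is
also provided. No sea-level series is packaged; panels E–I run only when
the user supplies one (and are exercised on synthetic covariates in the
tests).

## Collector's curves

Each species is counted once, at its earliest description year across
its records; regional curves attribute the species to the region of that
earliest record, ties broken alphabetically, so regional curves
partition the global one exactly. Species lacking a year are excluded
and counted. Note one documented ambiguity in the source material: the
species total quoted for collector's curves (516) exceeds the cleaned
dataset's species count (468), implying the curve was extracted before
cleaning; `collectors_curve()` accepts either table state, and the
acceptance check takes the raw-table total as the published figure while
also computing the cleaned-table total.

## The synthetic generator

`generate_occurrences()` realises the qualitative structure the analysis
assumes, not a taphonomic model: per interval × region, locality counts
are Poisson; occurrences per locality are shifted geometric (mean 3 by
default), making per-interval occurrence counts overdispersed — the
simplest compound process with that property; genera and species are
drawn under a Zipf law with exponent 1.5, giving a few heavily recorded
waste-basket genera and many monotypic ones, qualitatively matching the
44, 30, 20, … species-per-problem-genus skew seen in real compilations;
indeterminacy, scales-only material and freshwater labels are
independent Bernoulli draws; description years follow
start-year + Exponential(rate), defaults 1820 and 0.02/yr (median
description ~1855, long tail into the present).

Two presets over the packaged scheme and three sampling regions embed
their seeds: `flat_diversity_varying_effort` (true richness 40
everywhere, per-region locality rate ramping 2–60 across intervals) and
`trending_diversity_uniform_effort` (true richness ramping 5–80,
constant rate 30). The first demonstrates bias — a significant positive
richness–localities slope arises in ≥95% of replicates although true
diversity is flat; the second demonstrates recovery — Spearman
correlation between true and sampled richness ≥0.8 in ≥95% of
replicates. What passing these checks does *not* show: the generator has
no spatially autocorrelated preservation, no Lagerstätten, no
range-through taxon durations (genus pools are nested, so taxa never go
locally extinct within the simulation), and no misdating; real
occurrence data violate all four, so pipeline correctness on synthetic
data does not certify unbiasedness on real data — only that the counting
and fitting machinery computes what it claims.

## Problem sizes and runtime choices

Test and acceptance runs use sizes chosen to exercise the code paths at
negligible cost: oracle comparisons run on 100 random 30-row tables over
a 3-bin toy timescale with a 500 km grid; the replicate studies use 100
pipeline replicates per scenario (~5,500 occurrences each) in the test
suite and 60 in the acceptance script; partition checks use 10,000
uniform sphere points at 50 km spacing (~204,000 cells). The full suite
runs in a few minutes on one CPU.

## Known limitations

No sampling-standardised estimators (coverage-based rarefaction, shared
quorum subsampling): face-value counts plus proxies only, as in the
source analysis — standardisation is the natural next step on top of
these containers. No synonymy resolution or nomenclature validation; the
normaliser canonicalises strings, it does not adjudicate taxonomy. No
probabilistic age models; dating uncertainty enters only through the
three binning policies. Modern coordinates only. The PBDB reader maps
the standard download columns but performs no API access.
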