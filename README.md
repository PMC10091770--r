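# actinodiv

Occurrence-based diversity dynamics for Palaeozoic ray-finned fishes
(Actinopterygii) — and for any clade whose fossil record comes as a
literature-compiled occurrence table.

Palaeozoic actinopterygians are wildly under-studied relative to their
modern dominance: their apparent ("face-value") diversity through time is
entangled with how unevenly the rock record has been sampled. `actinodiv`
implements the standard analysis pipeline for interrogating such a record:

- **Cleaning.** Occurrence tables (one row per taxon-at-locality datum)
  are normalised (quoted 'waste-basket' genera, `cf.`/`aff.` qualifiers,
  case/whitespace) and cleaned by the usual rules: taxonomically
  indeterminate records and occurrences known only from scales or teeth
  are dropped, keeping identifiable body fossils.
- **Binning.** Occurrences are placed into composite time intervals of
  roughly equal length (~9 Myr) built from ICS stages and regional
  substages — short stages merged (Kasimovian + Gzhelian), long stages
  split at substage boundaries (Visean → Chadian–Holkerian and
  Asbian–Brigantian) — as well as into raw ICS stages for comparison.
- **Richness and sampling proxies.** Sampled-in-bin genus and species
  richness per interval, alongside three sampling-effort proxies: unique
  localities, unique geological units, and occupied cells of a
  deterministic ~50 km equal-area global grid.
- **Regressions.** The nine-panel OLS suite of genus richness against
  localities, geological units, grid cells, interval length and sea
  level (with freshwater/marine and Devonian-excluded variants). For a
  simple fit of richness S on covariate x, S = a + b·x, the package
  reports b, a, R², the two-sided p for b = 0, and n.
- **Collector's curves.** Cumulative counts of described species against
  publication year, globally and by present-day region.
- **Synthetic data.** A seeded generator with known true diversity,
  configurable per-interval/per-region sampling effort (compound
  Poisson–geometric), Zipf-skewed taxonomy and cleaning-rule targets, so
  the whole pipeline is testable without any data download.

## Worked example

```r
library(actinodiv)

ts     <- load_timescale()                    # packaged ICS boundary ages
scheme <- build_composite_intervals(ts)       # packaged equal-length bins
scheme
#> <interval_scheme 'equal_length'> 20 intervals, 419.2-251.9 Ma, durations 5.1-12.2 Myr

# a synthetic record with FLAT true diversity but ramping sampling effort
syn <- generate_occurrences(scenario("flat_diversity_varying_effort"))
occ <- clean_occurrences(normalize_names(syn$table))
summarize_occurrences(occ)
#> 4934 occurrences, 353 species, 40 genera, 1794 unique localities

b    <- assign_to_intervals(occ, scheme, ts, policy = "strict")
rich <- richness_per_interval(b, occ, "genus")
grid <- build_grid(50)
prox <- sampling_proxies_per_interval(b, occ, grid)
regress(rich, prox$localities)
#> OLS genus_richness ~ localities: slope 0.1499, R^2 = 0.81, p = 7.79e-08 (n = 20)
```

True genus richness is constant at 40 in every bin, yet sampled-in-bin
richness correlates strongly and significantly with the number of
localities (R² = 0.81): the apparent diversity signal here is entirely a
sampling artefact — which is exactly the bias this pipeline is built to
expose. The companion preset `trending_diversity_uniform_effort` shows
the converse: under uniform effort, sampled richness tracks a true
5 → 80 genus ramp (Spearman ρ ≈ 0.9). Interval length, by construction of
the roughly equal-length bins, does not correlate with richness
(panel D of `regression_suite()`: p = 0.67 here).

One call runs everything and writes tidy CSVs plus a run log:

```r
run_full_analysis(occ, "out/", spacing_km = 50, seed = 1)
```

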