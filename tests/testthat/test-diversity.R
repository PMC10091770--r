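tts <- toy_timescale()
tsc <- toy_scheme(tts)
grid <- build_grid(200)

test_that("richness counts distinct taxa per bin, zero-filling empty bins", {
  t <- occ_fixture(occ_row("r1", genus = "Aus", species = "x", stage = "S1"),
                   occ_row("r2", genus = "Aus", species = "y", stage = "S1"),
                   occ_row("r3", genus = "Bus", species = "x", stage = "S1"))
  b <- assign_to_intervals(t, tsc, tts)
  g <- richness_per_interval(b, t, "genus")
  expect_equal(g$value, c(2L, 0L, 0L))
  s <- richness_per_interval(b, t, "species")
  expect_equal(s$value, c(3L, 0L, 0L))
})

test_that("genus-determinate species-indeterminate records count for genera only", {
  t <- occ_fixture(occ_row("r1", genus = "Aus", species = "", stage = "S1"),
                   occ_row("r2", genus = "Aus", species = "alpha", stage = "S1"))
  b <- assign_to_intervals(t, tsc, tts)
  expect_equal(richness_per_interval(b, t, "genus")$value[1], 1L)
  expect_equal(richness_per_interval(b, t, "species")$value[1], 1L)
  none <- occ_fixture(occ_row("r3", genus = "Aus", species = "", stage = "S1"))
  bn <- assign_to_intervals(none, tsc, tts)
  expect_warning(sp <- richness_per_interval(bn, none, "species"),
                 "no species-determinate")
  expect_equal(sp$value, c(0L, 0L, 0L))
})

test_that("proxy counts: localities and geological units deduplicate within bins", {
  t <- occ_fixture(
    occ_row("p1", locality_name = "L1", latitude = 10, longitude = 10,
            geological_unit = "Bear Gulch Lst", stage = "S1"),
    occ_row("p2", locality_name = "L1", latitude = 10, longitude = 10,
            geological_unit = "bear gulch lst", stage = "S1"),
    occ_row("p3", locality_name = "L2", latitude = 30, longitude = 40,
            geological_unit = "Heath Fm", stage = "S1"))
  b <- assign_to_intervals(t, tsc, tts)
  prox <- sampling_proxies_per_interval(b, t, grid)
  expect_equal(prox$localities$value, c(2L, 0L, 0L))
  expect_equal(prox$geological_units$value, c(2L, 0L, 0L))
  expect_equal(prox$grid_cells$value, c(2L, 0L, 0L))
})

test_that("richness and proxies equal nested-loop oracles on random tables", {
  set.seed(41)
  for (rep in 1:8) {
    t <- random_occ_table(50)
    b <- assign_to_intervals(t, tsc, tts)
    prox <- sampling_proxies_per_interval(b, t, grid)
    gen <- richness_per_interval(b, t, "genus")
    spp <- richness_per_interval(b, t, "species")
    for (k in seq_along(tsc$intervals$id)) {
      id <- tsc$intervals$id[k]
      ids <- b$assignments$occurrence_id[b$assignments$interval_id == id]
      sub <- t[t$occurrence_id %in% ids, ]
      genera <- species <- locs <- units <- character(0)
      coords <- NULL
      for (i in seq_len(nrow(sub))) {
        if (sub$qualifier[i] != "indet" && nzchar(sub$genus[i])) {
          genera <- union(genera, sub$genus[i])
          if (nzchar(sub$species[i]))
            species <- union(species, paste(sub$genus[i], sub$species[i]))
        }
        lkey <- paste(sub$locality_name[i], round(sub$latitude[i], 2),
                      round(sub$longitude[i], 2))
        if (!lkey %in% locs) {
          locs <- c(locs, lkey)
          coords <- rbind(coords, c(sub$latitude[i], sub$longitude[i]))
        }
        if (nzchar(sub$geological_unit[i]))
          units <- union(units, tolower(sub$geological_unit[i]))
      }
      expect_equal(gen$value[k], length(genera))
      expect_equal(spp$value[k], length(species))
      expect_equal(prox$localities$value[k], length(locs))
      expect_equal(prox$geological_units$value[k], length(units))
      expect_equal(prox$grid_cells$value[k],
                   if (is.null(coords)) 0L else
                     occupied_cells_count(grid, as.data.frame(coords)))
    }
  }
})

test_that("per-interval counts obey the proxy ordering invariant", {
  set.seed(42)
  t <- random_occ_table(80)
  b <- assign_to_intervals(t, tsc, tts)
  prox <- sampling_proxies_per_interval(b, t, grid)
  occ_in_bin <- vapply(tsc$intervals$id, function(id)
    sum(b$assignments$interval_id == id), 0L)
  expect_true(all(prox$grid_cells$value <= prox$localities$value))
  expect_true(all(prox$localities$value <= occ_in_bin))
})

test_that("counts are invariant to record order", {
  set.seed(43)
  t <- random_occ_table(60)
  perm <- sample(nrow(t))
  t2 <- as_occurrence_table(as.data.frame(t)[perm, ])
  b1 <- assign_to_intervals(t, tsc, tts)
  b2 <- assign_to_intervals(t2, tsc, tts)
  expect_equal(richness_per_interval(b1, t, "genus")$value,
               richness_per_interval(b2, t2, "genus")$value)
  p1 <- sampling_proxies_per_interval(b1, t, grid)
  p2 <- sampling_proxies_per_interval(b2, t2, grid)
  for (m in names(p1)) expect_equal(p1[[m]]$value, p2[[m]]$value)
})

test_that("richness of a union is bounded by its disjoint parts", {
  set.seed(44)
  t <- random_occ_table(80)
  half <- seq_len(40)
  ta <- as_occurrence_table(as.data.frame(t)[half, ])
  tb <- as_occurrence_table(as.data.frame(t)[-half, ])
  rich <- function(x) {
    richness_per_interval(assign_to_intervals(x, tsc, tts), x, "genus")$value
  }
  ru <- rich(t); ra <- rich(ta); rb <- rich(tb)
  expect_true(all(ru >= pmax(ra, rb)))
  expect_true(all(ru <= ra + rb))
})

test_that("subsetting filters by environment, region, locality and interval", {
  t <- occ_fixture(
    occ_row("s1", environment = "freshwater", stage = "S1"),
    occ_row("s2", environment = "marine", stage = "S2"),
    occ_row("s3", environment = "marine", locality_name = "Bear Gulch",
            stage = "S3"),
    occ_row("s4", environment = "marine", locality_name = "Glencartholm",
            stage = "S3"))
  expect_equal(subset_occurrences(t, environment = "freshwater")$occurrence_id, "s1")
  expect_error(subset_occurrences(t, environment = "brackish"), "unknown environment")
  expect_error(subset_occurrences(t, region = "Atlantis"), "unknown region")
  no_lager <- subset_occurrences(
    t, exclude_localities = c("Bear Gulch", "Glencartholm"))
  expect_setequal(no_lager$occurrence_id, c("s1", "s2"))
  no_s1 <- subset_occurrences(
    t, exclude_intervals = tsc$intervals[1, ], ts = tts)
  expect_setequal(no_s1$occurrence_id, c("s2", "s3", "s4"))
})

test_that("excluding Devonian intervals leaves nothing older than 358.9 Ma", {
  ts <- load_timescale()
  eq <- build_composite_intervals(ts)
  t <- occ_fixture(occ_row("d1", stage = "Famennian"),
                   occ_row("d2", stage = "Frasnian"),
                   occ_row("d3", stage = "Tournaisian"),
                   occ_row("d4", stage = "Moscovian"))
  dev <- eq$intervals[eq$intervals$end_ma >= 358.9 - 1e-6, ]
  kept <- subset_occurrences(t, exclude_intervals = dev, ts = ts)
  spans <- ts$stages[match(kept$stage, ts$stages$name), ]
  expect_true(all(spans$start_ma <= 358.9 + 1e-6))
  expect_setequal(kept$occurrence_id, c("d3", "d4"))
})
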