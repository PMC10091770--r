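test_that("canonical-dialect files parse and coordinates are normalised", {
  t <- occ_fixture(
    occ_row("a1"),
    occ_row("a2", longitude = 270),   # wraps to -90
    occ_row("a3", latitude = -33.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(t, path)
  t2 <- read_occurrences(path, dialect = "s1")
  expect_equal(nrow(t2), 3)
  expect_equal(t2$longitude[t2$occurrence_id == "a2"], -90)
})

test_that("rows with impossible values get row-numbered diagnostics", {
  t <- occ_fixture(occ_row("a1"), occ_row("a2"), occ_row("a3"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(t, path)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  raw$latitude[2] <- 95
  raw$max_ma[3] <- 300; raw$min_ma[3] <- 310
  utils::write.csv(raw, path, row.names = FALSE)
  t2 <- read_occurrences(path, on_error = "skip")
  expect_equal(nrow(t2), 1)
  errs <- attr(t2, "errors")
  expect_equal(errs$row, c(2L, 3L))
  expect_match(errs$message[1], "latitude")
  expect_match(errs$message[2], "max_ma")
  expect_error(read_occurrences(path, on_error = "fail"), "row 2")
})

test_that("PBDB-dialect downloads map onto the canonical schema", {
  pb <- data.frame(occurrence_no = 1:2,
                   accepted_name = c("Cheirolepis trailli", "Cheirolepis"),
                   lat = c(57.5, 46.8), lng = c(-3.9, -71.2),
                   cc = c("UK", "CA"),
                   collection_name = c("Lethen Bar", "Miguasha"),
                   formation = c("Nairn", "Escuminac"),
                   early_interval = c("Givetian", "Frasnian"),
                   environment = c("lacustrine", "marginal marine"),
                   stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(pb, path, row.names = FALSE)
  t <- read_occurrences(path, dialect = "pbdb")
  expect_equal(t$genus, c("Cheirolepis", "Cheirolepis"))
  expect_equal(t$species, c("trailli", ""))
  expect_equal(t$region, c("UK & Ireland", "North America"))
  expect_equal(t$environment, c("freshwater", "marine"))
  expect_equal(t$stage, c("Givetian", "Frasnian"))
})

test_that("name normalisation strips quotes and moves cf./aff. into the qualifier", {
  t <- occ_fixture(
    occ_row("n1", genus = "'Elonichthys'", species = "macropercularis"),
    occ_row("n2", genus = "ELONICHTHYS", species = "robisoni "),
    occ_row("n3", genus = "cf. Platysomus sp.", species = ""),
    occ_row("n4", genus = "aff. Rhadinichthys", species = "ornatus"),
    occ_row("n5", genus = "indet.", species = ""))
  t <- normalize_names(t)
  expect_equal(t$genus[1], "Elonichthys")
  expect_equal(t$qualifier[1], "quoted")
  expect_equal(t$genus[2], "Elonichthys")
  expect_equal(t$species[2], "robisoni")
  expect_equal(t$qualifier[2], "none")
  expect_equal(t$genus[3], "Platysomus")
  expect_equal(t$species[3], "")
  expect_equal(t$qualifier[3], "cf")
  expect_equal(t$qualifier[4], "aff")
  expect_equal(t$qualifier[5], "indet")
})

test_that("cleaning drops indeterminate and scales/teeth-only records, idempotently", {
  rows <- c(
    lapply(1:7, function(i) occ_row(sprintf("k%d", i), genus = sprintf("Genus%d", i))),
    list(occ_row("k8", genus = "indet.", qualifier = "indet"),
         occ_row("k9", genus = "indet.", qualifier = "indet"),
         occ_row("k10", material = "scales_only")))
  t <- normalize_names(do.call(occ_fixture, rows))
  cleaned <- clean_occurrences(t)
  expect_equal(nrow(cleaned), 7)
  log <- attr(cleaned, "cleaning_log")
  expect_equal(log$removed[log$rule == "taxonomically_indeterminate"], 2L)
  expect_equal(log$removed[log$rule == "scales_only"], 1L)
  # occurrence balance: removed + retained = input
  expect_equal(nrow(cleaned) + sum(log$removed), nrow(t))
  # idempotence
  twice <- clean_occurrences(cleaned)
  expect_equal(as.data.frame(twice), as.data.frame(cleaned))
  # a determinate body fossil passes untouched
  keep <- clean_occurrences(normalize_names(occ_fixture(occ_row("z1"))))
  expect_equal(nrow(keep), 1)
})

test_that("summary counts match a brute-force oracle", {
  expect_equal(unclass(summarize_occurrences(occ_fixture(occ_row("e")[0, ]))),
               list(n_occurrences = 0L, n_species = 0L, n_genera = 0L,
                    n_localities = 0L))
  set.seed(11)
  for (rep in 1:5) {
    t <- random_occ_table(60)
    s <- summarize_occurrences(t)
    # nested-loop distinct counts
    sp <- character(0); gn <- character(0); loc <- character(0)
    for (i in seq_len(nrow(t))) {
      if (t$qualifier[i] != "indet") {
        if (nzchar(t$species[i]))
          sp <- union(sp, paste(t$genus[i], t$species[i]))
        if (nzchar(t$genus[i])) gn <- union(gn, t$genus[i])
      }
      loc <- union(loc, paste(t$locality_name[i], round(t$latitude[i], 2),
                              round(t$longitude[i], 2)))
    }
    expect_equal(s$n_occurrences, nrow(t))
    expect_equal(s$n_species, length(sp))
    expect_equal(s$n_genera, length(gn))
    expect_equal(s$n_localities, length(loc))
  }
})

test_that("read-write-read round trip preserves every field", {
  set.seed(7)
  t <- normalize_names(random_occ_table(30))
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_occurrences(t, p1)
  t2 <- read_occurrences(p1)
  write_occurrences(t2, p2)
  t3 <- read_occurrences(p2)
  expect_identical(strip_attrs(t2), strip_attrs(t3))
  expect_identical(readLines(p1), readLines(p2))
})

test_that("duplicate occurrence ids are rejected", {
  expect_error(occ_fixture(occ_row("d1"), occ_row("d1")), "duplicated occurrence_id")
})
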