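# fixtures built in code: canonical occurrence rows and small configs

occ_row <- function(occurrence_id = "o1", genus = "Genusa", species = "alpha",
                    qualifier = "none", locality_name = "Loc A",
                    latitude = 10, longitude = 20, country = "USA",
                    region = "North America", geological_unit = "A Formation",
                    stage = "Serpukhovian", substage = "", max_ma = NA,
                    min_ma = NA, environment = "marine", material = "body",
                    authority = "Smith", year_described = 1900L) {
  data.frame(occurrence_id = occurrence_id, genus = genus, species = species,
             qualifier = qualifier, locality_name = locality_name,
             latitude = latitude, longitude = longitude, country = country,
             region = region, geological_unit = geological_unit, stage = stage,
             substage = substage, max_ma = max_ma, min_ma = min_ma,
             environment = environment, material = material,
             authority = authority, year_described = year_described,
             stringsAsFactors = FALSE)
}

occ_fixture <- function(...) {
  rows <- list(...)
  as_occurrence_table(do.call(rbind, rows))
}

# a tiny 3-interval scheme + matching timescale for fast synthetic configs
toy_timescale <- function() {
  load_timescale(
    data.frame(name = c("S1", "S2", "S3"), period = "P",
               start_ma = c(330, 318, 309), end_ma = c(318, 309, 300)),
    data.frame(name = character(), parent_stage = character(),
               start_ma = numeric(), end_ma = numeric()))
}

toy_scheme <- function(ts = toy_timescale()) {
  build_composite_intervals(ts, data.frame(
    composite_id = c("I1", "I2", "I3"), label = c("S1", "S2", "S3"),
    member_kind = "stage", member_name = c("S1", "S2", "S3"),
    stringsAsFactors = FALSE))
}

toy_config <- function(...) {
  synthetic_config(
    scheme = toy_scheme(),
    regions = list("North America" = list(lat = c(30, 50), lon = c(-110, -80),
                                          country = "USA")),
    true_genus_richness = 12, locality_rate = 6,
    occurrences_per_locality_mean = 3, ...)
}

# random small occurrence table for oracle comparisons
random_occ_table <- function(n = 40, n_intervals = 3) {
  stages <- c("S1", "S2", "S3")[seq_len(n_intervals)]
  as_occurrence_table(data.frame(
    occurrence_id = sprintf("r%03d", seq_len(n)),
    genus = sample(c("Aus", "Bus", "Cus", "Dus", "Eus"), n, replace = TRUE),
    species = sample(c("", "alpha", "beta", "gamma"), n, replace = TRUE),
    qualifier = sample(c("none", "none", "none", "cf", "indet"), n, replace = TRUE),
    locality_name = sample(sprintf("L%d", 1:8), n, replace = TRUE),
    latitude = round(runif(n, -60, 60), 2),
    longitude = round(runif(n, -170, 170), 2),
    country = "USA", region = "North America",
    geological_unit = sample(c("F1", "F2", "F3", ""), n, replace = TRUE),
    stage = sample(stages, n, replace = TRUE), substage = "",
    max_ma = NA, min_ma = NA,
    environment = sample(c("marine", "freshwater"), n, replace = TRUE),
    material = "body", authority = "A",
    year_described = sample(1820:2000, n, replace = TRUE),
    stringsAsFactors = FALSE))
}

# plain data: drop provenance/log attributes for content comparisons
strip_attrs <- function(t) {
  df <- as.data.frame(t)
  attr(df, "provenance") <- NULL
  attr(df, "cleaning_log") <- NULL
  attr(df, "errors") <- NULL
  class(df) <- "data.frame"
  df
}

# interval_series constructor for regression tests
make_series <- function(values, ids = sprintf("i%02d", seq_along(values)),
                        metric = "test") {
  structure(data.frame(interval_id = ids, value = values,
                       stringsAsFactors = FALSE),
            scheme_id = "toy", metric = metric,
            class = c("interval_series", "data.frame"))
}
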