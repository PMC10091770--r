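# Occurrence tables: reading, validation, name normalisation, cleaning and
# summary counts. The canonical ("s1") dialect is a flat CSV with one row per
# taxon-at-locality occurrence.

OCC_COLUMNS <- c("occurrence_id", "genus", "species", "qualifier",
                 "locality_name", "latitude", "longitude", "country", "region",
                 "geological_unit", "stage", "substage", "max_ma", "min_ma",
                 "environment", "material", "authority", "year_described")

QUALIFIERS <- c("none", "cf", "aff", "quoted", "indet")
ENVIRONMENTS <- c("marine", "freshwater", "unknown")
MATERIALS <- c("body", "scales_only", "teeth_only", "other")

#' The nine present-day regions used for regional subsetting
#'
#' @return Character vector of region names.
#' @export
occurrence_regions <- function() {
  c("UK & Ireland", "Western Europe", "Central Europe", "Eastern Europe",
    "North America", "Africa", "Asia", "South America", "Oceania")
}

# build/validate an occ_table from a data.frame with the canonical columns
new_occ_table <- function(df, provenance = "in-memory",
                          cleaning_log = empty_cleaning_log()) {
  missing <- setdiff(OCC_COLUMNS, names(df))
  if (length(missing)) {
    stop("occurrence table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df <- df[, OCC_COLUMNS, drop = FALSE]
  for (col in c("occurrence_id", "genus", "species", "qualifier", "locality_name",
                "country", "region", "geological_unit", "stage", "substage",
                "environment", "material", "authority")) {
    df[[col]] <- as.character(df[[col]])
    df[[col]][is.na(df[[col]])] <- ""
  }
  for (col in c("latitude", "longitude", "max_ma", "min_ma")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$year_described <- suppressWarnings(as.integer(df$year_described))
  if (any(duplicated(df$occurrence_id))) {
    stop("duplicated occurrence_id(s): ",
         paste(utils::head(unique(df$occurrence_id[duplicated(df$occurrence_id)]), 5),
               collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  structure(df, provenance = provenance, cleaning_log = cleaning_log,
            class = c("occ_table", "data.frame"))
}

empty_cleaning_log <- function() {
  data.frame(rule = character(), removed = integer(), stringsAsFactors = FALSE)
}

#' Coerce a data.frame to an occurrence table
#'
#' Validates column presence and types, blanks missing text fields and
#' enforces unique `occurrence_id`s.
#'
#' @param df A data.frame with the canonical occurrence columns (see
#'   [read_occurrences()] for the schema).
#' @return An `occ_table`.
#' @export
as_occurrence_table <- function(df) {
  new_occ_table(as.data.frame(df, stringsAsFactors = FALSE))
}

#' @export
print.occ_table <- function(x, ...) {
  cat(sprintf("<occ_table> %d occurrences (%s)\n", nrow(x),
              attr(x, "provenance")))
  log <- attr(x, "cleaning_log")
  if (!is.null(log) && nrow(log)) {
    cat("  cleaning:", paste(sprintf("%s=%d", log$rule, log$removed),
                             collapse = ", "), "\n")
  }
  NextMethod()
}

# map PBDB country codes to the country names used by the region lookup
PBDB_CC <- c(US = "USA", CA = "Canada", MX = "Mexico", GL = "Greenland",
             UK = "United Kingdom", GB = "United Kingdom", IE = "Ireland",
             FR = "France", BE = "Belgium", NL = "Netherlands", ES = "Spain",
             PT = "Portugal", IT = "Italy", CH = "Switzerland",
             DE = "Germany", CZ = "Czechia", PL = "Poland", AT = "Austria",
             SK = "Slovakia", RU = "Russia", UA = "Ukraine", EE = "Estonia",
             LV = "Latvia", LT = "Lithuania", CN = "China", KZ = "Kazakhstan",
             IN = "India", IR = "Iran", TR = "Turkey", VN = "Vietnam",
             ZA = "South Africa", "NA" = "Namibia", ZW = "Zimbabwe",
             MA = "Morocco", BR = "Brazil", UY = "Uruguay", AR = "Argentina",
             CL = "Chile", BO = "Bolivia", AU = "Australia", NZ = "New Zealand")

pbdb_environment <- function(x) {
  x <- tolower(x)
  out <- rep("unknown", length(x))
  out[grepl("fluvial|lacustrine|pond|alluvial|fresh|terrestrial|channel|floodplain|crevasse|levee|mire|swamp", x)] <- "freshwater"
  out[grepl("marine|reef|shoal|lagoon|delta|estuar|coast|shore|basin|slope|shelf|ramp|platform", x)] <- "marine"
  out
}

# first token capitalised = genus; second lower-case token = species epithet
split_binomial <- function(name) {
  name <- squish(name)
  parts <- strsplit(name, " ", fixed = TRUE)
  t(vapply(parts, function(p) {
    p <- p[nzchar(p)]
    if (!length(p)) return(c(genus = "", species = ""))
    genus <- p[1]
    species <- if (length(p) >= 2) p[2] else ""
    c(genus = genus, species = species)
  }, c(genus = "", species = "")))
}

#' Read an occurrence table
#'
#' Parses an occurrence CSV in either the canonical `"s1"` dialect (one
#' column per field of the schema below) or the `"pbdb"` dialect (a standard
#' Paleobiology Database occurrence download, mapped onto the canonical
#' schema through a fixed column map). Longitudes are normalised to
#' \[-180, 180); rows with impossible latitudes, unparseable coordinates or
#' inverted age ranges are rejected with row-numbered diagnostics. Empty
#' `region` fields are filled from `country` using the packaged nine-region
#' lookup.
#'
#' The canonical columns are: `occurrence_id, genus, species, qualifier,
#' locality_name, latitude, longitude, country, region, geological_unit,
#' stage, substage, max_ma, min_ma, environment, material, authority,
#' year_described`.
#'
#' @param path CSV file path.
#' @param dialect `"s1"` (canonical) or `"pbdb"`.
#' @param on_error `"skip"` (default) collects per-row problems in the
#'   `errors` attribute and drops those rows; `"fail"` stops at the first
#'   problem.
#' @param region_lookup Path or data.frame with columns `country, region`;
#'   `NULL` for the packaged lookup.
#' @return An `occ_table` (a data.frame with attributes `provenance`,
#'   `cleaning_log` and `errors`).
#' @export
read_occurrences <- function(path, dialect = c("s1", "pbdb"),
                             on_error = c("skip", "fail"),
                             region_lookup = NULL) {
  dialect <- match.arg(dialect)
  on_error <- match.arg(on_error)
  raw <- read_table_csv(path)

  if (dialect == "s1") {
    missing <- setdiff(OCC_COLUMNS, names(raw))
    if (length(missing)) {
      stop("not an s1-dialect file, missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    df <- raw[, OCC_COLUMNS]
  } else {
    need <- c("occurrence_no", "accepted_name", "lat", "lng")
    missing <- setdiff(need, names(raw))
    if (length(missing)) {
      stop("not a pbdb-dialect file, missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    get <- function(col, default = "") {
      if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
    }
    nm <- split_binomial(as.character(raw$accepted_name))
    cc <- toupper(as.character(get("cc")))
    df <- data.frame(
      occurrence_id = as.character(raw$occurrence_no),
      genus = nm[, "genus"], species = nm[, "species"], qualifier = "none",
      locality_name = as.character(get("collection_name")),
      latitude = suppressWarnings(as.numeric(raw$lat)),
      longitude = suppressWarnings(as.numeric(raw$lng)),
      country = ifelse(is.na(PBDB_CC[cc]), cc, PBDB_CC[cc]),
      region = "",
      geological_unit = as.character(get("formation")),
      stage = as.character(get("early_interval")),
      substage = "",
      max_ma = suppressWarnings(as.numeric(get("max_ma", NA))),
      min_ma = suppressWarnings(as.numeric(get("min_ma", NA))),
      environment = pbdb_environment(as.character(get("environment"))),
      material = "body",
      authority = as.character(get("accepted_attr")),
      year_described = suppressWarnings(as.integer(get("ref_pubyr", NA))),
      stringsAsFactors = FALSE)
  }

  df$latitude <- suppressWarnings(as.numeric(df$latitude))
  df$longitude <- suppressWarnings(as.numeric(df$longitude))
  df$max_ma <- suppressWarnings(as.numeric(df$max_ma))
  df$min_ma <- suppressWarnings(as.numeric(df$min_ma))
  df$year_described <- suppressWarnings(as.integer(df$year_described))

  problems <- character(nrow(df))
  has_coord <- !is.na(df$latitude) | !is.na(df$longitude)
  bad_lat <- has_coord & (is.na(df$latitude) | df$latitude < -90 | df$latitude > 90)
  problems[bad_lat] <- "latitude outside [-90, 90] or unparseable"
  bad_lon <- has_coord & is.na(df$longitude) & !bad_lat
  problems[bad_lon] <- "unparseable longitude"
  both_ages <- !is.na(df$max_ma) & !is.na(df$min_ma)
  bad_age <- both_ages & !(df$max_ma > df$min_ma)
  problems[bad_age & problems == ""] <- "max_ma not greater than min_ma"

  errors <- data.frame(row = which(problems != ""),
                       message = problems[problems != ""],
                       stringsAsFactors = FALSE)
  if (nrow(errors) && on_error == "fail") {
    stop(sprintf("row %d: %s", errors$row[1], errors$message[1]), call. = FALSE)
  }
  keep <- problems == ""
  df <- df[keep, , drop = FALSE]
  df$longitude <- ifelse(is.na(df$longitude), NA_real_, normalize_lon(df$longitude))

  lookup <- as_table(if (is.null(region_lookup))
    actinodiv_extdata("country_regions.csv") else region_lookup,
    c("country", "region"))
  blank <- !nzchar(as.character(df$region)) | is.na(df$region)
  hit <- match(tolower(squish(as.character(df$country[blank]))),
               tolower(lookup$country))
  df$region[blank] <- ifelse(is.na(hit), "", lookup$region[hit])

  out <- new_occ_table(df, provenance = paste0(path, " [", dialect, "]"))
  attr(out, "errors") <- errors
  out
}

#' Write an occurrence table in the canonical dialect
#'
#' Inverse of [read_occurrences()] for the `"s1"` dialect: a
#' read-write-read round trip preserves every field.
#'
#' @param t An `occ_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(t, path) {
  stopifnot(inherits(t, "occ_table"))
  df <- as.data.frame(t)[, OCC_COLUMNS]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

INDET_PATTERNS <- "^(indet\\.?|indeterminate|gen\\.?( et sp\\.?)?( indet\\.?)?|\\?+|actinopterygii( indet\\.?)?|incertae sedis)$"

# normalise one genus/species pair; returns list(genus, species, qualifier)
normalize_one <- function(genus, species, qualifier) {
  g <- squish(genus)
  s <- squish(species)
  q <- if (qualifier %in% QUALIFIERS && qualifier != "none") qualifier else "none"

  # a full name string may sit in the genus field ("cf. Platysomus sp.")
  if (!nzchar(s) && grepl(" ", g)) {
    parts <- strsplit(g, " ", fixed = TRUE)[[1]]
    parts <- parts[nzchar(parts)]
    is_qual <- tolower(parts) %in% c("cf.", "cf", "aff.", "aff")
    quals <- parts[is_qual]
    parts <- parts[!is_qual]
    if (length(quals) && q == "none") q <- sub("\\.$", "", tolower(quals[1]))
    g <- if (length(parts)) parts[1] else ""
    s <- if (length(parts) >= 2) parts[2] else ""
  }

  # quoted ("waste-basket") genera: count under the name, flag the doubt
  if (grepl("^['\"‘’“”].*['\"‘’“”]$", g)) {
    g <- gsub("^['\"‘’“”]+|['\"‘’“”]+$", "", g)
    if (q %in% c("none", "cf", "aff")) q <- "quoted"
  }
  for (tok in c("cf", "aff")) {
    pat <- paste0("^", tok, "\\.?\\s+")
    if (grepl(pat, g, ignore.case = TRUE)) {
      g <- squish(sub(pat, "", g, ignore.case = TRUE))
      if (q == "none") q <- tok
    }
    if (grepl(pat, s, ignore.case = TRUE)) {
      s <- squish(sub(pat, "", s, ignore.case = TRUE))
      if (q == "none") q <- tok
    }
  }

  if (grepl("^(sp{1,2}\\.?|indet\\.?|sp\\.? indet\\.?)$", tolower(s))) s <- ""
  g_cap <- capitalise(g)
  s <- tolower(s)
  if (!nzchar(g) || grepl(INDET_PATTERNS, tolower(g))) {
    q <- "indet"
    g_cap <- g
  }
  list(genus = g_cap, species = s, qualifier = q)
}

#' Canonicalise taxon names
#'
#' Strips quoting from 'waste-basket' genus names into
#' `qualifier = "quoted"`, moves `cf.`/`aff.` markers into the qualifier,
#' canonicalises case and whitespace (genus capitalised, epithet
#' lower-case), empties placeholder epithets (`sp.`, `indet.`) and marks
#' records whose genus cannot be resolved to a valid name as
#' `qualifier = "indet"`. Pure normalisation: no records are removed.
#'
#' Records qualified `cf`, `aff` or `quoted` still count toward the named
#' genus and species in all richness tallies; only `indet` records are
#' excluded (by [clean_occurrences()]).
#'
#' @param t An `occ_table`.
#' @return The normalised `occ_table`.
#' @examples
#' t <- as_occurrence_table(data.frame(
#'   occurrence_id = "x1", genus = "'Elonichthys'", species = "ROBISONI ",
#'   qualifier = "none", locality_name = "L", latitude = 0, longitude = 0,
#'   country = "USA", region = "", geological_unit = "", stage = "Moscovian",
#'   substage = "", max_ma = NA, min_ma = NA, environment = "unknown",
#'   material = "body", authority = "", year_described = 1890))
#' normalize_names(t)[, c("genus", "species", "qualifier")]
#' @export
normalize_names <- function(t) {
  stopifnot(inherits(t, "occ_table"))
  res <- Map(normalize_one, t$genus, t$species, t$qualifier)
  t$genus <- vapply(res, `[[`, "", "genus")
  t$species <- vapply(res, `[[`, "", "species")
  t$qualifier <- vapply(res, `[[`, "", "qualifier")
  t$locality_name <- squish(t$locality_name)
  t$geological_unit <- squish(t$geological_unit)
  t$stage <- capitalise(squish(t$stage))
  t$substage <- squish(t$substage)
  env <- tolower(squish(t$environment))
  t$environment <- ifelse(env %in% ENVIRONMENTS, env, "unknown")
  mat <- tolower(squish(t$material))
  t$material <- ifelse(mat %in% MATERIALS, mat, "other")
  t
}

#' Apply the standard cleaning rules
#'
#' Drops taxonomically indeterminate occurrences (those that cannot be
#' confidently assigned to a valid genus, `qualifier = "indet"`) and
#' occurrences represented solely by scales or teeth, so that only
#' identifiable body fossils remain. Counts removed per rule are appended
#' to the table's cleaning log. Cleaning is idempotent.
#'
#' Genus-determinate but species-indeterminate records (empty epithet) are
#' retained: they carry information for genus-level analyses.
#'
#' @param t A normalised `occ_table`.
#' @return The cleaned `occ_table`; its `cleaning_log` attribute records
#'   the number of records removed by each rule.
#' @export
clean_occurrences <- function(t) {
  stopifnot(inherits(t, "occ_table"))
  log <- attr(t, "cleaning_log")
  drop_indet <- t$qualifier == "indet"
  drop_scales <- !drop_indet & t$material == "scales_only"
  drop_teeth <- !drop_indet & t$material == "teeth_only"
  new <- data.frame(
    rule = c("taxonomically_indeterminate", "scales_only", "teeth_only"),
    removed = c(sum(drop_indet), sum(drop_scales), sum(drop_teeth)),
    stringsAsFactors = FALSE)
  # accumulate per rule so repeated cleaning leaves the log unchanged
  for (j in seq_len(nrow(new))) {
    k <- match(new$rule[j], log$rule)
    if (is.na(k)) log <- rbind(log, new[j, ]) else
      log$removed[k] <- log$removed[k] + new$removed[j]
  }
  rownames(log) <- NULL
  keep <- !(drop_indet | drop_scales | drop_teeth)
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cleaning_log") <- log
  attr(out, "provenance") <- attr(t, "provenance")
  class(out) <- class(t)
  out
}

# locality identity: exact name plus coordinates rounded to 2 decimal degrees
locality_key <- function(t) {
  paste(t$locality_name,
        ifelse(is.na(t$latitude), "NA", sprintf("%.2f", round(t$latitude, 2))),
        ifelse(is.na(t$longitude), "NA", sprintf("%.2f", round(t$longitude, 2))),
        sep = "|")
}

# geological-unit identity: canonicalised name; where alternatives are listed
# ("Heath Fm; Bear Gulch Mbr") prefer the one naming a formation
unit_key <- function(x) {
  x <- squish(x)
  multi <- grepl(";", x, fixed = TRUE)
  x[multi] <- vapply(strsplit(x[multi], ";"), function(p) {
    p <- squish(p)
    fm <- grepl("\\b(formation|fm\\.?)\\b", tolower(p))
    if (any(fm)) p[which(fm)[1]] else p[1]
  }, "")
  tolower(x)
}

species_key <- function(t) {
  ok <- t$qualifier != "indet" & nzchar(t$species)
  ifelse(ok, paste(t$genus, t$species), NA_character_)
}

genus_key <- function(t) {
  ifelse(t$qualifier != "indet" & nzchar(t$genus), t$genus, NA_character_)
}

#' Summarise an occurrence table
#'
#' Counts occurrences, distinct species (genus + epithet binomials among
#' species-determinate records), distinct genera, and unique geographic
#' localities (exact locality name plus coordinates rounded to 2 decimal
#' degrees, tolerating sub-km coordinate jitter between literature
#' sources).
#'
#' @param t An `occ_table`.
#' @return A `dataset_summary` list: `n_occurrences`, `n_species`,
#'   `n_genera`, `n_localities`.
#' @export
summarize_occurrences <- function(t) {
  stopifnot(inherits(t, "occ_table"))
  structure(list(
    n_occurrences = nrow(t),
    n_species = length(unique(stats::na.omit(species_key(t)))),
    n_genera = length(unique(stats::na.omit(genus_key(t)))),
    n_localities = if (nrow(t)) length(unique(locality_key(t))) else 0L
  ), class = "dataset_summary")
}

#' @export
print.dataset_summary <- function(x, ...) {
  cat(sprintf("%d occurrences, %d species, %d genera, %d unique localities\n",
              x$n_occurrences, x$n_species, x$n_genera, x$n_localities))
  invisible(x)
}
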