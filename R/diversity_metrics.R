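# Per-interval sampled-in-bin richness and sampling-effort proxies.

# common constructor for per-interval count series
new_interval_series <- function(interval_ids, counts, scheme_id, metric) {
  df <- data.frame(interval_id = interval_ids,
                   value = as.integer(counts), stringsAsFactors = FALSE)
  structure(df, scheme_id = scheme_id, metric = metric,
            class = c("interval_series", "data.frame"))
}

#' @export
print.interval_series <- function(x, ...) {
  cat(sprintf("<interval_series '%s'> scheme '%s', %d intervals\n",
              attr(x, "metric"), attr(x, "scheme_id"), nrow(x)))
  NextMethod()
}

# per-interval distinct count of `keys` (NA keys ignored); zero-filled
per_interval_distinct <- function(b, t, keys) {
  idx <- match(b$assignments$occurrence_id, t$occurrence_id)
  k <- keys[idx]
  iv <- b$assignments$interval_id
  keep <- !is.na(k)
  counts <- vapply(b$interval_ids, function(id) {
    length(unique(k[keep & iv == id]))
  }, integer(1))
  counts
}

#' Sampled-in-bin richness per interval
#'
#' Counts distinct genera (or distinct genus + epithet binomials among
#' species-determinate records) whose occurrences are assigned to each
#' interval. Face-value richness: no range interpolation between bins, and
#' intervals with no assignments report zero. Genus-level counts include
#' genus-determinate, species-indeterminate records; species-level counts
#' ignore them.
#'
#' @param b A `binned_occurrences` object.
#' @param t The `occ_table` the assignments refer to.
#' @param rank `"genus"` or `"species"`.
#' @return An `interval_series` data.frame (`interval_id, value`) ordered
#'   oldest to youngest, with attributes `scheme_id` and `metric`.
#' @export
richness_per_interval <- function(b, t, rank = c("genus", "species")) {
  stopifnot(inherits(b, "binned_occurrences"), inherits(t, "occ_table"))
  rank <- match.arg(rank)
  keys <- if (rank == "genus") genus_key(t) else species_key(t)
  if (rank == "species" && !any(!is.na(keys))) {
    warning("no species-determinate records; species richness is all zero")
  }
  new_interval_series(b$interval_ids, per_interval_distinct(b, t, keys),
                      b$scheme_id, paste0(rank, "_richness"))
}

#' Sampling-effort proxies per interval
#'
#' Computes the three per-interval sampling proxies: unique geographic
#' localities, unique geological units (formation/member/group names after
#' whitespace/case canonicalisation), and occupied equal-area grid cells.
#' Records without coordinates are excluded from the grid-cell proxy only
#' (their count is reported in the `missing_coordinates` attribute).
#'
#' @param b A `binned_occurrences` object.
#' @param t The `occ_table` the assignments refer to.
#' @param grid An `equal_area_grid` from [build_grid()].
#' @return Named list of three `interval_series`: `localities`,
#'   `geological_units`, `grid_cells`.
#' @export
sampling_proxies_per_interval <- function(b, t, grid) {
  stopifnot(inherits(b, "binned_occurrences"), inherits(t, "occ_table"),
            inherits(grid, "equal_area_grid"))
  loc <- new_interval_series(b$interval_ids,
                             per_interval_distinct(b, t, locality_key(t)),
                             b$scheme_id, "localities")
  units <- unit_key(t$geological_unit)
  units[!nzchar(units)] <- NA_character_
  geo <- new_interval_series(b$interval_ids, per_interval_distinct(b, t, units),
                             b$scheme_id, "geological_units")

  idx <- match(b$assignments$occurrence_id, t$occurrence_id)
  lat <- t$latitude[idx]
  lon <- t$longitude[idx]
  lkey <- locality_key(t)[idx]
  has_coord <- is.finite(lat) & is.finite(lon)
  iv <- b$assignments$interval_id
  cells <- vapply(b$interval_ids, function(id) {
    sel <- has_coord & iv == id
    if (!any(sel)) return(0L)
    dedup <- !duplicated(lkey[sel])
    occupied_cells_count(grid, data.frame(lat = lat[sel][dedup],
                                          lon = lon[sel][dedup]))
  }, integer(1))
  gc <- new_interval_series(b$interval_ids, cells, b$scheme_id, "grid_cells")
  attr(gc, "missing_coordinates") <- sum(!has_coord)
  list(localities = loc, geological_units = geo, grid_cells = gc)
}

#' Subset an occurrence table
#'
#' Retains records matching every stated predicate: depositional
#' environment, present-day region, exclusion of named localities (e.g. the
#' exceptionally diverse Bear Gulch and Glencartholm Lagerstaetten), and
#' exclusion of time intervals (records whose dated span overlaps any
#' excluded interval are dropped, e.g. to remove the Devonian).
#'
#' @param t An `occ_table`.
#' @param environment `"marine"`, `"freshwater"` or `"unknown"` (optional).
#' @param region One of [occurrence_regions()] (optional).
#' @param exclude_localities Character vector of locality names to drop
#'   (matched case-insensitively against `locality_name`).
#' @param exclude_intervals An `interval_scheme` or a data.frame with
#'   `start_ma`/`end_ma` columns listing spans to drop.
#' @param ts `timescale` used to resolve record spans when
#'   `exclude_intervals` is given.
#' @return The filtered `occ_table`; the applied filter is appended to its
#'   `provenance` attribute.
#' @export
subset_occurrences <- function(t, environment = NULL, region = NULL,
                               exclude_localities = NULL,
                               exclude_intervals = NULL,
                               ts = NULL) {
  stopifnot(inherits(t, "occ_table"))
  keep <- rep(TRUE, nrow(t))
  desc <- character(0)
  if (!is.null(environment)) {
    if (!environment %in% ENVIRONMENTS) {
      stop("unknown environment '", environment, "'", call. = FALSE)
    }
    keep <- keep & t$environment == environment
    desc <- c(desc, paste0("environment=", environment))
  }
  if (!is.null(region)) {
    if (!region %in% occurrence_regions()) {
      stop("unknown region '", region, "'", call. = FALSE)
    }
    keep <- keep & t$region == region
    desc <- c(desc, paste0("region=", region))
  }
  if (!is.null(exclude_localities)) {
    keep <- keep & !(tolower(t$locality_name) %in% tolower(exclude_localities))
    desc <- c(desc, paste0("exclude_localities=",
                           paste(exclude_localities, collapse = "+")))
  }
  if (!is.null(exclude_intervals)) {
    spans <- if (inherits(exclude_intervals, "interval_scheme"))
      exclude_intervals$intervals else as.data.frame(exclude_intervals)
    if (is.null(ts)) ts <- load_timescale()
    rs <- resolve_spans(t, ts)
    overlaps <- rep(FALSE, nrow(t))
    dated <- is.na(rs$reason)
    for (j in seq_len(nrow(spans))) {
      overlaps <- overlaps | (dated &
        pmin(rs$start_ma, spans$start_ma[j]) -
          pmax(rs$end_ma, spans$end_ma[j]) > AGE_TOL)
    }
    keep <- keep & !overlaps
    desc <- c(desc, sprintf("exclude_intervals=%d spans", nrow(spans)))
  }
  out <- t[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cleaning_log") <- attr(t, "cleaning_log")
  attr(out, "provenance") <- paste0(attr(t, "provenance"),
                                    if (length(desc)) paste0(" | filter: ",
                                                             paste(desc, collapse = ", ")))
  class(out) <- class(t)
  out
}

#' Export per-interval series in tidy form
#'
#' Stacks one or more `interval_series` into a tidy data.frame
#' (`scheme_id, interval_id, metric, value`) ready for CSV export or
#' plotting.
#'
#' @param ... `interval_series` objects (or a single list of them).
#' @return A tidy data.frame.
#' @export
series_table <- function(...) {
  xs <- list(...)
  if (length(xs) == 1 && !inherits(xs[[1]], "interval_series")) xs <- xs[[1]]
  do.call(rbind, lapply(xs, function(s) {
    data.frame(scheme_id = attr(s, "scheme_id"), interval_id = s$interval_id,
               metric = attr(s, "metric"), value = s$value,
               stringsAsFactors = FALSE)
  }))
}
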