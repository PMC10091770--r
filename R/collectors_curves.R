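# Collector's curves: cumulative counts of described species through
# publication year, globally and by present-day region.

#' Collector's curve of species descriptions
#'
#' Builds cumulative counts of distinct described species against the year
#' each species was first described. Every species (distinct genus +
#' epithet binomial among species-determinate records) is counted once, at
#' the earliest `year_described` across its records; with
#' `by_region = TRUE` the species is attributed to the region of that
#' earliest-described record (ties broken alphabetically by region), so the
#' stacked regional curves sum exactly to the global curve. Species without
#' a description year are excluded and counted in the `excluded` attribute.
#'
#' Curves are sparse: one point per year in which at least one new species
#' was described. A plateau in the curve suggests sampling saturation of
#' the record.
#'
#' @param t An `occ_table` (cleaned or raw; the species total depends on
#'   which is supplied).
#' @param by_region Also break the curve down by present-day region.
#' @return A `collectors_curve` data.frame `group, year,
#'   cumulative_count`, where `group` is `"global"` and, if requested, each
#'   region; attribute `excluded` counts species lacking a year.
#' @examples
#' \donttest{
#' syn <- generate_occurrences(scenario("trending_diversity_uniform_effort"))
#' cc <- collectors_curve(clean_occurrences(normalize_names(syn$table)))
#' utils::tail(cc, 1)  # final cumulative total
#' }
#' @export
collectors_curve <- function(t, by_region = FALSE) {
  stopifnot(inherits(t, "occ_table"))
  sp <- species_key(t)
  ok <- !is.na(sp)
  df <- data.frame(species = sp[ok], year = t$year_described[ok],
                   region = t$region[ok], stringsAsFactors = FALSE)
  has_year <- !is.na(df$year)
  excluded <- length(setdiff(unique(df$species), unique(df$species[has_year])))
  df <- df[has_year, , drop = FALSE]

  # earliest description per species; region ties broken alphabetically
  df <- df[order(df$species, df$year, df$region), , drop = FALSE]
  first <- df[!duplicated(df$species), , drop = FALSE]

  cum_curve <- function(years, group) {
    tab <- table(years)
    yr <- as.integer(names(tab))
    data.frame(group = group, year = yr,
               cumulative_count = cumsum(as.integer(tab)),
               stringsAsFactors = FALSE)
  }
  out <- cum_curve(first$year, "global")
  if (by_region) {
    reg <- first$region
    reg[!nzchar(reg)] <- "(no region)"
    for (r in sort(unique(reg))) {
      out <- rbind(out, cum_curve(first$year[reg == r], r))
    }
  }
  rownames(out) <- NULL
  structure(out, excluded = excluded,
            class = c("collectors_curve", "data.frame"))
}

#' Plot collector's curves
#'
#' Step plot of cumulative described species against year, one line per
#' group.
#'
#' @param x A `collectors_curve`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.collectors_curve <- function(x, ...) {
  groups <- unique(x$group)
  graphics::plot(NA, xlim = range(x$year), ylim = c(0, max(x$cumulative_count)),
                 xlab = "year described", ylab = "cumulative species", ...)
  for (i in seq_along(groups)) {
    g <- x[x$group == groups[i], ]
    graphics::lines(g$year, g$cumulative_count, type = "s", col = i)
  }
  if (length(groups) > 1) {
    graphics::legend("topleft", legend = groups, col = seq_along(groups),
                     lty = 1, cex = 0.7, bty = "n")
  }
  invisible(x)
}
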