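# OLS regressions of per-interval richness against sampling proxies,
# interval length and sea level.

#' Ordinary least-squares fit of one series on another
#'
#' Simple linear regression of per-interval richness on a per-interval
#' covariate, on raw (untransformed) values. Intervals missing from either
#' side are dropped pairwise; the p-value is the two-sided t test of zero
#' slope (equivalent to the F test for a simple regression) and R-squared
#' is the coefficient of determination.
#'
#' @param y An `interval_series` (the response, typically richness).
#' @param x An `interval_series` or a data.frame `interval_id, value` (the
#'   covariate).
#' @param log_y Regress `log1p(y)` instead of raw counts (off by default;
#'   raw linear regressions are the standard reporting).
#' @return A `regression_result`: list with `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, plus `n_dropped` and the series names.
#' @examples
#' s <- function(v, m) structure(data.frame(interval_id = letters[1:5], value = v),
#'                               scheme_id = "x", metric = m,
#'                               class = c("interval_series", "data.frame"))
#' regress(s(c(3, 5, 7, 9, 11), "richness"), s(1:5, "effort"))  # slope 2, R^2 1
#' @export
regress <- function(y, x, log_y = FALSE) {
  ydf <- as.data.frame(y)[, c("interval_id", "value")]
  xdf <- as.data.frame(x)[, c("interval_id", "value")]
  names(ydf)[2] <- "y"
  names(xdf)[2] <- "x"
  m <- merge(ydf, xdf, by = "interval_id")
  m <- m[is.finite(m$y) & is.finite(m$x), , drop = FALSE]
  n_dropped <- length(unique(c(ydf$interval_id, xdf$interval_id))) - nrow(m)
  if (nrow(m) < 3) {
    stop("need at least 3 shared intervals, have ", nrow(m), call. = FALSE)
  }
  xname <- attr(x, "metric")
  if (is.null(xname)) xname <- "x"
  if (stats::var(m$x) == 0) {
    stop("covariate '", xname, "' has zero variance", call. = FALSE)
  }
  yy <- if (log_y) log1p(m$y) else m$y
  fit <- stats::lm(yy ~ m$x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = nrow(m),
                 n_dropped = n_dropped,
                 response = attr(y, "metric"),
                 covariate = xname,
                 log_y = log_y),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS %s ~ %s: slope %.4g, R^2 = %.2f, p = %.3g (n = %d)\n",
              if (is.null(x$response)) "y" else x$response, x$covariate,
              x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Aggregate a sea-level time series onto intervals
#'
#' Collapses a sampled sea-level curve (age in Ma, level) to one value per
#' composite interval, either as the mean of the samples falling inside the
#' interval (default) or by linear interpolation at the interval midpoint.
#'
#' @param series Data.frame (or path to a 2-column CSV) with columns
#'   `age_ma, level`.
#' @param scheme An `interval_scheme`.
#' @param method `"mean"` or `"midpoint"`.
#' @return An `interval_series` of class numeric values (metric
#'   `"sea_level"`).
#' @export
sea_level_per_interval <- function(series, scheme, method = c("mean", "midpoint")) {
  method <- match.arg(method)
  stopifnot(inherits(scheme, "interval_scheme"))
  series <- as_table(series, c("age_ma", "level"))
  series$age_ma <- as.numeric(series$age_ma)
  series$level <- as.numeric(series$level)
  iv <- scheme$intervals
  vals <- if (method == "mean") {
    v <- vapply(seq_len(nrow(iv)), function(i) {
      sel <- series$age_ma > iv$end_ma[i] - AGE_TOL &
        series$age_ma <= iv$start_ma[i] + AGE_TOL
      if (!any(sel)) return(NA_real_)
      mean(series$level[sel])
    }, 0)
    if (any(is.na(v))) {
      stop("no sea-level samples inside interval(s): ",
           paste(iv$id[is.na(v)], collapse = ", "), call. = FALSE)
    }
    v
  } else {
    mid <- (iv$start_ma + iv$end_ma) / 2
    if (any(mid > max(series$age_ma) + AGE_TOL | mid < min(series$age_ma) - AGE_TOL)) {
      bad <- mid > max(series$age_ma) + AGE_TOL | mid < min(series$age_ma) - AGE_TOL
      stop("sea-level series does not cover interval midpoint(s): ",
           paste(iv$id[bad], collapse = ", "), call. = FALSE)
    }
    stats::approx(series$age_ma, series$level, xout = mid, ties = mean)$y
  }
  df <- data.frame(interval_id = iv$id, value = vals, stringsAsFactors = FALSE)
  structure(df, scheme_id = scheme$scheme_id, metric = "sea_level",
            class = c("interval_series", "data.frame"))
}

# interval-length covariate from a scheme
interval_length_series <- function(scheme) {
  df <- data.frame(interval_id = scheme$intervals$id,
                   value = scheme$intervals$duration_myr,
                   stringsAsFactors = FALSE)
  structure(df, scheme_id = scheme$scheme_id, metric = "interval_length",
            class = c("interval_series", "data.frame"))
}

# drop intervals lying (entirely) in the Devonian, i.e. older than the
# Devonian-Carboniferous boundary at 358.9 Ma
drop_devonian <- function(series, scheme, boundary_ma = 358.9) {
  iv <- scheme$intervals
  dev <- iv$id[iv$end_ma >= boundary_ma - AGE_TOL]
  out <- series[!series$interval_id %in% dev, , drop = FALSE]
  attributes(out)[c("scheme_id", "metric", "class")] <-
    attributes(series)[c("scheme_id", "metric", "class")]
  out
}

#' The nine-panel richness-correlate regression suite
#'
#' Runs the standard panel suite of genus-richness regressions on one
#' occurrence table binned into one scheme: (A) localities, (B) geological
#' units, (C) occupied equal-area grid cells, (D) interval length, (E) sea
#' level; (F) freshwater and (G) marine genus richness against sea level;
#' and (H) overall and (I) freshwater genus richness against sea level with
#' the Devonian intervals excluded. Panels E-I are skipped with a warning
#' when no sea-level series is supplied.
#'
#' @param t A cleaned `occ_table`.
#' @param scheme An `interval_scheme`.
#' @param ts A `timescale`.
#' @param grid An `equal_area_grid`.
#' @param sea_level Optional sea-level series (data.frame `age_ma, level`
#'   or CSV path).
#' @param policy Binning policy passed to [assign_to_intervals()].
#' @param sea_level_method Aggregation method for
#'   [sea_level_per_interval()].
#' @return A named list of `regression_result`s (class
#'   `regression_suite`); convert with `as.data.frame()` for the tidy
#'   results table.
#' @export
regression_suite <- function(t, scheme, ts, grid, sea_level = NULL,
                             policy = "strict", sea_level_method = "mean") {
  stopifnot(inherits(t, "occ_table"))
  b <- assign_to_intervals(t, scheme, ts, policy)
  rich <- richness_per_interval(b, t, "genus")
  prox <- sampling_proxies_per_interval(b, t, grid)

  out <- list(
    A_localities = regress(rich, prox$localities),
    B_geological_units = regress(rich, prox$geological_units),
    C_grid_cells = regress(rich, prox$grid_cells),
    D_interval_length = regress(rich, interval_length_series(scheme))
  )
  if (is.null(sea_level)) {
    warning("no sea-level series supplied; panels E-I skipped")
  } else {
    sl <- sea_level_per_interval(sea_level, scheme, sea_level_method)
    fresh <- subset_occurrences(t, environment = "freshwater")
    marine <- subset_occurrences(t, environment = "marine")
    rich_f <- richness_per_interval(assign_to_intervals(fresh, scheme, ts, policy),
                                    fresh, "genus")
    rich_m <- richness_per_interval(assign_to_intervals(marine, scheme, ts, policy),
                                    marine, "genus")
    out$E_sea_level <- regress(rich, sl)
    out$F_freshwater_sea_level <- regress(rich_f, sl)
    out$G_marine_sea_level <- regress(rich_m, sl)
    out$H_sea_level_no_devonian <- regress(drop_devonian(rich, scheme),
                                           drop_devonian(sl, scheme))
    out$I_freshwater_sea_level_no_devonian <-
      regress(drop_devonian(rich_f, scheme), drop_devonian(sl, scheme))
  }
  structure(out, class = "regression_suite")
}

#' @export
print.regression_suite <- function(x, ...) {
  for (nm in names(x)) {
    cat(format(nm, width = 36))
    print(x[[nm]])
  }
  invisible(x)
}

#' Tidy table of a regression suite
#'
#' @param x A `regression_suite`.
#' @param ... Unused.
#' @return Data.frame `panel, response, covariate, slope, intercept,
#'   r_squared, p_value, n`.
#' @export
as.data.frame.regression_suite <- function(x, ...) {
  do.call(rbind, lapply(names(x), function(nm) {
    r <- x[[nm]]
    data.frame(panel = sub("_.*", "", nm), response = r$response,
               covariate = r$covariate, slope = r$slope,
               intercept = r$intercept, r_squared = r$r_squared,
               p_value = r$p_value, n = r$n, stringsAsFactors = FALSE)
  }))
}
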