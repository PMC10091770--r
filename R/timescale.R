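#' Load a chronostratigraphic timescale
#'
#' Reads a stage table (ICS stage boundary ages) and a regional substage
#' table, validates them, and returns a `timescale` object used by interval
#' construction and occurrence binning. All ages are in Ma before present
#' (positive, older = larger). By default the packaged tables are used:
#' ICS boundary ages for the Lochkovian through Changhsingian stages
#' (v2021/10 chart) plus standard British/regional substage spans for the
#' Visean and Serpukhovian and substage-level splits of the Emsian and
#' Famennian. Both tables are plain CSV and user-replaceable.
#'
#' Stages must be ordered oldest to youngest and contiguous: the younger
#' bound of stage *i* must equal the older bound of stage *i* + 1 to within
#' `1e-6` Ma. Substage spans must lie within (or at least overlap) their
#' parent stage's span.
#'
#' @param stage_table Path to a CSV with columns `name, period, start_ma,
#'   end_ma`, or a data.frame with those columns. `NULL` for the packaged
#'   ICS table.
#' @param substage_table Path or data.frame with columns `name,
#'   parent_stage, start_ma, end_ma`. `NULL` for the packaged table.
#' @return An object of class `timescale`: a list with data.frames
#'   `stages` and `substages`.
#' @examples
#' ts <- load_timescale()
#' stage_duration(ts, "Kasimovian")  # 3.3 Myr
#' @export
load_timescale <- function(stage_table = NULL, substage_table = NULL) {
  if (is.null(stage_table)) stage_table <- actinodiv_extdata("ics_stages.csv")
  if (is.null(substage_table)) substage_table <- actinodiv_extdata("substages.csv")
  stages <- as_table(stage_table, c("name", "period", "start_ma", "end_ma"))
  substages <- as_table(substage_table, c("name", "parent_stage", "start_ma", "end_ma"))

  stages$start_ma <- as.numeric(stages$start_ma)
  stages$end_ma <- as.numeric(stages$end_ma)
  substages$start_ma <- as.numeric(substages$start_ma)
  substages$end_ma <- as.numeric(substages$end_ma)

  if (any(duplicated(stages$name))) {
    stop("duplicated stage name(s): ",
         paste(unique(stages$name[duplicated(stages$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!(stages$start_ma > stages$end_ma))) {
    bad <- stages$name[!(stages$start_ma > stages$end_ma)]
    stop("stage(s) with start_ma <= end_ma: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(stages$end_ma <= 0)) stop("stage ages must be positive", call. = FALSE)

  # order oldest -> youngest and check contiguity
  stages <- stages[order(-stages$start_ma), , drop = FALSE]
  rownames(stages) <- NULL
  if (nrow(stages) > 1) {
    gap <- abs(stages$end_ma[-nrow(stages)] - stages$start_ma[-1])
    if (any(gap > AGE_TOL)) {
      i <- which(gap > AGE_TOL)[1]
      stop(sprintf(
        "stages are not contiguous: gap/overlap of %.6g Myr between %s and %s",
        gap[i], stages$name[i], stages$name[i + 1]), call. = FALSE)
    }
  }

  unknown_parent <- setdiff(substages$parent_stage, stages$name)
  if (length(unknown_parent)) {
    stop("substage parent stage(s) not in stage table: ",
         paste(unknown_parent, collapse = ", "), call. = FALSE)
  }
  if (any(!(substages$start_ma > substages$end_ma))) {
    stop("substage(s) with start_ma <= end_ma", call. = FALSE)
  }
  # substage must overlap its parent stage
  parent <- stages[match(substages$parent_stage, stages$name), ]
  overlaps <- pmin(substages$start_ma, parent$start_ma) -
    pmax(substages$end_ma, parent$end_ma) > AGE_TOL
  if (any(!overlaps)) {
    stop("substage(s) outside their parent stage's span: ",
         paste(substages$name[!overlaps], collapse = ", "), call. = FALSE)
  }

  structure(list(stages = stages, substages = substages), class = "timescale")
}

#' @export
print.timescale <- function(x, ...) {
  cat(sprintf("<timescale> %d stages (%s, %.4g-%.4g Ma), %d substages\n",
              nrow(x$stages),
              paste(unique(x$stages$period), collapse = "/"),
              max(x$stages$start_ma), min(x$stages$end_ma),
              nrow(x$substages)))
  invisible(x)
}

#' Duration of a named stage
#'
#' @param ts A `timescale`.
#' @param name Stage name.
#' @return Duration in Myr.
#' @export
stage_duration <- function(ts, name) {
  stopifnot(inherits(ts, "timescale"))
  i <- match(name, ts$stages$name)
  if (is.na(i)) stop("unknown stage: ", name, call. = FALSE)
  ts$stages$start_ma[i] - ts$stages$end_ma[i]
}

# look up the span of a scheme member (stage or substage); NULL if unknown
member_span <- function(ts, kind, name) {
  tab <- if (identical(kind, "stage")) ts$stages else
    if (identical(kind, "substage")) ts$substages else
      stop("member_kind must be 'stage' or 'substage', got '", kind, "'",
           call. = FALSE)
  i <- match(tolower(name), tolower(tab$name))
  if (is.na(i)) return(NULL)
  c(start_ma = tab$start_ma[i], end_ma = tab$end_ma[i])
}

#' Build composite time intervals from a scheme table
#'
#' Constructs named composite intervals (time bins) by merging and/or
#' splitting stages according to a scheme table, as used to form bins of
#' roughly equal length (~9 Myr) from Palaeozoic stages whose durations
#' span 2.2-15.8 Myr. The packaged default scheme merges short stages
#' (e.g. Kasimovian + Gzhelian) and splits long ones at substage
#' boundaries (e.g. the Visean into a Chadian-Holkerian and an
#' Asbian-Brigantian sub-interval).
#'
#' The scheme table has one row per composite member:
#' `composite_id, label, member_kind (stage|substage), member_name`.
#' Members of a composite must be contiguous, and composites must not
#' overlap; the interval list is returned ordered oldest to youngest.
#'
#' @param ts A `timescale` from [load_timescale()].
#' @param scheme Path or data.frame in the scheme format; `NULL` for the
#'   packaged equal-length scheme.
#' @return An object of class `interval_scheme`: list with `intervals`
#'   (data.frame `id, label, start_ma, end_ma, duration_myr`), `members`
#'   (the scheme rows with resolved spans) and `scheme_id`.
#' @examples
#' ts <- load_timescale()
#' eq <- build_composite_intervals(ts)
#' range(eq$intervals$duration_myr)
#' @export
build_composite_intervals <- function(ts, scheme = NULL) {
  stopifnot(inherits(ts, "timescale"))
  scheme_id <- if (is.null(scheme)) "equal_length" else
    if (is.character(scheme)) tools::file_path_sans_ext(basename(scheme)) else "custom"
  if (is.null(scheme)) scheme <- actinodiv_extdata("equal_length_intervals.csv")
  members <- as_table(scheme, c("composite_id", "label", "member_kind", "member_name"))

  spans <- t(vapply(seq_len(nrow(members)), function(i) {
    sp <- member_span(ts, members$member_kind[i], members$member_name[i])
    if (is.null(sp)) {
      stop("scheme member not found in timescale: ",
           members$member_kind[i], " '", members$member_name[i], "'",
           call. = FALSE)
    }
    sp
  }, c(start_ma = 0, end_ma = 0)))
  members$start_ma <- spans[, "start_ma"]
  members$end_ma <- spans[, "end_ma"]

  ids <- unique(members$composite_id)
  intervals <- do.call(rbind, lapply(ids, function(id) {
    m <- members[members$composite_id == id, , drop = FALSE]
    m <- m[order(-m$start_ma), , drop = FALSE]
    # members must tile the composite without gaps
    if (nrow(m) > 1) {
      gap <- abs(m$end_ma[-nrow(m)] - m$start_ma[-1])
      if (any(gap > AGE_TOL)) {
        stop("members of composite '", id, "' are not contiguous", call. = FALSE)
      }
    }
    data.frame(id = id, label = m$label[1],
               start_ma = m$start_ma[1], end_ma = m$end_ma[nrow(m)],
               stringsAsFactors = FALSE)
  }))
  intervals$duration_myr <- intervals$start_ma - intervals$end_ma
  intervals <- intervals[order(-intervals$start_ma), , drop = FALSE]
  rownames(intervals) <- NULL

  if (nrow(intervals) > 1) {
    overlap <- intervals$end_ma[-nrow(intervals)] - intervals$start_ma[-1] < -AGE_TOL
    if (any(overlap)) {
      i <- which(overlap)[1]
      stop("overlapping composites: ", intervals$id[i], " and ",
           intervals$id[i + 1], call. = FALSE)
    }
  }

  structure(list(intervals = intervals, members = members, scheme_id = scheme_id),
            class = "interval_scheme")
}

#' One composite interval per stage
#'
#' The identity scheme: each ICS stage becomes its own interval (used for
#' comparing richness trends in standard stages against the equal-length
#' composite bins).
#'
#' @param ts A `timescale`.
#' @return An `interval_scheme` whose intervals coincide with the stages.
#' @export
stage_intervals <- function(ts) {
  stopifnot(inherits(ts, "timescale"))
  members <- data.frame(composite_id = ts$stages$name, label = ts$stages$name,
                        member_kind = "stage", member_name = ts$stages$name,
                        stringsAsFactors = FALSE)
  out <- build_composite_intervals(ts, members)
  out$scheme_id <- "ics_stages"
  out
}

#' @export
print.interval_scheme <- function(x, ...) {
  cat(sprintf("<interval_scheme '%s'> %d intervals, %.4g-%.4g Ma, durations %.3g-%.3g Myr\n",
              x$scheme_id, nrow(x$intervals),
              max(x$intervals$start_ma), min(x$intervals$end_ma),
              min(x$intervals$duration_myr), max(x$intervals$duration_myr)))
  invisible(x)
}

#' Write an interval scheme back to its CSV format
#'
#' Writes the scheme member table (`composite_id, label, member_kind,
#' member_name`) so that [build_composite_intervals()] on the written file
#' reconstructs the identical scheme.
#'
#' @param scheme An `interval_scheme`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_interval_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "interval_scheme"))
  utils::write.csv(
    scheme$members[, c("composite_id", "label", "member_kind", "member_name")],
    path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# interval membership for point ages: half-open (end_ma, start_ma], closed at
# the older bound so a boundary-aged datum belongs to the older interval; the
# scheme's youngest bound is additionally closed so the youngest interval
# contains its own younger boundary.
interval_of_age <- function(scheme, age) {
  iv <- scheme$intervals
  youngest <- min(iv$end_ma)
  idx <- vapply(age, function(a) {
    hit <- which(a <= iv$start_ma + AGE_TOL &
                   (a > iv$end_ma + AGE_TOL |
                      abs(iv$end_ma - youngest) <= AGE_TOL & a > iv$end_ma - AGE_TOL))
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  iv$id[idx]
}
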