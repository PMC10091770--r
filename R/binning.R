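# Assignment of occurrences to composite intervals.

# resolve the dated span of each record: substage span if present, else stage
# span, else the numeric [max_ma, min_ma] range
resolve_spans <- function(t, ts) {
  n <- nrow(t)
  start <- rep(NA_real_, n)
  end <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  sub_idx <- match(tolower(t$substage), tolower(ts$substages$name))
  stage_idx <- match(tolower(t$stage), tolower(ts$stages$name))
  for (i in seq_len(n)) {
    if (nzchar(t$substage[i])) {
      if (is.na(sub_idx[i])) {
        reason[i] <- paste0("unknown substage '", t$substage[i], "'")
        next
      }
      start[i] <- ts$substages$start_ma[sub_idx[i]]
      end[i] <- ts$substages$end_ma[sub_idx[i]]
    } else if (nzchar(t$stage[i])) {
      if (is.na(stage_idx[i])) {
        reason[i] <- paste0("unknown stage '", t$stage[i], "'")
        next
      }
      start[i] <- ts$stages$start_ma[stage_idx[i]]
      end[i] <- ts$stages$end_ma[stage_idx[i]]
    } else if (!is.na(t$max_ma[i]) && !is.na(t$min_ma[i])) {
      start[i] <- t$max_ma[i]
      end[i] <- t$min_ma[i]
    } else {
      reason[i] <- "no dating information"
    }
  }
  data.frame(start_ma = start, end_ma = end, reason = reason,
             stringsAsFactors = FALSE)
}

#' Assign occurrences to composite intervals
#'
#' Places each occurrence in interval(s) of a scheme using its dated span.
#' Dating resolution order: regional substage span if present (the substage
#' wins even when it conflicts with the named stage, as when a record
#' labelled Bashkirian carries an Arnsbergian substage and so belongs in
#' the Serpukhovian), else the ICS stage span, else the numeric
#' `[max_ma, min_ma]` range.
#'
#' Policies:
#' \describe{
#'   \item{`strict`}{assign only when the dated span lies inside a single
#'     interval; spans straddling a boundary (e.g. a bare "Visean" record
#'     under the split-Visean scheme) are left unassigned. The default and
#'     the most conservative reading of sampled-in-bin counting.}
#'   \item{`all_overlapping`}{assign to every interval the span intersects.}
#'   \item{`midpoint`}{assign to the interval containing the span midpoint
#'     (boundary midpoints fall to the older interval).}
#' }
#'
#' @param t An `occ_table`.
#' @param scheme An `interval_scheme`.
#' @param ts The `timescale` used to resolve stage/substage names.
#' @param policy `"strict"`, `"all_overlapping"` or `"midpoint"`.
#' @return A `binned_occurrences` object: list with `assignments`
#'   (data.frame `occurrence_id, interval_id`), `unassigned` (data.frame
#'   `occurrence_id, reason`), `scheme_id`, `policy` and the scheme's
#'   ordered `interval_ids`.
#' @export
assign_to_intervals <- function(t, scheme, ts,
                                policy = c("strict", "all_overlapping", "midpoint")) {
  stopifnot(inherits(t, "occ_table"), inherits(scheme, "interval_scheme"),
            inherits(ts, "timescale"))
  policy <- match.arg(policy)
  iv <- scheme$intervals
  spans <- resolve_spans(t, ts)

  # records sharing a dated span share an assignment: resolve each unique
  # span once, then expand back to records
  key <- ifelse(is.na(spans$reason),
                paste(spans$start_ma, spans$end_ma),
                paste("!", spans$reason))
  uniq <- !duplicated(key)
  resolved <- lapply(which(uniq), function(i) {
    if (!is.na(spans$reason[i])) {
      return(list(ids = character(0), reason = spans$reason[i]))
    }
    s0 <- spans$start_ma[i]
    s1 <- spans$end_ma[i]
    hits <- which(pmin(s0, iv$start_ma) - pmax(s1, iv$end_ma) > AGE_TOL)
    ids <- switch(policy,
      strict = {
        inside <- hits[s0 <= iv$start_ma[hits] + AGE_TOL &
                         s1 >= iv$end_ma[hits] - AGE_TOL]
        if (length(inside) == 1) iv$id[inside] else character(0)
      },
      all_overlapping = iv$id[hits],
      midpoint = {
        id <- interval_of_age(scheme, (s0 + s1) / 2)
        if (is.na(id)) character(0) else id
      })
    if (length(ids)) {
      list(ids = ids, reason = NA_character_)
    } else {
      list(ids = character(0),
           reason = if (length(hits) > 1) "span straddles multiple intervals"
             else "span outside scheme")
    }
  })
  names(resolved) <- key[uniq]

  per_rec <- resolved[key]
  n_ids <- vapply(per_rec, function(r) length(r$ids), 0L)
  all_ids <- unlist(lapply(per_rec, `[[`, "ids"), use.names = FALSE)
  assignments <- data.frame(
    occurrence_id = rep(t$occurrence_id, n_ids),
    interval_id = if (is.null(all_ids)) character(0) else all_ids,
    stringsAsFactors = FALSE)
  bad <- n_ids == 0
  un <- data.frame(occurrence_id = t$occurrence_id[bad],
                   reason = vapply(per_rec[bad], `[[`, "", "reason"),
                   stringsAsFactors = FALSE)
  rownames(un) <- NULL
  structure(list(assignments = assignments, unassigned = un,
                 scheme_id = scheme$scheme_id, policy = policy,
                 interval_ids = iv$id),
            class = "binned_occurrences")
}

#' @export
print.binned_occurrences <- function(x, ...) {
  cat(sprintf("<binned_occurrences> scheme '%s', policy '%s': %d assignments (%d occurrences), %d unassigned\n",
              x$scheme_id, x$policy, nrow(x$assignments),
              length(unique(x$assignments$occurrence_id)), nrow(x$unassigned)))
  invisible(x)
}

#' Export bin assignments as a data.frame
#'
#' @param x A `binned_occurrences` object.
#' @param ... Unused.
#' @return Data.frame with `occurrence_id, interval_id, policy, scheme_id`.
#' @export
as.data.frame.binned_occurrences <- function(x, ...) {
  if (!nrow(x$assignments)) {
    return(data.frame(occurrence_id = character(), interval_id = character(),
                      policy = character(), scheme_id = character(),
                      stringsAsFactors = FALSE))
  }
  data.frame(x$assignments, policy = x$policy, scheme_id = x$scheme_id,
             stringsAsFactors = FALSE)
}
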