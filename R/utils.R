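# internal helpers shared across modules

AGE_TOL <- 1e-6

#' Path to a packaged reference table
#'
#' Convenience accessor for the CSV tables shipped with the package
#' (ICS stage boundaries, regional substage spans, the equal-length
#' composite-interval scheme and the country-to-region lookup).
#'
#' @param file File name within the package's `extdata` directory. With no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
actinodiv_extdata <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "actinodiv")))
  }
  path <- system.file("extdata", file, package = "actinodiv")
  if (!nzchar(path)) {
    stop("no packaged file '", file, "'", call. = FALSE)
  }
  path
}

# collapse internal whitespace and trim
squish <- function(x) {
  gsub("^\\s+|\\s+$", "", gsub("\\s+", " ", x))
}

# "ELONICHTHYS" -> "Elonichthys"; species epithets are lower-cased elsewhere
capitalise <- function(x) {
  out <- tolower(x)
  has <- nzchar(out)
  substr(out[has], 1, 1) <- toupper(substr(out[has], 1, 1))
  out
}

# normalise longitudes to [-180, 180)
normalize_lon <- function(lon) {
  ((lon + 180) %% 360) - 180
}

# read a CSV with a mandatory header, keeping strings as strings
read_table_csv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing)) {
      stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  df
}

# coerce a path-or-data.frame argument
as_table <- function(x, required = NULL) {
  if (is.character(x) && length(x) == 1) {
    return(read_table_csv(x, required))
  }
  if (is.data.frame(x)) {
    if (!is.null(required)) {
      missing <- setdiff(required, names(x))
      if (length(missing)) {
        stop("missing column(s): ", paste(missing, collapse = ", "), call. = FALSE)
      }
    }
    return(x)
  }
  stop("expected a file path or data.frame", call. = FALSE)
}
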