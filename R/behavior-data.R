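#' One dyad's interval-coded behaviour series
#'
#' A `behavior_series` holds the binary presence/absence matrix of one
#' dyad's interaction: `T` observation intervals (rows, 1-based and
#' contiguous) by behaviour categories (columns). Several categories may
#' co-occur within one interval. The interval length (default 2 s) is
#' carried as metadata only; all statistics are index-based.
#'
#' @param dyad_id dyad identifier (coerced to character).
#' @param values binary matrix or data frame, intervals x categories, with
#'   column names giving the category identifiers.
#' @param interval_length interval duration in seconds (metadata).
#' @return An object of class `behavior_series`.
#' @examples
#' behavior_series("d1", cbind(`M+` = c(1, 0, 1), `C+` = c(0, 1, 1)))
#' @export
behavior_series <- function(dyad_id, values, interval_length = 2) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    stop("'values' must have category column names")
  storage.mode(values) <- "numeric"
  if (anyNA(values) || !all(values %in% c(0, 1)))
    stop("behaviour values must be binary 0/1")
  rownames(values) <- NULL
  structure(list(dyad_id = as.character(dyad_id),
                 interval_length = interval_length,
                 values = values),
            class = "behavior_series")
}

#' @export
print.behavior_series <- function(x, ...) {
  cat("Behavior series for dyad '", x$dyad_id, "': ",
      nrow(x$values), " intervals x ", ncol(x$values), " categories (",
      x$interval_length, " s each)\n", sep = "")
  invisible(x)
}

n_intervals <- function(series) nrow(series$values)

#' Read interval-coded behaviour tables
#'
#' Reads a long- or wide-layout CSV of binary behaviour codes into a list
#' of [behavior_series()], one per dyad. The long layout has columns
#' `dyad_id,interval,category,value`; the wide layout has `dyad_id,
#' interval` plus one column per category. Interval indices must run
#' `1..T` without gaps within each dyad; every cell must be 0 or 1.
#' Category labels not present in `scheme` are rejected, so that typos do
#' not silently become empty categories. Categories never coded for a
#' dyad are filled with zero columns: the result always spans the full
#' category set of the scheme.
#'
#' @param source path or connection to a CSV file (header required).
#' @param scheme a [coding_scheme()]; defaults to [mcam_scheme()].
#' @param layout `"long"` or `"wide"`.
#' @param interval_length interval duration in seconds (metadata).
#' @return Named list of `behavior_series`, one element per dyad, in
#'   order of first appearance.
#' @export
read_behavior_table <- function(source, scheme = mcam_scheme(),
                                layout = c("long", "wide"),
                                interval_length = 2) {
  layout <- match.arg(layout)
  df <- utils::read.csv(source, stringsAsFactors = FALSE, check.names = FALSE)
  if (layout == "long") {
    need <- c("dyad_id", "interval", "category", "value")
    if (!all(need %in% names(df)))
      stop("long layout needs columns: ", paste(need, collapse = ", "))
    unknown <- setdiff(unique(df$category), scheme$categories)
    if (length(unknown))
      stop("unknown category labels: ", paste(unknown, collapse = ", "))
    if (anyDuplicated(df[c("dyad_id", "interval", "category")]))
      stop("duplicate (dyad_id, interval, category) rows")
    split_rows <- split(df, factor(df$dyad_id, levels = unique(df$dyad_id)))
    lapply(split_rows, function(d) {
      tt <- sort(unique(d$interval))
      if (!identical(as.numeric(tt), as.numeric(seq_along(tt))))
        stop("interval indices for dyad '", d$dyad_id[1],
             "' must form 1..T without gaps")
      m <- matrix(0, nrow = length(tt), ncol = length(scheme$categories),
                  dimnames = list(NULL, scheme$categories))
      m[cbind(d$interval, match(d$category, scheme$categories))] <- d$value
      behavior_series(d$dyad_id[1], m, interval_length)
    })
  } else {
    if (!all(c("dyad_id", "interval") %in% names(df)))
      stop("wide layout needs columns dyad_id and interval")
    cats <- setdiff(names(df), c("dyad_id", "interval"))
    unknown <- setdiff(cats, scheme$categories)
    if (length(unknown))
      stop("unknown category labels: ", paste(unknown, collapse = ", "))
    if (anyDuplicated(df[c("dyad_id", "interval")]))
      stop("duplicate (dyad_id, interval) rows")
    split_rows <- split(df, factor(df$dyad_id, levels = unique(df$dyad_id)))
    lapply(split_rows, function(d) {
      d <- d[order(d$interval), , drop = FALSE]
      if (!identical(as.numeric(d$interval), as.numeric(seq_len(nrow(d)))))
        stop("interval indices for dyad '", d$dyad_id[1],
             "' must form 1..T without gaps")
      m <- matrix(0, nrow = nrow(d), ncol = length(scheme$categories),
                  dimnames = list(NULL, scheme$categories))
      m[, cats] <- as.matrix(d[cats])
      behavior_series(d$dyad_id[1], m, interval_length)
    })
  }
}

#' Write behaviour series to long-layout CSV
#'
#' Inverse of [read_behavior_table()] with `layout = "long"`: writing a
#' list of series and reading the file back reproduces each binary matrix
#' bit-exactly (zero cells included, so absent-vs-zero is unambiguous).
#'
#' @param series_list list of [behavior_series()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_behavior_table <- function(series_list, path) {
  rows <- lapply(series_list, function(s) {
    v <- s$values
    data.frame(dyad_id = s$dyad_id,
               interval = rep(seq_len(nrow(v)), times = ncol(v)),
               category = rep(colnames(v), each = nrow(v)),
               value = as.vector(v),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Aggregate subcategory codes into main-category codes
#'
#' A main category is scored present in an interval iff at least one of
#' its subcategories is present (logical OR), so duplicated subcategory
#' columns cannot inflate the code beyond 1. Categories the scheme codes
#' directly (no subcategories, e.g. `MAlone`) are passed through from an
#' identically named column when present, and zero-filled otherwise.
#'
#' @param sub a [behavior_series()] whose columns are subcategory (or
#'   directly coded category) identifiers.
#' @param scheme a [coding_scheme()].
#' @return A `behavior_series` over the scheme's main categories.
#' @export
aggregate_subcategories <- function(sub, scheme = mcam_scheme()) {
  v <- sub$values
  direct <- setdiff(scheme$categories, unname(scheme$subcategory_map))
  unmapped <- setdiff(colnames(v), c(names(scheme$subcategory_map), direct))
  if (length(unmapped))
    stop("unmapped subcategories: ", paste(unmapped, collapse = ", "))
  m <- matrix(0, nrow = nrow(v), ncol = length(scheme$categories),
              dimnames = list(NULL, scheme$categories))
  for (cat in scheme$categories) {
    subs <- names(scheme$subcategory_map)[scheme$subcategory_map == cat]
    cols <- intersect(c(subs, if (cat %in% direct) cat), colnames(v))
    if (length(cols))
      m[, cat] <- as.numeric(rowSums(v[, cols, drop = FALSE]) > 0)
  }
  behavior_series(sub$dyad_id, m, sub$interval_length)
}

#' Validate a behaviour series
#'
#' Reports (rather than errors on) invariant violations: non-binary
#' cells, fewer than two intervals (too short for any lag-1 sequencing),
#' and an empty category set. An empty character vector means the series
#' satisfies all invariants.
#'
#' @param series object to validate (normally a [behavior_series()], but
#'   malformed list structures are reported, not rejected).
#' @return Character vector of violation messages; `character(0)` if valid.
#' @export
validate_series <- function(series) {
  out <- character()
  v <- series$values
  if (is.null(v) || !is.matrix(v)) return("values is not a matrix")
  if (ncol(v) == 0) out <- c(out, "empty category set")
  if (nrow(v) < 2) out <- c(out, "too short for sequencing (T < 2)")
  if (anyNA(v) || !all(v %in% c(0, 1))) out <- c(out, "non-binary cell values")
  out
}

#' Read dyad-level attachment covariate scores
#'
#' Expects a CSV with columns `dyad_id,trust,avoidance,anxiety`; empty
#' cells become missing values and the record is retained. Scores outside
#' their instrument ranges (trust 1--4; avoidance and anxiety 1--7) are
#' flagged in an `out_of_range` attribute but not altered, leaving the
#' handling to the caller.
#'
#' @param source path or connection to a CSV file.
#' @return Data frame with one row per dyad and an `out_of_range`
#'   attribute (character vector of flags, possibly empty).
#' @export
read_attachment_scores <- function(source) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  need <- c("dyad_id", "trust", "avoidance", "anxiety")
  if (!all(need %in% names(df)))
    stop("scores file needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$dyad_id))
    stop("duplicate dyad_id in scores table")
  df <- df[need]
  df$dyad_id <- as.character(df$dyad_id)
  for (v in c("trust", "avoidance", "anxiety")) df[[v]] <- as.numeric(df[[v]])
  flags <- character()
  rng <- list(trust = c(1, 4), avoidance = c(1, 7), anxiety = c(1, 7))
  for (v in names(rng)) {
    bad <- which(!is.na(df[[v]]) & (df[[v]] < rng[[v]][1] | df[[v]] > rng[[v]][2]))
    if (length(bad))
      flags <- c(flags, sprintf("%s: %s out of range [%g, %g]",
                                df$dyad_id[bad], v, rng[[v]][1], rng[[v]][2]))
  }
  attr(df, "out_of_range") <- flags
  df
}

#' Instrument score ranges for the attachment covariates
#'
#' Trust is rated 1--4; avoidance and anxiety 1--7.
#' @return Named list of `c(min, max)` per covariate.
#' @export
attachment_ranges <- function() {
  list(trust = c(1, 4), avoidance = c(1, 7), anxiety = c(1, 7))
}
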