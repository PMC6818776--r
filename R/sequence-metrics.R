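#' Relative frequency of a behaviour category
#'
#' Proportion of observation intervals in which the category is present,
#' over the full series.
#'
#' @param series a [behavior_series()].
#' @param category category identifier.
#' @return Proportion in `[0, 1]`.
#' @examples
#' s <- behavior_series("d", cbind(`M+` = c(1, 0, 1, 1)))
#' relative_frequency(s, "M+")  # 0.75
#' @export
relative_frequency <- function(series, category) {
  v <- series$values
  if (!category %in% colnames(v)) stop("unknown category: ", category)
  mean(v[, category])
}

#' Lag-1 contingency counts for an ordered behaviour pair
#'
#' Over the `T - 1` ordered interval pairs `(t, t + 1)`, counts how often
#' the first behaviour at `t` is (`n11`) or is not (`n10`) followed by
#' the second behaviour at `t + 1`, how often the second appears at
#' `t + 1` without the first at `t` (`n01`), and how often neither does
#' (`n00`). `first` and `second` may name the same category (an
#' auto-loop, i.e. behavioural persistence).
#'
#' @param series a [behavior_series()] with at least two intervals.
#' @param first,second category identifiers.
#' @return List of class `lag_contingency` with elements `n11`, `n10`,
#'   `n01`, `n00` and `pairs` (`= T - 1`).
#' @export
lag_contingency <- function(series, first, second) {
  v <- series$values
  T <- nrow(v)
  if (T < 2) stop("need at least 2 intervals for lag-1 sequencing")
  for (id in unique(c(first, second)))
    if (!id %in% colnames(v)) stop("unknown category: ", id)
  a <- v[-T, first]   # first behaviour at t = 1..T-1
  b <- v[-1, second]  # second behaviour at t+1 = 2..T
  structure(list(n11 = sum(a == 1 & b == 1),
                 n10 = sum(a == 1 & b == 0),
                 n01 = sum(a == 0 & b == 1),
                 n00 = sum(a == 0 & b == 0),
                 pairs = T - 1L),
            class = "lag_contingency")
}

#' Observed Jaccard index of a lag-1 contingency
#'
#' `n11 / (n11 + n10 + n01)`; `NA` when neither behaviour ever occurs in
#' its window (0/0).
#'
#' @param c a [lag_contingency()].
#' @return Value in `[0, 1]`, or `NA`.
#' @export
jaccard_observed <- function(c) {
  den <- c$n11 + c$n10 + c$n01
  if (den == 0) NA_real_ else c$n11 / den
}

#' Expected Jaccard index under independence
#'
#' The Jaccard value expected if the two behaviours were sequenced purely
#' by chance at their observed rates: `p1 * p2 / (1 - (1 - p1) * (1 - p2))`.
#' `NA` when `p1 = p2 = 0` (the index is then 0/0).
#'
#' @param p1,p2 relative frequencies in `[0, 1]` of the first behaviour
#'   (over intervals `1..T-1`) and the second (over `2..T`).
#' @return Value in `[0, 1]`, or `NA`.
#' @export
jaccard_expected <- function(p1, p2) {
  if (anyNA(c(p1, p2)) || p1 < 0 || p1 > 1 || p2 < 0 || p2 > 1)
    stop("p1 and p2 must lie in [0, 1]")
  den <- 1 - (1 - p1) * (1 - p2)
  if (den == 0) NA_real_ else p1 * p2 / den
}

#' Chance-corrected lag-1 sequencing likelihood (normalized Jaccard)
#'
#' The sequencing likelihood of `first` at `t` being followed by `second`
#' at `t + 1`, corrected for chance co-sequencing:
#' `jac_norm = (jac_obs - jac_exp) / (1 - jac_exp)`. Like kappa, 0 means
#' the sequence occurs no more often than expected from the two
#' behaviours' rates alone, and 1 means the second behaviour always and
#' only follows the first.
#'
#' By default (`p_window = "lagged"`) the rates entering `jac_exp` are
#' taken over the same interval windows that generate the lag-1 pairs:
#' `p1` over `1..T-1` and `p2` over `2..T`. This makes observed and
#' expected indices range over an identical pair set, so a behaviour that
#' is always on yields exactly 0 against any second stream.
#' `p_window = "full"` uses full-series frequencies instead, for
#' sensitivity analysis.
#'
#' The statistic is undefined (`NA`) when either behaviour never occurs
#' in its window or when `jac_exp = 1` (both behaviours always present).
#'
#' @param series a [behavior_series()] with `T >= 2`.
#' @param first,second category identifiers (may be equal: auto-loop).
#' @param p_window `"lagged"` (default) or `"full"`.
#' @return List of class `sequence_stat`: `first`, `second`, `p1`, `p2`,
#'   `jac_obs`, `jac_exp`, `jac_norm`, and the contingency counts.
#' @examples
#' s <- behavior_series("d", cbind(a = c(1, 0, 1, 0, 1), b = c(0, 1, 0, 1, 0)))
#' jaccard_normalized(s, "a", "b")$jac_norm  # 1: b always follows a
#' @export
jaccard_normalized <- function(series, first, second,
                               p_window = c("lagged", "full")) {
  p_window <- match.arg(p_window)
  ct <- lag_contingency(series, first, second)
  T <- n_intervals(series)
  if (p_window == "lagged") {
    p1 <- mean(series$values[-T, first])
    p2 <- mean(series$values[-1, second])
  } else {
    p1 <- relative_frequency(series, first)
    p2 <- relative_frequency(series, second)
  }
  jac_obs <- jaccard_observed(ct)
  jac_exp <- jaccard_expected(p1, p2)
  # undefined whenever either behaviour never occurs in its window: a
  # sequencing tendency of a behaviour that is absent is not 0, it is
  # unobservable
  jac_norm <- if (p1 == 0 || p2 == 0 ||
                    is.na(jac_obs) || is.na(jac_exp) || jac_exp == 1)
    NA_real_ else (jac_obs - jac_exp) / (1 - jac_exp)
  structure(c(list(first = first, second = second, p1 = p1, p2 = p2,
                   jac_obs = jac_obs, jac_exp = jac_exp,
                   jac_norm = jac_norm),
              unclass(ct)[c("n11", "n10", "n01", "n00", "pairs")]),
            class = "sequence_stat")
}

#' @export
print.sequence_stat <- function(x, ...) {
  cat(sprintf("%s -> %s: jac_norm = %s (obs %s, exp %s; n11=%d n10=%d n01=%d)\n",
              x$first, x$second,
              format(x$jac_norm, digits = 3), format(x$jac_obs, digits = 3),
              format(x$jac_exp, digits = 3), x$n11, x$n10, x$n01))
  invisible(x)
}

#' Full per-dyad profile: frequencies and all ordered-pair sequences
#'
#' Computes the relative frequency of every category (over all `T`
#' intervals) and the sequencing statistics of every ordered category
#' pair, auto-loops included (`K^2` pairs; 49 for the default 7-category
#' scheme). Undefined statistics are `NA`, never dropped, so the profile
#' is always complete.
#'
#' @param series a [behavior_series()] with `T >= 2`.
#' @param p_window passed to [jaccard_normalized()].
#' @return Object of class `dyad_profile`: `dyad_id`, `frequencies`
#'   (named numeric), and `sequences` (data frame with one row per
#'   ordered pair: `first`, `second`, `p1`, `p2`, `jac_obs`, `jac_exp`,
#'   `jac_norm`, `n11`, `n10`, `n01`, `n00`).
#' @export
dyad_profile <- function(series, p_window = c("lagged", "full")) {
  p_window <- match.arg(p_window)
  if (n_intervals(series) < 2)
    stop("need at least 2 intervals for a dyad profile")
  cats <- colnames(series$values)
  freqs <- vapply(cats, function(k) relative_frequency(series, k), numeric(1))
  grid <- expand.grid(second = cats, first = cats, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)[, c("first", "second")]
  stats_list <- Map(function(f, s) {
    st <- jaccard_normalized(series, f, s, p_window)
    unlist(st[c("p1", "p2", "jac_obs", "jac_exp", "jac_norm",
                "n11", "n10", "n01", "n00")])
  }, grid$first, grid$second)
  seqs <- cbind(grid, as.data.frame(do.call(rbind, stats_list)))
  rownames(seqs) <- NULL
  structure(list(dyad_id = series$dyad_id, frequencies = freqs,
                 sequences = seqs, p_window = p_window),
            class = "dyad_profile")
}

#' @export
print.dyad_profile <- function(x, ...) {
  cat("Dyad profile '", x$dyad_id, "': ", length(x$frequencies),
      " categories, ", nrow(x$sequences), " ordered pairs (",
      sum(!is.na(x$sequences$jac_norm)), " defined)\n", sep = "")
  invisible(x)
}

#' Export dyad profiles to long CSV
#'
#' One row per measure: `dyad_id,measure_type,first,second,value`, with
#' `measure_type` `"frequency"` (`second` empty) or `"sequence"`
#' (`value` = jac_norm, empty when undefined).
#'
#' @param profiles list of [dyad_profile()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    rbind(
      data.frame(dyad_id = p$dyad_id, measure_type = "frequency",
                 first = names(p$frequencies), second = "",
                 value = unname(p$frequencies), stringsAsFactors = FALSE),
      data.frame(dyad_id = p$dyad_id, measure_type = "sequence",
                 first = p$sequences$first, second = p$sequences$second,
                 value = p$sequences$jac_norm, stringsAsFactors = FALSE)
    )
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
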