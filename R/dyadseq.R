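#' Lag-sequential analysis of a sample of dyads
#'
#' The central analysis: for every dyad, the relative frequency of each
#' behaviour category and the chance-corrected lag-1 sequencing
#' likelihood (normalized Jaccard index) of every ordered category pair
#' are computed; across dyads, each measure is summarised (mean, SD,
#' range, number of dyads showing it, proportion exceeding chance,
#' upper-tailed one-sample t-test) and, when covariate scores are given,
#' correlated with trust, avoidance and anxiety by Spearman and partial
#' Spearman correlation.
#'
#' Before the sample-level stages, dyads whose score on
#' `outlier_scale` is extreme (leave-one-out `|z| >=
#' outlier_threshold`) are set aside: a single extreme dyad would
#' otherwise dominate the rank correlations. Excluded dyads keep their
#' profiles and can be compared to the retained sample with
#' [compare_dyad()].
#'
#' @param series list of [behavior_series()] (e.g. from
#'   [read_behavior_table()] or [generate_sample()]`$series`), or a
#'   `synthetic_sample`, in which case its scores are used too.
#' @param scores optional covariate data frame (see
#'   [read_attachment_scores()]).
#' @param alpha significance level used by downstream network building.
#' @param p_window frequency-window convention for the expected Jaccard
#'   index; see [jaccard_normalized()].
#' @param outlier_scale covariate used for outlier screening (default
#'   `"trust"`); `NULL` disables screening.
#' @param outlier_threshold leave-one-out |z| cutoff (default 3).
#' @return Object of class `dyadseq` with elements `profiles` (retained
#'   dyads), `excluded_profiles`, `summary` (a `sample_summary`),
#'   `correlations` (or `NULL`), `scores`, `excluded` (score rows of
#'   screened-out dyads), `alpha`, `p_window`, `call`.
#' @examples
#' sm <- generate_sample(generator_config(n_dyads = 8, T = 40, seed = 7))
#' fit <- dyadseq(sm)
#' coef(fit)["C+", "M+"]  # mean sequencing likelihood C+ -> M+
#' @export
dyadseq <- function(series, scores = NULL, alpha = 0.05,
                    p_window = c("lagged", "full"),
                    outlier_scale = "trust", outlier_threshold = 3) {
  p_window <- match.arg(p_window)
  cl <- match.call()
  if (inherits(series, "synthetic_sample")) {
    if (is.null(scores)) scores <- series$scores
    series <- series$series
  }
  if (inherits(series, "behavior_series")) series <- list(series)
  for (s in series) {
    bad <- validate_series(s)
    if (length(bad))
      stop("invalid series for dyad '", s$dyad_id, "': ",
           paste(bad, collapse = "; "))
  }
  ids <- vapply(series, function(s) s$dyad_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate dyad ids")
  profiles <- lapply(series, dyad_profile, p_window = p_window)
  names(profiles) <- ids

  excluded_ids <- character()
  excluded_scores <- NULL
  if (!is.null(scores) && !is.null(outlier_scale) && nrow(scores) >= 3) {
    scores <- scores[match(ids, scores$dyad_id), , drop = FALSE]
    fl <- flag_outliers(scores, scale = outlier_scale,
                        threshold = outlier_threshold)
    excluded_ids <- fl$excluded$dyad_id
    excluded_scores <- fl$excluded
    scores <- fl$retained
  }
  retained <- profiles[setdiff(ids, excluded_ids)]
  summ <- if (length(retained) >= 2) summarize_sample(retained) else NULL
  corr <- NULL
  if (!is.null(scores) && length(retained) >= 3) {
    corr <- correlate_attachment(retained, scores)
  }
  structure(list(profiles = retained,
                 excluded_profiles = profiles[excluded_ids],
                 summary = summ, correlations = corr, scores = scores,
                 excluded = excluded_scores, alpha = alpha,
                 p_window = p_window, call = cl),
            class = "dyadseq")
}

#' @export
print.dyadseq <- function(x, ...) {
  cat("Lag-sequential dyad analysis\n")
  cat("  dyads analysed:", length(x$profiles),
      if (length(x$excluded_profiles))
        paste0("(", length(x$excluded_profiles), " screened out)") else "",
      "\n")
  cat("  frequency convention for chance correction:", x$p_window, "\n")
  if (!is.null(x$summary)) {
    sig <- x$summary$sequences
    n_sig <- sum(!is.na(sig$p_value) & sig$p_value < x$alpha)
    cat("  sequences above chance at alpha =", x$alpha, ":", n_sig, "of",
        nrow(sig), "\n")
  }
  if (!is.null(x$correlations))
    cat("  covariate correlations computed for:",
        paste(unique(x$correlations$covariate), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.dyadseq <- function(object, ...) {
  structure(list(fit = object), class = "summary.dyadseq")
}

#' @export
print.summary.dyadseq <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (!is.null(fit$summary)) {
    cat("\n")
    print(fit$summary)
  }
  if (!is.null(fit$correlations)) {
    co <- fit$correlations
    sig <- co[(!is.na(co$p_value) & co$p_value < fit$alpha) |
                (!is.na(co$partial_p) & co$partial_p < fit$alpha), ]
    cat("\nSignificant covariate correlations (alpha =", fit$alpha, "):\n")
    print(sig, digits = 2, row.names = FALSE)
  }
  invisible(x)
}

#' Mean sequencing likelihood matrix
#'
#' The across-dyad mean normalized Jaccard index for every ordered
#' category pair, as a first-behaviour x second-behaviour matrix
#' (defined dyads only; `NA` where no dyad has a defined statistic).
#'
#' @param object a [dyadseq()] fit.
#' @param ... unused.
#' @return Numeric K x K matrix.
#' @export
coef.dyadseq <- function(object, ...) {
  if (is.null(object$summary)) stop("no sample summary in this fit")
  sq <- object$summary$sequences
  cats <- object$summary$frequencies$category
  m <- matrix(NA_real_, length(cats), length(cats),
              dimnames = list(first = cats, second = cats))
  m[cbind(match(sq$first, cats), match(sq$second, cats))] <- sq$mean
  m
}

#' Plot analysis networks
#'
#' `type = "sample"` draws the sample-average network (node size = mean
#' relative frequency, edges = sequences deviating from chance);
#' `type = "correlation"` draws the network of one covariate's Spearman
#' correlations with the profile measures.
#'
#' @param x a [dyadseq()] fit.
#' @param type `"sample"` or `"correlation"`.
#' @param covariate covariate for `type = "correlation"`.
#' @param partial use partial correlations (correlation network only).
#' @param ... passed on to [plot.network_spec()].
#' @return The plotted [network_spec()], invisibly.
#' @export
plot.dyadseq <- function(x, type = c("sample", "correlation"),
                         covariate = "trust", partial = FALSE, ...) {
  type <- match.arg(type)
  spec <- if (type == "sample") {
    if (is.null(x$summary)) stop("no sample summary in this fit")
    build_sample_network(x$summary, alpha = x$alpha)
  } else {
    if (is.null(x$correlations)) stop("no covariate correlations in this fit")
    build_correlation_network(
      x$correlations[x$correlations$covariate == covariate, ],
      alpha = x$alpha, partial = partial)
  }
  plot(spec, ...)
  invisible(spec)
}

#' Compare one dyad to the rest of the sample
#'
#' z-scores every frequency and every defined sequencing likelihood of
#' one dyad against the distribution of the remaining analysed dyads —
#' the standard way to situate a screened-out (e.g. low-trust) dyad
#' relative to the main sample. Measures with a degenerate reference
#' (fewer than 2 defined values or zero spread) or undefined for the
#' dyad get `NA`.
#'
#' @param fit a [dyadseq()] fit.
#' @param dyad_id the dyad to compare; may be one of the analysed or one
#'   of the screened-out dyads.
#' @return Data frame: `measure_type`, `first`, `second`, `value`,
#'   `ref_mean`, `ref_sd`, `z`.
#' @export
compare_dyad <- function(fit, dyad_id) {
  all_prof <- c(fit$profiles, fit$excluded_profiles)
  if (!dyad_id %in% names(all_prof)) stop("unknown dyad: ", dyad_id)
  target <- all_prof[[dyad_id]]
  ref <- fit$profiles[setdiff(names(fit$profiles), dyad_id)]
  if (length(ref) < 3) stop("reference sample needs at least 3 dyads")
  cats <- names(target$frequencies)
  pairs <- target$sequences[c("first", "second")]
  measures <- rbind(
    data.frame(measure_type = "frequency", first = cats, second = NA,
               stringsAsFactors = FALSE),
    data.frame(measure_type = "sequence", first = pairs$first,
               second = pairs$second, stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(measures)), function(i) {
    f <- measures$first[i]; s <- measures$second[i]
    val <- if (is.na(s)) unname(target$frequencies[f]) else {
      j <- which(target$sequences$first == f & target$sequences$second == s)
      target$sequences$jac_norm[j]
    }
    rv <- measure_values(ref, f, s)
    rv <- rv[!is.na(rv)]
    z <- if (!is.na(val) && length(rv) >= 2 && stats::sd(rv) > 0)
      zscore_vs_sample(val, rv) else NA_real_
    data.frame(measure_type = measures$measure_type[i], first = f,
               second = s, value = val,
               ref_mean = if (length(rv)) mean(rv) else NA_real_,
               ref_sd = if (length(rv) >= 2) stats::sd(rv) else NA_real_,
               z = z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline and write a results bundle
#'
#' End-to-end driver: reads (or generates) the behaviour data and
#' covariate scores, fits [dyadseq()], and writes dyad profiles, the
#' frequency and sequence summary tables, the covariate correlation
#' table, network exports, and a run log recording every convention in
#' force, into `out_dir`. Exactly one of `input` and `config` must be
#' given. With fewer than 3 dyads (or no scores) the correlation stage
#' is skipped with a logged warning; summaries are still produced when
#' at least 2 dyads are available.
#'
#' @param input path to a behaviour CSV (see [read_behavior_table()]).
#' @param scores_path optional path to a covariate CSV.
#' @param config a [generator_config()], or path to a generator config
#'   file, to simulate the input instead of reading it.
#' @param out_dir output directory (created if needed).
#' @param scheme a [coding_scheme()] for reading `input`.
#' @param layout CSV layout of `input`.
#' @param alpha,p_window,outlier_scale,outlier_threshold passed to
#'   [dyadseq()].
#' @param format network export format, `"dot"` or `"graphml"`.
#' @param seed optional integer overriding the generator config's seed.
#' @return The [dyadseq()] fit, invisibly, with attribute `"paths"`
#'   listing the files written.
#' @export
run_analysis <- function(input = NULL, scores_path = NULL, config = NULL,
                         out_dir, scheme = mcam_scheme(),
                         layout = c("long", "wide"), alpha = 0.05,
                         p_window = c("lagged", "full"),
                         outlier_scale = "trust", outlier_threshold = 3,
                         format = c("dot", "graphml"), seed = NULL) {
  layout <- match.arg(layout)
  p_window <- match.arg(p_window)
  format <- match.arg(format)
  if (is.null(input) == is.null(config))
    stop("give exactly one of 'input' and 'config'")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- c(paste("run started:", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
                 paste("alpha:", alpha),
                 paste("p_window:", p_window),
                 paste("outlier screening:",
                       if (is.null(outlier_scale)) "off"
                       else paste0(outlier_scale, ", |z| >= ",
                                   outlier_threshold, " (leave-one-out)")),
                 "sequence summary denominators: defined statistics only",
                 "sequence t-test: one-sample vs 0, upper-tailed")
  scores <- NULL
  if (!is.null(config)) {
    if (is.character(config)) config <- read_generator_config(config)
    if (!is.null(seed)) config$seed <- as.integer(seed)
    sample <- generate_sample(config)
    series <- sample$series
    scores <- sample$scores
    write_behavior_table(series, file.path(out_dir, "behavior.csv"))
    utils::write.csv(scores, file.path(out_dir, "scores.csv"),
                     row.names = FALSE, quote = FALSE)
    log_lines <- c(log_lines,
                   paste("input: simulated;", config$n_dyads, "dyads x",
                         config$T, "intervals; seed", config$seed))
  } else {
    series <- read_behavior_table(input, scheme = scheme, layout = layout)
    log_lines <- c(log_lines, paste("input:", input, "(", layout, "layout )"))
    if (!is.null(scores_path)) {
      scores <- read_attachment_scores(scores_path)
      log_lines <- c(log_lines, paste("scores:", scores_path))
    } else {
      log_lines <- c(log_lines,
                     "warning: no scores table; correlation stage skipped")
    }
  }
  fit <- dyadseq(series, scores = scores, alpha = alpha, p_window = p_window,
                 outlier_scale = if (is.null(scores)) NULL else outlier_scale,
                 outlier_threshold = outlier_threshold)
  if (length(fit$excluded_profiles))
    log_lines <- c(log_lines, paste("screened out dyads:",
                                    paste(names(fit$excluded_profiles),
                                          collapse = ", ")))
  paths <- character()
  p <- file.path(out_dir, "profiles.csv")
  write_profiles(c(fit$profiles, fit$excluded_profiles), p)
  paths <- c(paths, p)
  if (!is.null(fit$summary)) {
    p <- file.path(out_dir, "frequency_summary.csv")
    utils::write.csv(fit$summary$frequencies, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
    p <- file.path(out_dir, "sequence_summary.csv")
    utils::write.csv(fit$summary$sequences, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
    p <- file.path(out_dir, paste0("sample_network.",
                                   if (format == "dot") "dot" else "graphml"))
    export_network(build_sample_network(fit$summary, alpha = alpha),
                   format = format, path = p)
    paths <- c(paths, p)
  } else {
    log_lines <- c(log_lines,
                   "warning: fewer than 2 analysed dyads; summaries skipped")
  }
  if (!is.null(fit$correlations)) {
    p <- file.path(out_dir, "correlations.csv")
    utils::write.csv(fit$correlations, p, row.names = FALSE, na = "")
    paths <- c(paths, p)
    for (cv in unique(fit$correlations$covariate)) {
      spec <- build_correlation_network(
        fit$correlations[fit$correlations$covariate == cv, ], alpha = alpha)
      p <- file.path(out_dir, paste0("network_", cv, ".",
                                     if (format == "dot") "dot" else "graphml"))
      export_network(spec, format = format, path = p)
      paths <- c(paths, p)
    }
  } else if (!is.null(scores) || is.null(config)) {
    log_lines <- c(log_lines,
                   "warning: correlation stage skipped (no scores or < 3 dyads)")
  }
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  attr(fit, "paths") <- c(paths, file.path(out_dir, "run_log.txt"))
  invisible(fit)
}
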