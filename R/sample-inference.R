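#' Upper-tailed one-sample t-test against zero
#'
#' Tests whether the across-dyad mean of a measure (typically a
#' sequencing likelihood) exceeds 0, using the upper tail only: the
#' question is whether the sequence occurs more often than chance, not
#' less.
#'
#' @param values numeric vector of defined dyad values (`NA` removed
#'   internally); needs at least 2 values with nonzero spread.
#' @return List with `t_stat`, `p_value` (one-tailed), `df`, `n`.
#' @export
upper_tailed_t <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need at least 2 defined values")
  if (stats::sd(values) == 0) stop("zero variance: t statistic undefined")
  ht <- stats::t.test(values, mu = 0, alternative = "greater")
  list(t_stat = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter), n = length(values))
}

#' Proportion of strictly positive values among defined ones
#'
#' The "PropDy>0" column: the share of dyads whose chance-corrected
#' sequencing likelihood is strictly positive, counted over dyads for
#' which the statistic is defined. `NA` when nothing is defined.
#'
#' @param values numeric vector, `NA` allowed.
#' @return Proportion in `[0, 1]`, or `NA`.
#' @export
prop_positive <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values)) return(NA_real_)
  mean(values > 0)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided
#' asymptotic (t-approximation) p-value. Incomplete pairs are dropped.
#'
#' @param x,y paired numeric vectors.
#' @return List with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(rank(x)) == 0 || stats::sd(rank(y)) == 0)
    stop("zero rank variance")
  ht <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ht$estimate), p_value = ht$p.value, n = length(x))
}

#' First-order partial Spearman correlation
#'
#' All three variables are rank-transformed (average ranks for ties) and
#' the first-order partial Pearson correlation is taken on the ranks:
#' `r_xy.z = (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`.
#' A two-sided p-value uses the t distribution with `n - 3` degrees of
#' freedom. With `control = NULL` this reduces to [spearman_cor()].
#'
#' @param x,y paired numeric vectors.
#' @param control control variable, or `NULL` for the unconditional
#'   correlation.
#' @return List with `rho`, `p_value`, `n`, `controlled` (logical).
#' @export
partial_spearman <- function(x, y, control = NULL) {
  if (is.null(control)) {
    out <- spearman_cor(x, y)
    out$controlled <- FALSE
    return(out)
  }
  ok <- stats::complete.cases(x, y, control)
  x <- x[ok]; y <- y[ok]; z <- control[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete triples")
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0 || stats::sd(rz) == 0)
    stop("zero rank variance")
  r_xy <- stats::cor(rx, ry)
  r_xz <- stats::cor(rx, rz)
  r_yz <- stats::cor(ry, rz)
  if (abs(r_xz) >= 1 - 1e-12 || abs(r_yz) >= 1 - 1e-12)
    stop("degenerate: control is rank-identical to x or y")
  pr <- (r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))
  pr <- max(-1, min(1, pr))
  tt <- pr * sqrt((n - 3) / max(1 - pr^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tt), df = n - 3)
  list(rho = pr, p_value = p, n = n, controlled = TRUE)
}

#' z-score of one value against a reference sample
#'
#' `(value - mean(reference)) / sd(reference)` with the `n - 1` sample
#' standard deviation, as used to compare a single dyad to the rest of
#' the sample.
#'
#' @param value numeric scalar.
#' @param reference numeric vector with at least 2 values and sd > 0
#'   (`NA` removed).
#' @return The z-score.
#' @export
zscore_vs_sample <- function(value, reference) {
  reference <- reference[!is.na(reference)]
  if (length(reference) < 2) stop("reference needs at least 2 values")
  s <- stats::sd(reference)
  if (s == 0) stop("zero reference standard deviation")
  (value - mean(reference)) / s
}

#' Flag covariate outliers by leave-one-out z-score
#'
#' For each dyad, its score on the chosen scale is z-scored against the
#' remaining dyads' scores; dyads with `|z| >= threshold` are excluded.
#' This mirrors screening out a single extreme dyad (e.g. one very
#' low-trust child) before sample-level analyses.
#'
#' @param scores data frame as from [read_attachment_scores()].
#' @param scale one of the covariate column names (default `"trust"`).
#' @param threshold absolute z-score cutoff (default 3).
#' @return List with `retained` and `excluded` (data frames) and `z`
#'   (named vector of leave-one-out z-scores; `NA` for missing scores).
#' @export
flag_outliers <- function(scores, scale = "trust", threshold = 3) {
  if (!scale %in% names(scores)) stop("unknown scale: ", scale)
  if (nrow(scores) < 3) stop("need at least 3 dyads")
  x <- scores[[scale]]
  z <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i])) next
    z[i] <- zscore_vs_sample(x[i], x[-i])
  }
  names(z) <- scores$dyad_id
  drop <- !is.na(z) & abs(z) >= threshold
  list(retained = scores[!drop, , drop = FALSE],
       excluded = scores[drop, , drop = FALSE],
       z = z)
}

#' Pooled Cohen's kappa across all interval-by-category decisions
#'
#' All binary coding decisions of two raters (every interval of every
#' dyad, every category) are pooled into a single 2x2 agreement table;
#' kappa corrects the observed agreement for the agreement expected from
#' the two raters' marginal presence rates. The 95% confidence interval
#' uses the large-sample standard error
#' `sqrt(p_o (1 - p_o) / (N (1 - p_e)^2))`; a nonparametric bootstrap
#' over pooled decisions is available as an alternative.
#'
#' @param coder_a,coder_b [behavior_series()] or lists thereof; same
#'   dyads, interval counts and categories in the same order.
#' @param ci `"asymptotic"` (default) or `"bootstrap"`.
#' @param nboot bootstrap replicates when `ci = "bootstrap"`.
#' @return List with `kappa`, `ci95` (length-2), `p_o`, `p_e`, `n`.
#' @export
pooled_kappa <- function(coder_a, coder_b, ci = c("asymptotic", "bootstrap"),
                         nboot = 1000) {
  ci <- match.arg(ci)
  if (inherits(coder_a, "behavior_series")) coder_a <- list(coder_a)
  if (inherits(coder_b, "behavior_series")) coder_b <- list(coder_b)
  if (length(coder_a) != length(coder_b))
    stop("coders must cover the same dyads")
  a <- unlist(lapply(coder_a, function(s) as.vector(s$values)))
  b <- unlist(lapply(coder_b, function(s) as.vector(s$values)))
  if (length(a) != length(b)) stop("shape mismatch between coders")
  n <- length(a)
  p_o <- mean(a == b)
  pa <- mean(a); pb <- mean(b)
  p_e <- pa * pb + (1 - pa) * (1 - pb)
  if (p_e >= 1) stop("degenerate marginals: expected agreement is 1")
  kap <- (p_o - p_e) / (1 - p_e)
  if (ci == "asymptotic") {
    se <- sqrt(p_o * (1 - p_o) / (n * (1 - p_e)^2))
    ci95 <- kap + c(-1, 1) * stats::qnorm(0.975) * se
  } else {
    boots <- replicate(nboot, {
      idx <- sample.int(n, n, replace = TRUE)
      ab <- a[idx]; bb <- b[idx]
      peb <- mean(ab) * mean(bb) + (1 - mean(ab)) * (1 - mean(bb))
      if (peb >= 1) NA_real_ else (mean(ab == bb) - peb) / (1 - peb)
    })
    ci95 <- unname(stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE))
  }
  list(kappa = kap, ci95 = ci95, p_o = p_o, p_e = p_e, n = n)
}

#' Between-coder agreement on derived dyad measures
#'
#' Correlates the focal measures of two independent coders — either the
#' relative frequencies or the sequencing likelihoods, computed per dyad
#' — across all paired defined values. Pearson by default; Spearman
#' available.
#'
#' @param profiles_a,profiles_b lists of [dyad_profile()] for the same
#'   dyads, in the same order.
#' @param measure_class `"frequency"` or `"sequence"`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return List with `r`, `p_value`, `n` (paired defined values).
#' @export
coder_measure_agreement <- function(profiles_a, profiles_b,
                                    measure_class = c("frequency", "sequence"),
                                    method = c("pearson", "spearman")) {
  measure_class <- match.arg(measure_class)
  method <- match.arg(method)
  if (length(profiles_a) != length(profiles_b))
    stop("both coders must profile the same dyads")
  pull <- function(p) {
    if (measure_class == "frequency") unname(p$frequencies)
    else p$sequences$jac_norm
  }
  va <- unlist(lapply(profiles_a, pull))
  vb <- unlist(lapply(profiles_b, pull))
  ok <- stats::complete.cases(va, vb)
  if (sum(ok) < 3) stop("fewer than 3 paired defined values")
  ht <- suppressWarnings(
    stats::cor.test(va[ok], vb[ok], method = method, exact = FALSE))
  list(r = unname(ht$estimate), p_value = ht$p.value, n = sum(ok))
}

# Collect one measure's value across dyad profiles: a frequency
# (second = NA) or a sequence pair's jac_norm.
measure_values <- function(profiles, first, second = NA) {
  vapply(profiles, function(p) {
    if (is.na(second)) unname(p$frequencies[first])
    else {
      i <- which(p$sequences$first == first & p$sequences$second == second)
      p$sequences$jac_norm[i]
    }
  }, numeric(1))
}

#' Across-dyad summary of frequencies and sequencing likelihoods
#'
#' Aggregates a sample of dyad profiles into two summary tables.
#'
#' The frequency table has, per category: the total count of intervals in
#' which it occurs, the number of dyads showing it at all, and the mean,
#' SD, min and max of its relative frequency.
#'
#' The sequence table has, per ordered pair: the number of dyads in which
#' the sequence is actually observed (`n11 > 0`), the number with a
#' defined likelihood, the proportion of those exceeding chance
#' (`prop_gt0`), the mean, SD, min and max of the defined likelihoods,
#' and an upper-tailed one-sample t-test of their mean against 0. Means,
#' SDs, ranges and `prop_gt0` are all computed over dyads with a defined
#' statistic only; `NA` marks summaries that cannot be formed.
#'
#' @param profiles list of [dyad_profile()] objects.
#' @return List of class `sample_summary` with data frames `frequencies`
#'   and `sequences`, and `n_dyads`.
#' @export
summarize_sample <- function(profiles) {
  if (!length(profiles)) stop("no profiles to summarize")
  cats <- names(profiles[[1]]$frequencies)
  # T per profile recovered from the lag-pair count: pairs = T - 1
  Ts <- vapply(profiles, function(p)
    sum(unlist(p$sequences[1, c("n11", "n10", "n01", "n00")])) + 1, numeric(1))
  freq_rows <- lapply(cats, function(k) {
    v <- measure_values(profiles, k)
    tot <- sum(v * Ts)
    data.frame(category = k, total = round(tot), dyads = sum(v > 0),
               mean = mean(v), sd = stats::sd(v),
               min = min(v), max = max(v), stringsAsFactors = FALSE)
  })
  pairs <- profiles[[1]]$sequences[c("first", "second")]
  seq_rows <- lapply(seq_len(nrow(pairs)), function(i) {
    f <- pairs$first[i]; s <- pairs$second[i]
    v <- measure_values(profiles, f, s)
    n11s <- vapply(profiles, function(p) {
      j <- which(p$sequences$first == f & p$sequences$second == s)
      p$sequences$n11[j]
    }, numeric(1))
    d <- v[!is.na(v)]
    tres <- if (length(d) >= 2 && stats::sd(d) > 0) upper_tailed_t(d)
            else list(t_stat = NA_real_, p_value = NA_real_)
    data.frame(first = f, second = s,
               dyads = sum(n11s > 0), n_defined = length(d),
               prop_gt0 = prop_positive(v),
               mean = if (length(d)) mean(d) else NA_real_,
               sd = if (length(d) >= 2) stats::sd(d) else NA_real_,
               min = if (length(d)) min(d) else NA_real_,
               max = if (length(d)) max(d) else NA_real_,
               t_stat = tres$t_stat, p_value = tres$p_value,
               stringsAsFactors = FALSE)
  })
  structure(list(frequencies = do.call(rbind, freq_rows),
                 sequences = do.call(rbind, seq_rows),
                 n_dyads = length(profiles)),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat("Sample summary over", x$n_dyads, "dyads\n\nRelative frequencies:\n")
  print(x$frequencies, digits = 3, row.names = FALSE)
  sig <- x$sequences[!is.na(x$sequences$p_value) & x$sequences$p_value < 0.05, ]
  cat("\nSequences exceeding chance (upper-tailed p < 0.05):",
      nrow(sig), "of", nrow(x$sequences), "\n")
  print(sig[c("first", "second", "dyads", "prop_gt0", "mean", "sd",
              "p_value")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Correlate dyad measures with attachment covariates
#'
#' Spearman correlations of every relative frequency and every
#' sequencing likelihood with trust, avoidance and anxiety, plus partial
#' Spearman correlations for avoidance controlling anxiety and vice
#' versa (the two subscales overlap substantially). No multiple-testing
#' correction is applied by default, matching the descriptive use of the
#' full correlation grid; Benjamini--Hochberg adjustment is available.
#'
#' @param profiles list of [dyad_profile()] objects.
#' @param scores covariate data frame (see [read_attachment_scores()]),
#'   matched to profiles by `dyad_id`.
#' @param adjust `"none"` (default) or `"BH"`; applied within each
#'   covariate column across measures.
#' @return Data frame, one row per measure x covariate: `measure_type`,
#'   `first`, `second`, `covariate`, `rho`, `p_value`, `partial_rho`,
#'   `partial_p` (partial columns `NA` for trust), `n`.
#' @export
correlate_attachment <- function(profiles, scores, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  ids <- vapply(profiles, function(p) p$dyad_id, character(1))
  scores <- scores[match(ids, scores$dyad_id), , drop = FALSE]
  covars <- c("trust", "avoidance", "anxiety")
  controls <- c(trust = NA, avoidance = "anxiety", anxiety = "avoidance")
  cats <- names(profiles[[1]]$frequencies)
  pairs <- profiles[[1]]$sequences[c("first", "second")]
  measures <- rbind(
    data.frame(measure_type = "frequency", first = cats, second = NA,
               stringsAsFactors = FALSE),
    data.frame(measure_type = "sequence", first = pairs$first,
               second = pairs$second, stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(measures)), function(i) {
    v <- measure_values(profiles, measures$first[i], measures$second[i])
    do.call(rbind, lapply(covars, function(cv) {
      res <- tryCatch(spearman_cor(v, scores[[cv]]),
                      error = function(e) list(rho = NA_real_,
                                               p_value = NA_real_, n = NA))
      ctrl <- controls[[cv]]
      pres <- if (is.na(ctrl)) list(rho = NA_real_, p_value = NA_real_)
      else tryCatch(partial_spearman(v, scores[[cv]], scores[[ctrl]]),
                    error = function(e) list(rho = NA_real_,
                                             p_value = NA_real_))
      data.frame(measure_type = measures$measure_type[i],
                 first = measures$first[i], second = measures$second[i],
                 covariate = cv, rho = res$rho, p_value = res$p_value,
                 partial_rho = pres$rho, partial_p = pres$p_value,
                 n = if (is.null(res$n)) NA else res$n,
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust == "BH") {
    for (cv in covars) {
      sel <- out$covariate == cv
      out$p_value[sel] <- stats::p.adjust(out$p_value[sel], method = "BH")
      out$partial_p[sel] <- stats::p.adjust(out$partial_p[sel], method = "BH")
    }
  }
  out
}
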