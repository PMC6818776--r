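# Run expr with a temporarily seeded RNG, restoring global state after.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic 32-bit substream seed from (seed, index).
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 10007 + as.double(index) * 7919) %% 2147483587)
}

#' Configuration of the synthetic dyad generator
#'
#' Defines the study conditions a generated sample emulates: number of
#' dyads, interaction length, per-category base rates, first-order
#' cross-lag couplings between stream pairs, and dyad-level covariates
#' linked to the realized coupling strengths.
#'
#' A coupling `(first, second, q1, q0)` makes the second stream at
#' interval `t + 1` Bernoulli(`q1`) when the first stream was present at
#' `t` and Bernoulli(`q0`) otherwise; categories targeted by no coupling
#' stay independent Bernoulli draws at their base rate, and several
#' couplings onto one target combine by noisy-OR. Per dyad, the realized
#' `q1` is jittered by a Gaussian deviation (sd `coupling_sd`, clipped to
#' `[0, 1]`), so dyads genuinely differ in sequencing strength; covariate
#' scores are built from the weighted sum of those deviations
#' (`covariate_link`), mixed with Gaussian noise so that the deviations
#' explain a `link_strength` share of the covariate's standardized
#' variance, then truncated to the instrument range.
#'
#' The defaults mirror a sample of 54 mother--child dyads observed for
#' 90 two-second intervals, with base rates near the typical relative
#' frequencies of the seven MCAM categories, persistent auto-loops plus
#' a positive mother--child loop (`M+` <-> `C+`) and a weaker negative
#' loop (`M-` -> `C-`), and covariates on the trust (1--4) and
#' avoidance/anxiety (1--7) scales with trust linked negatively, and
#' avoidance/anxiety positively, to the negative-loop strength.
#'
#' @param n_dyads number of dyads.
#' @param T intervals per dyad (default 90, i.e. 3 min of 2-s intervals).
#' @param base_rates named probability vector, one entry per category.
#' @param couplings data frame with columns `first`, `second`, `q1`,
#'   `q0`; each ordered pair at most once.
#' @param covariate_link named list: covariate -> data frame with columns
#'   `first`, `second`, `weight`.
#' @param covariate_moments named list: covariate -> `c(mean, sd)`.
#' @param coupling_sd sd of the per-dyad deviation added to each
#'   coupling's `q1`.
#' @param link_strength proportion (in `[0, 1)`) of covariate variance
#'   carried by the linked coupling deviations.
#' @param seed integer seed; all randomness derives from it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_dyads = 54, T = 90,
                             base_rates = c(`M+` = 0.45, `M-` = 0.02,
                                            `C+` = 0.39, `C-` = 0.05,
                                            MAlone = 0.13, CAlone = 0.47,
                                            Together = 0.04),
                             couplings = default_couplings(),
                             covariate_link = default_covariate_link(),
                             covariate_moments = list(
                               trust = c(3.51, 0.32),
                               avoidance = c(2.44, 0.84),
                               anxiety = c(2.11, 0.79)),
                             coupling_sd = 0.08,
                             link_strength = 0.6,
                             seed = 1L) {
  if (T < 2) stop("T must be at least 2")
  if (any(base_rates < 0 | base_rates > 1)) stop("base rates must be in [0, 1]")
  if (is.null(names(base_rates))) stop("base_rates must be named by category")
  couplings <- as.data.frame(couplings, stringsAsFactors = FALSE)
  if (nrow(couplings)) {
    if (!all(c("first", "second", "q1", "q0") %in% names(couplings)))
      stop("couplings need columns first, second, q1, q0")
    if (anyDuplicated(couplings[c("first", "second")]))
      stop("each ordered pair may appear at most once in couplings")
    if (any(couplings$q1 < 0 | couplings$q1 > 1 |
              couplings$q0 < 0 | couplings$q0 > 1))
      stop("coupling probabilities must be in [0, 1]")
    bad <- setdiff(unique(c(couplings$first, couplings$second)),
                   names(base_rates))
    if (length(bad))
      stop("couplings refer to unknown categories: ", paste(bad, collapse = ", "))
  }
  if (link_strength < 0 || link_strength >= 1)
    stop("link_strength must be in [0, 1)")
  structure(list(n_dyads = n_dyads, T = T, base_rates = base_rates,
                 couplings = couplings, covariate_link = covariate_link,
                 covariate_moments = covariate_moments,
                 coupling_sd = coupling_sd, link_strength = link_strength,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' @rdname generator_config
#' @export
default_couplings <- function() {
  data.frame(
    first  = c("M+", "C+", "M+", "C+", "M-", "C-", "M-",
               "MAlone", "CAlone", "Together"),
    second = c("M+", "M+", "C+", "C+", "M-", "C-", "C-",
               "MAlone", "CAlone", "Together"),
    q1 = c(0.55, 0.45, 0.40, 0.50, 0.30, 0.25, 0.25, 0.55, 0.75, 0.35),
    q0 = c(0.25, 0.25, 0.20, 0.20, 0.015, 0.04, 0.04, 0.065, 0.22, 0.027),
    stringsAsFactors = FALSE)
}

#' @rdname generator_config
#' @export
default_covariate_link <- function() {
  list(
    trust = data.frame(first = c("M-", "C-"), second = c("C-", "C-"),
                       weight = c(-1, -0.5), stringsAsFactors = FALSE),
    avoidance = data.frame(first = c("M-", "M+"), second = c("C-", "M+"),
                           weight = c(1, 0.5), stringsAsFactors = FALSE),
    anxiety = data.frame(first = "M-", second = "C-",
                         weight = 1, stringsAsFactors = FALSE)
  )
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Generator config:", x$n_dyads, "dyads x", x$T, "intervals;",
      nrow(x$couplings), "couplings; seed", x$seed, "\n")
  invisible(x)
}

#' Generate one dyad's behaviour series
#'
#' Simulates the coupled binary streams of a single dyad under `config`.
#' Interval 1 is drawn from the base rates; from interval 2 on, each
#' category targeted by couplings follows the (dyad-specific) lag-1
#' conditionals combined by noisy-OR, and every other category is an
#' independent Bernoulli draw. Fully reproducible from
#' `(config$seed, dyad_index)`; the global RNG state is left untouched.
#'
#' @param config a [generator_config()].
#' @param dyad_index 1-based dyad index, used both for the dyad id and
#'   the RNG substream.
#' @return A [behavior_series()] with attribute `"realized_couplings"`
#'   (the coupling table with dyad-specific `q1` and the deviation
#'   `delta` actually applied).
#' @export
generate_dyad <- function(config, dyad_index) {
  cats <- names(config$base_rates)
  K <- length(cats)
  cp <- config$couplings
  with_local_seed(derive_seed(config$seed, dyad_index), {
    if (nrow(cp)) {
      cp$delta <- stats::rnorm(nrow(cp), 0, config$coupling_sd)
      cp$q1_dyad <- pmin(1, pmax(0, cp$q1 + cp$delta))
    } else {
      cp$delta <- numeric(0)
      cp$q1_dyad <- numeric(0)
    }
    v <- matrix(0, nrow = config$T, ncol = K, dimnames = list(NULL, cats))
    v[1, ] <- stats::rbinom(K, 1, config$base_rates)
    targeted <- unique(cp$second)
    for (t in 2:config$T) {
      prob <- config$base_rates
      for (k in targeted) {
        rows <- which(cp$second == k)
        cond <- ifelse(v[t - 1, cp$first[rows]] == 1,
                       cp$q1_dyad[rows], cp$q0[rows])
        prob[k] <- 1 - prod(1 - cond)
      }
      v[t, ] <- stats::rbinom(K, 1, prob)
    }
    out <- behavior_series(sprintf("dyad%03d", dyad_index), v)
    attr(out, "realized_couplings") <- cp
    out
  })
}

#' Generate a full synthetic sample with linked covariates
#'
#' Generates `n_dyads` behaviour series via [generate_dyad()] and builds
#' attachment-style covariate scores from the dyads' realized coupling
#' deviations: for covariate `c` with moments `(m, s)` and linked
#' deviation sum `u_i` (weights from `covariate_link`),
#' `score_i = m + s * (sqrt(link_strength) * u_i / sd_pop(u) +
#' sqrt(1 - link_strength) * e_i)`, `e_i ~ N(0, 1)`, truncated to the
#' instrument range. `sd_pop(u)` is the theoretical sd
#' `coupling_sd * sqrt(sum w^2)`, so dyads remain independent.
#'
#' @param config a [generator_config()].
#' @return Object of class `synthetic_sample`: `series` (list of
#'   [behavior_series()]), `scores` (covariate data frame), and `truth`
#'   (the config plus the per-dyad realized coupling deviations).
#' @export
generate_sample <- function(config) {
  series <- lapply(seq_len(config$n_dyads), function(i)
    generate_dyad(config, i))
  ids <- vapply(series, function(s) s$dyad_id, character(1))
  deltas <- do.call(rbind, lapply(series, function(s)
    attr(s, "realized_couplings")$delta))
  if (!is.null(deltas) && ncol(deltas))
    colnames(deltas) <- paste(config$couplings$first, config$couplings$second,
                              sep = "->")
  ranges <- attachment_ranges()
  scores <- data.frame(dyad_id = ids, stringsAsFactors = FALSE)
  with_local_seed(derive_seed(config$seed, 0L), {
    for (cv in names(config$covariate_moments)) {
      m <- config$covariate_moments[[cv]][1]
      s <- config$covariate_moments[[cv]][2]
      link <- config$covariate_link[[cv]]
      u <- rep(0, config$n_dyads)
      sd_pop <- 0
      if (!is.null(link) && nrow(link) && !is.null(deltas)) {
        key <- paste(link$first, link$second, sep = "->")
        present <- key %in% colnames(deltas)
        if (any(present)) {
          u <- as.vector(deltas[, key[present], drop = FALSE] %*%
                           link$weight[present])
          sd_pop <- config$coupling_sd * sqrt(sum(link$weight[present]^2))
        }
      }
      lam <- if (sd_pop > 0) config$link_strength else 0
      e <- stats::rnorm(config$n_dyads)
      raw <- m + s * (sqrt(lam) * (if (sd_pop > 0) u / sd_pop else 0) +
                        sqrt(1 - lam) * e)
      rng <- if (cv %in% names(ranges)) ranges[[cv]] else c(-Inf, Inf)
      scores[[cv]] <- pmin(rng[2], pmax(rng[1], raw))
    }
  })
  structure(list(series = series, scores = scores,
                 truth = list(config = config, deltas = deltas)),
            class = "synthetic_sample")
}

#' @export
print.synthetic_sample <- function(x, ...) {
  cat("Synthetic sample:", length(x$series), "dyads x",
      x$truth$config$T, "intervals; covariates:",
      paste(setdiff(names(x$scores), "dyad_id"), collapse = ", "), "\n")
  invisible(x)
}

#' Read a generator configuration from a flat key-value file
#'
#' Lines of the form `key = value` (`#` comments allowed). Scalar keys:
#' `n_dyads`, `T`, `seed`, `coupling_sd`, `link_strength`. Dotted keys:
#' `base_rate.<category> = p`, `coupling.<first>.<second> = q1,q0`,
#' `link.<covariate>.<first>.<second> = weight`,
#' `covariate.<name> = mean,sd`. Keys not given keep their
#' [generator_config()] defaults; if any `base_rate.*` key is present
#' the default rate table is replaced wholesale, and likewise for
#' `coupling.*`, `link.*` and `covariate.*`.
#'
#' @param path path to the config file.
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, character(1), 1)
  vals <- vapply(kv, `[`, character(1), 2)
  args <- list()
  scalars <- c("n_dyads", "T", "seed", "coupling_sd", "link_strength")
  for (s in intersect(keys, scalars)) args[[s]] <- as.numeric(vals[keys == s])
  br <- grepl("^base_rate\\.", keys)
  if (any(br))
    args$base_rates <- stats::setNames(as.numeric(vals[br]),
                                       sub("^base_rate\\.", "", keys[br]))
  cpl <- grepl("^coupling\\.", keys)
  if (any(cpl)) {
    parts <- strsplit(sub("^coupling\\.", "", keys[cpl]), ".", fixed = TRUE)
    qq <- lapply(strsplit(vals[cpl], ","), as.numeric)
    args$couplings <- data.frame(
      first = vapply(parts, `[`, character(1), 1),
      second = vapply(parts, `[`, character(1), 2),
      q1 = vapply(qq, `[`, numeric(1), 1),
      q0 = vapply(qq, `[`, numeric(1), 2), stringsAsFactors = FALSE)
  }
  lk <- grepl("^link\\.", keys)
  if (any(lk)) {
    parts <- strsplit(sub("^link\\.", "", keys[lk]), ".", fixed = TRUE)
    df <- data.frame(cov = vapply(parts, `[`, character(1), 1),
                     first = vapply(parts, `[`, character(1), 2),
                     second = vapply(parts, `[`, character(1), 3),
                     weight = as.numeric(vals[lk]), stringsAsFactors = FALSE)
    args$covariate_link <- lapply(split(df, df$cov), function(d)
      d[c("first", "second", "weight")])
  }
  cvm <- grepl("^covariate\\.", keys)
  if (any(cvm)) {
    mm <- lapply(strsplit(vals[cvm], ","), as.numeric)
    args$covariate_moments <- stats::setNames(mm,
                                              sub("^covariate\\.", "", keys[cvm]))
  }
  do.call(generator_config, args)
}
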