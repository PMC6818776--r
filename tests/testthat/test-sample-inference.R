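test_that("upper-tailed t-test matches closed form and is monotone in the mean", {
  res <- upper_tailed_t(c(0.1, 0.2, 0.3))
  expect_equal(res$t_stat, 0.2 / (0.1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(res$t_stat, 3.4641, tolerance = 1e-4)
  expect_equal(res$p_value, pt(res$t_stat, df = 2, lower.tail = FALSE))
  expect_equal(res$p_value, 0.0371, tolerance = 1e-3)

  sym <- upper_tailed_t(c(-1, 1))
  expect_equal(sym$t_stat, 0)
  expect_equal(sym$p_value, 0.5)

  expect_error(upper_tailed_t(c(0.2, 0.2, 0.2)), "variance")
  expect_error(upper_tailed_t(0.2), "at least 2")

  # p strictly decreasing in the sample mean at fixed sd and n
  base <- c(-0.1, 0, 0.1)
  ps <- sapply(seq(0, 0.5, by = 0.1), function(m) upper_tailed_t(base + m)$p_value)
  expect_true(all(diff(ps) < 0))
})

test_that("prop_positive counts strictly positive values among defined ones", {
  expect_equal(prop_positive(c(0.1, -0.2, 0.3, NA)), 2 / 3)
  expect_equal(prop_positive(c(1, 2, 3)), 1)
  expect_equal(prop_positive(c(0, -1)), 0)
  expect_true(is.na(prop_positive(c(NA_real_, NA_real_))))
})

test_that("spearman correlation matches the rank-Pearson oracle", {
  expect_equal(spearman_cor(1:3, c(10, 20, 30))$rho, 1)
  expect_equal(spearman_cor(1:3, c(3, 2, 1))$rho, -1)
  # tie case: oracle is Pearson on average ranks, computed here
  x <- c(1, 2, 2, 4); y <- c(1, 3, 2, 4)
  expect_equal(spearman_cor(x, y)$rho, cor(rank(x), rank(y)))
  expect_equal(spearman_cor(x, y)$rho, 0.9486833, tolerance = 1e-6)
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
  expect_error(spearman_cor(c(1, 1, 1), 1:3), "rank variance")

  # invariance under strictly monotone transforms
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(15); b <- rnorm(15)
    r0 <- spearman_cor(a, b)$rho
    expect_equal(spearman_cor(exp(a), b)$rho, r0)
    expect_equal(spearman_cor(a, b^3)$rho, r0)
  }
})

test_that("partial spearman agrees with rank-residualization and reduces cleanly", {
  set.seed(9)
  for (i in 1:10) {
    n <- sample(8:30, 1)
    z <- rnorm(n)
    x <- 0.5 * z + rnorm(n)
    y <- -0.3 * z + rnorm(n)
    got <- partial_spearman(x, y, z)$rho
    expect_equal(got, oracle_partial_resid(x, y, z), tolerance = 1e-10)
  }
  # empty control falls back to the plain spearman correlation
  for (i in 1:10) {
    x <- rnorm(12); y <- rnorm(12)
    expect_equal(partial_spearman(x, y, NULL)$rho, spearman_cor(x, y)$rho)
  }
  # plugging the first-order formula directly: r_xy = r_xz = r_yz = 0.5
  pr <- (0.5 - 0.5 * 0.5) / sqrt((1 - 0.25) * (1 - 0.25))
  expect_equal(pr, 1 / 3)
  yy <- rnorm(10)
  expect_error(partial_spearman(rnorm(10), yy, yy), "degenerate")
  expect_error(partial_spearman(1:3, 3:1, c(2, 1, 3)), "at least 4")
})

test_that("z-scores against a reference sample use the n-1 sd", {
  ref <- c(3.2, 3.4, 3.5, 3.6, 3.8)
  expect_equal(zscore_vs_sample(mean(ref), ref), 0)
  expect_equal(zscore_vs_sample(1.5, ref), (1.5 - mean(ref)) / sd(ref))
  expect_error(zscore_vs_sample(1, rep(2, 5)), "zero")
  expect_error(zscore_vs_sample(1, 2), "at least 2")
  # on the published reference moments the low-trust child sits ~ -6.3 sd out
  expect_equal((1.5 - 3.51) / 0.32, -6.28, tolerance = 1e-2)
})

test_that("leave-one-out outlier screening isolates a single extreme dyad", {
  sc <- data.frame(dyad_id = paste0("d", 1:55),
                   trust = c(rnorm(54, 3.5, 0.15), 1.5),
                   avoidance = 2.4, anxiety = 2.1)
  fl <- flag_outliers(sc, "trust", threshold = 3)
  expect_equal(fl$excluded$dyad_id, "d55")
  expect_equal(nrow(fl$retained), 54)
  # re-screening the retained sample finds nothing at the same threshold
  fl2 <- flag_outliers(fl$retained, "trust", threshold = 3)
  expect_equal(nrow(fl2$excluded), 0)

  homog <- data.frame(dyad_id = paste0("d", 1:10),
                      trust = seq(3.3, 3.7, length.out = 10))
  expect_equal(nrow(flag_outliers(homog, "trust", 3)$excluded), 0)
  expect_equal(nrow(flag_outliers(homog, "trust", 0)$retained), 0)
})

test_that("pooled kappa matches hand arithmetic and the independent implementation", {
  sA <- behavior_series("d", cbind(a = c(1, 1, 1, 1, 1), b = c(0, 0, 0, 0, 0)))
  sB <- behavior_series("d", cbind(a = c(1, 1, 1, 1, 1), b = c(1, 0, 0, 0, 0)))
  # pooled: 10 decisions, 9 agreements, marginals .5 and .6 -> kappa .8
  res <- pooled_kappa(sA, sB)
  expect_equal(res$p_o, 0.9)
  expect_equal(res$p_e, 0.5)
  expect_equal(res$kappa, 0.8)
  expect_equal(length(res$ci95), 2)
  expect_lt(res$ci95[1], res$kappa)
  expect_gt(res$ci95[2], res$kappa)

  expect_equal(pooled_kappa(sA, sA)$kappa, 1)
  opp <- behavior_series("d", 1 - sA$values)
  expect_equal(pooled_kappa(sA, opp)$kappa, -1)

  set.seed(33)
  for (i in 1:50) {
    a <- rand_series(20, 3, runif(1, 0.2, 0.8), "x")
    flip <- rand_series(20, 3, 0.2, "x")
    b <- behavior_series("x", abs(a$values - flip$values))
    got <- pooled_kappa(a, b)$kappa
    tab <- table(factor(as.vector(a$values), levels = 0:1),
                 factor(as.vector(b$values), levels = 0:1))
    expect_equal(got, e1071::classAgreement(tab)$kappa, tolerance = 1e-12)
    expect_gte(got, -1); expect_lte(got, 1)
  }
  expect_error(pooled_kappa(sA, behavior_series("d", cbind(a = c(1, 0)))),
               "mismatch")
})

test_that("coder measure agreement correlates paired defined measures", {
  sm <- small_sample(n = 5, T = 40)
  profs <- lapply(sm$series, dyad_profile)
  expect_equal(coder_measure_agreement(profs, profs, "frequency")$r, 1)
  doubled <- lapply(profs, function(p) {
    p$frequencies <- p$frequencies * 2  # linear rescale
    p
  })
  expect_equal(coder_measure_agreement(profs, doubled, "frequency")$r, 1)
  # hand-built Pearson oracle on 5 paired frequency values
  pa <- list(structure(list(frequencies = c(a = .1, b = .2, c = .3, d = .5, e = .9),
                            sequences = data.frame(jac_norm = numeric())),
                       class = "dyad_profile"))
  pb <- list(structure(list(frequencies = c(a = .2, b = .1, c = .4, d = .4, e = .8),
                            sequences = data.frame(jac_norm = numeric())),
                       class = "dyad_profile"))
  got <- coder_measure_agreement(pa, pb, "frequency")$r
  x <- c(.1, .2, .3, .5, .9); y <- c(.2, .1, .4, .4, .8)
  expect_equal(got, sum((x - mean(x)) * (y - mean(y))) /
                 sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))
  expect_equal(coder_measure_agreement(profs, profs, "sequence")$r, 1)
})

test_that("sample summaries honour their definitional identities", {
  sm <- small_sample(n = 12, T = 60, seed = 3)
  profs <- lapply(sm$series, dyad_profile)
  su <- summarize_sample(profs)
  expect_equal(nrow(su$frequencies), 7)
  expect_equal(nrow(su$sequences), 49)
  for (i in sample(nrow(su$sequences), 10)) {
    f <- su$sequences$first[i]; s <- su$sequences$second[i]
    v <- sapply(profs, function(p) {
      j <- which(p$sequences$first == f & p$sequences$second == s)
      p$sequences$jac_norm[j]
    })
    n11 <- sapply(profs, function(p) {
      j <- which(p$sequences$first == f & p$sequences$second == s)
      p$sequences$n11[j]
    })
    d <- v[!is.na(v)]
    expect_equal(su$sequences$dyads[i], sum(n11 > 0))
    expect_equal(su$sequences$n_defined[i], length(d))
    if (length(d)) {
      expect_equal(su$sequences$prop_gt0[i], mean(d > 0))
      expect_equal(su$sequences$mean[i], mean(d))
      expect_equal(su$sequences$min[i], min(d))
      expect_equal(su$sequences$max[i], max(d))
    }
  }
  # frequency side: dyads showing and totals
  Ts <- 60
  for (k in su$frequencies$category) {
    v <- sapply(profs, function(p) unname(p$frequencies[k]))
    expect_equal(su$frequencies$dyads[su$frequencies$category == k], sum(v > 0))
    expect_equal(su$frequencies$total[su$frequencies$category == k],
                 round(sum(v * Ts)))
  }
})

test_that("covariate correlation table covers the full measure grid", {
  sm <- small_sample(n = 10, T = 50, seed = 21)
  profs <- lapply(sm$series, dyad_profile)
  names(profs) <- sapply(sm$series, function(s) s$dyad_id)
  co <- correlate_attachment(profs, sm$scores)
  expect_equal(nrow(co), (7 + 49) * 3)
  expect_setequal(unique(co$covariate), c("trust", "avoidance", "anxiety"))
  expect_true(all(is.na(co$partial_rho[co$covariate == "trust"])))
  expect_true(all(abs(co$rho) <= 1, na.rm = TRUE))
  # BH adjustment never decreases a p-value
  co_bh <- correlate_attachment(profs, sm$scores, adjust = "BH")
  expect_true(all(co_bh$p_value >= co$p_value - 1e-12, na.rm = TRUE))
})
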