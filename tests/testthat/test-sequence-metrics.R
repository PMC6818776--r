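test_that("relative frequency is the proportion of intervals present", {
  s <- behavior_series("d", cbind(a = c(1, 0, 1, 1)))
  expect_equal(relative_frequency(s, "a"), 0.75)
  z <- behavior_series("d", cbind(a = rep(0, 5)))
  expect_equal(relative_frequency(z, "a"), 0)
  ten <- behavior_series("d", cbind(a = c(1, 1, rep(0, 8))))
  expect_equal(relative_frequency(ten, "a"), 0.2)
  expect_error(relative_frequency(s, "b"), "unknown")
})

test_that("lag-1 contingency counts match hand enumeration", {
  s <- two_stream(c(1, 0, 1, 1, 0), c(0, 1, 1, 0, 1))
  ct <- lag_contingency(s, "first", "second")
  expect_equal(unclass(ct)[c("n11", "n10", "n01", "n00")],
               list(n11 = 2, n10 = 1, n01 = 1, n00 = 0))
  expect_equal(ct$pairs, 4L)

  s2 <- two_stream(c(1, 0, 1, 0, 1), c(0, 1, 0, 1, 0))
  ct2 <- lag_contingency(s2, "first", "second")
  expect_equal(unclass(ct2)[c("n11", "n10", "n01", "n00")],
               list(n11 = 2, n10 = 0, n01 = 0, n00 = 2))

  auto <- behavior_series("d", cbind(a = c(1, 1, 0)))
  ct3 <- lag_contingency(auto, "a", "a")
  expect_equal(unclass(ct3)[c("n11", "n10", "n01", "n00")],
               list(n11 = 1, n10 = 1, n01 = 0, n00 = 0))

  expect_error(lag_contingency(behavior_series("d", cbind(a = 1)), "a", "a"),
               "at least 2")
})

test_that("contingency counts agree with the brute-force loop on random series", {
  set.seed(101)
  for (i in 1:300) {
    T <- sample(2:50, 1)
    s <- rand_series(T, K = 2, p = runif(1, 0.05, 0.95))
    ct <- lag_contingency(s, "k1", "k2")
    expect_equal(unlist(unclass(ct)[c("n11", "n10", "n01", "n00")]),
                 oracle_lag_counts(s$values[, "k1"], s$values[, "k2"]))
    expect_equal(ct$n11 + ct$n10 + ct$n01 + ct$n00, T - 1)
  }
})

test_that("observed and expected Jaccard follow their closed forms", {
  mk <- function(n11, n10, n01, n00)
    structure(list(n11 = n11, n10 = n10, n01 = n01, n00 = n00,
                   pairs = n11 + n10 + n01 + n00), class = "lag_contingency")
  expect_equal(jaccard_observed(mk(2, 1, 1, 0)), 0.5)
  expect_equal(jaccard_observed(mk(2, 0, 0, 2)), 1)
  expect_true(is.na(jaccard_observed(mk(0, 0, 0, 4))))

  expect_equal(jaccard_expected(0.75, 0.75), 0.6)
  expect_equal(jaccard_expected(0.5, 0.5), 1 / 3)
  expect_equal(jaccard_expected(1, 1), 1)
  expect_true(is.na(jaccard_expected(0, 0)))
  expect_error(jaccard_expected(-0.1, 0.5), "\\[0, 1\\]")
  expect_error(jaccard_expected(0.5, 1.2), "\\[0, 1\\]")
})

test_that("normalized Jaccard hits its anchors: perfect following, chance, below chance", {
  perfect <- two_stream(c(1, 0, 1, 0, 1), c(0, 1, 0, 1, 0))
  st <- jaccard_normalized(perfect, "first", "second")
  expect_equal(st$jac_obs, 1)
  expect_equal(st$jac_exp, 1 / 3)
  expect_equal(st$jac_norm, 1)

  chance <- two_stream(rep(1, 5), c(0, 1, 1, 0, 1))
  st2 <- jaccard_normalized(chance, "first", "second")
  expect_equal(st2$jac_obs, 0.75)
  expect_equal(st2$p1, 1)
  expect_equal(st2$p2, 0.75)
  expect_equal(st2$jac_exp, 0.75)
  expect_equal(st2$jac_norm, 0)

  below <- two_stream(c(1, 0, 1, 1, 0), c(0, 1, 1, 0, 1))
  st3 <- jaccard_normalized(below, "first", "second")
  expect_equal(st3$jac_obs, 0.5)
  expect_equal(st3$jac_exp, 0.6)
  expect_equal(st3$jac_norm, -0.25)
})

test_that("jac_norm bounds and attainment conditions hold on random series", {
  set.seed(202)
  saw_one <- saw_floor <- FALSE
  for (i in 1:400) {
    s <- rand_series(sample(2:40, 1), K = 2, p = runif(1, 0.1, 0.9))
    st <- jaccard_normalized(s, "k1", "k2")
    if (is.na(st$jac_norm)) next
    expect_lte(st$jac_norm, 1)
    if (st$jac_norm == 1) {
      expect_true(st$n10 == 0 && st$n01 == 0 && st$n11 > 0)
      saw_one <- TRUE
    }
    if (st$n11 == 0) {
      expect_equal(st$jac_norm, -st$jac_exp / (1 - st$jac_exp))
      saw_floor <- TRUE
    }
    expect_gte(st$jac_norm, -st$jac_exp / (1 - st$jac_exp) - 1e-12)
  }
  expect_true(saw_floor)
})

test_that("never-occurring behaviour yields NA, not zero and not an error", {
  s <- behavior_series("d", cbind(a = c(0, 0, 0, 0), b = c(1, 0, 1, 0)))
  st <- jaccard_normalized(s, "a", "b")
  expect_true(is.na(st$jac_norm))       # first never occurs
  st2 <- jaccard_normalized(s, "b", "a")
  expect_true(is.na(st2$jac_norm))      # second never occurs
  st3 <- jaccard_normalized(s, "a", "a")
  expect_true(is.na(st3$jac_norm))
})

test_that("the full-series frequency convention is available as a switch", {
  s <- two_stream(c(1, 1, 1, 1, 0), c(0, 1, 1, 0, 1))
  lag <- jaccard_normalized(s, "first", "second")
  full <- jaccard_normalized(s, "first", "second", p_window = "full")
  expect_equal(lag$p1, 1)        # first over 1..T-1
  expect_equal(full$p1, 0.8)     # first over all T
  expect_equal(lag$jac_obs, full$jac_obs)  # contingency unaffected
})

test_that("dyad profiles are complete with NA for undefined statistics", {
  m <- matrix(0, 2, 7, dimnames = list(NULL, mcam_scheme()$categories))
  m[, "M+"] <- 1
  p <- dyad_profile(behavior_series("d", m))
  expect_equal(unname(p$frequencies["M+"]), 1)
  expect_equal(sum(p$frequencies), 1)
  expect_equal(nrow(p$sequences), 49)
  auto <- p$sequences[p$sequences$first == "M+" & p$sequences$second == "M+", ]
  expect_true(is.na(auto$jac_norm))  # p1 = p2 = 1 => jac_exp = 1

  z <- dyad_profile(behavior_series("d", matrix(0, 3, 7,
         dimnames = list(NULL, mcam_scheme()$categories))))
  expect_true(all(z$frequencies == 0))
  expect_true(all(is.na(z$sequences$jac_norm)))

  expect_error(dyad_profile(behavior_series("d", m[1, , drop = FALSE])),
               "at least 2")
})

test_that("profile export writes one row per measure with blanks for NA", {
  sm <- small_sample(n = 2, T = 20)
  profs <- lapply(sm$series, dyad_profile)
  f <- withr::local_tempfile(fileext = ".csv")
  write_profiles(profs, f)
  df <- read.csv(f, stringsAsFactors = FALSE)
  expect_equal(nrow(df), 2 * (7 + 49))
  expect_setequal(unique(df$measure_type), c("frequency", "sequence"))
  freqs <- df[df$measure_type == "frequency" & df$dyad_id == profs[[1]]$dyad_id, ]
  expect_equal(freqs$value, unname(profs[[1]]$frequencies))
})
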