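test_that("lz is the log-probability of the chosen pattern", {
  # single item with chosen-category probability 0.5
  m1 <- toy_model(0, list(0), n_categories = 2)      # P = (0.5, 0.5)
  expect_equal(lz_observed(m1, 2L, 0), log(0.5), tolerance = 1e-12)
  # n identical items: additivity
  m4 <- toy_model(rep(0, 4), replicate(4, qlogis(0.3), simplify = FALSE),
                  n_categories = 2)
  expect_equal(lz_observed(m4, rep(2L, 4), 0), 4 * log(0.3),
               tolerance = 1e-12)
  expect_error(lz_observed(m1, NA_integer_, 0), "complete")
  expect_error(lz_observed(m1, 2L, Inf), "finite")
})

test_that("lz matches the exhaustive oracle on every 2-item pattern", {
  a <- c(1.3, 0.9)
  d <- list(c(2, 1, -1, -2), c(1.5, 0.5, -0.5, -1.5))
  model <- toy_model(a, d, n_categories = 5)
  theta <- 0.37
  for (y1 in 1:5) for (y2 in 1:5) {
    oracle <- log(raw_cat_probs(a[1], d[[1]], theta)[y1] *
                    raw_cat_probs(a[2], d[[2]], theta)[y2])
    expect_equal(lz_observed(model, c(y1, y2), theta), oracle,
                 tolerance = 1e-12)
  }
})

test_that("conditional moments agree with hand arithmetic and enumeration", {
  # symmetric two-point distribution: lz is constant, SD = 0
  m5 <- toy_model(0, list(0), n_categories = 2)
  cm <- conditional_moments(m5, 0)
  expect_equal(cm$e_lz, log(0.5), tolerance = 1e-12)
  expect_equal(cm$sd_lz, 0, tolerance = 1e-12)

  # P = (0.9, 0.1): E and Var by hand
  m9 <- toy_model(0, list(qlogis(0.1)), n_categories = 2)
  cm9 <- conditional_moments(m9, 0)
  E <- 0.9 * log(0.9) + 0.1 * log(0.1)
  V <- 0.9 * log(0.9)^2 + 0.1 * log(0.1)^2 - E^2
  expect_equal(cm9$e_lz, E, tolerance = 1e-10)
  expect_equal(cm9$sd_lz, sqrt(V), tolerance = 1e-10)

  # additivity over items
  m2i <- toy_model(c(0, 0), list(qlogis(0.1), qlogis(0.3)), n_categories = 2)
  cm2 <- conditional_moments(m2i, 0)
  e2 <- conditional_moments(toy_model(0, list(qlogis(0.3)), 2), 0)
  expect_equal(cm2$e_lz, cm9$e_lz + e2$e_lz, tolerance = 1e-10)

  # full-enumeration cross-check on a 3-item, 3-category toy model:
  # E(lz) and Var(lz) equal the pattern-weighted moments of lz itself
  probs <- list(c(0.5, 0.3, 0.2), c(0.2, 0.5, 0.3), c(0.1, 0.6, 0.3))
  m3 <- toy_model(rep(0, 3), lapply(probs, function(p)
    qlogis(rev(cumsum(rev(p)))[-1])), n_categories = 3)
  cm3 <- conditional_moments(m3, 0)
  pats <- as.matrix(expand.grid(1:3, 1:3, 1:3))
  lzs <- apply(pats, 1, function(y) lz_observed(m3, y, 0))
  wts <- apply(pats, 1, function(y)
    probs[[1]][y[1]] * probs[[2]][y[2]] * probs[[3]][y[3]])
  expect_equal(cm3$e_lz, sum(wts * lzs), tolerance = 1e-10)
  expect_equal(cm3$sd_lz, sqrt(sum(wts * lzs^2) - sum(wts * lzs)^2),
               tolerance = 1e-10)

  # a pattern made of modal categories beats its conditional expectation
  modal <- vapply(probs, which.max, 0L)
  zh_modal <- (lz_observed(m3, modal, 0) - cm3$e_lz) / cm3$sd_lz
  expect_gt(zh_modal, 0)
})

test_that("classification respects the cutoff with strict inequalities", {
  expect_identical(classify_zh(-3.92791), "misfitting")
  expect_identical(classify_zh(2.221422), "overfitting")
  expect_identical(classify_zh(c(-2, 2)), c("typical", "typical"))
  expect_identical(classify_zh(0.5, cutoff = 0.4), "overfitting")
  expect_error(classify_zh(1, cutoff = 0), "positive")
  expect_error(classify_zh(1, cutoff = -2), "positive")
})

test_that("Zh is invariant to item ordering", {
  cal <- cushingqol_calibration()
  pat <- c(1L, 2L, 4L, 4L, 4L, 5L, 4L, 3L, 3L, 2L, 5L, 5L)
  set.seed(42)
  perm <- sample(12)
  calp <- permute_model(cal, perm)
  zh1 <- zh_statistic(cal, pat)$zh
  zh2 <- zh_statistic(calp, pat[perm])$zh
  expect_equal(zh1, zh2, tolerance = 1e-10)
})

test_that("degenerate conditional variance yields a flagged NA result", {
  # equiprobable zero-slope items: log-probability constant everywhere
  m <- toy_model(c(0, 0), list(0, 0), n_categories = 2)
  pf <- person_fit(m, response_matrix(rbind(c(1L, 2L)), n_categories = 2))
  expect_true(pf$degenerate)
  expect_true(is.na(pf$zh))
})

test_that("on model-consistent cohorts Zh behaves like a standardized score", {
  cal <- cushingqol_calibration()
  coh <- simulate_clean(1000, cal, seed = 2024)
  pf <- person_fit(cal, coh$responses)
  # evaluating lz at the estimated (shrunken) theta biases Zh slightly
  # positive on clean data -- the known behaviour of uncorrected lz-type
  # statistics -- so the mean sits a few tenths above 0, not at 0
  expect_true(mean(pf$zh) > -0.3 && mean(pf$zh) < 0.5)
  expect_lt(mean(abs(pf$zh) > 2), 0.10)
  # sample standardization produces an exact z-score of lz
  pfs <- person_fit(cal, coh$responses, standardize = "sample")
  expect_equal(mean(pfs$zh), 0, tolerance = 1e-10)
  expect_equal(sd(pfs$zh), 1, tolerance = 1e-10)
})

test_that("random responders score stochastically lower than clean ones", {
  cal <- cushingqol_calibration()
  coh <- simulate_clean(500, cal, seed = 13)
  coh <- inject_aberrant(coh, "random", 0.05, seed = 14)
  pf <- person_fit(cal, coh$responses)
  zc <- pf$zh[coh$labels == "clean"]
  za <- pf$zh[coh$labels == "random"]
  expect_lt(median(za) - median(zc), -1)
})

test_that("ML theta estimation is available and tracks EAP", {
  cal <- cushingqol_calibration()
  pat <- c(3L, 4L, 5L, 4L, 4L, 4L, 3L, 4L, 4L, 4L, 3L, 3L)
  rm <- response_matrix(matrix(pat, 1))
  eap <- person_fit(cal, rm, theta_method = "EAP")
  ml <- person_fit(cal, rm, theta_method = "ML")
  # ML is less shrunken but close for a central, information-rich pattern
  expect_lt(abs(ml$theta.P - eap$theta.P), 0.5)
  expect_lt(abs(ml$zh - eap$zh), 0.5)
})
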