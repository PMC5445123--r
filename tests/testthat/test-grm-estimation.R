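test_that("marginal log-likelihood equals a hand-summed quadrature oracle", {
  grid <- quadrature_grid(1, quadpts = 3, theta_range = c(-3, 3))
  a <- c(1.2, 0.8)
  d <- list(c(1, -1), c(0.5, -0.5))
  model <- toy_model(a, d, n_categories = 3)
  Y <- rbind(c(1L, 3L), c(2L, 2L))
  rm <- response_matrix(Y, n_categories = 3)
  oracle <- 0
  for (p in 1:2) {
    like <- 0
    for (q in 1:3) {
      th <- grid$nodes[q, 1]
      like <- like + grid$weights[q] *
        raw_cat_probs(a[1], d[[1]], th)[Y[p, 1]] *
        raw_cat_probs(a[2], d[[2]], th)[Y[p, 2]]
    }
    oracle <- oracle + log(like)
  }
  expect_equal(marginal_loglik(model, rm, grid), oracle, tolerance = 1e-12)

  # additivity: duplicating a respondent doubles their contribution
  one <- response_matrix(Y[1, , drop = FALSE], n_categories = 3)
  two <- response_matrix(Y[c(1, 1), ], n_categories = 3)
  expect_equal(marginal_loglik(model, two, grid),
               2 * marginal_loglik(model, one, grid), tolerance = 1e-12)

  # theta-independent item with equal category probabilities
  m0 <- toy_model(0, list(qlogis(c(0.8, 0.6, 0.4, 0.2))), n_categories = 5)
  rm0 <- response_matrix(matrix(4L), n_categories = 5)
  expect_equal(marginal_loglik(m0, rm0, quadrature_grid(1, 5)), log(0.2),
               tolerance = 1e-9)
  expect_error(marginal_loglik(model, rm, quadrature_grid(2, 5)))
})

test_that("EAP scores match a three-node posterior-mean oracle and shrink", {
  # single two-category item, slope 1, intercept 0
  model <- toy_model(1, list(0), n_categories = 2)
  grid <- quadrature_grid(1, quadpts = 3, theta_range = c(-3, 3))
  rm <- response_matrix(matrix(2L), n_categories = 2)
  w <- grid$weights
  nodes <- grid$nodes[, 1]
  lik <- 1 / (1 + exp(-nodes))          # P(Y = 2 | node)
  oracle <- sum(nodes * w * lik) / sum(w * lik)
  eap <- eap_scores(model, rm, grid)
  expect_equal(eap$theta.F1, oracle, tolerance = 1e-12)

  # zero-slope model: posterior equals prior, theta-hat exactly 0
  m0 <- toy_model(c(0, 0), list(qlogis(c(0.7, 0.3)), qlogis(c(0.6, 0.2))),
                  n_categories = 3)
  rm0 <- response_matrix(rbind(c(1L, 3L), c(2L, 2L)), n_categories = 3)
  e0 <- eap_scores(m0, rm0)
  expect_equal(e0$theta.F1, c(0, 0), tolerance = 1e-12)

  # monotone likelihood ratio: all-max pattern scores above all-min
  cal <- cushingqol_calibration()
  ext <- response_matrix(rbind(rep(1L, 12), rep(5L, 12)))
  ee <- eap_scores(cal, ext)
  expect_true(all(ee[2, c("theta.P", "theta.S")] >
                    ee[1, c("theta.P", "theta.S")]))
  # shrinkage: posterior means stay inside the grid range
  expect_true(all(abs(ee$theta.P) < 6 & abs(ee$theta.S) < 6))
})

test_that("EM fits recover one-factor parameters and never decrease logLik", {
  slopes <- c(1.0, 1.5, 2.2, 1.2, 1.8, 2.6)
  d <- list(c(1.7, 0.1, -1.3, -3.4), c(2.3, 1.0, -0.4, -2.2),
            c(2.9, 1.1, -0.8, -2.8), c(1.2, -0.2, -1.7, -3.7),
            c(2.4, 0.7, -1.4, -3.9), c(0.6, -1.0, -3.5, -5.4))
  truth <- toy_model(slopes, d, n_categories = 5)
  coh <- simulate_clean(2000, truth, seed = 31)
  spec <- truth$spec
  fit <- fit_grm(coh$responses, spec, quadpts = 31)
  expect_true(fit$converged)
  a_hat <- vapply(fit$items, function(it) it$slopes[1], 0)
  expect_lt(mean(abs(a_hat - slopes)), 0.15)
  expect_true(all(a_hat > 0))
  d_err <- unlist(Map(function(itf, dt) itf$intercepts - dt, fit$items, d))
  expect_lt(mean(abs(d_err)), 0.15)
  ll <- fit$loglik_trace
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-1])))
  # intercept ordering survives estimation
  for (it in fit$items) expect_true(all(diff(it$intercepts) < 0))
})

test_that("the factor correlation is recovered in a two-factor fit", {
  spec <- model_spec(list(A = 1:3, B = 4:6), n_categories = 3)
  items <- lapply(1:6, function(i) {
    a <- numeric(2); a[spec$factor_map[i]] <- c(1.6, 2.0, 1.3, 1.8, 1.5, 2.2)[i]
    grm_item(a, c(1, -1))
  })
  truth <- fitted_grm(spec, items, matrix(c(1, 0.6, 0.6, 1), 2))
  truth$quadpts <- 21; truth$theta_range <- c(-6, 6)
  coh <- simulate_clean(2000, truth, seed = 8)
  fit <- fit_grm(coh$responses, spec, quadpts = 21)
  expect_true(abs(fit$factor_corr[1, 2] - 0.6) < 0.08)
  expect_true(all(diff(fit$loglik_trace) >=
                    -1e-8 * abs(fit$loglik_trace[-1])))
})

test_that("degenerate inputs are rejected with informative errors", {
  Y <- matrix(c(rep(2L, 10), sample(1:3, 10, replace = TRUE)), 10, 2)
  rm <- response_matrix(Y, n_categories = 3)
  spec <- model_spec(list(F1 = 1:2), n_categories = 3)
  expect_error(fit_grm(rm, spec), "item 1")
  Yna <- matrix(sample(1:3, 20, replace = TRUE), 10, 2)
  Yna[1, 1] <- NA
  expect_error(fit_grm(response_matrix(Yna, n_categories = 3), spec),
               "complete cases")
})

test_that("theta estimates and lz are stable under quadrature refinement", {
  cal <- cushingqol_calibration()
  pats <- published_person_table()
  rm <- response_matrix(as.matrix(pats[c(1, 11, 30), -(1:2)]),
                        ids = pats$id[c(1, 11, 30)])
  g31 <- quadrature_grid(2, 31, corr = cal$factor_corr)
  g61 <- quadrature_grid(2, 61, corr = cal$factor_corr)
  pf31 <- person_fit(cal, rm, grid = g31)
  pf61 <- person_fit(cal, rm, grid = g61)
  expect_true(max(abs(pf31$theta.P - pf61$theta.P)) < 0.01)
  expect_true(max(abs(pf31$theta.S - pf61$theta.S)) < 0.01)
  expect_true(max(abs(pf31$lz - pf61$lz)) < 0.01)
})
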