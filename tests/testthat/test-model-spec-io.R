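test_that("model_spec validates simple structure", {
  spec <- model_spec(list(P = c(2, 5:12), S = c(1, 3, 4)))
  expect_equal(spec$n_items, 12L)
  expect_equal(spec$n_factors, 2L)
  expect_equal(spec$factor_map, c(2, 1, 2, 2, rep(1, 8)))
  uni <- model_spec(list(F1 = 1:12), estimate_cov = TRUE)
  expect_equal(uni$n_factors, 1L)
  expect_false(uni$estimate_cov)        # nothing to estimate with 1 factor
  expect_error(model_spec(list(A = c(1, 2, 3), B = c(3, 4))), "more than one")
  expect_error(model_spec(list(A = c(1, 2), B = 4)), "not assigned")
  expect_error(model_spec(list(A = 1:3), n_categories = 1), "at least 2")
})

test_that("response CSVs round-trip and invalid cells are rejected", {
  set.seed(21)
  Y <- matrix(sample(1:5, 60, replace = TRUE), 5, 12)
  path <- write_response_csv(Y)
  rm <- read_responses(path)
  expect_s3_class(rm, "response_matrix")
  expect_equal(unname(rm$responses), Y)
  expect_length(attr(rm, "excluded"), 0)

  # read -> write -> read is the identity on valid data
  path2 <- write_response_csv(rm$responses)
  expect_equal(read_responses(path2)$responses, rm$responses)

  # out-of-range category
  Ybad <- Y; Ybad[2, 3] <- 6L
  expect_error(read_responses(write_response_csv(Ybad)), "out of range")
  # non-integer cell named by position
  df <- as.data.frame(Y); df[3, 4] <- "x"
  p3 <- tempfile(fileext = ".csv"); write.csv(df, p3, row.names = FALSE)
  expect_error(read_responses(p3), "non-integer cell")
  expect_error(read_responses(tempfile(fileext = ".csv")), "not found")
})

test_that("incomplete respondents are excluded and flagged", {
  Y <- matrix(sample(1:5, 60, replace = TRUE), 5, 12)
  df <- as.data.frame(Y)
  df[3, 7] <- NA
  path <- tempfile(fileext = ".csv")
  write.csv(cbind(id = paste0("r", 1:5), df), path, row.names = FALSE)
  rm <- read_responses(path, id_column = "id")
  expect_equal(nrow(rm$responses), 4L)
  expect_equal(attr(rm, "excluded"), "r3")
  expect_equal(rm$ids, paste0("r", c(1, 2, 4, 5)))
})

test_that("validation rejects fuzzed out-of-range corruptions", {
  set.seed(99)
  for (r in 1:25) {
    Y <- matrix(sample(1:5, 48, replace = TRUE), 4, 12)
    i <- sample(4, 1); j <- sample(12, 1)
    Y[i, j] <- sample(c(0L, 6L, -2L, 11L), 1)
    expect_error(response_matrix(Y, n_categories = 5), "out of range")
  }
  expect_error(response_matrix(matrix(1:4, 2), ids = c("a", "a")), "unique")
})

test_that("model config files parse factors, ranges and the cov flag", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("P: [2, 5-12]", "S: [1, 3, 4]", "cov: true"), cfg)
  spec <- read_model_spec(cfg)
  expect_equal(spec$factor_names, c("P", "S"))
  expect_equal(which(spec$factor_map == 1), c(2L, 5:12))
  expect_equal(which(spec$factor_map == 2), c(1L, 3L, 4L))
  expect_true(spec$estimate_cov)

  uni <- tempfile(fileext = ".yaml")
  writeLines("F1: [1-12]", uni)
  expect_equal(read_model_spec(uni)$n_factors, 1L)

  js <- tempfile(fileext = ".json")
  writeLines('{"A": [1, 2], "B": [3], "cov": false, "n_categories": 3}', js)
  sj <- read_model_spec(js)
  expect_equal(sj$n_categories, c(3L, 3L, 3L))
  expect_false(sj$estimate_cov)

  dup <- tempfile(fileext = ".yaml")
  writeLines(c("A: [1, 2, 3]", "B: [3, 4]"), dup)
  expect_error(read_model_spec(dup), "more than one")
  gap <- tempfile(fileext = ".yaml")
  writeLines(c("A: [1, 2]", "B: [4]"), gap)
  expect_error(read_model_spec(gap), "not assigned")
})

test_that("augmented output binds Zh to responses and round-trips", {
  set.seed(5)
  cal <- cushingqol_calibration()
  Y <- matrix(sample(1:5, 36, replace = TRUE), 3, 12)
  rm <- response_matrix(Y, ids = c("a", "b", "c"))
  pf <- person_fit(cal, rm)
  out <- tempfile(fileext = ".csv")
  write_augmented_responses(rm, pf, out)
  back <- read.csv(out)
  expect_equal(nrow(back), 3L)
  expect_equal(ncol(back), 3L + 2L + 12L)   # id, zh, lz, 2 thetas, items
  expect_equal(back$zh, pf$zh, tolerance = 1e-6)
  expect_equal(as.matrix(back[, paste0("item", 1:12)]), Y,
               ignore_attr = TRUE)

  expect_error(write_augmented_responses(rm, pf[0, ], out), "empty")
  pf2 <- pf; pf2$id <- c("x", "y", "z")
  expect_error(write_augmented_responses(rm, pf2, out), "missing for id")
})
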