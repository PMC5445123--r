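# inline logistic category probabilities: the independent oracle used by
# probability/likelihood tests; deliberately re-derives the arithmetic
# instead of calling the package kernel
raw_cat_probs <- function(a, d, theta) {
  cum <- c(1, 1 / (1 + exp(-(a * theta + d))), 0)
  cum[-length(cum)] - cum[-1]
}

# one-factor toy model with K categories per item
toy_model <- function(slopes, intercepts_list, n_categories) {
  spec <- model_spec(list(F1 = seq_along(slopes)),
                     n_categories = n_categories, estimate_cov = FALSE)
  items <- Map(function(a, d) grm_item(a, d), slopes, intercepts_list)
  m <- fitted_grm(spec, items)
  m$quadpts <- 21
  m$theta_range <- c(-6, 6)
  m
}

# zero-slope item whose marginal category probabilities are `probs`
const_item <- function(probs, n_factors = 1) {
  cum <- rev(cumsum(rev(probs)))[-1]   # P(Y >= k), k = 2..K
  grm_item(rep(0, n_factors), qlogis(cum))
}

# reorder the items of a fitted model (and its spec) by `perm`
permute_model <- function(model, perm) {
  spec <- model$spec
  fmap <- spec$factor_map[perm]
  factors <- lapply(seq_len(spec$n_factors), function(f) which(fmap == f))
  names(factors) <- spec$factor_names
  spec2 <- model_spec(factors, n_categories = spec$n_categories[perm],
                      estimate_cov = spec$estimate_cov)
  m <- fitted_grm(spec2, model$items[perm], model$factor_corr)
  m$quadpts <- model$quadpts
  m$theta_range <- model$theta_range
  m
}

# published Zh / response-pattern table used by ordering and acceptance
# tests: the 30 listed patients (misfitting, well fitting, overfitting)
published_person_table <- function() {
  txt <- "id zh q1 q2 q3 q4 q5 q6 q7 q8 q9 q10 q11 q12
392 -3.92791 1 2 4 4 4 5 4 3 3 2 5 5
345 -3.79973 2 5 5 3 2 2 1 1 5 5 3 1
379 -3.52911 4 3 3 4 4 5 3 1 5 3 5 4
81 -3.47521 2 5 4 2 1 1 2 1 5 2 1 1
113 -2.94507 1 1 2 1 1 5 4 4 2 2 1 2
391 -2.79318 2 1 3 3 3 4 4 5 1 2 4 1
1 -2.54869 2 1 5 4 4 3 5 2 2 1 2 4
185 -2.39281 1 2 4 3 1 1 3 5 1 1 1 1
229 -2.24675 3 3 1 4 3 3 4 3 3 1 3 4
221 -2.21036 3 3 2 2 4 3 2 4 3 1 5 4
48 -0.03243 4 4 5 4 5 4 4 5 3 5 4 3
130 -0.02635 2 1 3 3 3 4 3 2 1 1 1 1
302 -0.00813 4 4 2 1 3 4 2 3 2 4 2 1
43 -0.0019 4 1 4 2 3 1 1 1 1 1 3 1
256 0.007965 5 5 5 5 4 2 5 5 5 5 3 3
136 0.02727 5 5 4 3 4 5 5 5 5 5 5 5
111 0.02917 1 5 2 1 3 1 1 3 2 3 1 1
202 0.033304 4 3 5 5 4 4 4 4 3 2 1 1
297 0.036985 4 2 1 1 2 1 1 1 1 1 1 1
55 0.041895 4 4 5 5 5 3 5 5 3 4 3 3
157 1.944592 3 4 3 3 4 3 3 2 3 3 3 3
389 1.984945 2 3 2 2 3 2 2 2 2 2 2 2
67 1.98928 2 3 3 3 3 3 4 3 3 3 2 2
128 1.99864 3 4 4 3 4 3 2 4 4 4 3 3
162 2.070151 3 4 3 3 3 3 3 4 4 3 3 3
331 2.098399 4 4 5 5 3 3 2 3 3 3 3 2
235 2.155638 3 4 3 3 4 4 3 3 4 4 3 3
362 2.196376 2 3 3 3 3 3 2 2 2 2 2 1
380 2.202284 2 5 4 3 4 4 4 4 4 4 3 3
320 2.221422 3 4 5 4 4 4 3 4 4 4 3 3"
  read.table(text = txt, header = TRUE, colClasses = c("character", rep(NA, 13)))
}

# write a small response CSV and return its path
write_response_csv <- function(mat, path = tempfile(fileext = ".csv"),
                               ids = NULL) {
  df <- as.data.frame(mat)
  names(df) <- paste0("item", seq_len(ncol(mat)))
  if (!is.null(ids)) df <- cbind(id = ids, df)
  write.csv(df, path, row.names = FALSE)
  path
}
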