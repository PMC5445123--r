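#' Define the factor structure of a questionnaire model
#'
#' A model specification maps every item to exactly one factor (simple
#' structure) and records the number of response categories per item. Factor
#' indices follow the order of declaration in `factors`; factor names are
#' free labels with no semantics attached.
#'
#' @param factors named list of integer item indices, one element per factor,
#'   e.g. `list(P = c(2, 5:12), S = c(1, 3, 4))`. Every item from 1 to
#'   `n_items` must appear in exactly one element.
#' @param n_categories integer; number of ordered response categories per
#'   item. Either a scalar (uniform) or a vector of length `n_items`.
#' @param estimate_cov logical; estimate the factor correlation(s) rather
#'   than fixing them to zero. Ignored for one-factor models.
#' @param n_items total number of items; defaults to the largest index in
#'   `factors`.
#'
#' @return An object of class `"model_spec"`: a list with elements
#'   `n_items`, `n_categories` (length `n_items`), `factor_map` (item ->
#'   factor index), `n_factors`, `factor_names`, `estimate_cov`.
#' @examples
#' spec <- model_spec(list(P = c(2, 5:12), S = c(1, 3, 4)))
#' spec$factor_map
#' @export
model_spec <- function(factors, n_categories = 5, estimate_cov = TRUE,
                       n_items = NULL) {
  if (!is.list(factors) || length(factors) < 1L)
    stop("`factors` must be a non-empty list of item index vectors")
  if (is.null(names(factors)) || any(!nzchar(names(factors))))
    names(factors) <- paste0("F", seq_along(factors))
  idx <- unlist(factors, use.names = FALSE)
  if (any(idx != as.integer(idx)) || any(idx < 1L))
    stop("item indices must be positive integers")
  idx <- as.integer(idx)
  if (anyDuplicated(idx)) {
    dup <- unique(idx[duplicated(idx)])
    stop("item(s) ", paste(dup, collapse = ", "),
         " assigned to more than one factor; simple structure requires ",
         "exactly one factor per item")
  }
  if (is.null(n_items)) n_items <- max(idx)
  missing_items <- setdiff(seq_len(n_items), idx)
  if (length(missing_items))
    stop("item(s) ", paste(missing_items, collapse = ", "),
         " not assigned to any factor")
  if (any(lengths(factors) == 0L))
    stop("every factor must have at least one item")

  n_categories <- as.integer(n_categories)
  if (length(n_categories) == 1L) n_categories <- rep(n_categories, n_items)
  if (length(n_categories) != n_items)
    stop("`n_categories` must be scalar or length n_items")
  if (any(n_categories < 2L))
    stop("every item needs at least 2 response categories")

  factor_map <- integer(n_items)
  for (f in seq_along(factors)) factor_map[factors[[f]]] <- f

  structure(
    list(n_items = n_items,
         n_categories = n_categories,
         factor_map = factor_map,
         n_factors = length(factors),
         factor_names = names(factors),
         estimate_cov = isTRUE(estimate_cov) && length(factors) > 1L),
    class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("GRM model specification:", x$n_items, "items,", x$n_factors,
      "factor(s)\n")
  for (f in seq_len(x$n_factors))
    cat("  ", x$factor_names[f], ": items ",
        paste(which(x$factor_map == f), collapse = ", "), "\n", sep = "")
  cat("  categories per item:",
      if (length(unique(x$n_categories)) == 1L) x$n_categories[1]
      else paste(x$n_categories, collapse = ", "), "\n")
  cat("  factor covariance:",
      if (x$estimate_cov) "estimated" else "fixed at 0", "\n")
  invisible(x)
}

#' Item parameters of a graded response item
#'
#' Holds the discrimination (slope) vector and the ordered category
#' intercepts of one item. Under simple structure at most one slope is
#' nonzero; an all-zero slope vector (a theta-independent item) is allowed
#' and useful for testing. Intercepts must be strictly decreasing
#' (d1 > d2 > ... > d_{K-1}), which guarantees positive category
#' probabilities at every trait value.
#'
#' @param slopes numeric vector, one entry per factor; logit units per
#'   trait SD.
#' @param intercepts numeric vector of length K - 1, strictly decreasing;
#'   logit units.
#' @return An object of class `"grm_item"`.
#' @examples
#' grm_item(slopes = c(0, 1.034), intercepts = c(1.748, 0.146, -1.314, -3.380))
#' @export
grm_item <- function(slopes, intercepts) {
  slopes <- as.numeric(slopes)
  intercepts <- as.numeric(intercepts)
  if (any(!is.finite(slopes)) || any(!is.finite(intercepts)))
    stop("item parameters must be finite")
  if (length(intercepts) < 1L)
    stop("an item needs at least one intercept (two categories)")
  if (length(intercepts) > 1L && any(diff(intercepts) >= 0))
    stop("intercepts must be strictly decreasing (d1 > d2 > ... )")
  if (sum(slopes != 0) > 1L)
    stop("simple structure: at most one nonzero slope per item")
  structure(list(slopes = slopes, intercepts = intercepts),
            class = "grm_item")
}

n_cat <- function(item) length(item$intercepts) + 1L

#' Respondent-by-item matrix of ordinal responses
#'
#' Validates and wraps an integer response matrix. Entries are category
#' codes 1..K (per-item K); `NA` marks a missing response. Respondent ids
#' must be unique.
#'
#' @param responses integer matrix, persons in rows, items in columns.
#' @param ids respondent identifiers; default `1:n`.
#' @param n_categories scalar or per-item vector of category counts used
#'   for range validation.
#' @return An object of class `"response_matrix"`: list with `responses`
#'   (integer matrix) and `ids` (character).
#' @export
response_matrix <- function(responses, ids = NULL, n_categories = 5) {
  responses <- as.matrix(responses)
  if (!nrow(responses)) stop("empty response matrix")
  storage <- suppressWarnings(as.numeric(responses))
  if (any(!is.na(storage) & storage != round(storage)))
    stop("responses must be integer category codes")
  responses <- matrix(as.integer(storage), nrow(responses), ncol(responses))
  K <- as.integer(n_categories)
  if (length(K) == 1L) K <- rep(K, ncol(responses))
  if (length(K) != ncol(responses))
    stop("`n_categories` must be scalar or one per item")
  for (j in seq_len(ncol(responses))) {
    bad <- which(!is.na(responses[, j]) &
                   (responses[, j] < 1L | responses[, j] > K[j]))
    if (length(bad))
      stop("response out of range 1..", K[j], " in column ", j,
           ", row(s) ", paste(head(bad, 5L), collapse = ", "))
  }
  if (is.null(ids)) ids <- as.character(seq_len(nrow(responses)))
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("respondent ids must be unique")
  if (length(ids) != nrow(responses))
    stop("length(ids) must equal nrow(responses)")
  structure(list(responses = responses, ids = ids, n_categories = K),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat("Response matrix:", nrow(x$responses), "respondents x",
      ncol(x$responses), "items\n")
  excl <- attr(x, "excluded")
  if (!is.null(excl) && length(excl))
    cat("  (", length(excl), " incomplete respondent(s) excluded: ",
        paste(head(excl, 5L), collapse = ", "),
        if (length(excl) > 5L) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Assemble a fitted (or frozen) graded response model
#'
#' Container for a set of item parameters together with the factor
#' correlation matrix and, for models produced by [fit_grm()], the EM
#' log-likelihood trace. Also used to hold fixed published calibrations
#' (see [cushingqol_calibration()]).
#'
#' @param spec a [model_spec()].
#' @param items list of [grm_item()] objects, one per item.
#' @param factor_corr factor correlation matrix (unit diagonal, positive
#'   definite). Default identity.
#' @param loglik_trace numeric vector of marginal log-likelihoods per EM
#'   iteration (empty for frozen calibrations).
#' @param converged logical flag.
#' @return An object of class `"fitted_grm"` with an `n_free_params`
#'   element counting free slopes + free intercepts + free correlations.
#' @export
fitted_grm <- function(spec, items, factor_corr = NULL,
                       loglik_trace = numeric(0), converged = NA) {
  stopifnot(inherits(spec, "model_spec"))
  if (length(items) != spec$n_items)
    stop("need one grm_item per item in the spec")
  for (i in seq_along(items)) {
    if (!inherits(items[[i]], "grm_item"))
      stop("items[[", i, "]] is not a grm_item")
    if (length(items[[i]]$slopes) != spec$n_factors)
      stop("item ", i, ": slope vector length != n_factors")
    if (n_cat(items[[i]]) != spec$n_categories[i])
      stop("item ", i, ": intercept count inconsistent with n_categories")
  }
  if (is.null(factor_corr)) factor_corr <- diag(spec$n_factors)
  factor_corr <- as.matrix(factor_corr)
  if (!isSymmetric(unname(factor_corr), tol = 1e-10) ||
      any(abs(diag(factor_corr) - 1) > 1e-10))
    stop("factor_corr must be symmetric with unit diagonal")
  ev <- eigen(factor_corr, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("factor_corr must be positive definite")
  if (length(loglik_trace) > 1L &&
      any(diff(loglik_trace) < -1e-8 * abs(loglik_trace[-1])))
    stop("loglik_trace must be non-decreasing")
  n_slopes <- sum(vapply(items, function(it) sum(it$slopes != 0), 0L))
  n_intercepts <- sum(spec$n_categories - 1L)
  n_corr <- if (spec$estimate_cov)
    spec$n_factors * (spec$n_factors - 1L) / 2L else 0L
  structure(
    list(spec = spec, items = items, factor_corr = factor_corr,
         loglik_trace = loglik_trace, converged = converged,
         n_free_params = n_slopes + n_intercepts + n_corr),
    class = "fitted_grm")
}

#' @export
print.fitted_grm <- function(x, ...) {
  cat("Graded response model:", x$spec$n_items, "items,",
      x$spec$n_factors, "factor(s),", x$n_free_params, "free parameters\n")
  if (length(x$loglik_trace)) {
    cat("  marginal logLik:", format(tail(x$loglik_trace, 1), digits = 8),
        "after", length(x$loglik_trace), "EM iterations",
        if (isTRUE(x$converged)) "(converged)" else "(NOT converged)", "\n")
  }
  if (x$spec$n_factors > 1L)
    cat("  factor correlation:",
        format(x$factor_corr[upper.tri(x$factor_corr)], digits = 3), "\n")
  invisible(x)
}

#' Item parameter table of a fitted model
#'
#' Returns the slopes, intercepts, difficulty conversions and standardized
#' loadings of every item as a data frame (one row per item), mirroring the
#' parameter tables conventionally reported for graded response models.
#'
#' @param model a `fitted_grm`.
#' @return data.frame with columns `item`, `factor`, `a`, `d1..d{K-1}`,
#'   `b2..bK` (difficulties) and `loading`.
#' @export
parameter_table <- function(model) {
  stopifnot(inherits(model, "fitted_grm"))
  spec <- model$spec
  Kmax <- max(spec$n_categories)
  out <- data.frame(item = seq_len(spec$n_items),
                    factor = spec$factor_names[spec$factor_map])
  out$a <- vapply(model$items, function(it) {
    nz <- which(it$slopes != 0)
    if (length(nz)) it$slopes[nz[1]] else 0
  }, 0)
  for (k in seq_len(Kmax - 1L))
    out[[paste0("d", k)]] <- vapply(model$items, function(it)
      if (k <= length(it$intercepts)) it$intercepts[k] else NA_real_, 0)
  for (k in 2:Kmax)
    out[[paste0("b", k)]] <- vapply(seq_len(spec$n_items), function(i) {
      it <- model$items[[i]]
      if (k > n_cat(it) || all(it$slopes == 0)) return(NA_real_)
      intercept_to_difficulty(it, k)
    }, 0)
  out$loading <- vapply(model$items, slope_to_loading, 0)
  out
}
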