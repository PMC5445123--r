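#' Observed lz statistic of one response pattern
#'
#' Log-likelihood of the chosen categories at a trait value:
#' \eqn{lz = \sum_i \log P(Y_i = y_i \mid \theta)}. Always nonpositive.
#' Probabilities are clipped away from zero (see `prob_floor`) so that lz
#' stays finite even for a response the model deems essentially
#' impossible.
#'
#' @param model a `fitted_grm`.
#' @param pattern integer vector of category responses, one per item,
#'   complete (no `NA`).
#' @param theta numeric trait vector, one entry per factor.
#' @param prob_floor probability clip, default 1e-10.
#' @return scalar lz (<= 0).
#' @export
lz_observed <- function(model, pattern, theta, prob_floor = 1e-10) {
  stopifnot(inherits(model, "fitted_grm"))
  if (length(pattern) != model$spec$n_items)
    stop("pattern length must equal the number of items")
  if (anyNA(pattern))
    stop("person fit is defined on complete response patterns")
  if (any(!is.finite(theta))) stop("theta must be finite")
  sum(vapply(seq_along(model$items), function(i)
    log(clip_prob(
      category_probabilities(model$items[[i]], theta)[pattern[i]],
      prob_floor)), 0))
}

#' Conditional mean and SD of lz at a trait value
#'
#' Given theta, the item responses are independent with known category
#' probabilities, so lz is a sum of independent discrete variables
#' `log P_ik` with weights `P_ik`:
#' \deqn{E(lz) = \sum_i \sum_k P_{ik} \log P_{ik},}
#' \deqn{Var(lz) = \sum_i [\sum_k P_{ik} (\log P_{ik})^2 -
#'   (\sum_k P_{ik} \log P_{ik})^2].}
#' These are the moments used by the conditional standardization of Zh.
#'
#' @inheritParams lz_observed
#' @return list with `e_lz` and `sd_lz`; `sd_lz = 0` marks a degenerate
#'   case (every item's log-probability constant at this theta).
#' @export
conditional_moments <- function(model, theta, prob_floor = 1e-10) {
  stopifnot(inherits(model, "fitted_grm"))
  if (any(!is.finite(theta))) stop("theta must be finite")
  e <- 0; v <- 0
  for (it in model$items) {
    p <- clip_prob(category_probabilities(it, theta), prob_floor)
    lp <- log(p)
    ei <- sum(p * lp)
    e <- e + ei
    v <- v + sum(p * lp^2) - ei^2
  }
  list(e_lz = e, sd_lz = sqrt(max(v, 0)))
}

#' Zh person-fit statistic for one response pattern
#'
#' Estimates the respondent's trait (EAP by default, ML optional),
#' evaluates lz there, and standardizes:
#' \eqn{Zh = (lz - E(lz)) / SD(lz)} with the conditional moments of
#' [conditional_moments()]. Negative Zh marks patterns less likely than
#' expected under the model (misfit); positive Zh marks over-consistent
#' patterns (overfit).
#'
#' @param model a `fitted_grm`.
#' @param pattern integer response vector, one per item.
#' @param theta_method `"EAP"` (default) or `"ML"`.
#' @param grid optional [quadrature_grid()] for EAP scoring.
#' @param prob_floor probability clip.
#' @return one-row data.frame as in [person_fit()].
#' @examples
#' cal <- cushingqol_calibration(rho = 0.7)
#' zh_statistic(cal, c(1, 2, 4, 4, 4, 5, 4, 3, 3, 2, 5, 5))
#' @export
zh_statistic <- function(model, pattern, theta_method = c("EAP", "ML"),
                         grid = NULL, prob_floor = 1e-10) {
  rm <- response_matrix(matrix(pattern, nrow = 1),
                        n_categories = model$spec$n_categories)
  person_fit(model, rm, theta_method = theta_method, grid = grid,
             prob_floor = prob_floor)
}

#' Person-fit (lz / Zh) statistics for every respondent
#'
#' The screening workhorse: per respondent, a trait estimate, the observed
#' lz, its conditional mean and SD at the estimate, the standardized Zh,
#' and a misfitting / typical / overfitting label at the chosen cutoff.
#'
#' `standardize = "conditional"` (default) divides `lz - E(lz | theta)` by
#' `SD(lz | theta)`, the canonical Zh of Drasgow-style person fit.
#' `standardize = "sample"` instead centres and scales lz by its sample
#' mean and SD across respondents — a literal z-score of lz, occasionally
#' seen in applied descriptions; it needs at least 2 respondents.
#'
#' @param model a `fitted_grm`.
#' @param rm a [response_matrix()] with complete rows.
#' @param theta_method `"EAP"` (default) or `"ML"` trait estimation.
#' @param standardize `"conditional"` (default) or `"sample"`.
#' @param cutoff classification cutoff (positive; default 2.0). A starting
#'   point for screening, not a significance test.
#' @param grid optional [quadrature_grid()]; defaults to the model's own
#'   settings.
#' @param prob_floor probability clip.
#' @return data.frame of class `"person_fit"`: `id`, `theta.<factor>`
#'   columns, `lz`, `e_lz`, `sd_lz`, `zh`, `degenerate`, `label`.
#'   Degenerate rows (conditional SD of 0) carry `zh = NA`.
#' @export
person_fit <- function(model, rm, theta_method = c("EAP", "ML"),
                       standardize = c("conditional", "sample"),
                       cutoff = 2.0, grid = NULL, prob_floor = 1e-10) {
  stopifnot(inherits(model, "fitted_grm"), inherits(rm, "response_matrix"))
  theta_method <- match.arg(theta_method)
  standardize <- match.arg(standardize)
  if (anyNA(rm$responses))
    stop("person fit is defined on complete response patterns")
  if (is.null(grid)) grid <- default_grid(model)

  eap <- eap_scores(model, rm, grid, prob_floor)
  fn <- model$spec$factor_names
  theta_cols <- paste0("theta.", fn)
  Th <- as.matrix(eap[, theta_cols, drop = FALSE])
  if (theta_method == "ML") {
    tr <- grid$theta_range %||% c(-6, 6)
    for (p in seq_len(nrow(Th)))
      Th[p, ] <- ml_theta(model, rm$responses[p, ], Th[p, ], tr, prob_floor)
  }

  n <- nrow(rm$responses)
  lz <- e_lz <- sd_lz <- numeric(n)
  for (p in seq_len(n)) {
    lz[p] <- lz_observed(model, rm$responses[p, ], Th[p, ], prob_floor)
    cmom <- conditional_moments(model, Th[p, ], prob_floor)
    e_lz[p] <- cmom$e_lz
    sd_lz[p] <- cmom$sd_lz
  }

  if (standardize == "conditional") {
    degenerate <- sd_lz <= 0
    zh <- ifelse(degenerate, NA_real_, (lz - e_lz) / sd_lz)
  } else {
    if (n < 2L) stop("sample standardization needs >= 2 respondents")
    s <- sd(lz)
    degenerate <- rep(s <= 0, n)
    zh <- if (s > 0) (lz - mean(lz)) / s else rep(NA_real_, n)
  }

  out <- data.frame(id = rm$ids)
  for (f in seq_along(fn)) out[[theta_cols[f]]] <- Th[, f]
  out$lz <- lz
  out$e_lz <- e_lz
  out$sd_lz <- sd_lz
  out$zh <- zh
  out$degenerate <- degenerate
  out$label <- ifelse(is.na(zh), NA_character_, classify_zh(zh, cutoff))
  class(out) <- c("person_fit", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Classify Zh values against a symmetric cutoff
#'
#' `zh < -cutoff` is misfitting, `zh > +cutoff` overfitting, anything in
#' between (boundary included, strict inequalities) typical. The default
#' cutoff of 2.0 mimics familiar z-conventions and is a screening starting
#' point, not a hypothesis test: the Zh distribution is known to be
#' non-normal.
#'
#' @param zh numeric vector of finite Zh values.
#' @param cutoff positive scalar, default 2.0.
#' @return character vector: `"misfitting"`, `"typical"`, `"overfitting"`.
#' @export
classify_zh <- function(zh, cutoff = 2.0) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff <= 0)
    stop("cutoff must be a positive scalar")
  ifelse(zh < -cutoff, "misfitting",
         ifelse(zh > cutoff, "overfitting", "typical"))
}
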