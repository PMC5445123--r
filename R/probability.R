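#' Cumulative boundary probability of a graded response item
#'
#' Probability of responding in category `k` or above,
#' \eqn{P(Y \ge k \mid \theta) = \mathrm{logit}^{-1}(a'\theta + d_{k-1})},
#' the building block of the graded response model. `k = 1` is the trivial
#' boundary (probability 1) and is rejected; valid boundaries are
#' `k = 2..K`.
#'
#' All formulas use the pure logistic metric (no 1.702 scaling constant):
#' the loading conversion \eqn{\lambda = a/\sqrt{1+a^2}} and difficulty
#' conversion \eqn{b_k = -d_{k-1}/a} are exact in this metric.
#'
#' @param item a [grm_item()].
#' @param theta numeric vector of latent trait values, one per factor
#'   (trait SD units).
#' @param k category index, `2 <= k <= K`.
#' @return probability in (0, 1), strictly increasing in theta along the
#'   item's loaded factor when the slope is positive.
#' @examples
#' it <- grm_item(c(0, 1.034), c(1.748, 0.146, -1.314, -3.380))
#' boundary_probability(it, c(0, -1.748 / 1.034), 2)  # 0.5 at the boundary
#' @export
boundary_probability <- function(item, theta, k) {
  stopifnot(inherits(item, "grm_item"))
  K <- n_cat(item)
  if (length(k) != 1L || k != round(k) || k < 2L || k > K)
    stop("boundary index k must be a single integer in 2..", K)
  theta <- as.numeric(theta)
  if (length(theta) != length(item$slopes))
    stop("theta must have one entry per factor")
  if (any(!is.finite(theta))) stop("theta must be finite")
  plogis(sum(item$slopes * theta) + item$intercepts[k - 1L])
}

#' Category response probabilities at a trait value
#'
#' Adjacent-boundary differences
#' \eqn{P(Y = k) = P(Y \ge k) - P(Y \ge k+1)} with \eqn{P(Y \ge 1) = 1}
#' and \eqn{P(Y \ge K+1) = 0}; the K probabilities telescope to 1.
#'
#' @inheritParams boundary_probability
#' @return numeric vector of length K summing to 1.
#' @export
category_probabilities <- function(item, theta) {
  stopifnot(inherits(item, "grm_item"))
  theta <- as.numeric(theta)
  if (length(theta) != length(item$slopes))
    stop("theta must have one entry per factor")
  if (any(!is.finite(theta))) stop("theta must be finite")
  eta <- sum(item$slopes * theta)
  cum <- c(1, plogis(eta + item$intercepts), 0)
  p <- -diff(cum)
  if (any(p < 0)) # cannot happen with strictly decreasing intercepts
    stop("negative category probability: intercepts not strictly decreasing")
  p
}

# Q x K matrix of category probabilities for one item over a grid of theta
# rows (Q x n_factors). Vectorized core used by estimation, M2 and person
# fit; identical arithmetic to category_probabilities().
item_prob_table <- function(item, theta_mat) {
  eta <- as.numeric(theta_mat %*% item$slopes)
  K <- n_cat(item)
  cum <- cbind(1, plogis(outer(eta, item$intercepts, `+`)), 0)
  cum[, seq_len(K), drop = FALSE] - cum[, -1L, drop = FALSE]
}

# clip probabilities away from 0/1 before taking logs, so lz stays finite
# for near-deterministic items; floor configurable via the prob_floor
# argument of downstream functions
clip_prob <- function(p, floor = 1e-10) pmin(pmax(p, floor), 1 - floor)

#' Standardized factor loading implied by a slope
#'
#' Converts a graded-response discrimination to the standardized loading
#' \eqn{\lambda = a / \sqrt{1 + a^2}} (logistic metric). For an item that
#' loads on no factor the loading is 0.
#'
#' @param item a [grm_item()] with at most one nonzero slope.
#' @return loading in (-1, 1), same sign as the slope.
#' @examples
#' slope_to_loading(grm_item(1.034, c(1.748, 0.146, -1.314, -3.380)))  # 0.719
#' @export
slope_to_loading <- function(item) {
  stopifnot(inherits(item, "grm_item"))
  a <- item$slopes[item$slopes != 0]
  if (!length(a)) return(0)
  a / sqrt(1 + a^2)
}

#' Recover a slope from a standardized loading
#'
#' Algebraic inverse of [slope_to_loading()]: \eqn{a = \lambda /
#' \sqrt{1 - \lambda^2}}.
#'
#' @param loading numeric in (-1, 1).
#' @return slope in logit units.
#' @export
loading_to_slope <- function(loading) {
  if (any(abs(loading) >= 1)) stop("loading must lie in (-1, 1)")
  loading / sqrt(1 - loading^2)
}

#' Difficulty (location) parameter of a category boundary
#'
#' Converts the intercept of the k-th boundary to the trait value at which
#' the boundary probability is 0.5: \eqn{b_k = -d_{k-1} / a}. Strictly
#' increasing in k for a fixed item. Undefined for zero-slope items.
#'
#' @param item a [grm_item()] with exactly one nonzero slope.
#' @param k boundary index, `2 <= k <= K`.
#' @return difficulty in trait SD units.
#' @examples
#' it <- grm_item(1.034, c(1.748, 0.146, -1.314, -3.380))
#' intercept_to_difficulty(it, 2)  # -1.748/1.034 = -1.69
#' @export
intercept_to_difficulty <- function(item, k) {
  stopifnot(inherits(item, "grm_item"))
  K <- n_cat(item)
  if (length(k) != 1L || k != round(k) || k < 2L || k > K)
    stop("boundary index k must be a single integer in 2..", K)
  a <- item$slopes[item$slopes != 0]
  if (!length(a)) stop("difficulty undefined for a zero-slope item")
  -item$intercepts[k - 1L] / a
}
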