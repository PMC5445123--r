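#' Degrees of freedom of the reduced M2 statistic
#'
#' `m + m(m-1)/2 - xi`, where `m` is the number of items (univariate
#' moments), `m(m-1)/2` the number of bivariate moments, and `xi` the
#' number of free model parameters: one slope per item (simple structure),
#' `K - 1` intercepts per item, and one correlation per estimated factor
#' pair.
#'
#' @param spec a [model_spec()].
#' @return positive integer degrees of freedom; a nonpositive count is an
#'   error (the model is not testable by M2).
#' @examples
#' m2_dof(model_spec(list(P = c(2, 5:12), S = c(1, 3, 4))))  # 17
#' @export
m2_dof <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  m <- spec$n_items
  xi <- m + sum(spec$n_categories - 1L) +
    if (spec$estimate_cov) spec$n_factors * (spec$n_factors - 1L) / 2L else 0L
  df <- m + m * (m - 1L) / 2L - xi
  if (df <= 0L)
    stop("nonpositive degrees of freedom (", df,
         "): model not testable by reduced M2")
  as.integer(df)
}

# pair index table in the canonical order (1,2),(1,3),...,(m-1,m)
pair_index <- function(m) {
  if (m < 2L) stop("need at least 2 items for bivariate moments")
  t(utils::combn(m, 2L))
}

#' Observed first- and second-order score moments
#'
#' Category scores 0..K-1. Returns the concatenation of the m univariate
#' means and the m(m-1)/2 bivariate cross-product means in the order
#' (1,2), (1,3), ..., (m-1,m).
#'
#' @param rm a [response_matrix()] with complete rows.
#' @return named numeric vector of length m + m(m-1)/2.
#' @export
reduced_moments <- function(rm) {
  stopifnot(inherits(rm, "response_matrix"))
  Y <- rm$responses
  if (!nrow(Y)) stop("no respondents")
  if (anyNA(Y)) stop("reduced moments require complete cases")
  X <- Y - 1
  m <- ncol(X)
  p1 <- colMeans(X)
  pr <- pair_index(m)
  p2 <- colMeans(X[, pr[, 1], drop = FALSE] * X[, pr[, 2], drop = FALSE])
  setNames(c(p1, p2),
           c(paste0("m", seq_len(m)),
             paste0("m", pr[, 1], ".", pr[, 2])))
}

# conditional score moments per item over grid nodes:
# list(m1 = E[x|q], m2 = E[x^2|q]) as m x Q matrices
conditional_score_moments <- function(items, nodes) {
  m <- length(items); Q <- nrow(nodes)
  m1 <- matrix(0, m, Q); m2 <- matrix(0, m, Q)
  for (i in seq_len(m)) {
    P <- item_prob_table(items[[i]], nodes)        # Q x K
    sc <- 0:(ncol(P) - 1L)
    m1[i, ] <- P %*% sc
    m2[i, ] <- P %*% sc^2
  }
  list(m1 = m1, m2 = m2)
}

# model-implied moment vector (same order as reduced_moments)
implied_moments <- function(items, grid) {
  cm <- conditional_score_moments(items, grid$nodes)
  w <- grid$weights
  m <- nrow(cm$m1)
  pi1 <- as.numeric(cm$m1 %*% w)
  pr <- pair_index(m)
  pi2 <- as.numeric((cm$m1[pr[, 1], , drop = FALSE] *
                       cm$m1[pr[, 2], , drop = FALSE]) %*% w)
  c(pi1, pi2)
}

# asymptotic covariance of the sample moment vector under the model.
# Entry (t, u) = E[s_t s_u] - pi_t pi_u where s_t is the per-person score
# product; joint expectations factor over items given theta (local
# independence), with E[x^2 | theta] wherever an item is shared.
moment_covariance <- function(items, grid, pi_vec) {
  cm <- conditional_score_moments(items, grid$nodes)
  w <- grid$weights
  m <- nrow(cm$m1)
  pr <- pair_index(m)
  s <- m + nrow(pr)
  members <- c(lapply(seq_len(m), identity),
               lapply(seq_len(nrow(pr)), function(r) pr[r, ]))
  Sigma <- matrix(0, s, s)
  for (t in seq_len(s)) {
    for (u in t:s) {
      it <- c(members[[t]], members[[u]])
      tab <- table(it)
      prof <- rep(1, length(w))
      for (nm in names(tab)) {
        i <- as.integer(nm)
        prof <- prof * if (tab[[nm]] == 2L) cm$m2[i, ] else cm$m1[i, ]
      }
      Sigma[t, u] <- Sigma[u, t] <- sum(w * prof) - pi_vec[t] * pi_vec[u]
    }
  }
  Sigma
}

# free-parameter packing for the Jacobian: loaded slope then intercepts
# per item, correlation last (if estimated)
pack_params <- function(model) {
  spec <- model$spec
  par <- unlist(lapply(seq_len(spec$n_items), function(i) {
    it <- model$items[[i]]
    c(it$slopes[spec$factor_map[i]], it$intercepts)
  }))
  if (spec$estimate_cov && spec$n_factors == 2L)
    par <- c(par, model$factor_corr[1, 2])
  par
}

unpack_params <- function(par, spec) {
  items <- vector("list", spec$n_items)
  pos <- 1L
  for (i in seq_len(spec$n_items)) {
    len <- spec$n_categories[i]                    # a + (K-1) intercepts
    a <- numeric(spec$n_factors)
    a[spec$factor_map[i]] <- par[pos]
    d <- par[(pos + 1L):(pos + len - 1L)]
    items[[i]] <- structure(list(slopes = a, intercepts = d),
                            class = "grm_item")   # skip ordering check
    pos <- pos + len
  }
  R <- diag(spec$n_factors)
  if (spec$estimate_cov && spec$n_factors == 2L)
    R[1, 2] <- R[2, 1] <- par[pos]
  list(items = items, corr = R)
}

#' Reduced (limited-information) M2 goodness-of-fit statistic
#'
#' Quadratic form `N (p - pi)' C (p - pi)` in the residuals of the
#' univariate and bivariate score moments, with the weight matrix built
#' from the orthogonal complement of the moment Jacobian:
#' `C = D (D' Sigma D)^{-1} D'` where the columns of `D` span the
#' orthogonal complement of `d pi / d xi` and `Sigma` is the asymptotic
#' covariance of the sample moments under the model. This construction
#' makes the statistic asymptotically chi-square with
#' `m + m(m-1)/2 - xi` degrees of freedom for any root-n-consistent
#' parameter estimator, so sparse full contingency tables are never
#' formed. A p-value above 0.05 is conventionally read as adequate fit.
#'
#' @param model a converged `fitted_grm`.
#' @param rm the [response_matrix()] the model was fitted to.
#' @param grid optional [quadrature_grid()] for the implied moments;
#'   defaults to the model's own settings.
#' @param jacobian_step central-difference step for the moment Jacobian.
#' @return object of class `"m2_result"`: list with `statistic`, `df`,
#'   `p_value`, `N`, `m`, `n_free_params`.
#' @export
m2_statistic <- function(model, rm, grid = NULL, jacobian_step = 1e-5) {
  stopifnot(inherits(model, "fitted_grm"), inherits(rm, "response_matrix"))
  spec <- model$spec
  N <- nrow(rm$responses)
  if (N < 100)
    warning("M2 with N = ", N, " respondents; asymptotics are doubtful")
  df <- m2_dof(spec)
  if (is.null(grid)) grid <- default_grid(model)

  p <- reduced_moments(rm)
  pi_hat <- implied_moments(model$items, grid)
  s <- length(p)

  par0 <- pack_params(model)
  xi <- length(par0)
  stopifnot(s - xi == df)

  moments_at <- function(par) {
    up <- unpack_params(par, spec)
    g <- quadrature_grid(spec$n_factors, grid$quadpts, grid$theta_range,
                         up$corr)
    implied_moments(up$items, g)
  }
  Delta <- matrix(0, s, xi)
  for (j in seq_len(xi)) {
    h <- jacobian_step * max(1, abs(par0[j]))
    pp <- par0; pp[j] <- par0[j] + h
    pm <- par0; pm[j] <- par0[j] - h
    Delta[, j] <- (moments_at(pp) - moments_at(pm)) / (2 * h)
  }

  Sigma <- moment_covariance(model$items, grid, pi_hat)

  qr_D <- qr(Delta)
  if (qr_D$rank < xi)
    stop("moment Jacobian is rank-deficient; check model identification")
  Dperp <- qr.Q(qr_D, complete = TRUE)[, (xi + 1L):s, drop = FALSE]
  W <- crossprod(Dperp, Sigma %*% Dperp)
  r <- crossprod(Dperp, p - pi_hat)
  M2 <- tryCatch(as.numeric(N * crossprod(r, solve(W, r))),
                 error = function(e)
                   stop("singular weight matrix in M2; the model may be ",
                        "unidentified or degrees of freedom misspecified"))
  structure(list(statistic = M2, df = df,
                 p_value = pchisq(M2, df, lower.tail = FALSE),
                 N = N, m = spec$n_items, n_free_params = xi),
            class = "m2_result")
}

#' @export
print.m2_result <- function(x, ...) {
  cat(sprintf("Reduced M2(%d) = %.2f, N = %d, p = %.4g  [%s]\n",
              x$df, x$statistic, x$N, x$p_value,
              if (x$p_value > 0.05) "adequate fit" else "misfit"))
  invisible(x)
}
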