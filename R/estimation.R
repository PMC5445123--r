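#' Fixed rectangular quadrature grid for the latent trait
#'
#' Equally spaced nodes per factor over a symmetric range, crossed into a
#' full rectangular grid, weighted by the multivariate normal prior with
#' unit variances and the supplied correlation matrix, then normalized to
#' sum to 1. This is the discretized prior used throughout estimation,
#' scoring and model-implied-moment computation.
#'
#' @param n_factors number of latent factors.
#' @param quadpts nodes per dimension (default 31).
#' @param theta_range symmetric range of the grid, default `c(-6, 6)`.
#' @param corr factor correlation matrix (default identity).
#' @return object of class `"quadrature_grid"`: list with `nodes`
#'   (Q x n_factors matrix), `weights` (length Q, positive, sum 1),
#'   `nodes1d`, `dim_index` (Q x n_factors integer index into `nodes1d`),
#'   and `corr`.
#' @export
quadrature_grid <- function(n_factors, quadpts = 31,
                            theta_range = c(-6, 6), corr = NULL) {
  stopifnot(n_factors >= 1, quadpts >= 3)
  if (theta_range[1] != -theta_range[2])
    stop("theta_range must be symmetric about 0")
  if (is.null(corr)) corr <- diag(n_factors)
  nodes1d <- seq(theta_range[1], theta_range[2], length.out = quadpts)
  idx <- as.matrix(expand.grid(rep(list(seq_len(quadpts)), n_factors)))
  dimnames(idx) <- NULL
  nodes <- matrix(nodes1d[idx], nrow(idx), n_factors)
  w <- mvn_weights(nodes, corr)
  structure(list(nodes = nodes, weights = w, nodes1d = nodes1d,
                 dim_index = idx, corr = corr,
                 quadpts = quadpts, theta_range = theta_range),
            class = "quadrature_grid")
}

# normalized MVN(0, corr) density over grid rows
mvn_weights <- function(nodes, corr) {
  L <- chol(corr)
  z <- nodes %*% backsolve(L, diag(ncol(corr)))
  logd <- -0.5 * rowSums(z^2)
  w <- exp(logd - max(logd))
  w / sum(w)
}

# n x Q matrix: log-likelihood of each person's pattern at each node;
# NA responses contribute 0. Indicator-times-table products keep the hot
# loop inside BLAS.
pattern_loglik <- function(items, Y, nodes, prob_floor = 1e-10) {
  n <- nrow(Y); Q <- nrow(nodes)
  M <- matrix(0, n, Q)
  for (i in seq_along(items)) {
    Ti <- log(clip_prob(item_prob_table(items[[i]], nodes), prob_floor))
    y <- Y[, i]
    if (anyNA(y)) {
      ok <- which(!is.na(y))
      M[ok, ] <- M[ok, ] + cat_indicator(y[ok], ncol(Ti)) %*% t(Ti)
    } else {
      M <- M + cat_indicator(y, ncol(Ti)) %*% t(Ti)
    }
  }
  M
}

# row maxima without apply()
row_max <- function(A) A[cbind(seq_len(nrow(A)), max.col(A, ties.method = "first"))]

#' Marginal log-likelihood of a GRM over a quadrature grid
#'
#' \eqn{\sum_p \log \sum_q w_q \prod_i P(Y_{pi} \mid \theta_q)}: the MML
#' objective that the EM algorithm of [fit_grm()] maximizes, evaluated by
#' direct summation over the grid.
#'
#' @param model a `fitted_grm`.
#' @param rm a [response_matrix()].
#' @param grid a [quadrature_grid()]; defaults to the model's own grid
#'   settings with its estimated correlation.
#' @param prob_floor probability clip applied before logs.
#' @return finite scalar log-likelihood.
#' @export
marginal_loglik <- function(model, rm, grid = NULL, prob_floor = 1e-10) {
  stopifnot(inherits(model, "fitted_grm"), inherits(rm, "response_matrix"))
  if (!nrow(rm$responses)) stop("empty response matrix")
  if (ncol(rm$responses) != model$spec$n_items)
    stop("response matrix and model disagree on the number of items")
  if (is.null(grid)) grid <- default_grid(model)
  M <- pattern_loglik(model$items, rm$responses, grid$nodes, prob_floor)
  A <- sweep(M, 2, log(grid$weights), `+`)
  mx <- row_max(A)
  sum(mx + log(rowSums(exp(A - mx))))
}

default_grid <- function(model, quadpts = NULL) {
  qp <- if (!is.null(quadpts)) quadpts
        else if (!is.null(model$quadpts)) model$quadpts else 31
  tr <- if (!is.null(model$theta_range)) model$theta_range else c(-6, 6)
  quadrature_grid(model$spec$n_factors, qp, tr, model$factor_corr)
}

#' Fit a multidimensional graded response model by MML-EM
#'
#' Marginal maximum likelihood with an EM algorithm over a fixed
#' rectangular quadrature grid. Factor variances are fixed at 1 for
#' identification; slopes are initialized at +1 on the loaded factor (the
#' positivity convention), intercepts at the logits of the observed
#' cumulative proportions, and the factor correlation (when estimated) at
#' 0. The intercept ordering d1 > d2 > ... is enforced throughout by
#' optimizing log-gaps, so categories cannot collapse.
#'
#' The E-step computes posterior node weights per respondent; the M-step
#' maximizes each item's expected complete-data log-likelihood
#' (quasi-Newton on the collapsed one-dimensional grid of its loaded
#' factor) and, for two-factor models with `estimate_cov`, the discretized
#' prior term over the correlation by one-dimensional search. Both steps
#' only ever increase the objective, so the marginal log-likelihood trace
#' is non-decreasing.
#'
#' @param rm a [response_matrix()] (complete cases; rows with `NA` are
#'   rejected).
#' @param spec a [model_spec()].
#' @param quadpts quadrature nodes per dimension (default 31).
#' @param theta_range grid range, default `c(-6, 6)`.
#' @param tol convergence tolerance on the maximum absolute parameter
#'   change between iterations (default 1e-4).
#' @param max_iter maximum EM iterations (default 500); non-convergence
#'   yields a warning and a result flagged `converged = FALSE`.
#' @param seed optional integer; controls only a small random jitter of
#'   the starting values (estimation itself is deterministic given data
#'   and grid).
#' @param prob_floor probability clip before logs, default 1e-10.
#' @param verbose print the log-likelihood every 10 iterations.
#' @return a [fitted_grm()] with `loglik_trace`, estimated `factor_corr`,
#'   and the grid settings stored for downstream scoring.
#' @export
fit_grm <- function(rm, spec, quadpts = 31, theta_range = c(-6, 6),
                    tol = 1e-4, max_iter = 500, seed = NULL,
                    prob_floor = 1e-10, verbose = FALSE) {
  stopifnot(inherits(rm, "response_matrix"), inherits(spec, "model_spec"))
  Y <- rm$responses
  if (ncol(Y) != spec$n_items)
    stop("data have ", ncol(Y), " items but spec declares ", spec$n_items)
  if (anyNA(Y))
    stop("fit_grm requires complete cases; filter with read_responses()")
  for (i in seq_len(spec$n_items)) {
    obs <- unique(Y[, i])
    if (length(obs) < 2L)
      stop("item ", i, " shows a single observed category (",
           obs, "); it cannot be calibrated")
  }
  if (spec$n_factors > 2L && spec$estimate_cov)
    stop("factor-correlation estimation is implemented for <= 2 factors")

  n <- nrow(Y)
  Kv <- spec$n_categories

  # starting values: cumulative-proportion logits, unit slopes
  items <- vector("list", spec$n_items)
  for (i in seq_len(spec$n_items)) {
    props <- tabulate(Y[, i], Kv[i]) / n
    cum <- rev(cumsum(rev(props)))[-1L]            # P(Y >= k), k = 2..K
    cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
    d0 <- qlogis(cum)
    # enforce strict decrease in degenerate samples
    for (k in seq_along(d0)[-1L])
      if (d0[k] >= d0[k - 1L]) d0[k] <- d0[k - 1L] - 0.05
    a0 <- numeric(spec$n_factors)
    a0[spec$factor_map[i]] <- 1
    items[[i]] <- grm_item(a0, d0)
  }
  rho <- 0
  if (!is.null(seed)) {
    set.seed(as.integer(seed))
    for (i in seq_len(spec$n_items)) {
      f <- spec$factor_map[i]
      items[[i]]$slopes[f] <- items[[i]]$slopes[f] * exp(rnorm(1, 0, 0.05))
      items[[i]]$intercepts <- sort(items[[i]]$intercepts + rnorm(1, 0, 0.05),
                                    decreasing = TRUE)
    }
  }

  grid0 <- quadrature_grid(spec$n_factors, quadpts, theta_range)
  nodes <- grid0$nodes
  dim_index <- grid0$dim_index
  est_rho <- spec$estimate_cov && spec$n_factors == 2L

  corr_mat <- function(r) {
    R <- diag(spec$n_factors)
    if (spec$n_factors == 2L) R[1, 2] <- R[2, 1] <- r
    R
  }
  w <- mvn_weights(nodes, corr_mat(rho))

  trace <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    ## E-step
    M <- pattern_loglik(items, Y, nodes, prob_floor)
    A <- sweep(M, 2, log(w), `+`)
    mx <- row_max(A)
    E <- exp(A - mx)
    denom <- rowSums(E)
    ll <- sum(mx + log(denom))
    trace <- c(trace, ll)
    if (verbose && iter %% 10 == 1)
      message("iter ", iter, "  logLik ", format(ll, digits = 10))
    post <- E / denom                              # n x Q

    ## M-step: items, on the collapsed 1-D grid of each loaded factor
    max_change <- 0
    for (i in seq_len(spec$n_items)) {
      f <- spec$factor_map[i]
      idx_f <- dim_index[, f]
      # expected category-by-node counts, collapsed over the other factor
      r_full <- crossprod(cat_indicator(Y[, i], Kv[i]), post)   # K x Q
      r1 <- t(rowsum(t(r_full), idx_f))                         # K x quadpts
      new_item <- mstep_item(items[[i]], r1, grid0$nodes1d, f,
                             spec$n_factors, prob_floor)
      max_change <- max(max_change,
                        abs(new_item$slopes - items[[i]]$slopes),
                        abs(new_item$intercepts - items[[i]]$intercepts))
      items[[i]] <- new_item
    }

    ## M-step: factor correlation from the discretized prior term
    if (est_rho) {
      Nq <- colSums(post)
      obj <- function(r) sum(Nq * log(mvn_weights(nodes, corr_mat(r))))
      opt <- optimize(obj, c(-0.95, 0.95), maximum = TRUE, tol = 1e-6)
      if (opt$objective >= obj(rho)) {
        max_change <- max(max_change, abs(opt$maximum - rho))
        rho <- opt$maximum
      }
      w <- mvn_weights(nodes, corr_mat(rho))
    }

    if (max_change < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("EM did not converge in ", max_iter,
            " iterations (max parameter change ", format(max_change),
            "); returning the partial fit")

  fit <- fitted_grm(spec, items, corr_mat(rho), loglik_trace = trace,
                    converged = converged)
  fit$quadpts <- quadpts
  fit$theta_range <- theta_range
  fit
}

# n x K indicator of chosen categories
cat_indicator <- function(y, K) {
  Z <- matrix(0, length(y), K)
  Z[cbind(seq_along(y), y)] <- 1
  Z
}

# maximize sum_{q,k} r1[k,q] log P_k(node_q) over (a, d); generalized
# EM: the update is kept only if it improves the objective.
mstep_item <- function(item, r1, nodes1d, factor, n_factors, prob_floor) {
  K <- nrow(r1)
  a0 <- item$slopes[factor]
  d0 <- item$intercepts
  par0 <- c(a0, d0[1L], if (K > 2L) log(-diff(d0)))
  unpack <- function(par) {
    d <- par[2L]
    if (K > 2L) d <- c(d, d[1L] - cumsum(exp(par[-(1:2)])))
    list(a = par[1L], d = d)
  }
  negobj <- function(par) {
    p <- unpack(par)
    eta <- p$a * nodes1d
    cum <- cbind(1, plogis(outer(eta, p$d, `+`)), 0)
    P <- clip_prob(cum[, seq_len(K), drop = FALSE] -
                     cum[, -1L, drop = FALSE], prob_floor)
    -sum(t(r1) * log(P))
  }
  opt <- tryCatch(
    optim(par0, negobj, method = "BFGS",
          control = list(maxit = 50, reltol = 1e-10)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value) || opt$value > negobj(par0))
    return(item)
  p <- unpack(opt$par)
  slopes <- numeric(n_factors)
  slopes[factor] <- p$a
  grm_item(slopes, p$d)
}

#' Expected a posteriori (EAP) trait scores
#'
#' Posterior mean and SD of the latent trait per respondent, under the
#' fitted model's multivariate normal prior discretized on the quadrature
#' grid. Estimates shrink toward the prior mean 0; a respondent whose
#' pattern carries no information (all zero slopes) scores exactly 0.
#'
#' @param model a `fitted_grm`.
#' @param rm a [response_matrix()] with complete rows.
#' @param grid optional [quadrature_grid()]; defaults to the model's own
#'   settings.
#' @param prob_floor probability clip before logs.
#' @return data.frame: `id`, then `theta.<factor>` posterior means and
#'   `se.<factor>` posterior SDs.
#' @export
eap_scores <- function(model, rm, grid = NULL, prob_floor = 1e-10) {
  stopifnot(inherits(model, "fitted_grm"), inherits(rm, "response_matrix"))
  if (anyNA(rm$responses)) stop("EAP scoring requires complete patterns")
  if (is.null(grid)) grid <- default_grid(model)
  M <- pattern_loglik(model$items, rm$responses, grid$nodes, prob_floor)
  A <- sweep(M, 2, log(grid$weights), `+`)
  mx <- row_max(A)
  P <- exp(A - mx)
  post <- P / rowSums(P)
  mean_t <- post %*% grid$nodes                    # n x F
  m2 <- post %*% (grid$nodes^2)
  sd_t <- sqrt(pmax(m2 - mean_t^2, 0))
  fn <- model$spec$factor_names
  out <- data.frame(id = rm$ids)
  for (f in seq_len(model$spec$n_factors)) {
    out[[paste0("theta.", fn[f])]] <- mean_t[, f]
    out[[paste0("se.", fn[f])]] <- sd_t[, f]
  }
  out
}

# maximum-likelihood theta for one pattern, box-constrained to the grid
# range; started at the EAP estimate for stability
ml_theta <- function(model, pattern, start, theta_range, prob_floor = 1e-10) {
  nf <- model$spec$n_factors
  nll <- function(th)
    -sum(vapply(seq_along(model$items), function(i)
      log(clip_prob(category_probabilities(model$items[[i]], th)[pattern[i]],
                    prob_floor)), 0))
  opt <- optim(start, nll, method = "L-BFGS-B",
               lower = rep(theta_range[1], nf),
               upper = rep(theta_range[2], nf))
  opt$par
}
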