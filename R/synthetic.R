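#' Published CushingQoL graded-response calibration
#'
#' The frozen two-factor calibration of the 12-item, five-category
#' CushingQoL quality-of-life questionnaire: simple structure with items
#' 2 and 5-12 on one subscale ("P") and items 1, 3, 4 on the other ("S"),
#' published slopes and ordered intercepts per item. The factor
#' correlation was not published; it is supplied by the caller (default
#' 0.7, the midpoint of the 0.6-0.8 range used for sensitivity checks).
#'
#' @param rho factor correlation in (-1, 1); default 0.7.
#' @return a [fitted_grm()] usable anywhere a fitted model is (person
#'   fit, simulation, implied moments), with an empty log-likelihood
#'   trace since nothing was estimated here.
#' @examples
#' cal <- cushingqol_calibration()
#' parameter_table(cal)[1:3, ]
#' @export
cushingqol_calibration <- function(rho = 0.7) {
  if (!is.numeric(rho) || length(rho) != 1L || abs(rho) >= 1)
    stop("rho must be a single value in (-1, 1)")
  # slope, d1..d4, factor (1 = "P", 2 = "S") per item 1..12
  tab <- list(
    list(1.034, c(1.748,  0.146, -1.314, -3.380), 2L),
    list(1.809, c(2.285,  1.017, -0.396, -2.174), 1L),
    list(3.819, c(5.261,  2.564, -0.772, -3.875), 2L),
    list(2.059, c(2.858,  1.143, -0.806, -2.842), 2L),
    list(1.403, c(2.981,  1.173, -0.640, -3.407), 1L),
    list(2.248, c(2.321,  0.480, -1.537, -3.685), 1L),
    list(2.067, c(1.239, -0.193, -1.702, -3.673), 1L),
    list(2.634, c(3.052,  0.417, -1.331, -3.739), 1L),
    list(3.233, c(2.850,  0.847, -1.374, -3.645), 1L),
    list(3.268, c(2.358,  0.676, -1.427, -3.931), 1L),
    list(1.593, c(1.812, -0.359, -2.677, -4.598), 1L),
    list(1.697, c(0.561, -0.995, -3.490, -5.433), 1L))
  fmap <- vapply(tab, `[[`, 0L, 3L)
  spec <- model_spec(list(P = which(fmap == 1L), S = which(fmap == 2L)),
                     n_categories = 5, estimate_cov = TRUE)
  items <- lapply(seq_along(tab), function(i) {
    a <- numeric(2)
    a[fmap[i]] <- tab[[i]][[1]]
    grm_item(a, tab[[i]][[2]])
  })
  R <- matrix(c(1, rho, rho, 1), 2)
  fit <- fitted_grm(spec, items, R)
  fit$quadpts <- 31
  fit$theta_range <- c(-6, 6)
  fit
}

#' Simulate a model-consistent (clean) cohort
#'
#' Draws latent traits from the multivariate normal prior (unit
#' variances, the model's factor correlation) and responses from each
#' item's category probabilities at the drawn trait. Every respondent is
#' labelled `"clean"`; [inject_aberrant()] overwrites a subset with
#' labelled aberrant mechanisms.
#'
#' @param n number of respondents.
#' @param model a `fitted_grm` (defaults to the CushingQoL calibration).
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @param ids respondent ids, default `"1".."n"`.
#' @return object of class `"labeled_cohort"`: list with `responses` (a
#'   [response_matrix()]), `theta` (n x n_factors true traits), `labels`
#'   (character), and the generating `model`.
#' @export
simulate_clean <- function(n, model = cushingqol_calibration(),
                           seed = NULL, ids = NULL) {
  stopifnot(inherits(model, "fitted_grm"), n >= 1)
  if (!is.null(seed)) set.seed(as.integer(seed))
  nf <- model$spec$n_factors
  theta <- MASS::mvrnorm(n, mu = rep(0, nf), Sigma = model$factor_corr)
  theta <- matrix(theta, n, nf)
  Y <- matrix(0L, n, model$spec$n_items)
  for (i in seq_len(model$spec$n_items)) {
    P <- item_prob_table(model$items[[i]], theta)        # n x K
    cum <- t(apply(P, 1, cumsum))
    u <- runif(n)
    Y[, i] <- 1L + rowSums(u > cum[, -ncol(cum), drop = FALSE])
  }
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(list(responses = response_matrix(Y, ids = ids,
                                             n_categories = model$spec$n_categories),
                 theta = theta,
                 labels = rep("clean", n),
                 model = model),
            class = "labeled_cohort")
}

#' @export
print.labeled_cohort <- function(x, ...) {
  cat("Labelled cohort:", nrow(x$responses$responses), "respondents\n")
  print(table(x$labels))
  invisible(x)
}

#' Replace a fraction of a cohort with labelled aberrant responders
#'
#' Overwrites the rows of randomly selected respondents with responses
#' from a known aberrance mechanism, keeping truth labels unambiguous:
#' \describe{
#'   \item{`random`}{uniform over 1..K per item — careless/distracted
#'     responding.}
#'   \item{`extreme_alternating`}{each response drawn from the extreme
#'     categories \{1, K\}, rejection-sampled (up to `max_attempts` draws)
#'     until every subscale raw total lies within `total_tol_sd` clean-
#'     cohort SDs of the clean mean. These responders are extreme item by
#'     item yet average in total score — exactly the pattern boxplot
#'     screening cannot see.}
#'   \item{`midpoint`}{every response at the middle category — the
#'     over-consistent, overfit-direction mechanism.}
#' }
#'
#' @param cohort a [simulate_clean()] cohort.
#' @param mechanism one of `"random"`, `"extreme_alternating"`,
#'   `"midpoint"`.
#' @param proportion fraction of respondents to replace, in `[0, 1)`;
#'   0 returns the cohort unchanged.
#' @param seed integer seed for selection and replacement draws.
#' @param total_tol_sd subscale-total tolerance (in clean SD units) for
#'   `extreme_alternating`, default 0.5.
#' @param max_attempts rejection-sampling cap per person (default 1000);
#'   on exhaustion the closest attempt is kept.
#' @return the cohort with replaced rows and updated labels.
#' @export
inject_aberrant <- function(cohort,
                            mechanism = c("random", "extreme_alternating",
                                          "midpoint"),
                            proportion, seed = NULL,
                            total_tol_sd = 0.5, max_attempts = 1000) {
  stopifnot(inherits(cohort, "labeled_cohort"))
  mechanism <- match.arg(mechanism)
  if (proportion < 0 || proportion >= 1)
    stop("proportion must lie in [0, 1)")
  if (proportion == 0) return(cohort)
  if (!is.null(seed)) set.seed(as.integer(seed))

  Y <- cohort$responses$responses
  n <- nrow(Y)
  spec <- cohort$model$spec
  Kv <- spec$n_categories
  n_ab <- max(1L, round(proportion * n))
  clean_idx <- which(cohort$labels == "clean")
  if (n_ab > length(clean_idx))
    stop("not enough clean respondents left to replace")
  sel <- sample(clean_idx, n_ab)

  if (mechanism == "random") {
    for (p in sel)
      Y[p, ] <- vapply(Kv, function(K) sample.int(K, 1L), 0L)
  } else if (mechanism == "midpoint") {
    mid <- as.integer(ceiling((Kv + 1) / 2))
    for (p in sel) Y[p, ] <- mid
  } else {
    # clean-cohort subscale total means/SDs as the matching target
    keep <- setdiff(clean_idx, sel)
    tgt <- lapply(seq_len(spec$n_factors), function(f) {
      itms <- which(spec$factor_map == f)
      tot <- rowSums(Y[keep, itms, drop = FALSE])
      list(items = itms, mean = mean(tot), sd = sd(tot))
    })
    for (p in sel) {
      best <- NULL; best_dev <- Inf
      for (att in seq_len(max_attempts)) {
        cand <- vapply(Kv, function(K) sample(c(1L, K), 1L), 0L)
        dev <- max(vapply(tgt, function(g)
          abs(sum(cand[g$items]) - g$mean) / g$sd, 0))
        if (dev < best_dev) { best <- cand; best_dev <- dev }
        if (dev <= total_tol_sd) break
      }
      Y[p, ] <- best
    }
  }

  cohort$responses <- response_matrix(Y, ids = cohort$responses$ids,
                                      n_categories = Kv)
  cohort$labels[sel] <- mechanism
  cohort
}
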