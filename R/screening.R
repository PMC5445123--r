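#' Subscale raw sums and 0-100 transformed scores
#'
#' Sums each respondent's responses within each factor's item set and
#' applies the affine transform to 0-100: for a subscale of items with
#' category counts K_j, `transformed = (raw - q) * 100 / sum(K_j - 1)`
#' where `q` is the item count. 0 means all-minimum responses (worst), 100
#' all-maximum (best); higher categories are assumed to mean better
#' standing (use `reverse = TRUE` for instruments coded the other way).
#'
#' @param rm a [response_matrix()] with complete rows.
#' @param spec a [model_spec()] defining the subscales.
#' @param reverse flip the orientation so category 1 maps to 100.
#' @return data.frame: `id`, then `raw.<factor>` and `score.<factor>`
#'   per subscale.
#' @export
subscale_scores <- function(rm, spec, reverse = FALSE) {
  stopifnot(inherits(rm, "response_matrix"), inherits(spec, "model_spec"))
  if (anyNA(rm$responses)) stop("subscale scoring requires complete rows")
  if (ncol(rm$responses) != spec$n_items)
    stop("data and spec disagree on the number of items")
  out <- data.frame(id = rm$ids)
  for (f in seq_len(spec$n_factors)) {
    itms <- which(spec$factor_map == f)
    raw <- rowSums(rm$responses[, itms, drop = FALSE])
    q <- length(itms)
    span <- sum(spec$n_categories[itms] - 1L)
    sc <- (raw - q) * 100 / span
    if (reverse) sc <- 100 - sc
    out[[paste0("raw.", spec$factor_names[f])]] <- raw
    out[[paste0("score.", spec$factor_names[f])]] <- sc
  }
  out
}

#' Tukey-fence boxplot outliers
#'
#' Flags values outside `[Q1 - coef*IQR, Q3 + coef*IQR]`. Quartiles use
#' linear interpolation (`stats::quantile` type 7, the common default);
#' the convention is configurable via `type` because different quartile
#' rules move the fences.
#'
#' @param scores numeric vector of per-person scores.
#' @param ids identifiers aligned with `scores`; default names or indices.
#' @param coef fence multiplier, default 1.5.
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return character vector of flagged ids (possibly empty).
#' @export
boxplot_outliers <- function(scores, ids = NULL, coef = 1.5, type = 7) {
  if (length(scores) < 4L)
    stop("boxplot outlier detection needs at least 4 observations")
  if (is.null(ids)) ids <- names(scores) %||% as.character(seq_along(scores))
  q <- quantile(scores, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  lo <- q[1] - coef * iqr
  hi <- q[2] + coef * iqr
  ids[scores < lo | scores > hi]
}

#' Head and tail of the Zh-sorted person table
#'
#' Sorts person-fit results by ascending Zh (most misfitting first) with
#' stable id tie-break and returns the first `n_head` rows and the last
#' `n_tail` rows, each bound to the respondent's full response pattern —
#' the inspection tables of the screening workflow.
#'
#' @param pf a [person_fit()] result.
#' @param rm the matching [response_matrix()] (for the patterns); optional.
#' @param n_head,n_tail rows in each table (default 20 and 20).
#' @return list with data.frames `head` (lowest Zh, ascending) and `tail`
#'   (highest Zh, ascending). If fewer rows are available the tables are
#'   truncated with a warning.
#' @export
sorted_person_table <- function(pf, rm = NULL, n_head = 20, n_tail = 20) {
  pf <- as.data.frame(pf)
  if (!nrow(pf)) stop("empty person-fit result")
  if (nrow(pf) < n_head + n_tail) {
    warning("only ", nrow(pf), " results for head ", n_head, " + tail ",
            n_tail, "; tables truncated")
    n_head <- min(n_head, nrow(pf))
    n_tail <- min(n_tail, nrow(pf))
  }
  ord <- order(pf$zh, pf$id)
  sorted <- pf[ord, c("id", "zh")]
  if (!is.null(rm)) {
    m <- match(sorted$id, rm$ids)
    patt <- as.data.frame(rm$responses[m, , drop = FALSE])
    names(patt) <- paste0("item", seq_len(ncol(rm$responses)))
    sorted <- cbind(sorted, patt)
  }
  rownames(sorted) <- NULL
  list(head = head(sorted, n_head), tail = tail(sorted, n_tail))
}

#' Histogram of Zh values with cutoff lines
#'
#' Writes a PNG histogram of the Zh distribution with vertical lines at
#' plus/minus the cutoff — the visual used to choose a screening
#' threshold. Bin rule: Sturges (the base default), fixed and documented
#' so snapshots are deterministic.
#'
#' @param pf a [person_fit()] result.
#' @param path output PNG path.
#' @param cutoff cutoff drawn as vertical lines, default 2.
#' @param breaks passed to [graphics::hist()], default `"Sturges"`.
#' @return the path, invisibly.
#' @export
zh_histogram <- function(pf, path, cutoff = 2.0, breaks = "Sturges") {
  pf <- as.data.frame(pf)
  zh <- pf$zh[!is.na(pf$zh)]
  if (!length(zh)) stop("no finite Zh values to plot")
  grDevices::png(path, width = 800, height = 600)
  on.exit(grDevices::dev.off())
  graphics::hist(zh, breaks = breaks, main = "Distribution of Zh",
                 xlab = "Zh (standardized person fit)", col = "grey85")
  graphics::abline(v = c(-cutoff, cutoff), col = "red", lwd = 2)
  invisible(path)
}

#' Side-by-side screening report: person fit vs boxplot outliers
#'
#' The headline comparison of the screening pipeline: classify every
#' respondent by Zh at the cutoff, run conventional boxplot outlier
#' detection on the subscale scores (per subscale, and on the mean of the
#' subscale scores as a total), and report the set of respondents flagged
#' by person fit but invisible to the boxplots.
#'
#' @param rm a [response_matrix()].
#' @param spec the [model_spec()] defining subscales.
#' @param pf a [person_fit()] result for the same respondents.
#' @param cutoff Zh classification cutoff, default 2.
#' @return object of class `"screening_report"`: counts per label, group
#'   mean/SD of Zh for the flagged groups, boxplot outlier ids per
#'   subscale and for the total, and `zh_only` — ids flagged by Zh but by
#'   no boxplot.
#' @export
comparison_report <- function(rm, spec, pf, cutoff = 2.0) {
  stopifnot(inherits(rm, "response_matrix"), inherits(spec, "model_spec"))
  pf <- as.data.frame(pf)
  if (!nrow(pf)) stop("empty person-fit result")
  if (!setequal(pf$id, rm$ids))
    stop("person-fit results and responses cover different respondents")

  zh_ok <- pf[!is.na(pf$zh), ]
  lab <- classify_zh(zh_ok$zh, cutoff)
  counts <- c(misfitting = sum(lab == "misfitting"),
              typical = sum(lab == "typical"),
              overfitting = sum(lab == "overfitting"))
  grp_stats <- lapply(c("misfitting", "overfitting"), function(g) {
    z <- zh_ok$zh[lab == g]
    list(n = length(z),
         mean = if (length(z)) mean(z) else NA_real_,
         sd = if (length(z) > 1) sd(z) else NA_real_)
  })
  names(grp_stats) <- c("misfitting", "overfitting")

  ss <- subscale_scores(rm, spec)
  box <- list()
  for (f in spec$factor_names)
    box[[f]] <- boxplot_outliers(ss[[paste0("score.", f)]], ids = ss$id)
  total <- rowMeans(as.matrix(ss[, paste0("score.", spec$factor_names),
                                 drop = FALSE]))
  box[["total"]] <- boxplot_outliers(total, ids = ss$id)

  zh_flagged <- zh_ok$id[lab != "typical"]
  box_flagged <- unique(unlist(box))
  structure(list(n = nrow(pf), counts = counts, group_stats = grp_stats,
                 boxplot_outliers = box,
                 zh_flagged = zh_flagged,
                 zh_only = setdiff(zh_flagged, box_flagged),
                 cutoff = cutoff),
            class = "screening_report")
}

#' @export
print.screening_report <- function(x, ...) {
  cat("Person-fit screening report (cutoff ±", x$cutoff, ")\n", sep = "")
  cat("  n =", x$n, "respondents:", x$counts["misfitting"], "misfitting,",
      x$counts["typical"], "typical,", x$counts["overfitting"],
      "overfitting\n")
  gm <- x$group_stats$misfitting; go <- x$group_stats$overfitting
  if (gm$n) cat(sprintf("  misfitting: M = %.2f, SD = %.2f\n", gm$mean, gm$sd))
  if (go$n) cat(sprintf("  overfitting: M = %.2f, SD = %.2f\n", go$mean, go$sd))
  cat("  boxplot outliers:", sum(lengths(x$boxplot_outliers)),
      "flag(s) across", length(x$boxplot_outliers), "score(s)\n")
  cat("  flagged by Zh but by no boxplot:", length(x$zh_only), "\n")
  invisible(x)
}
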