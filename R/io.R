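#' Read a respondent-by-item response CSV
#'
#' Reads a comma-separated file of integer category responses (codes 1..K),
#' with an optional header row and an optional respondent-id column. Rows
#' containing any missing item are excluded from the returned matrix
#' (listwise exclusion) and reported via the `"excluded"` attribute; the
#' default handling mirrors complete-case analysis of questionnaire data
#' rather than imputation.
#'
#' @param path path to a CSV file.
#' @param id_column name (or index) of the respondent-id column, or `NULL`
#'   if the file has no id column (row numbers become ids).
#' @param n_categories scalar or per-item category count K for range
#'   validation; default 5.
#' @param header does the file carry a header row? Default `TRUE`.
#' @return a [response_matrix()]; attribute `"excluded"` holds the ids of
#'   respondents dropped for missingness.
#' @export
read_responses <- function(path, id_column = NULL, n_categories = 5,
                           header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- read.csv(path, header = header, colClasses = "character",
                  check.names = FALSE, na.strings = c("", "NA"))
  if (!nrow(raw)) stop("no data rows in ", path)
  if (!is.null(id_column)) {
    if (is.character(id_column)) {
      if (!id_column %in% names(raw))
        stop("id column '", id_column, "' not found")
      id_column <- match(id_column, names(raw))
    }
    ids <- raw[[id_column]]
    raw <- raw[, -id_column, drop = FALSE]
  } else {
    ids <- as.character(seq_len(nrow(raw)))
  }
  num <- suppressWarnings(
    vapply(raw, function(col) as.numeric(col), numeric(nrow(raw))))
  num <- matrix(num, nrow = nrow(raw))
  for (j in seq_len(ncol(raw))) {
    bad <- which(!is.na(raw[[j]]) & is.na(num[, j]))
    if (length(bad))
      stop("non-integer cell at row ", bad[1], ", column '",
           names(raw)[j], "'")
    frac <- which(!is.na(num[, j]) & num[, j] != round(num[, j]))
    if (length(frac))
      stop("non-integer cell at row ", frac[1], ", column '",
           names(raw)[j], "'")
  }
  complete <- rowSums(is.na(num)) == 0L
  excluded <- ids[!complete]
  if (!any(complete)) stop("no complete respondents in ", path)
  rm <- response_matrix(num[complete, , drop = FALSE], ids = ids[complete],
                        n_categories = n_categories)
  attr(rm, "excluded") <- excluded
  rm
}

#' Read a factor-structure configuration file
#'
#' Parses a YAML (or JSON) mapping of factor names to 1-based item index
#' lists, plus an optional `cov: true|false` key controlling whether the
#' factor correlation is estimated, and an optional `n_categories` key
#' (default 5). Declaration order fixes the factor index. Item lists may
#' use explicit integers or `"a-b"` range strings.
#'
#' @param path path to a YAML or JSON config file.
#' @return a [model_spec()].
#' @examples
#' cfg <- tempfile(fileext = ".yaml")
#' writeLines(c("P: [2, 5-12]", "S: [1, 3, 4]", "cov: true"), cfg)
#' read_model_spec(cfg)
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (!is.list(cfg) || is.null(names(cfg)))
    stop("config must be a mapping of factor names to item lists")
  estimate_cov <- TRUE
  if ("cov" %in% names(cfg)) {
    estimate_cov <- isTRUE(cfg$cov)
    cfg$cov <- NULL
  }
  n_categories <- 5
  if ("n_categories" %in% names(cfg)) {
    n_categories <- cfg$n_categories
    cfg$n_categories <- NULL
  }
  if (!length(cfg)) stop("config declares no factors")
  factors <- lapply(cfg, expand_item_indices)
  model_spec(factors, n_categories = n_categories,
             estimate_cov = estimate_cov)
}

# "5-12" -> 5:12; integers pass through
expand_item_indices <- function(x) {
  out <- lapply(x, function(el) {
    if (is.character(el) && grepl("^\\s*\\d+\\s*-\\s*\\d+\\s*$", el)) {
      ab <- as.integer(strsplit(el, "-")[[1]])
      return(seq(ab[1], ab[2]))
    }
    n <- suppressWarnings(as.numeric(el))
    if (is.na(n) || n != round(n))
      stop("cannot parse item index '", el, "'")
    as.integer(n)
  })
  unlist(out)
}

#' Write responses augmented with person-fit results
#'
#' Binds the person-fit columns (Zh, lz, per-factor trait estimates) to the
#' original response matrix, aligned by respondent id, and writes the
#' result as CSV: `id, zh, lz, theta.<factor>..., item columns`. The file
#' round-trips: re-reading recovers the Zh values exactly (within
#' write precision, >= 6 decimals).
#'
#' @param rm a [response_matrix()].
#' @param pf a person-fit data frame from [person_fit()].
#' @param path output CSV path.
#' @return the output path, invisibly.
#' @export
write_augmented_responses <- function(rm, pf, path) {
  stopifnot(inherits(rm, "response_matrix"))
  if (is.null(pf) || !nrow(as.data.frame(pf)))
    stop("empty person-fit result")
  pf <- as.data.frame(pf)
  if (!all(c("id", "zh", "lz") %in% names(pf)))
    stop("person-fit result must carry id, zh and lz columns")
  m <- match(rm$ids, pf$id)
  if (any(is.na(m)))
    stop("person-fit results missing for id(s): ",
         paste(head(rm$ids[is.na(m)], 5L), collapse = ", "))
  theta_cols <- grep("^theta\\.", names(pf), value = TRUE)
  resp <- as.data.frame(rm$responses)
  names(resp) <- paste0("item", seq_len(ncol(rm$responses)))
  out <- cbind(data.frame(id = rm$ids,
                          zh = pf$zh[m], lz = pf$lz[m],
                          check.names = FALSE),
               pf[m, theta_cols, drop = FALSE], resp)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
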