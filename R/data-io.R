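#' Construct and validate an abundance matrix
#'
#' The canonical container for mass-spectrometry abundance data is a numeric
#' matrix with features in rows and samples in columns. A cell holding exactly
#' zero is a point mass value (PMV); all other cells must be strictly positive
#' abundances. Missing values are rejected: censoring must already be expressed
#' as zeros.
#'
#' @param x A numeric matrix, or a data frame whose first column holds feature
#'   identifiers and whose remaining columns hold per-sample abundances.
#' @param feature_ids,sample_ids Optional character vectors overriding the
#'   dimnames of `x`.
#'
#' @return A numeric matrix with unique `rownames` (feature ids) and
#'   `colnames` (sample ids), all values finite and non-negative.
#' @export
#' @examples
#' m <- abundance_matrix(matrix(c(0, 2, 3, 1, 0, 5), nrow = 2,
#'   dimnames = list(c("f1", "f2"), c("s1", "s2", "s3"))))
abundance_matrix <- function(x, feature_ids = NULL, sample_ids = NULL) {
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("abundance table needs a feature-id column plus at least one sample column")
    ids <- as.character(x[[1L]])
    vals <- as.matrix(x[, -1L, drop = FALSE])
    storage.mode(vals) <- "double"
    rownames(vals) <- ids
    x <- vals
  }
  if (!is.matrix(x) || !is.numeric(x)) stop("`x` must be a numeric matrix or a data frame")
  if (nrow(x) == 0L) stop("no features")
  if (!is.null(feature_ids)) rownames(x) <- feature_ids
  if (!is.null(sample_ids)) colnames(x) <- sample_ids
  if (is.null(rownames(x))) rownames(x) <- paste0("feature_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("sample_", seq_len(ncol(x)))
  if (anyDuplicated(rownames(x))) stop("duplicate feature ids: ",
    paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x))) stop("duplicate sample ids: ",
    paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!is.finite(x) | x < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("invalid abundance (missing or negative) at feature '",
      rownames(x)[bad[1L, 1L]], "', sample '", colnames(x)[bad[1L, 2L]], "'")
  }
  x
}

#' Read an abundance matrix from a delimited text file
#'
#' Expects a header row of sample ids and a first column of feature ids; every
#' other cell must parse as a non-negative real. Zeros encode point mass
#' values; empty cells are an error, not zeros.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, default tab.
#' @return A validated abundance matrix (see [abundance_matrix()]).
#' @export
read_abundance_matrix <- function(path, delimiter = "\t") {
  df <- readr::read_delim(path, delim = delimiter, show_col_types = FALSE,
    progress = FALSE)
  if (nrow(df) == 0L) stop("no features")
  abundance_matrix(as.data.frame(df))
}

#' Write an abundance matrix to a delimited text file
#'
#' @param x An abundance matrix.
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @export
write_abundance_matrix <- function(x, path, delimiter = "\t") {
  df <- tibble::as_tibble(x, rownames = "feature_id")
  readr::write_delim(df, path, delim = delimiter)
  invisible(path)
}

#' Build a design matrix from a sample table
#'
#' Produces the intercept-plus-covariates design used by all model fits. For a
#' two-group comparison the group column is coded as a 0/1 indicator with the
#' reference level being the first label in sorted order (override via
#' `reference`).
#'
#' @param samples A data frame with one row per sample, containing at least
#'   `sample_id` and the group column.
#' @param group Name of the group column (default `"group"`).
#' @param covariates Optional character vector of additional numeric covariate
#'   columns.
#' @param reference Optional reference group label.
#' @return A numeric design matrix with an intercept first column, rownames
#'   set to sample ids, and attribute `"group_levels"`.
#' @export
build_design <- function(samples, group = "group", covariates = character(),
                         reference = NULL) {
  samples <- as.data.frame(samples)
  if (!"sample_id" %in% names(samples)) stop("sample table needs a `sample_id` column")
  if (!group %in% names(samples)) stop("group column '", group, "' not found")
  g <- as.character(samples[[group]])
  lev <- sort(unique(g))
  if (!is.null(reference)) {
    if (!reference %in% lev) stop("reference level '", reference, "' not present")
    lev <- c(reference, setdiff(lev, reference))
  }
  if (length(lev) != 2L) stop("two-group designs only: found ", length(lev), " group levels")
  X <- cbind(intercept = 1, group = as.numeric(g == lev[2L]))
  for (cv in covariates) {
    if (!cv %in% names(samples)) stop("covariate '", cv, "' not found")
    X <- cbind(X, as.numeric(samples[[cv]]))
    colnames(X)[ncol(X)] <- cv
  }
  rownames(X) <- as.character(samples$sample_id)
  attr(X, "group_levels") <- lev
  X
}

#' Log-scale detection limit of one feature
#'
#' The censoring threshold for the lognormal component: the minimum
#' log-transformed non-PMV observation minus a small offset `epsilon`
#' (natural logarithm; default 0.1).
#'
#' @param feature_values Non-negative abundances for one feature.
#' @param epsilon Offset below the minimum log non-PMV value.
#' @return The detection limit on the log scale.
#' @export
#' @examples
#' compute_detection_limit(c(exp(2), exp(3), 0))  # 1.9
compute_detection_limit <- function(feature_values, epsilon = 0.1) {
  pos <- feature_values[feature_values > 0]
  if (length(pos) == 0L) stop("no non-PMV observations")
  min(log(pos)) - epsilon
}

#' Detection limits for all features of a matrix
#'
#' @param x An abundance matrix.
#' @inheritParams compute_detection_limit
#' @return Named numeric vector of per-feature detection limits.
#' @export
detection_limits <- function(x, epsilon = 0.1) {
  apply(x, 1L, compute_detection_limit, epsilon = epsilon)
}

#' Detect perfect separation of zeros by group
#'
#' A feature is perfectly separated when one group contains only PMVs and the
#' other only non-PMVs; the logistic zero-proportion component is then
#' unidentifiable and the feature should not be fitted.
#'
#' @param feature_values Non-negative abundances for one feature.
#' @param group A 0/1 (or two-level) group vector aligned with the values.
#' @return `TRUE` iff one group is all-PMV and the other all-non-PMV.
#' @export
detect_perfect_separation <- function(feature_values, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("two-group designs only")
  z <- feature_values == 0
  a <- z[g == levels(g)[1L]]
  b <- z[g == levels(g)[2L]]
  (all(a) && !any(b)) || (!any(a) && all(b))
}

#' Filter features prior to model fitting
#'
#' Keeps features with at least `min_nonpmv` non-PMV observations overall and,
#' when `require_mixed_per_group` is set, at least one PMV and one non-PMV in
#' each group. Perfectly separated features are reported separately (they also
#' violate the mixed-per-group rule, but the distinct diagnosis matters in
#' practice).
#'
#' @param x An abundance matrix.
#' @param design A design matrix from [build_design()] (its `group` column is
#'   used), or a plain two-level group vector.
#' @param min_nonpmv Minimum number of non-PMV observations per feature.
#' @param require_mixed_per_group Require >=1 PMV and >=1 non-PMV per group.
#' @return A list with `kept_ids`, `dropped_ids`, and `report`, a tibble with
#'   columns `feature_id`, `kept`, `reason`, `n_nonpmv`, `n_pmv`.
#' @export
filter_features <- function(x, design, min_nonpmv = 3,
                            require_mixed_per_group = TRUE) {
  group <- design_group(design)
  z <- x == 0
  n_nonpmv <- rowSums(!z)
  n_pmv <- rowSums(z)
  g1 <- group == 1
  reason <- rep(NA_character_, nrow(x))
  low <- n_nonpmv < min_nonpmv
  reason[low] <- "insufficient non-PMVs"
  if (require_mixed_per_group) {
    sep <- vapply(seq_len(nrow(x)), function(k) {
      is.na(reason[k]) && detect_perfect_separation(x[k, ], group)
    }, logical(1L))
    reason[sep] <- "perfect separation"
    mixed_ok <- vapply(seq_len(nrow(x)), function(k) {
      zk <- z[k, ]
      any(zk[g1]) && any(!zk[g1]) && any(zk[!g1]) && any(!zk[!g1])
    }, logical(1L))
    miss <- is.na(reason) & !mixed_ok
    reason[miss] <- "missing PMV or non-PMV in a group"
  }
  if (any(reason %in% "perfect separation")) {
    warning(sum(reason %in% "perfect separation"),
      " feature(s) dropped for perfect separation")
  }
  report <- tibble::tibble(
    feature_id = rownames(x),
    kept = is.na(reason),
    reason = reason,
    n_nonpmv = as.integer(n_nonpmv),
    n_pmv = as.integer(n_pmv)
  )
  list(
    kept_ids = report$feature_id[report$kept],
    dropped_ids = report$feature_id[!report$kept],
    report = report
  )
}

# Extract the 0/1 group indicator from a design matrix or a raw group vector.
design_group <- function(design) {
  if (is.matrix(design)) {
    if (!"group" %in% colnames(design)) stop("design matrix has no `group` column")
    return(design[, "group"])
  }
  g <- as.factor(design)
  if (nlevels(g) != 2L) stop("two-group designs only")
  as.numeric(g == levels(g)[2L])
}
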