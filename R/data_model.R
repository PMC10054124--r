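#' Construct a concentration table
#'
#' A `conc_table` holds per-sample element concentrations (mg/kg) together
#' with optional covariate columns (e.g. pH, soil organic matter). It is the
#' common input container for all screening, risk and apportionment stages.
#'
#' @param values numeric matrix, n samples x m elements, strictly positive.
#' @param sample_ids character vector of unique sample identifiers
#'   (default `"S1"..."Sn"`).
#' @param elements character vector of element names; defaults to the column
#'   names of `values`.
#' @param covariates optional data.frame of per-sample covariates (n rows).
#' @return An object of class `conc_table`: a list with components
#'   `values` (matrix with dimnames), `sample_ids`, `elements`, `covariates`.
#' @details Concentrations must be finite and strictly positive: the
#'   measurement model assumes every value is above the detection limit, so
#'   zeros are rejected rather than imputed. At least two elements are
#'   required for any multivariate stage.
#' @export
conc_table <- function(values, sample_ids = NULL, elements = NULL,
                       covariates = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(elements)) elements <- colnames(values)
  if (is.null(elements)) stop("element names are required", call. = FALSE)
  elements <- clean_element(elements)
  if (ncol(values) != length(elements))
    stop("number of element names does not match columns of 'values'",
         call. = FALSE)
  if (ncol(values) < 2L)
    stop("at least 2 elements are required", call. = FALSE)
  if (nrow(values) < 1L)
    stop("empty concentration table is forbidden", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(values)))
  sample_ids <- as.character(sample_ids)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample IDs: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  bad <- which(!is.finite(values) | values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("non-positive or non-finite concentration for sample '",
         sample_ids[bad[1L, 1L]], "', element '", elements[bad[1L, 2L]], "'",
         call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(values))
      stop("covariates must have one row per sample", call. = FALSE)
    rownames(covariates) <- sample_ids
  }
  dimnames(values) <- list(sample_ids, elements)
  structure(list(values = values, sample_ids = sample_ids,
                 elements = elements, covariates = covariates),
            class = "conc_table")
}

# canonical element spelling: trimmed, first letter upper, rest preserved
clean_element <- function(x) trimws(as.character(x))

# case-insensitive, whitespace-stripped element matching; returns indices
match_elements <- function(wanted, available, where = "table") {
  idx <- match(tolower(trimws(wanted)), tolower(trimws(available)))
  if (anyNA(idx))
    stop("element(s) not found in ", where, ": ",
         paste(wanted[is.na(idx)], collapse = ", "), call. = FALSE)
  idx
}

#' @export
print.conc_table <- function(x, ...) {
  cat("Concentration table: ", nrow(x$values), " samples x ",
      ncol(x$values), " elements (mg/kg)\n", sep = "")
  cat("Elements:", paste(x$elements, collapse = ", "), "\n")
  if (!is.null(x$covariates))
    cat("Covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  invisible(x)
}

#' Read a concentration table from CSV
#'
#' Expects one row per sample with the sample identifier in `id_column`
#' (default: first column) and one numeric column per element in mg/kg.
#' Any further columns named in `covariate_columns` are carried along.
#'
#' @param path path to a CSV file with a header row.
#' @param element_columns character vector naming the element columns
#'   (matched case-insensitively, whitespace-stripped).
#' @param id_column name of the sample-id column; default the first column.
#' @param covariate_columns optional character vector of covariate column
#'   names (e.g. `c("pH", "SOM")`).
#' @return A [conc_table].
#' @export
read_concentrations <- function(path, element_columns, id_column = NULL,
                                covariate_columns = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (is.null(id_column)) id_column <- names(df)[1L]
  nm <- names(df)
  idc <- match(tolower(trimws(id_column)), tolower(trimws(nm)))
  if (is.na(idc))
    stop("missing id column '", id_column, "' in ", path, call. = FALSE)
  eidx <- tryCatch(match_elements(element_columns, nm, where = path),
                   error = function(e) stop(conditionMessage(e), call. = FALSE))
  vals <- as.matrix(df[eidx])
  if (!is.numeric(vals))
    stop("non-numeric concentration column in ", path, call. = FALSE)
  colnames(vals) <- clean_element(element_columns)
  cov <- NULL
  if (!is.null(covariate_columns)) {
    cidx <- match_elements(covariate_columns, nm, where = path)
    cov <- df[cidx]
    names(cov) <- trimws(covariate_columns)
  }
  conc_table(vals, sample_ids = df[[idc]], covariates = cov)
}

#' Construct or read a per-element reference table
#'
#' The reference table carries, per element: the regional geochemical
#' background value (mg/kg), the regulatory screening value (mg/kg), the
#' Hakanson toxic-response coefficient (dimensionless), the method detection
#' limit MDL (mg/kg), and the relative standard deviation theta used by the
#' PMF uncertainty model. MDL and theta may be left `NA`; stages that need
#' them apply documented defaults (theta = 0.10, MDL = 5% of the element
#' mean) unless overridden.
#'
#' @param df data.frame with columns `element`, `background`, `screening`,
#'   `toxicity` and optionally `mdl`, `theta`.
#' @return An object of class `ref_table` (a validated data.frame).
#' @export
ref_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("element", "background", "screening", "toxicity")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("reference table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!"mdl" %in% names(df)) df$mdl <- NA_real_
  if (!"theta" %in% names(df)) df$theta <- NA_real_
  df$element <- clean_element(df$element)
  for (col in c("background", "toxicity")) {
    v <- df[[col]]
    if (any(!is.finite(v) | v <= 0))
      stop("reference column '", col, "' must be positive for every element",
           call. = FALSE)
  }
  if (any(!is.na(df$mdl) & df$mdl < 0))
    stop("mdl must be >= 0", call. = FALSE)
  if (any(!is.na(df$theta) & (df$theta < 0 | df$theta >= 1)))
    stop("theta must be in [0, 1)", call. = FALSE)
  if (anyDuplicated(tolower(df$element)))
    stop("duplicate element in reference table", call. = FALSE)
  class(df) <- c("ref_table", "data.frame")
  df
}

#' @rdname ref_table
#' @param path path to a CSV file with columns
#'   `element,background,screening,toxicity[,mdl,theta]`.
#' @export
read_reference <- function(path) {
  ref_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Look up reference values for a set of elements
#'
#' @param refs a [ref_table].
#' @param elements character vector of element names.
#' @param field one of `"background"`, `"screening"`, `"toxicity"`,
#'   `"mdl"`, `"theta"`.
#' @return Named numeric vector in the requested element order.
#' @export
ref_lookup <- function(refs, elements,
                       field = c("background", "screening", "toxicity",
                                 "mdl", "theta")) {
  field <- match.arg(field)
  idx <- match_elements(elements, refs$element, where = "reference table")
  stats::setNames(refs[[field]][idx], clean_element(elements))
}

#' Subset a concentration table by sample ID
#'
#' Supports outlier-sample removal workflows: the returned table keeps the
#' original element order and covariates for the retained rows.
#'
#' @param table a [conc_table].
#' @param keep character vector of sample IDs to retain (a subset of
#'   `table$sample_ids`); order of the original table is preserved.
#' @return A [conc_table] with the retained samples.
#' @export
subset_samples <- function(table, keep) {
  stopifnot(inherits(table, "conc_table"))
  keep <- as.character(keep)
  unknown <- setdiff(keep, table$sample_ids)
  if (length(unknown))
    stop("unknown sample ID(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sel <- table$sample_ids %in% keep
  if (!any(sel))
    stop("empty concentration table is forbidden", call. = FALSE)
  conc_table(table$values[sel, , drop = FALSE],
             sample_ids = table$sample_ids[sel],
             elements = table$elements,
             covariates = if (!is.null(table$covariates))
               table$covariates[sel, , drop = FALSE])
}

#' Write a concentration table to CSV
#'
#' Inverse of [read_concentrations()]; round-trips values at full printed
#' precision (15 significant digits).
#'
#' @param table a [conc_table].
#' @param path output CSV path.
#' @export
write_concentrations <- function(table, path) {
  stopifnot(inherits(table, "conc_table"))
  df <- data.frame(sample = table$sample_ids, table$values,
                   check.names = FALSE)
  if (!is.null(table$covariates)) df <- cbind(df, table$covariates)
  utils::write.csv(df, path, row.names = FALSE)
}
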