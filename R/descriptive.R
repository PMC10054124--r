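#' Classify a coefficient of variation
#'
#' Standard geochemical CV bands: weak variation when CV is at most 15%,
#' moderate strictly between 15% and 36%, high at 36% and above. High
#' variation flags elements whose spatial distribution is dominated by
#' external (anthropogenic) inputs rather than parent material.
#'
#' @param cv numeric vector of coefficients of variation, in percent.
#' @return Factor with ordered levels `weak < moderate < high`.
#' @export
classify_cv <- function(cv) {
  if (any(!is.finite(cv) | cv < 0))
    stop("cv must be non-negative and finite", call. = FALSE)
  cls <- ifelse(cv <= 15, "weak", ifelse(cv < 36, "moderate", "high"))
  factor(cls, levels = c("weak", "moderate", "high"), ordered = TRUE)
}

#' Descriptive screening statistics per element
#'
#' For each element: min, max, mean, sample standard deviation, coefficient
#' of variation (100 * sd / mean) with its class, ratio of the mean to the
#' regional background value, and the screening-value exceedance rate
#' (percent of samples with concentration strictly above the screening
#' value).
#'
#' @param table a [conc_table].
#' @param refs a [ref_table] covering every element of `table`.
#' @param exceed_strict use strict `>` against the screening value
#'   (default `TRUE`); set `FALSE` for `>=`.
#' @return data.frame with one row per element and columns `element`,
#'   `min`, `max`, `mean`, `sd`, `cv`, `cv_class`, `background_ratio`,
#'   `exceedance_rate`.
#' @details The sample (n-1) standard deviation is used. Background ratios
#'   are conventionally quoted at one decimal; full precision is returned
#'   and rounding is left to the caller.
#' @export
summarize_elements <- function(table, refs, exceed_strict = TRUE) {
  stopifnot(inherits(table, "conc_table"))
  X <- table$values
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  bg <- ref_lookup(refs, table$elements, "background")
  scr <- ref_lookup(refs, table$elements, "screening")
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  exceed <- if (exceed_strict) sweep(X, 2L, scr, ">") else sweep(X, 2L, scr, ">=")
  cv <- 100 * sdv / mu
  data.frame(
    element = table$elements,
    min = apply(X, 2L, min),
    max = apply(X, 2L, max),
    mean = mu,
    sd = sdv,
    cv = cv,
    cv_class = classify_cv(cv),
    background_ratio = mu / bg,
    exceedance_rate = 100 * colMeans(exceed),
    row.names = NULL
  )
}

#' Pearson correlation matrix with two-tailed p-values
#'
#' Pairwise Pearson correlations among elements (and optionally covariates),
#' with two-tailed p-values from the t transform on n - 2 degrees of
#' freedom, and significance stars at the 0.05 (`*`) and 0.01 (`**`) levels.
#'
#' @param table a [conc_table].
#' @param include_covariates prepend the covariate columns (pH, SOM, ...)
#'   to the variable set (default `TRUE` when present).
#' @return List of class `metal_cor` with components `r` (correlations),
#'   `p` (p-values, `NA` on the diagonal), `stars` (character matrix),
#'   `n`, and `undefined` (names of zero-variance variables, whose rows and
#'   columns are `NA`-flagged rather than dropped).
#' @export
element_correlations <- function(table, include_covariates = !is.null(table$covariates)) {
  stopifnot(inherits(table, "conc_table"))
  M <- table$values
  if (isTRUE(include_covariates) && !is.null(table$covariates)) {
    num <- vapply(table$covariates, is.numeric, logical(1L))
    M <- cbind(as.matrix(table$covariates[num]), M)
  }
  n <- nrow(M)
  if (n < 3L) stop("need at least 3 samples for correlations", call. = FALSE)
  sds <- apply(M, 2L, stats::sd)
  undef <- colnames(M)[sds == 0]
  r <- suppressWarnings(stats::cor(M))
  diag(r) <- 1
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(r) >= 1] <- 0
  diag(p) <- NA_real_
  stars <- matrix("", nrow(p), ncol(p), dimnames = dimnames(p))
  stars[!is.na(p) & p < 0.05] <- "*"
  stars[!is.na(p) & p < 0.01] <- "**"
  structure(list(r = r, p = p, stars = stars, n = n, undefined = undef),
            class = "metal_cor")
}

#' @export
print.metal_cor <- function(x, digits = 3, ...) {
  lab <- matrix(paste0(format(round(x$r, digits)), x$stars),
                nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  lab[upper.tri(lab)] <- ""
  print(lab, quote = FALSE)
  if (length(x$undefined))
    cat("zero-variance (undefined):", paste(x$undefined, collapse = ", "), "\n")
  cat("n =", x$n,
      " (* p < 0.05, ** p < 0.01, two-tailed)\n")
  invisible(x)
}
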