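#' Single-element potential ecological risk factor
#'
#' Hakanson's Eri: the toxic-response coefficient times the enrichment of
#' the measured concentration over the regional background,
#' `Eri = Tr * C / S`.
#'
#' @param c measured concentration, mg/kg (vectorised).
#' @param s background (reference) value, mg/kg.
#' @param tr toxic-response coefficient (dimensionless; conventional set
#'   Zn = 1, Cr = 2, Cu = Ni = Pb = 5, Cd = 30).
#' @return Numeric Eri value(s), dimensionless.
#' @export
single_risk <- function(c, s, tr) {
  if (any(s <= 0)) stop("background value s must be > 0", call. = FALSE)
  if (any(tr <= 0)) stop("toxicity coefficient tr must be > 0", call. = FALSE)
  if (any(c <= 0)) stop("concentration c must be > 0", call. = FALSE)
  tr * c / s
}

#' Comprehensive potential ecological risk index
#'
#' RI is the exact sum of the single-element risk factors of one sample.
#'
#' @param eri_row numeric vector of non-negative Eri values.
#' @return The RI value.
#' @export
risk_index <- function(eri_row) {
  if (length(eri_row) == 0L) stop("empty Eri vector", call. = FALSE)
  if (any(eri_row < 0)) stop("Eri values must be >= 0", call. = FALSE)
  sum(eri_row)
}

.eri_breaks <- c(0, 40, 80, 160, 320, Inf)
.ri_breaks <- c(0, 150, 300, 600, 1200, Inf)
.risk_levels <- c("low", "moderate", "considerable", "high", "very high")

#' Risk class bands for Eri and RI
#'
#' Eri bands: `[0,40)` low, `[40,80)` moderate, `[80,160)` considerable,
#' `[160,320)` high, `[320,Inf)` very high. RI bands: `[0,150)` low,
#' `[150,300)` moderate, `[300,600)` considerable, `[600,1200)` high,
#' `[1200,Inf)` very high. Band lower edges are inclusive.
#'
#' @param e,r numeric vector of Eri (resp. RI) values, non-negative.
#' @return Ordered factor of class labels.
#' @export
classify_eri <- function(e) {
  if (any(!is.finite(e) | e < 0)) stop("Eri must be non-negative", call. = FALSE)
  cut(e, .eri_breaks, labels = .risk_levels, right = FALSE, ordered_result = TRUE)
}

#' @rdname classify_eri
#' @export
classify_ri <- function(r) {
  if (any(!is.finite(r) | r < 0)) stop("RI must be non-negative", call. = FALSE)
  cut(r, .ri_breaks, labels = .risk_levels, right = FALSE, ordered_result = TRUE)
}

#' Potential ecological risk table for a dataset
#'
#' Computes the full n x m matrix of single-element risk factors, the
#' per-sample comprehensive index RI, class labels for both, and a summary
#' (per-element min/max/mean/sd of Eri, the same statistics for RI, and
#' each element's share of the mean RI in percent).
#'
#' @param table a [conc_table].
#' @param refs a [ref_table] with `background` and `toxicity` for every
#'   element of `table`.
#' @return List of class `risk_result` with components `eri` (n x m),
#'   `ri` (length n), `eri_class`, `ri_class`, `summary` (data.frame) and
#'   `ri_stats` (min/max/mean/sd of RI).
#' @export
risk_table <- function(table, refs) {
  stopifnot(inherits(table, "conc_table"))
  bg <- ref_lookup(refs, table$elements, "background")
  tr <- ref_lookup(refs, table$elements, "toxicity")
  X <- table$values
  eri <- sweep(sweep(X, 2L, bg, "/"), 2L, tr, "*")
  ri <- rowSums(eri)
  mean_ri <- mean(ri)
  summ <- data.frame(
    element = table$elements,
    min = apply(eri, 2L, min),
    max = apply(eri, 2L, max),
    mean = colMeans(eri),
    sd = apply(eri, 2L, stats::sd),
    share = 100 * colMeans(eri) / mean_ri,
    row.names = NULL
  )
  structure(list(
    eri = eri, ri = ri,
    eri_class = apply(eri, 2L, classify_eri),
    ri_class = classify_ri(ri),
    summary = summ,
    ri_stats = c(min = min(ri), max = max(ri), mean = mean_ri,
                 sd = stats::sd(ri))
  ), class = "risk_result")
}

#' @export
print.risk_result <- function(x, digits = 2, ...) {
  cat("Potential ecological risk over", length(x$ri), "samples\n")
  s <- x$summary
  s[-1L] <- round(s[-1L], digits)
  print(s, row.names = FALSE)
  cat("RI: ", paste(names(x$ri_stats), round(x$ri_stats, digits),
                    sep = " = ", collapse = ", "), "\n")
  cat("Mean RI class:", as.character(classify_ri(x$ri_stats[["mean"]])), "\n")
  invisible(x)
}
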