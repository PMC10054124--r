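#' Standardize a concentration table
#'
#' Column-wise z-scores, `Z_ij = (C_ij - mean_i) / sd_i`, with the sample
#' (n-1) standard deviation. The means and sds are returned so the
#' artificial zero-concentration sample, whose standardized coordinates are
#' `-mean_i / sd_i`, can be scored later.
#'
#' @param table a [conc_table], n >= 3 samples.
#' @return List with `z` (n x m matrix), `means`, `sds`.
#' @export
standardize <- function(table) {
  stopifnot(inherits(table, "conc_table"))
  X <- table$values
  if (nrow(X) < 3L) stop("need at least 3 samples", call. = FALSE)
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  zero <- which(sdv == 0)
  if (length(zero))
    stop("zero-variance element(s): ",
         paste(table$elements[zero], collapse = ", "), call. = FALSE)
  z <- sweep(sweep(X, 2L, mu, "-"), 2L, sdv, "/")
  list(z = z, means = mu, sds = sdv)
}

#' Principal components of the correlation matrix
#'
#' Eigendecomposition of the correlation matrix of the standardized data,
#' optional varimax rotation, and the regression-method factor score
#' coefficients that map standardized data to component (factor) scores.
#'
#' @param z standardized matrix from [standardize()].
#' @param retention `"eigen"` (Kaiser rule, eigenvalue > 1), or an integer
#'   number of components to keep.
#' @param rotate `"varimax"` (default) or `"none"`.
#' @return List with `loadings` (m x p), `score_coef` (m x p, so that
#'   `scores = z %*% score_coef`), `explained` (percent variance per
#'   retained component, after rotation when rotated), `eigenvalues`
#'   (all m), `p`.
#' @details Loadings are eigenvectors scaled by the square root of their
#'   eigenvalues (component-correlation scaling). Score coefficients use
#'   the regression method, `R^{-1} L`; after varimax the rotated loadings
#'   are used, so rotated scores remain least-squares estimates.
#' @export
fit_components <- function(z, retention = "eigen", rotate = c("varimax", "none")) {
  rotate <- match.arg(rotate)
  m <- ncol(z)
  R <- stats::cor(z)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  p <- if (identical(retention, "eigen")) sum(ev > 1) else as.integer(retention)
  if (is.na(p) || p < 1L || p > m)
    stop("retention must keep between 1 and m components (got ", p, ")",
         call. = FALSE)
  L <- eig$vectors[, seq_len(p), drop = FALSE] %*%
    diag(sqrt(ev[seq_len(p)]), p)
  # fix sign: largest-magnitude loading positive, for reproducibility
  sgn <- apply(L, 2L, function(v) sign(v[which.max(abs(v))]))
  L <- sweep(L, 2L, sgn, "*")
  if (rotate == "varimax" && p > 1L) {
    vr <- stats::varimax(L, normalize = TRUE)
    L <- L %*% vr$rotmat
  }
  dimnames(L) <- list(colnames(z), paste0("F", seq_len(p)))
  # regression-method score coefficients; pseudo-inverse when R is singular
  # (perfectly collinear elements)
  B <- tryCatch(solve(R, L), error = function(e) pracma::pinv(R) %*% L)
  dimnames(B) <- dimnames(L)
  explained <- 100 * colSums(L^2) / m
  list(loadings = L, score_coef = B, explained = explained,
       eigenvalues = ev, p = p)
}

#' Absolute principal component scores
#'
#' Factor scores of every sample minus the factor score of the artificial
#' "zero-pollution" sample (all concentrations zero, standardized
#' coordinates `-mean_i / sd_i`). The shift makes the scores absolute
#' (non-centred), so they can be regressed against raw concentrations.
#'
#' @param comp result of [fit_components()].
#' @param z,means,sds output of [standardize()].
#' @return n x p matrix of absolute scores.
#' @export
absolute_scores <- function(comp, z, means, sds) {
  if (ncol(z) != nrow(comp$score_coef))
    stop("dimension mismatch between z and score coefficients", call. = FALSE)
  scores <- z %*% comp$score_coef
  z0 <- matrix(-means / sds, nrow = 1L)
  score0 <- z0 %*% comp$score_coef
  sweep(scores, 2L, as.numeric(score0), "-")
}

#' Regression of concentrations on absolute scores and apportionment
#'
#' Per element, ordinary least squares of the raw concentration on all
#' absolute principal component scores. The mean contribution of factor p
#' to element i is `b_pi * mean(APCS_p)`. For percentage tables, negative
#' mean contributions are floored at zero and the remainder (including the
#' intercept's share) is reported as "unidentified"; rows are then
#' renormalized to 100%. Overall factor shares are the unweighted mean of
#' the per-element percentages.
#'
#' @param apcs n x p matrix from [absolute_scores()].
#' @param table the [conc_table] the scores came from.
#' @return List of class `apcs_mlr_result`; see Details.
#' @details Components: `intercepts`, `coefficients` (m x p), `r2`
#'   (squared Pearson correlation of predicted vs observed, per element),
#'   `raw_contrib` (p x m signed mean contributions, mg/kg),
#'   `percent` ((p+1) x m percent table including the `unidentified` row),
#'   `shares` (length p+1, percent), `predicted` (n x m).
#' @export
regress_and_apportion <- function(apcs, table) {
  stopifnot(inherits(table, "conc_table"))
  X <- table$values
  p <- ncol(apcs)
  n <- nrow(X)
  if (qr(cbind(1, apcs))$rank < p + 1L)
    stop("APCS columns are collinear; reduce the number of factors",
         call. = FALSE)
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, apcs), X)
  coefs <- fit$coefficients
  b0 <- coefs[1L, ]
  b <- t(coefs[-1L, , drop = FALSE])           # m x p
  pred <- cbind(1, apcs) %*% coefs
  r2 <- vapply(seq_len(ncol(X)), function(j)
    stats::cor(pred[, j], X[, j])^2, numeric(1L))
  names(r2) <- table$elements
  mean_apcs <- colMeans(apcs)
  raw <- t(b * rep(mean_apcs, each = nrow(b)))  # p x m signed contributions
  dimnames(raw) <- list(colnames(apcs), table$elements)
  mean_c <- colMeans(X)
  pos <- pmax(raw, 0)
  unid <- pmax(mean_c - colSums(pos), 0)
  pct <- rbind(pos, unidentified = unid)
  pct <- sweep(pct, 2L, colSums(pct), "/") * 100
  shares <- rowMeans(pct)
  structure(list(intercepts = b0, coefficients = b, r2 = r2,
                 raw_contrib = raw, percent = pct, shares = shares,
                 predicted = pred),
            class = "apcs_mlr_result")
}

#' APCS-MLR source apportionment
#'
#' Convenience wrapper running [standardize()], [fit_components()],
#' [absolute_scores()] and [regress_and_apportion()] in sequence.
#'
#' @inheritParams standardize
#' @inheritParams fit_components
#' @return The `apcs_mlr_result`, augmented with `loadings`, `explained`,
#'   `apcs`, and `profiles` (factor shares renormalized over identified
#'   factors only, rows of the percent table scaled to sum 1 per factor for
#'   cross-model profile comparison).
#' @export
apcs_mlr <- function(table, retention = "eigen", rotate = c("varimax", "none")) {
  std <- standardize(table)
  comp <- fit_components(std$z, retention = retention, rotate = rotate)
  apcs <- absolute_scores(comp, std$z, std$means, std$sds)
  res <- regress_and_apportion(apcs, table)
  res$loadings <- comp$loadings
  res$explained <- comp$explained
  res$apcs <- apcs
  # factor profiles in concentration units for alignment: positive part of
  # the mean contribution of each factor to each element
  prof <- pmax(res$raw_contrib, 0)
  rs <- rowSums(prof)
  rs[rs == 0] <- 1
  res$profiles <- prof / rs
  res
}

#' @export
print.apcs_mlr_result <- function(x, digits = 2, ...) {
  p <- ncol(x$coefficients)
  cat("APCS-MLR apportionment with", p, "factors\n")
  if (!is.null(x$explained))
    cat("Explained variance (%):",
        paste(round(x$explained, digits), collapse = ", "),
        sprintf("(cumulative %.2f)\n", sum(x$explained)))
  cat("Per-element r2:\n")
  print(round(x$r2, 3))
  cat("Overall source shares (%):\n")
  print(round(x$shares, digits))
  invisible(x)
}
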