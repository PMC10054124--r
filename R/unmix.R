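#' Min-max scale a concentration table
#'
#' Dispersion standardization per element,
#' `X' = (X - min) / (max - min)`, mapping every element to `[0, 1]`
#' before geometric source resolution. The per-element minima and maxima
#' are retained so profiles can be mapped back to concentration units.
#'
#' @param table a [conc_table] (or plain matrix).
#' @return List with `x` (scaled matrix), `mins`, `maxs`.
#' @export
minmax_scale <- function(table) {
  X <- if (inherits(table, "conc_table")) table$values else as.matrix(table)
  mins <- apply(X, 2L, min)
  maxs <- apply(X, 2L, max)
  if (any(maxs - mins == 0))
    stop("constant element(s): ",
         paste(colnames(X)[maxs - mins == 0], collapse = ", "),
         call. = FALSE)
  list(x = sweep(sweep(X, 2L, mins, "-"), 2L, maxs - mins, "/"),
       mins = mins, maxs = maxs)
}

#' Invert a min-max scaling
#'
#' @param xs scaled matrix.
#' @param mins,maxs per-element extremes from [minmax_scale()].
#' @return Matrix in original concentration units.
#' @export
minmax_invert <- function(xs, mins, maxs) {
  sweep(sweep(xs, 2L, maxs - mins, "*"), 2L, mins, "+")
}

#' Estimate the number of sources from the scaled data
#'
#' Singular value decomposition of the column-centred scaled matrix. For a
#' candidate rank r, the noise floor is the mean of the squared trailing
#' singular values beyond r, and a component's signal-to-noise is its
#' squared singular value over that floor. The retained source count k is
#' the smallest self-consistent rank: the smallest r for which exactly r
#' components exceed S/N 2 under its own noise floor (at least 1).
#' Candidate ranks whose trailing components are numerically zero
#' (relative to the leading one) indicate exact low-rank structure and are
#' accepted outright.
#'
#' @param xs scaled matrix from [minmax_scale()], n > m.
#' @return List with `k`, `sig_noise` (per-component S/N at the chosen
#'   rank), `singular_values`, and `low_confidence` (`TRUE` at the k = 1
#'   floor: a single component cannot be resolved as a mixture).
#' @export
estimate_sources <- function(xs) {
  n <- nrow(xs); m <- ncol(xs)
  if (n <= m) stop("need more samples than elements", call. = FALSE)
  xc <- scale(xs, center = TRUE, scale = FALSE)
  sv <- svd(xc, nu = 0, nv = 0)$d
  if (sv[1L] <= 0) stop("degenerate (rank 0) matrix", call. = FALSE)
  s2 <- sv^2
  tiny <- 1e-12 * s2[1L]
  k <- NA_integer_
  for (r in seq_len(m - 1L)) {
    floor_r <- mean(s2[(r + 1L):m])
    if (floor_r <= tiny) {          # exact low-rank structure at rank r
      k <- r
      break
    }
    if (sum(s2 / floor_r > 2) == r) {
      k <- r
      break
    }
  }
  if (is.na(k))                      # no self-consistent rank: floor case
    k <- 1L
  floor_k <- max(mean(s2[(k + 1L):m]), tiny)
  sn <- s2 / floor_k
  list(k = k, sig_noise = sn, singular_values = sv,
       low_confidence = (k == 1L))
}

# non-negative least squares with a bounded-optimizer fallback for the
# degenerate systems where the active-set method stalls
.nnls <- function(A, b) {
  r <- tryCatch(pracma::lsqnonneg(A, b)$x, error = function(e) NULL)
  if (!is.null(r)) return(r)
  stats::optim(rep(0, ncol(A)), fn = function(x) sum((A %*% x - b)^2),
               gr = function(x) as.numeric(2 * crossprod(A, A %*% x - b)),
               method = "L-BFGS-B", lower = 0)$par
}

# log absolute volume of the simplex spanned by rows `idx` of `coords`
.simplex_logvol <- function(coords, idx) {
  d <- t(coords[idx[-1L], , drop = FALSE]) -
    as.numeric(coords[idx[1L], ])
  determinant(crossprod(d), logarithm = TRUE)$modulus / 2
}

# choose k vertex rows maximizing simplex volume in (k-1)-dim coords;
# exhaustive when the candidate count is small, greedy inflation otherwise
.max_volume_vertices <- function(coords, k, exhaustive_limit = 20000L) {
  n <- nrow(coords)
  if (choose(n, k) <= exhaustive_limit) {
    combs <- utils::combn(n, k)
    vols <- apply(combs, 2L, function(ix) .simplex_logvol(coords, ix))
    best <- max(vols)
    # ties: lexicographically smallest index set
    cand <- which(vols >= best - 1e-9)
    combs[, cand[1L]]
  } else {
    # greedy: start from the two most distant points, inflate
    dd <- as.matrix(stats::dist(coords))
    idx <- as.integer(arrayInd(which.max(dd), dim(dd)))
    idx <- sort(idx)
    while (length(idx) < k) {
      rest <- setdiff(seq_len(n), idx)
      vols <- vapply(rest, function(j)
        .simplex_logvol(coords, c(idx, j)), numeric(1L))
      idx <- sort(c(idx, rest[which.max(vols)]))
    }
    idx
  }
}

#' Resolve sources geometrically (simplified UNMIX)
#'
#' A simplified self-modeling mixture resolution: samples are projected
#' onto the top k-1 principal axes of the scaled data, the k samples
#' spanning the maximum-volume simplex are taken as near-pure vertices,
#' their compositions (mapped back to concentration units) seed the source
#' profiles, per-sample contributions follow by non-negative least
#' squares, and alternating NNLS passes (contributions given profiles,
#' profiles given contributions) refine both until the fit stops
#' improving or `n_refine` passes are reached. This
#' substitutes a published, testable pure-sample (vertex) algorithm for
#' EPA UNMIX's unpublished edge-finding internals while keeping its role:
#' an independent geometric cross-check that needs no preset source count
#' or uncertainties.
#'
#' @param table a [conc_table].
#' @param k number of sources; `"auto"` (default) uses
#'   [estimate_sources()].
#' @param n_refine maximum alternating NNLS refinement passes
#'   (default 15).
#' @return List of class `unmix_result`: `k`, `f` (k x m non-negative
#'   profiles, rows sum to 1), `s` (n x k non-negative contributions,
#'   mg/kg), `r2` (per element), `min_rsq`, `min_sig_noise`, `valid`
#'   (`min_rsq > 0.8` and `min_sig_noise > 2`), `scaling`,
#'   `vertex_samples`, `shares` (percent).
#' @export
unmix_resolve <- function(table, k = "auto", n_refine = 15L) {
  stopifnot(inherits(table, "conc_table"))
  X <- table$values
  sc <- minmax_scale(table)
  est <- estimate_sources(sc$x)
  if (identical(k, "auto")) k <- max(est$k, 2L)
  k <- as.integer(k)
  if (k < 2L || k > ncol(X))
    stop("k must be between 2 and the number of elements", call. = FALSE)
  xc <- scale(sc$x, center = TRUE, scale = FALSE)
  pc <- svd(xc, nu = 0, nv = k - 1L)
  coords <- xc %*% pc$v
  vert <- .max_volume_vertices(coords, k)
  if (.simplex_logvol(coords, vert) < log(1e-12))
    stop("degenerate simplex; try a smaller k", call. = FALSE)
  Fmat <- X[vert, , drop = FALSE]                     # k x m, conc units
  S <- t(apply(X, 1L, function(x) .nnls(t(Fmat), x)))  # n x k
  rss_prev <- Inf
  for (pass in seq_len(max(n_refine, 0L))) {
    Fref <- vapply(seq_len(ncol(X)), function(j)
      .nnls(S, X[, j]), numeric(k))                    # k x m
    if (!all(is.finite(Fref)) || any(rowSums(Fref) == 0)) break
    Fmat <- Fref
    S <- t(apply(X, 1L, function(x) .nnls(t(Fmat), x)))
    rss <- sum((X - S %*% Fmat)^2)
    if (rss_prev - rss <= 1e-10 * max(rss, 1)) break
    rss_prev <- rss
  }
  # normalize profile rows to unit sum; absorb scale into S
  rs <- rowSums(Fmat)
  S <- S * rep(rs, each = nrow(S))
  Fmat <- Fmat / rs
  dimnames(Fmat) <- list(paste0("U", seq_len(k)), table$elements)
  dimnames(S) <- list(table$sample_ids, paste0("U", seq_len(k)))
  recon <- S %*% Fmat
  r2 <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(recon[, j]) == 0) return(0)
    stats::cor(X[, j], recon[, j])^2
  }, numeric(1L))
  names(r2) <- table$elements
  min_rsq <- min(r2)
  min_sn <- min(est$sig_noise[seq_len(min(k, length(est$sig_noise)))])
  shares <- 100 * colMeans(S) / sum(colMeans(S))
  structure(list(k = k, f = Fmat, s = S, r2 = r2, min_rsq = min_rsq,
                 min_sig_noise = min_sn,
                 valid = (min_rsq > 0.8 && min_sn > 2),
                 scaling = list(mins = sc$mins, maxs = sc$maxs),
                 vertex_samples = table$sample_ids[vert],
                 shares = shares,
                 estimate = est),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, digits = 3, ...) {
  cat("Simplified geometric UNMIX, k =", x$k, "sources\n")
  cat(sprintf("Min Rsq = %.3f, Min Sig/Noise = %.2f, valid = %s\n",
              x$min_rsq, x$min_sig_noise, x$valid))
  cat("Vertex samples:", paste(x$vertex_samples, collapse = ", "), "\n")
  cat("Source shares (%):\n")
  print(round(x$shares, 2))
  invisible(x)
}
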