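#' PMF configuration
#'
#' Collects the tuning parameters of the positive matrix factorization
#' stage with validated defaults.
#'
#' @param k_min,k_max factor-count range for [scan_factors()].
#' @param n_runs random restarts per factor count (default 20).
#' @param seed base seed; run r uses `seed + r - 1`.
#' @param max_iter maximum multiplicative-update iterations per run.
#' @param tol convergence threshold on the relative change of Q between
#'   successive iterations.
#' @param robust_alpha scaled-residual cutoff for the robust Q (default 4,
#'   the conventional |scaled residual| > 4 outlier band).
#' @param outlier_gap_tol stop outlier removal once
#'   `(Q_true - Q_robust) / Q_robust` falls to this value or below
#'   (default 0.005: under well-behaved Gaussian scaled residuals the two
#'   objectives coincide almost exactly, so any gap above half a percent
#'   signals residual cells beyond the robust cutoff).
#' @param max_removals cap on removed samples during outlier screening.
#' @return List of class `pmf_config`.
#' @export
pmf_config <- function(k_min = 4L, k_max = 7L, n_runs = 20L, seed = 1L,
                       max_iter = 2000L, tol = 1e-8, robust_alpha = 4,
                       outlier_gap_tol = 0.005, max_removals = 20L) {
  stopifnot(k_min >= 1L, k_max >= k_min, n_runs >= 1L, max_iter >= 1L,
            tol > 0, robust_alpha > 0, outlier_gap_tol >= 0,
            max_removals >= 0L)
  structure(list(k_min = as.integer(k_min), k_max = as.integer(k_max),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 max_iter = as.integer(max_iter), tol = tol,
                 robust_alpha = robust_alpha,
                 outlier_gap_tol = outlier_gap_tol,
                 max_removals = as.integer(max_removals)),
            class = "pmf_config")
}

#' Concentration uncertainty matrix
#'
#' Error-fraction uncertainty model: for every cell,
#' `U_ij = sqrt((theta_j * C_ij)^2 + MDL_j^2)`, where theta is the
#' per-element relative standard deviation and MDL the method detection
#' limit. Elements with no theta/MDL in the reference table fall back to
#' the documented defaults (theta 0.10, MDL 5% of the element mean).
#'
#' @param table a [conc_table].
#' @param refs a [ref_table]; its `theta` and `mdl` columns may be `NA`.
#' @param default_theta,default_mdl_frac defaults applied where the
#'   reference table has no value; `default_mdl_frac` is a fraction of the
#'   element's mean concentration.
#' @return n x m positive matrix of uncertainties, mg/kg.
#' @export
uncertainty <- function(table, refs = NULL, default_theta = 0.10,
                        default_mdl_frac = 0.05) {
  stopifnot(inherits(table, "conc_table"))
  X <- table$values
  m <- ncol(X)
  theta <- rep(default_theta, m)
  mdl <- default_mdl_frac * colMeans(X)
  if (!is.null(refs)) {
    th <- ref_lookup(refs, table$elements, "theta")
    md <- ref_lookup(refs, table$elements, "mdl")
    theta[!is.na(th)] <- th[!is.na(th)]
    mdl[!is.na(md)] <- md[!is.na(md)]
  }
  U <- sqrt(sweep(X, 2L, theta, "*")^2 + rep(mdl^2, each = nrow(X)))
  if (any(U <= 0))
    stop("uncertainty must be positive everywhere; set theta or MDL > 0",
         call. = FALSE)
  dimnames(U) <- dimnames(X)
  U
}

#' Per-element signal-to-noise ratio
#'
#' EPA-PMF-5.0-style S/N: per element, the average over samples of the
#' excess of the concentration over its uncertainty, in uncertainty units —
#' `d_ij = (X_ij - U_ij) / U_ij` where `X_ij > U_ij`, else 0. Elements
#' with S/N <= 2 are conventionally down-weighted as "weak"; S/N below 0.2
#' is "bad".
#'
#' @param X concentration matrix (or [conc_table]).
#' @param U matching uncertainty matrix.
#' @return data.frame with `element`, `sn`, `category`
#'   (`strong`/`weak`/`bad`).
#' @export
signal_to_noise <- function(X, U) {
  if (inherits(X, "conc_table")) X <- X$values
  if (!all(dim(X) == dim(U))) stop("shape mismatch", call. = FALSE)
  d <- pmax((X - U) / U, 0)
  sn <- colMeans(d)
  data.frame(element = colnames(X) %||% paste0("V", seq_along(sn)),
             sn = sn,
             category = ifelse(sn > 2, "strong",
                               ifelse(sn > 0.2, "weak", "bad")),
             row.names = NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' True and robust Q for a PMF solution
#'
#' `Q_true` is the sum of squared uncertainty-scaled residuals
#' `r = (X - G F) / U`. `Q_robust` replaces each squared residual with a
#' Huber-type term that grows linearly beyond the cutoff:
#' `h(r) = r^2` for `|r| <= alpha`, `h(r) = alpha * (2 |r| - alpha)`
#' otherwise (continuous at the cutoff), which bounds the influence of
#' outlying cells.
#'
#' @param X,U,G,F concentration, uncertainty, contribution (n x k) and
#'   profile (k x m) matrices.
#' @param robust_alpha cutoff on the absolute scaled residual (default 4).
#' @return Named list `q_true`, `q_robust`.
#' @export
q_values <- function(X, U, G, F, robust_alpha = 4) {
  r <- (X - G %*% F) / U
  a <- robust_alpha
  r2 <- r^2
  h <- ifelse(abs(r) <= a, r2, a * (2 * abs(r) - a))
  list(q_true = sum(r2), q_robust = sum(h))
}

# one weighted-NMF multiplicative update pass; W = 1/U^2
.pmf_update <- function(X, W, G, F) {
  eps <- 1e-12
  WX <- W * X
  G <- G * ((WX %*% t(F)) / ((W * (G %*% F)) %*% t(F) + eps))
  F <- F * ((t(G) %*% WX) / (t(G) %*% (W * (G %*% F)) + eps))
  list(G = G, F = F)
}

# single seeded run from random init; returns G, F, Q trace, convergence flag
.pmf_run <- function(X, W, k, seed, max_iter, tol) {
  n <- nrow(X); m <- ncol(X)
  set.seed(seed)
  colmean <- colMeans(X)
  # uniform(0,1] init scaled by column magnitudes so G F starts near X scale
  G <- matrix(stats::runif(n * k), n, k)
  F <- matrix(stats::runif(k * m), k, m) * rep(colmean, each = k) * (2 / k)
  q_trace <- numeric(0L)
  q_prev <- Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    upd <- .pmf_update(X, W, G, F)
    G <- upd$G; F <- upd$F
    q <- sum(W * (X - G %*% F)^2)
    q_trace <- c(q_trace, q)
    if (is.finite(q_prev) && (q_prev - q) <= tol * max(q, .Machine$double.eps)) {
      converged <- TRUE
      break
    }
    q_prev <- q
  }
  list(G = G, F = F, q = q, q_trace = q_trace, converged = converged,
       seed = seed)
}

#' Fit a positive matrix factorization
#'
#' Weighted non-negative factorization `X ~ G F` minimizing
#' `Q = sum((X - G F)^2 / U^2)` by multiplicative updates (weights
#' `1 / U^2`), which keep both factors non-negative and never increase Q.
#' The best of `n_runs` seeded random restarts is returned. For
#' comparability across runs, each profile row of `F` is normalized to sum
#' to one, with the scale absorbed into `G` (so `G` is in mg/kg
#' total-contribution units).
#'
#' @param X concentration matrix or [conc_table].
#' @param U uncertainty matrix, same shape, strictly positive.
#' @param k number of factors, `k < min(n, m)` recommended and
#'   `k <= min(n, m)` enforced.
#' @param config a [pmf_config()].
#' @return List of class `pmf_result`: `g` (n x k), `f` (k x m, rows sum
#'   to 1), `residuals`, `scaled_residuals`, `q_true`, `q_robust`,
#'   `species_r2`, `sn_ratio`, `run_log` (per-restart best Q and
#'   convergence), `converged`, `k`, `config`.
#' @export
pmf_fit <- function(X, U, k, config = pmf_config()) {
  ids <- NULL
  if (inherits(X, "conc_table")) { ids <- X$sample_ids; X <- X$values }
  if (!all(dim(X) == dim(U))) stop("X and U shapes differ", call. = FALSE)
  if (any(U <= 0)) stop("U must be positive everywhere", call. = FALSE)
  n <- nrow(X); m <- ncol(X)
  if (k >= min(n, m) + 1L || k < 1L)
    stop("k must satisfy 1 <= k <= min(n, m)", call. = FALSE)
  W <- 1 / U^2
  runs <- lapply(seq_len(config$n_runs), function(r)
    .pmf_run(X, W, k, seed = config$seed + r - 1L,
             max_iter = config$max_iter, tol = config$tol))
  qs <- vapply(runs, `[[`, numeric(1L), "q")
  best <- runs[[which.min(qs)]]
  G <- best$G; F <- best$F
  # normalize factor rows of F to unit sum; absorb scale into G
  rs <- rowSums(F)
  rs[rs == 0] <- 1
  G <- G * rep(rs, each = n)
  F <- F / rs
  dimnames(F) <- list(paste0("F", seq_len(k)), colnames(X))
  dimnames(G) <- list(ids %||% rownames(X), paste0("F", seq_len(k)))
  E <- X - G %*% F
  qv <- q_values(X, U, G, F, config$robust_alpha)
  r2 <- species_fit(X, G, F)
  if (!best$converged)
    warning("PMF run did not reach the convergence tolerance within max_iter",
            call. = FALSE)
  structure(list(
    g = G, f = F, residuals = E, scaled_residuals = E / U,
    q_true = qv$q_true, q_robust = qv$q_robust,
    species_r2 = r2,
    sn_ratio = signal_to_noise(X, U),
    run_log = data.frame(run = seq_along(runs),
                         seed = vapply(runs, `[[`, numeric(1L), "seed"),
                         q = qs,
                         iterations = vapply(runs, function(r)
                           length(r$q_trace), integer(1L)),
                         converged = vapply(runs, `[[`, logical(1L),
                                            "converged")),
    q_trace = best$q_trace,
    converged = best$converged, k = k, config = config,
    removed_samples = character(0L)
  ), class = "pmf_result")
}

#' Per-element goodness of fit of a factorization
#'
#' Squared Pearson correlation between each observed element column and its
#' reconstruction `G F`.
#'
#' @param X observed matrix (or [conc_table]).
#' @param G,F fitted contribution and profile matrices.
#' @return Named numeric vector of r-squared values; `NA` where a column is
#'   constant (flagged, not dropped).
#' @export
species_fit <- function(X, G, F) {
  if (inherits(X, "conc_table")) X <- X$values
  recon <- G %*% F
  r2 <- vapply(seq_len(ncol(X)), function(j) {
    if (stats::sd(X[, j]) == 0) return(NA_real_)   # undefined: flagged
    if (stats::sd(recon[, j]) == 0) return(0)      # no association
    stats::cor(X[, j], recon[, j])^2
  }, numeric(1L))
  names(r2) <- colnames(X)
  r2
}

#' Iterative outlier-sample removal for PMF
#'
#' Refits PMF and removes, one at a time, the sample with the largest sum
#' of squared scaled residuals, until the relative gap between the true and
#' robust Q, `(Q_true - Q_robust) / Q_robust`, falls to `outlier_gap_tol`
#' or `max_removals` is reached. A closing gap indicates no residual cell
#' exceeds the robust cutoff, i.e. the remaining data carry no dominant
#' outliers. Whole samples are removed, never single cells.
#'
#' @param table a [conc_table].
#' @param refs optional [ref_table] passed to [uncertainty()].
#' @param k number of factors.
#' @param config a [pmf_config()].
#' @param U optional precomputed uncertainty matrix (otherwise derived from
#'   `table` and `refs`).
#' @return List with `table` (reduced [conc_table]), `fit` (the refit
#'   `pmf_result` with `removed_samples` set), and `log` (data.frame of
#'   removal step, sample ID, residual norm, Q gap before removal).
#' @export
remove_outliers <- function(table, refs = NULL, k, config = pmf_config(),
                            U = NULL) {
  stopifnot(inherits(table, "conc_table"))
  if (is.null(U)) U <- uncertainty(table, refs)
  cur <- table
  curU <- U
  log <- data.frame(step = integer(0L), sample = character(0L),
                    resid_norm = numeric(0L), q_gap = numeric(0L))
  removed <- character(0L)
  repeat {
    fit <- pmf_fit(cur, curU, k, config)
    gap <- (fit$q_true - fit$q_robust) / fit$q_robust
    if (gap <= config$outlier_gap_tol || length(removed) >= config$max_removals)
      break
    if (nrow(cur$values) - 1L < 3L * k) {
      warning("stopping removal: sample count would drop below 3k",
              call. = FALSE)
      break
    }
    norms <- rowSums(fit$scaled_residuals^2)
    worst <- which.max(norms)
    removed <- c(removed, cur$sample_ids[worst])
    log <- rbind(log, data.frame(step = length(removed),
                                 sample = cur$sample_ids[worst],
                                 resid_norm = norms[worst], q_gap = gap))
    keep <- cur$sample_ids[-worst]
    curU <- curU[-worst, , drop = FALSE]
    cur <- subset_samples(cur, keep)
  }
  fit$removed_samples <- removed
  list(table = cur, fit = fit, log = log)
}

#' Scan candidate factor counts
#'
#' Fits PMF for each k in `[k_min, k_max]` and reports the best-of-runs
#' true and robust Q, the ratio to the expected Q
#' (`Q_expected = n m - k (n + m)`, the degrees of freedom of the
#' factorization), and the run-to-run dispersion of Q. No automatic choice
#' is made; the row after which Q stops dropping steeply (the elbow,
#' largest drop ratio) is marked.
#'
#' @param X concentration matrix or [conc_table].
#' @param U uncertainty matrix.
#' @param config a [pmf_config()] (its `k_min`/`k_max` define the range).
#' @return data.frame with one row per k: `k`, `q_true`, `q_robust`,
#'   `q_expected`, `q_over_qexp`, `q_run_sd`, `elbow`.
#' @export
scan_factors <- function(X, U, config = pmf_config()) {
  if (inherits(X, "conc_table")) X <- X$values
  n <- nrow(X); m <- ncol(X)
  ks <- seq(config$k_min, config$k_max)
  rows <- lapply(ks, function(k) {
    fit <- pmf_fit(X, U, k, config)
    data.frame(k = k, q_true = fit$q_true, q_robust = fit$q_robust,
               q_expected = q_expected(n, m, k),
               q_over_qexp = fit$q_true / q_expected(n, m, k),
               q_run_sd = stats::sd(fit$run_log$q))
  })
  out <- do.call(rbind, rows)
  out$elbow <- FALSE
  if (nrow(out) > 1L) {
    # elbow: the k reached by the single largest relative drop in Q
    drop_ratio <- out$q_true[-nrow(out)] / out$q_true[-1L]
    out$elbow[which.max(drop_ratio) + 1L] <- TRUE
  } else out$elbow[1L] <- TRUE
  out
}

#' Expected Q of a PMF fit
#'
#' Degrees of freedom left after fitting k factors to an n x m matrix:
#' `n m - k (n + m)`.
#'
#' @param n,m,k samples, elements, factors.
#' @return Integer-valued numeric.
#' @export
q_expected <- function(n, m, k) n * m - k * (n + m)

#' @export
print.pmf_result <- function(x, digits = 3, ...) {
  cat("PMF solution, k =", x$k, "factors,", nrow(x$g), "samples\n")
  cat(sprintf("Q_true = %.4g, Q_robust = %.4g (best of %d runs)\n",
              x$q_true, x$q_robust, nrow(x$run_log)))
  cat("Species r2:\n"); print(round(x$species_r2, digits))
  cat("Factor shares (%):\n")
  print(round(pmf_shares(x), 2))
  if (length(x$removed_samples))
    cat("Removed samples:", paste(x$removed_samples, collapse = ", "), "\n")
  invisible(x)
}

#' Overall factor shares of a PMF solution
#'
#' With profile rows normalized to unit sum, the mass contributed by factor
#' k is `mean(G_k)`; shares are these means as percentages of their total.
#'
#' @param fit a `pmf_result`.
#' @return Named numeric vector summing to 100.
#' @export
pmf_shares <- function(fit) {
  mg <- colMeans(fit$g)
  100 * mg / sum(mg)
}
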