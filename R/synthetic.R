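#' Default synthetic multi-source scenario
#'
#' Emulates a farmland-soil survey around a point industrial source:
#' 101 samples of 6 elements (Cu, Zn, Pb, Cd, Cr, Ni) mixed from 4 sources
#' with target shares 35/30/21/14% — an industrial source marked by Cu and
#' Ni, an agricultural source marked by Cd and Zn, a traffic source marked
#' by Pb with Cu and Zn, and a natural (parent-material) source
#' concentrating at least ~80% of its profile mass on Cr. Sample totals
#' follow a log-normal load with 10% multiplicative measurement noise.
#'
#' @param n samples (default 101).
#' @param theta multiplicative noise relative standard deviation
#'   (default 0.10).
#' @param outlier_frac fraction of samples receiving outlier cells
#'   (default 0; at most 0.2).
#' @param outlier_multiplier factor applied to 1-3 elements of each
#'   outlier sample (default 8).
#' @param seed integer seed.
#' @return List of class `scenario_config`: `n`, `elements`, `k`,
#'   `profiles` (k x m, rows sum to 1), `shares` (sum to 1),
#'   `total_median`, `total_sigma` (log-normal load parameters, mg/kg),
#'   `dirichlet_conc`, `theta`, `outlier_frac`, `outlier_multiplier`,
#'   `seed`.
#' @export
default_scenario <- function(n = 101L, theta = 0.10, outlier_frac = 0,
                             outlier_multiplier = 8, seed = 1L) {
  elements <- c("Cu", "Zn", "Pb", "Cd", "Cr", "Ni")
  profiles <- rbind(
    industrial   = c(Cu = 0.45, Zn = 0.08, Pb = 0.05, Cd = 0.02, Cr = 0.05, Ni = 0.35),
    agricultural = c(Cu = 0.05, Zn = 0.55, Pb = 0.05, Cd = 0.25, Cr = 0.02, Ni = 0.08),
    traffic      = c(Cu = 0.15, Zn = 0.30, Pb = 0.45, Cd = 0.02, Cr = 0.03, Ni = 0.05),
    natural      = c(Cu = 0.04, Zn = 0.04, Pb = 0.02, Cd = 0.02, Cr = 0.80, Ni = 0.08))
  colnames(profiles) <- elements
  scenario_config(n = n, elements = elements, profiles = profiles,
                  shares = c(industrial = 0.35, agricultural = 0.30,
                             traffic = 0.21, natural = 0.14),
                  total_median = 500, total_sigma = 0.4,
                  dirichlet_conc = 4, theta = theta,
                  outlier_frac = outlier_frac,
                  outlier_multiplier = outlier_multiplier, seed = seed)
}

#' Construct a validated scenario configuration
#'
#' @param n samples; `elements` names; `profiles` k x m source signature
#'   matrix (rows renormalized to sum to 1); `shares` length-k target
#'   shares summing to 1; `total_median`, `total_sigma` log-normal total
#'   load (median mg/kg and log-sd); `dirichlet_conc` concentration
#'   parameter of the per-sample Dirichlet mixing; `theta` multiplicative
#'   noise sd; `outlier_frac` in `[0, 0.2]`; `outlier_multiplier`;
#'   `seed`.
#' @param elements,profiles,shares,total_median,total_sigma See above.
#' @param dirichlet_conc,theta,outlier_frac,outlier_multiplier,seed See above.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(n, elements, profiles, shares, total_median,
                            total_sigma, dirichlet_conc = 4, theta = 0.1,
                            outlier_frac = 0, outlier_multiplier = 8,
                            seed = 1L) {
  profiles <- as.matrix(profiles)
  stopifnot(n >= 1L, ncol(profiles) == length(elements),
            nrow(profiles) == length(shares),
            all(profiles >= 0), all(rowSums(profiles) > 0),
            all(shares > 0), total_median > 0, total_sigma >= 0,
            dirichlet_conc > 0, theta >= 0)
  if (abs(sum(shares) - 1) > 1e-8)
    stop("share targets must sum to 1", call. = FALSE)
  if (outlier_frac < 0 || outlier_frac > 0.2)
    stop("outlier fraction must be in [0, 0.2]", call. = FALSE)
  profiles <- profiles / rowSums(profiles)
  structure(list(n = as.integer(n), elements = elements, k = nrow(profiles),
                 profiles = profiles, shares = shares,
                 total_median = total_median, total_sigma = total_sigma,
                 dirichlet_conc = dirichlet_conc, theta = theta,
                 outlier_frac = outlier_frac,
                 outlier_multiplier = outlier_multiplier,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

# Dirichlet draw via normalized gammas
.rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              n, length(alpha))
  g / rowSums(g)
}

#' Simulate a concentration table with known ground truth
#'
#' Contributions `G` are per-sample Dirichlet mixing proportions (alpha
#' proportional to the target shares, scaled by the concentration
#' parameter) times log-normal total loads; concentrations are
#' `X = G F` perturbed cell-wise by multiplicative log-normal noise
#' `exp(eps)`, `eps ~ N(0, theta^2)`, so positivity is automatic and theta
#' plays the role of the relative standard deviation of the uncertainty
#' model. Outlier cells (1-3 elements of each flagged sample) are
#' multiplied by the configured factor afterwards. Deterministic given the
#' seed.
#'
#' @param config a [scenario_config] (default [default_scenario()]).
#' @return List with `table` (a [conc_table]) and `truth` (class
#'   `synthetic_truth`): `f_true` (k x m, rows sum to 1), `g_true`
#'   (n x k, mg/kg), `shares_true` (percent), `theta`, `outlier_mask`
#'   (n x m logical), `outlier_samples`, `seed`.
#' @export
simulate_scenario <- function(config = default_scenario()) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  n <- config$n; k <- config$k
  Ftrue <- config$profiles
  alpha <- config$dirichlet_conc * config$shares
  mix <- .rdirichlet(n, alpha)
  totals <- stats::rlnorm(n, meanlog = log(config$total_median),
                          sdlog = config$total_sigma)
  G <- mix * totals
  X <- G %*% Ftrue
  noise <- matrix(stats::rnorm(n * ncol(X), sd = config$theta), n, ncol(X))
  X <- X * exp(noise)
  mask <- matrix(FALSE, n, ncol(X))
  out_samples <- integer(0L)
  if (config$outlier_frac > 0) {
    n_out <- round(config$outlier_frac * n)
    out_samples <- sample.int(n, n_out)
    for (i in out_samples) {
      cells <- sample.int(ncol(X), sample(1:3, 1L))
      mask[i, cells] <- TRUE
      X[i, cells] <- X[i, cells] * config$outlier_multiplier
    }
  }
  ids <- sprintf("S%03d", seq_len(n))
  dimnames(mask) <- list(ids, config$elements)
  tab <- conc_table(X, sample_ids = ids, elements = config$elements)
  shares_true <- 100 * colMeans(G) / sum(colMeans(G))
  truth <- structure(list(f_true = Ftrue, g_true = G,
                          shares_true = shares_true, theta = config$theta,
                          outlier_mask = mask,
                          outlier_samples = ids[sort(out_samples)],
                          seed = config$seed),
                     class = "synthetic_truth")
  list(table = tab, truth = truth)
}

# cosine similarity between two vectors
.cosine <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(0)
  sum(a * b) / (na * nb)
}

# all permutations of 1..n (recursive; n <= 6 in practice)
.perms <- function(n) {
  if (n == 1L) return(matrix(1L))
  sub <- .perms(n - 1L)
  out <- do.call(rbind, lapply(seq_len(n), function(i)
    cbind(i, matrix(c(seq_len(n)[-i])[sub], nrow(sub)))))
  dimnames(out) <- NULL
  out
}

#' Match estimated factors to true sources and score recovery
#'
#' Finds the one-to-one factor-to-source assignment maximizing total
#' cosine similarity between profile rows (exhaustive over permutations,
#' k <= 6), then reports per-source cosine similarity and absolute share
#' errors in percentage points. When the estimate has a different number
#' of factors, the best partial matching over the smaller count is scored.
#'
#' @param f_est estimated profile matrix (factors x elements) or a result
#'   object with an `f`/`profiles` component.
#' @param shares_est estimated shares (percent; renormalized to 100 over
#'   the matched factors).
#' @param truth a `synthetic_truth`.
#' @return List with `assignment` (index of the estimated factor matched
#'   to each true source), `cosine` (per source), `mean_cosine`,
#'   `share_error` (per source, percentage points), `max_share_error`,
#'   `mean_share_error`.
#' @export
score_recovery <- function(f_est, shares_est, truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  Ft <- truth$f_true
  f_est <- as.matrix(f_est)
  if (ncol(f_est) != ncol(Ft))
    stop("element order/count mismatch", call. = FALSE)
  kt <- nrow(Ft); ke <- nrow(f_est)
  k <- min(kt, ke)
  simmat <- outer(seq_len(kt), seq_len(ke),
                  Vectorize(function(i, j) .cosine(Ft[i, ], f_est[j, ])))
  # exhaustive assignment over the larger side's permutations
  if (kt <= ke) {
    pp <- .perms(ke)
    tot <- apply(pp, 1L, function(pr)
      sum(simmat[cbind(seq_len(kt), pr[seq_len(kt)])]))
    best <- pp[which.max(tot), seq_len(kt)]
    assignment <- best
    cosines <- simmat[cbind(seq_len(kt), assignment)]
  } else {
    pp <- .perms(kt)
    tot <- apply(pp, 1L, function(pr)
      sum(simmat[cbind(pr[seq_len(ke)], seq_len(ke))]))
    bestp <- pp[which.max(tot), ]
    assignment <- rep(NA_integer_, kt)
    assignment[bestp[seq_len(ke)]] <- seq_len(ke)
    cosines <- ifelse(is.na(assignment), NA_real_,
                      simmat[cbind(seq_len(kt), assignment)])
  }
  share_err <- rep(NA_real_, kt)
  if (!is.null(shares_est)) {
    matched <- !is.na(assignment)
    se <- shares_est[assignment[matched]]
    se <- 100 * se / sum(se)
    st <- truth$shares_true[matched]
    share_err[matched] <- abs(se - st)
  }
  list(assignment = assignment,
       cosine = cosines, mean_cosine = mean(cosines, na.rm = TRUE),
       share_error = share_err,
       max_share_error = if (all(is.na(share_err))) NA_real_
         else max(share_err, na.rm = TRUE),
       mean_share_error = if (all(is.na(share_err))) NA_real_
         else mean(share_err, na.rm = TRUE))
}
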