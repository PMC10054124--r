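#' Align factors across apportionment models
#'
#' Matches factors of two or more apportionment results one-to-one by
#' maximizing the total cosine similarity between their source-profile
#' vectors (exhaustive over permutations, k <= 6). The first result is the
#' reference; every other model's factors are permuted onto it. The mean
#' matched cosine is reported as a cross-model agreement score in
#' `[0, 1]`; it equals 1 exactly when the profiles agree up to permutation
#' and positive per-factor scaling.
#'
#' @param results named list of two or more results, each either a matrix
#'   of profiles (factors x elements) or an object with an `f` or
#'   `profiles` component (`pmf_result`, `unmix_result`,
#'   `apcs_mlr_result`). All must share the same element set and order.
#' @return List of class `model_alignment`: `reference` (name),
#'   `maps` (per model: permutation onto the reference factors and the
#'   matched cosines), `agreement` (per model mean matched cosine),
#'   `overall_agreement`.
#' @export
align_models <- function(results) {
  if (length(results) < 2L) stop("need at least 2 results", call. = FALSE)
  profs <- lapply(results, .extract_profiles)
  cols <- lapply(profs, colnames)
  if (length(unique(vapply(profs, ncol, integer(1L)))) != 1L ||
      (!any(vapply(cols, is.null, logical(1L))) &&
       length(unique(lapply(cols, tolower))) != 1L))
    stop("results have differing element sets", call. = FALSE)
  nm <- names(results) %||% paste0("model", seq_along(results))
  ref <- profs[[1L]]
  maps <- list()
  agreement <- numeric(0L)
  for (i in seq_along(profs)[-1L]) {
    mt <- .match_profiles(ref, profs[[i]])
    maps[[nm[i]]] <- mt
    agreement[nm[i]] <- mean(mt$cosine, na.rm = TRUE)
  }
  structure(list(reference = nm[1L], maps = maps, agreement = agreement,
                 overall_agreement = mean(agreement)),
            class = "model_alignment")
}

.extract_profiles <- function(x) {
  if (is.matrix(x)) return(x)
  if (!is.null(x$f)) return(x$f)
  if (!is.null(x$profiles)) return(x$profiles)
  stop("cannot extract profiles from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

# match rows of B onto rows of A by maximum total cosine; exhaustive
.match_profiles <- function(A, B) {
  ka <- nrow(A); kb <- nrow(B)
  k <- min(ka, kb)
  simmat <- outer(seq_len(ka), seq_len(kb),
                  Vectorize(function(i, j) .cosine(A[i, ], B[j, ])))
  pp <- .perms(max(ka, kb))
  if (ka <= kb) {
    tot <- apply(pp, 1L, function(pr)
      sum(simmat[cbind(seq_len(ka), pr[seq_len(ka)])]))
    perm <- pp[which.max(tot), seq_len(ka)]
    cosine <- simmat[cbind(seq_len(ka), perm)]
  } else {
    tot <- apply(pp, 1L, function(pr)
      sum(simmat[cbind(pr[seq_len(kb)], seq_len(kb))]))
    bp <- pp[which.max(tot), ]
    perm <- rep(NA_integer_, ka)
    perm[bp[seq_len(kb)]] <- seq_len(kb)
    cosine <- ifelse(is.na(perm), NA_real_,
                     simmat[cbind(seq_len(ka), perm)])
  }
  list(permutation = perm, cosine = cosine)
}

#' @export
print.model_alignment <- function(x, ...) {
  cat("Factor alignment (reference:", x$reference, ")\n")
  for (nm in names(x$maps)) {
    mp <- x$maps[[nm]]
    cat(sprintf("  %s: permutation [%s], mean cosine %.3f\n", nm,
                paste(mp$permutation, collapse = ", "),
                mean(mp$cosine, na.rm = TRUE)))
  }
  cat(sprintf("Overall agreement: %.3f\n", x$overall_agreement))
  invisible(x)
}

#' Run the full source-apportionment pipeline from one configuration
#'
#' Executes any subset of the stages `describe`, `risk`, `apcs_mlr`,
#' `unmix`, `pmf` on either a CSV input pair or a synthetic scenario, then
#' aligns factors across the fitted models and assembles a cross-model
#' comparison (shares and per-element fit r-squared per model).
#'
#' @param config a named list, or the path to a YAML/JSON file holding
#'   one. Recognized fields:
#'   \describe{
#'     \item{input}{list with `samples` (CSV path), `elements`
#'       (column names), optional `refs` (CSV path), `id_column`,
#'       `covariates`; or}
#'     \item{scenario}{list of [default_scenario()] arguments (used when
#'       `input` is absent).}
#'     \item{stages}{character vector; default all five.}
#'     \item{seed}{integer, forwarded to the scenario and PMF.}
#'     \item{apcs}{list: `retention`, `rotate`.}
#'     \item{pmf}{list: `k`, plus [pmf_config()] arguments;
#'       `remove_outliers` flag.}
#'     \item{unmix}{list: `k`.}
#'   }
#' @param out_dir optional directory; when given, stage tables are written
#'   as CSVs and the comparison as JSON (requires jsonlite).
#' @return List of class `pipeline_result` with one component per
#'   executed stage, plus `comparison` (per-model shares and r2),
#'   `alignment` (when >= 2 models ran) and `provenance` (seed, stages,
#'   package version).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config)) {
      if (!requireNamespace("yaml", quietly = TRUE))
        stop("yaml package required to read YAML configs", call. = FALSE)
      yaml::read_yaml(config)
    } else {
      if (!requireNamespace("jsonlite", quietly = TRUE))
        stop("jsonlite package required to read JSON configs", call. = FALSE)
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stages <- config$stages %||% c("describe", "risk", "apcs_mlr", "unmix", "pmf")
  known <- c("describe", "risk", "apcs_mlr", "unmix", "pmf")
  if (length(setdiff(stages, known)))
    stop("unknown stage(s): ", paste(setdiff(stages, known), collapse = ", "),
         call. = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  refs <- NULL
  truth <- NULL
  if (!is.null(config$input)) {
    inp <- config$input
    table <- read_concentrations(inp$samples, inp$elements,
                                 id_column = inp$id_column,
                                 covariate_columns = inp$covariates)
    if (!is.null(inp$refs)) refs <- read_reference(inp$refs)
  } else {
    sc_args <- config$scenario %||% list()
    sc_args$seed <- sc_args$seed %||% seed
    sc <- do.call(default_scenario, sc_args)
    sim <- simulate_scenario(sc)
    table <- sim$table
    truth <- sim$truth
  }
  out <- list(table = table, truth = truth)
  if ("describe" %in% stages) {
    if (is.null(refs) && any(c("describe", "risk") %in% stages))
      refs <- refs %||% zhejiang_reference()
    out$describe <- list(summary = summarize_elements(table, refs),
                         correlations = element_correlations(table))
  }
  if ("risk" %in% stages) {
    refs <- refs %||% zhejiang_reference()
    out$risk <- risk_table(table, refs)
  }
  models <- list()
  if ("apcs_mlr" %in% stages) {
    a <- config$apcs %||% list()
    out$apcs_mlr <- apcs_mlr(table, retention = a$retention %||% "eigen",
                             rotate = a$rotate %||% "varimax")
    models$apcs_mlr <- out$apcs_mlr
  }
  if ("unmix" %in% stages) {
    u <- config$unmix %||% list()
    out$unmix <- unmix_resolve(table, k = u$k %||% "auto")
    models$unmix <- out$unmix
  }
  if ("pmf" %in% stages) {
    p <- config$pmf %||% list()
    k <- p$k %||% 4L
    cfg_args <- p[intersect(names(p), names(formals(pmf_config)))]
    cfg_args$seed <- cfg_args$seed %||% seed
    cfg <- do.call(pmf_config, cfg_args)
    U <- uncertainty(table, refs)
    if (isTRUE(p$remove_outliers)) {
      ro <- remove_outliers(table, refs, k = k, config = cfg, U = U)
      out$pmf <- ro$fit
      out$pmf_removal_log <- ro$log
    } else {
      out$pmf <- pmf_fit(table, U, k = k, config = cfg)
    }
    models$pmf <- out$pmf
  }
  out$comparison <- .comparison_table(models)
  if (length(models) >= 2L) out$alignment <- align_models(models)
  out$provenance <- list(seed = seed, stages = stages,
                         package_version =
                           as.character(utils::packageVersion("metalsource")))
  if (!is.null(out_dir)) .write_pipeline(out, out_dir)
  structure(out, class = "pipeline_result")
}

.model_shares <- function(x) {
  if (inherits(x, "pmf_result")) return(pmf_shares(x))
  if (inherits(x, "unmix_result")) return(x$shares)
  if (inherits(x, "apcs_mlr_result")) {
    s <- x$shares[setdiff(names(x$shares), "unidentified")]
    return(100 * s / sum(s))
  }
  stop("unknown model result", call. = FALSE)
}

.model_r2 <- function(x) {
  if (inherits(x, "pmf_result")) return(x$species_r2)
  if (inherits(x, "unmix_result")) return(x$r2)
  if (inherits(x, "apcs_mlr_result")) return(x$r2)
  stop("unknown model result", call. = FALSE)
}

.comparison_table <- function(models) {
  if (!length(models)) return(NULL)
  list(shares = lapply(models, .model_shares),
       r2 = lapply(models, .model_r2))
}

.write_pipeline <- function(out, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_concentrations(out$table, file.path(out_dir, "samples.csv"))
  if (!is.null(out$describe))
    utils::write.csv(out$describe$summary,
                     file.path(out_dir, "summary.csv"), row.names = FALSE)
  if (!is.null(out$risk))
    utils::write.csv(out$risk$summary,
                     file.path(out_dir, "risk_summary.csv"), row.names = FALSE)
  for (nm in c("apcs_mlr", "unmix", "pmf")) {
    if (is.null(out[[nm]])) next
    pr <- .extract_profiles(out[[nm]])
    utils::write.csv(as.data.frame(pr),
                     file.path(out_dir, paste0(nm, "_profiles.csv")))
  }
  if (!is.null(out$comparison) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(
      c(out$comparison, list(provenance = out$provenance)),
      file.path(out_dir, "comparison.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(NULL)
}

#' Built-in reference table for the Zhejiang farmland setting
#'
#' Per-element Zhejiang-province soil background values, GB 15618-2018
#' agricultural screening values (pH < 5.5 band where applicable), and the
#' conventional Hakanson toxic-response coefficients
#' (Zn 1, Cr 2, Cu/Ni/Pb 5, Cd 30) for Cu, Zn, Pb, Cd, Cr and Ni. MDL and
#' theta are left `NA` so the uncertainty model applies its documented
#' defaults.
#'
#' @return A [ref_table].
#' @export
zhejiang_reference <- function() {
  ref_table(data.frame(
    element = c("Cu", "Zn", "Pb", "Cd", "Cr", "Ni"),
    background = c(17.6, 70.6, 23.7, 0.07, 52.9, 24.60),
    screening = c(50, 200, 80, 0.30, 250, 60),
    toxicity = c(5, 1, 5, 30, 2, 5)))
}
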