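# small builders shared across test files

tiny_table <- function(values = NULL, ids = NULL) {
  if (is.null(values))
    values <- matrix(c(1, 2, 3, 2, 4, 6), ncol = 2,
                     dimnames = list(NULL, c("Cu", "Zn")))
  conc_table(values, sample_ids = ids)
}

tiny_refs <- function() {
  ref_table(data.frame(
    element = c("Cu", "Zn"),
    background = c(17.6, 70.6),
    screening = c(50, 200),
    toxicity = c(5, 1),
    mdl = c(0.5, 1),
    theta = c(0.1, 0.1)))
}

# independent recursive permutation enumerator (oracle; deliberately coded
# differently from the package's matcher)
oracle_perms <- function(n) {
  if (n == 0L) return(list(integer(0L)))
  out <- list()
  for (p in oracle_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# brute-force best assignment of estimate rows to truth rows by total cosine
oracle_best_assignment <- function(Ft, Fe) {
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  k <- nrow(Ft)
  best <- NULL; best_tot <- -Inf
  for (p in oracle_perms(k)) {
    tot <- sum(vapply(seq_len(k), function(i) cosv(Ft[i, ], Fe[p[i], ]),
                      numeric(1L)))
    if (tot > best_tot) { best_tot <- tot; best <- p }
  }
  list(perm = best, total = best_tot)
}

write_csv_fixture <- function(df) {
  f <- tempfile(fileext = ".csv")
  utils::write.csv(df, f, row.names = FALSE)
  f
}
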