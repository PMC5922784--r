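# Shared fixture builders. All randomness is seeded by the caller.

rand_simplex <- function(n, conc = 1) {
  g <- stats::rgamma(n, shape = conc)
  g / sum(g)
}

# A random valid confusion model with generic family ids (EXTRA last).
rand_model <- function(N, M) {
  aligned <- sprintf("a%02d", seq_len(N))
  existing <- c(sprintf("c%02d", seq_len(M - 1L)), "EXTRA")
  alpha <- matrix(0, N, M, dimnames = list(aligned, existing))
  for (j in seq_len(M)) alpha[, j] <- rand_simplex(N)
  beta <- rand_simplex(M)
  names(beta) <- existing
  confusion_model(alpha, beta, family_universe(aligned, existing))
}

# Random positive count vector over a model's aligned families.
rand_counts <- function(model, total = 1000L) {
  p <- as.vector(model$alpha %*% model$beta)
  y <- as.integer(stats::rmultinom(1L, total, p))
  names(y) <- rownames(model$alpha)
  y
}

# One BLAST tabular line with the given key fields.
blast_line <- function(read, subject, bit, evalue = 1e-10, pid = 95, len = 33) {
  sprintf(
    "%s\t%s\t%.1f\t%d\t0\t0\t1\t99\t10\t42\t%g\t%.1f",
    read, subject, pid, len, evalue, bit
  )
}

write_lines_tmp <- function(lines) {
  tf <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, tf)
  tf
}
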