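#' Profile-accuracy measurements
#'
#' Compares a fitted origin-proportion vector to the true one with the
#' four standard measurements, each summed over the real existing families
#' only — the reserved `EXTRA` family (last index) is excluded, since its
#' "true" proportion aggregates unclassified and non-coding sequence:
#' \describe{
#'   \item{RRMSE}{root relative mean square error,
#'     `sqrt(mean(((bh - b) / b)^2))`;}
#'   \item{AVGRE}{average relative error, `mean(|bh - b| / b)`;}
#'   \item{MAXRE}{maximum relative error, `max(|bh - b| / b)`;}
#'   \item{DTV}{total variation distance, `sum(|bh - b|) / 2`.}
#' }
#' Lower is more accurate; all four are zero iff the vectors agree on the
#' real families.
#'
#' @param beta_hat Estimated length-M probability vector (EXTRA last).
#' @param beta_true True length-M probability vector in the same family
#'   order; must be strictly positive on the first M-1 entries (relative
#'   errors are undefined at zero).
#' @return An object of class `accuracy_report`: list with `rrmse`,
#'   `avgre`, `maxre`, `dtv`.
#' @examples
#' profile_accuracy(c(0.6, 0.4), c(0.5, 0.5)) # MAXRE 0.2, DTV 0.05
#' @export
profile_accuracy <- function(beta_hat, beta_true) {
  beta_hat <- as.numeric(beta_hat)
  beta_true <- as.numeric(beta_true)
  if (length(beta_hat) != length(beta_true)) {
    stop("proportion vectors differ in length", call. = FALSE)
  }
  M <- length(beta_true)
  if (M < 2L) {
    stop("need at least two families (one real family plus EXTRA)", call. = FALSE)
  }
  idx <- seq_len(M - 1L)
  zero <- beta_true[idx] == 0
  if (any(zero)) {
    stop(
      "true proportion is zero for family index(es): ",
      paste(idx[zero], collapse = ", "),
      "; relative errors are undefined",
      call. = FALSE
    )
  }
  rel <- (beta_hat[idx] - beta_true[idx]) / beta_true[idx]
  structure(
    list(
      rrmse = sqrt(mean(rel^2)),
      avgre = mean(abs(rel)),
      maxre = max(abs(rel)),
      dtv = sum(abs(beta_hat[idx] - beta_true[idx])) / 2
    ),
    class = "accuracy_report"
  )
}

#' @export
print.accuracy_report <- function(x, digits = 4, ...) {
  cat(sprintf(
    "RRMSE %.*g  AVGRE %.*g  MAXRE %.*g  DTV %.*g\n",
    digits, x$rrmse, digits, x$avgre, digits, x$maxre, digits, x$dtv
  ))
  invisible(x)
}

#' Cross-annotation accounting per family
#'
#' Given, for each family, the number of reads truly originating from it,
#' the number best-hit assigned to it, and the number both originating
#' from and assigned to it, computes the two sides of cross-annotation:
#' `misassigned_in = assigned - correct` (reads credited to the family
#' that belong elsewhere) and `misassigned_out = true - correct` (reads
#' from the family credited elsewhere). A `TOTAL` row is appended.
#'
#' @param rows Data frame with columns `family_id`, `true_count`,
#'   `assigned_count`, `correct_count` (non-negative; `correct_count`
#'   cannot exceed either of the other two).
#' @return Data frame with the input columns plus `misassigned_in` and
#'   `misassigned_out`, and a final `TOTAL` row.
#' @export
cross_annotation_summary <- function(rows) {
  need <- c("family_id", "true_count", "assigned_count", "correct_count")
  if (!is.data.frame(rows) || !all(need %in% names(rows))) {
    stop(
      "rows must be a data frame with columns ",
      paste(need, collapse = ", "),
      call. = FALSE
    )
  }
  with(rows, {
    if (any(true_count < 0 | assigned_count < 0 | correct_count < 0)) {
      stop("counts must be non-negative", call. = FALSE)
    }
    bad <- correct_count > true_count | correct_count > assigned_count
    if (any(bad)) {
      stop(
        "correct_count exceeds true or assigned count for: ",
        paste(family_id[bad], collapse = ", "),
        call. = FALSE
      )
    }
  })
  out <- rows[, need]
  out$misassigned_in <- out$assigned_count - out$correct_count
  out$misassigned_out <- out$true_count - out$correct_count
  total <- data.frame(
    family_id = "TOTAL",
    true_count = sum(out$true_count),
    assigned_count = sum(out$assigned_count),
    correct_count = sum(out$correct_count),
    misassigned_in = sum(out$misassigned_in),
    misassigned_out = sum(out$misassigned_out),
    stringsAsFactors = FALSE
  )
  rbind(out, total)
}

#' Write an accuracy report as TSV
#'
#' @param report An `accuracy_report` from [profile_accuracy()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_accuracy_report <- function(report, path) {
  stopifnot(inherits(report, "accuracy_report"))
  df <- data.frame(
    measure = c("RRMSE", "AVGRE", "MAXRE", "DTV"),
    value = c(report$rrmse, report$avgre, report$maxre, report$dtv)
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}
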