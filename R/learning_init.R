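#' Estimate learning-sample confusion and origin distributions
#'
#' From a labeled learning sample — a joint (origin family x aligned
#' family) read-count matrix — estimates the two empirical conditional
#' distributions used to initialize the EM:
#' \describe{
#'   \item{`alpha_L[i, j]`}{the fraction of reads originating from origin
#'     family `j` that were aligned to family `i` (columns sum to 1 over
#'     the learning sample's aligned families);}
#'   \item{`gamma_L[j, i]`}{the fraction of reads aligned to family `i`
#'     that originated from family `j` (columns sum to 1 over origins).}
#' }
#' Origins with zero total reads are dropped from `alpha_L`; aligned
#' families with zero total reads are dropped from `gamma_L`.
#'
#' @param joint Non-negative integer matrix, rows = origin families,
#'   columns = aligned families, both dimensions named. See
#'   [read_joint_counts()].
#' @return An object of class `learned_priors` with elements `alpha_L`
#'   (aligned x origin), `gamma_L` (origin x aligned),
#'   `learning_aligned_ids` and `learning_origin_ids` (the full id lists of
#'   the learning sample).
#' @export
estimate_learning_distributions <- function(joint) {
  stopifnot(is.matrix(joint), !is.null(rownames(joint)), !is.null(colnames(joint)))
  if (any(joint < 0)) {
    stop("joint count matrix has negative entries", call. = FALSE)
  }
  if (sum(joint) == 0) {
    stop("joint count matrix is all zero; cannot estimate learning distributions",
      call. = FALSE
    )
  }
  origin_tot <- rowSums(joint)
  aligned_tot <- colSums(joint)
  alpha_L <- t(joint[origin_tot > 0, , drop = FALSE] / origin_tot[origin_tot > 0])
  gamma_L <- sweep(
    joint[, aligned_tot > 0, drop = FALSE], 2L,
    aligned_tot[aligned_tot > 0], "/"
  )
  structure(
    list(
      alpha_L = alpha_L, gamma_L = gamma_L,
      learning_aligned_ids = colnames(joint),
      learning_origin_ids = rownames(joint)
    ),
    class = "learned_priors"
  )
}

#' Assemble the initial confusion matrix for a new sample
#'
#' For each estimated existing family of the new sample:
#' \itemize{
#'   \item if the family was an origin in the learning sample, aligned
#'     families present in both samples copy the learned conditional
#'     probability `alpha_L`; aligned families present only in the new
#'     sample share the remaining probability mass
#'     `1 - sum(alpha_L over the shared aligned families)` equally;
#'   \item otherwise (the family — possibly `EXTRA` — was absent from the
#'     learning sample) every aligned family receives the uniform value
#'     `1/N`.
#' }
#' Each column is floored at `eps` and renormalized to sum to exactly 1.
#' The floor prevents exact zeros, which the EM's multiplicative updates
#' could never leave.
#'
#' @param priors A `learned_priors` object.
#' @param universe The new sample's [family_universe()].
#' @param eps Probability floor applied entrywise before renormalization.
#' @return An N x M column-stochastic matrix with `rownames =
#'   universe$aligned_ids`, `colnames = universe$existing_ids`.
#' @export
initialize_alpha <- function(priors, universe, eps = 1e-12) {
  stopifnot(inherits(priors, "learned_priors"), inherits(universe, "family_universe"))
  aligned <- universe$aligned_ids
  existing <- universe$existing_ids
  N <- length(aligned)
  alpha0 <- matrix(0, N, length(existing), dimnames = list(aligned, existing))
  known_origins <- colnames(priors$alpha_L)
  shared_aligned <- intersect(aligned, rownames(priors$alpha_L))
  new_only <- setdiff(aligned, rownames(priors$alpha_L))
  for (j in existing) {
    if (j %in% known_origins) {
      col <- numeric(N)
      names(col) <- aligned
      col[shared_aligned] <- priors$alpha_L[shared_aligned, j]
      if (length(new_only)) {
        remaining <- max(0, 1 - sum(col[shared_aligned]))
        col[new_only] <- remaining / length(new_only)
      }
      # learning-only aligned families can leave the column short of 1;
      # the closing renormalization absorbs that mass
      alpha0[, j] <- col
    } else {
      alpha0[, j] <- 1 / N
    }
  }
  alpha0 <- pmax(alpha0, eps)
  sweep(alpha0, 2L, colSums(alpha0), "/")
}

#' Assemble the initial origin proportions for a new sample
#'
#' For an existing family `j` also present as an origin in the learning
#' sample, the starting proportion is the learned origin mass of the new
#' sample's reads: `sum over shared aligned families i of
#' gamma_L[j, i] * y[i] / sum(y)`. Existing families absent from the
#' learning sample share the remaining probability equally. The vector is
#' floored at `eps` and renormalized to sum to exactly 1.
#'
#' @param priors A `learned_priors` object.
#' @param counts Named count vector over the new sample's aligned families.
#' @param universe The new sample's [family_universe()].
#' @param eps Probability floor.
#' @return Named length-M probability vector over
#'   `universe$existing_ids`.
#' @export
initialize_beta <- function(priors, counts, universe, eps = 1e-12) {
  stopifnot(inherits(priors, "learned_priors"), inherits(universe, "family_universe"))
  y <- align_counts(counts, universe$aligned_ids)
  total <- sum(y)
  if (total <= 0) {
    stop("count vector sums to zero; cannot initialize origin proportions",
      call. = FALSE
    )
  }
  existing <- universe$existing_ids
  beta0 <- numeric(length(existing))
  names(beta0) <- existing
  known <- intersect(existing, rownames(priors$gamma_L))
  shared_aligned <- intersect(universe$aligned_ids, colnames(priors$gamma_L))
  for (j in known) {
    beta0[j] <- sum(priors$gamma_L[j, shared_aligned] * y[shared_aligned]) / total
  }
  new_only <- setdiff(existing, known)
  if (length(new_only)) {
    beta0[new_only] <- max(0, 1 - sum(beta0[known])) / length(new_only)
  }
  beta0 <- pmax(beta0, eps)
  beta0 / sum(beta0)
}

# Reorder a named count vector onto a reference id list, erroring on
# missing families; ids not in the reference are an error too (counts must
# describe exactly the aligned universe).
align_counts <- function(counts, aligned_ids) {
  if (is.null(names(counts))) {
    if (length(counts) != length(aligned_ids)) {
      stop("unnamed count vector length does not match aligned families",
        call. = FALSE
      )
    }
    return(structure(as.numeric(counts), names = aligned_ids))
  }
  missing <- setdiff(aligned_ids, names(counts))
  if (length(missing)) {
    stop(
      "count vector missing aligned families: ",
      paste(utils::head(missing, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  extra <- setdiff(names(counts), aligned_ids)
  if (length(extra)) {
    stop(
      "count vector has families outside the aligned universe: ",
      paste(utils::head(extra, 5L), collapse = ", "),
      call. = FALSE
    )
  }
  structure(as.numeric(counts[aligned_ids]), names = aligned_ids)
}
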