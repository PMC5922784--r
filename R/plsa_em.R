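#' Confusion model: cross-annotation parameters
#'
#' The PLSA parameterization of cross-annotation. `alpha[i, j]` is the
#' probability that a read originating from existing family `j` is aligned
#' (best-hit assigned) to family `i`; every column lies on the simplex.
#' `beta[j]` is the probability that an aligned read originates from
#' family `j`; `beta` lies on the simplex. The observed count for aligned
#' family `i` then has expectation `total * sum_j alpha[i, j] * beta[j]`.
#'
#' @param alpha N x M numeric matrix of conditional alignment
#'   probabilities; columns must each sum to 1 (tolerance 1e-9).
#' @param beta Length-M probability vector summing to 1 (tolerance 1e-9).
#' @param universe Optional [family_universe()]; when supplied, dimnames
#'   of `alpha`/`beta` are set from it.
#' @return An object of class `confusion_model`.
#' @export
confusion_model <- function(alpha, beta, universe = NULL) {
  alpha <- as.matrix(alpha)
  beta <- as.numeric(beta)
  if (ncol(alpha) != length(beta)) {
    stop("alpha has ", ncol(alpha), " columns but beta has length ", length(beta),
      call. = FALSE
    )
  }
  if (!is.null(universe)) {
    stopifnot(inherits(universe, "family_universe"))
    if (nrow(alpha) != length(universe$aligned_ids) ||
      ncol(alpha) != length(universe$existing_ids)) {
      stop("alpha dimensions do not match the family universe", call. = FALSE)
    }
    dimnames(alpha) <- list(universe$aligned_ids, universe$existing_ids)
    names(beta) <- universe$existing_ids
  }
  if (any(alpha < 0) || any(alpha > 1) || any(beta < 0) || any(beta > 1)) {
    stop("confusion model parameters must lie in [0, 1]", call. = FALSE)
  }
  if (any(abs(colSums(alpha) - 1) > 1e-9)) {
    stop("every column of alpha must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  if (abs(sum(beta) - 1) > 1e-9) {
    stop("beta must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  structure(
    list(alpha = alpha, beta = beta, universe = universe),
    class = "confusion_model"
  )
}

#' @export
print.confusion_model <- function(x, ...) {
  cat(
    "confusion_model:", nrow(x$alpha), "aligned x", ncol(x$alpha),
    "existing families\n"
  )
  invisible(x)
}

#' E step: expected read allocation under the current parameters
#'
#' For each aligned family `i`, Bayes' rule gives the posterior probability
#' that one of its reads originates from existing family `j`:
#' `alpha[i, j] * beta[j] / sum_s alpha[i, s] * beta[s]`. Multiplying by
#' the observed count `y[i]` yields the expected allocation matrix
#' `phi[i, j]` and its column sums `psi[j]`, which carry the whole
#' conditional law of the latent origins — individual reads are never
#' materialized.
#'
#' @param model A [confusion_model()].
#' @param y Named count vector over the model's aligned families (or an
#'   unnamed vector of matching length).
#' @return An object of class `em_workspace` with `phi` (N x M), `psi`
#'   (length M) and the aligned `y`.
#' @details An aligned family with a positive count but zero marginal
#'   probability under the current parameters is an error: no origin can
#'   reach it, which signals a defective initialization.
#' @export
e_step <- function(model, y) {
  stopifnot(inherits(model, "confusion_model"))
  y <- align_to_model(model, y)
  marg <- as.vector(model$alpha %*% model$beta)
  dead <- y > 0 & marg <= 0
  if (any(dead)) {
    stop(
      "aligned family unreachable under current parameters: ",
      paste(utils::head(rownames(model$alpha)[dead], 5L), collapse = ", "),
      call. = FALSE
    )
  }
  scale <- ifelse(y > 0, y / marg, 0)
  phi <- model$alpha * outer(scale, model$beta)
  dimnames(phi) <- dimnames(model$alpha)
  structure(
    list(phi = phi, psi = colSums(phi), y = y),
    class = "em_workspace"
  )
}

#' M step: closed-form parameter update
#'
#' Maximizes the expected complete-data log-likelihood under the simplex
#' constraints: `alpha'[i, j] = phi[i, j] / psi[j]` and
#' `beta'[j] = psi[j] / sum(y)`. A column whose expected allocation `psi[j]`
#' is zero (family `j` currently explains no reads) keeps its previous
#' alpha column and receives a vanishing `beta` entry, after which `beta`
#' is renormalized; without this the update would divide by zero.
#'
#' @param workspace An `em_workspace` from [e_step()].
#' @param prev_alpha Previous alpha matrix; required only when some
#'   `psi[j] == 0`.
#' @return List with elements `alpha` and `beta` satisfying the
#'   [confusion_model()] constraints.
#' @export
m_step <- function(workspace, prev_alpha = NULL) {
  stopifnot(inherits(workspace, "em_workspace"))
  psi <- workspace$psi
  total <- sum(psi)
  if (total <= 0) {
    stop("all expected allocations are zero; cannot update parameters",
      call. = FALSE
    )
  }
  zero <- psi <= 0
  alpha <- workspace$phi
  alpha[, !zero] <- sweep(workspace$phi[, !zero, drop = FALSE], 2L, psi[!zero], "/")
  beta <- psi / total
  if (any(zero)) {
    if (is.null(prev_alpha)) {
      stop("psi has zero entries and no previous alpha was supplied", call. = FALSE)
    }
    alpha[, zero] <- prev_alpha[, zero]
    beta[zero] <- 1e-12
    beta <- beta / sum(beta)
  }
  list(alpha = alpha, beta = beta)
}

#' Observed-data log-likelihood
#'
#' The marginal (incomplete-data) log-likelihood of the fitted mixture:
#' `sum_i y[i] * log(sum_j alpha[i, j] * beta[j])`, in nats. This is the
#' objective the EM iterations monotonically increase.
#'
#' @param model A [confusion_model()].
#' @param y Count vector over the aligned families.
#' @return A finite scalar, or `-Inf` (with a warning) when some family
#'   carries reads but has zero marginal probability.
#' @export
observed_log_likelihood <- function(model, y) {
  stopifnot(inherits(model, "confusion_model"))
  y <- align_to_model(model, y)
  marg <- as.vector(model$alpha %*% model$beta)
  pos <- y > 0
  if (any(pos & marg <= 0)) {
    warning("zero marginal probability for a family with positive count; log-likelihood is -Inf")
    return(-Inf)
  }
  sum(y[pos] * log(marg[pos]))
}

#' Fit the PLSA cross-annotation model by EM
#'
#' Alternates [e_step()] and [m_step()] from the supplied starting values
#' until the largest absolute change across all parameters (every alpha
#' entry and every beta entry) falls below `tol`, or `max_iter` iterations
#' are reached. The observed-data log-likelihood is recorded each
#' iteration; by the EM guarantee the trace is non-decreasing.
#'
#' @param alpha0 Starting N x M column-stochastic matrix (e.g. from
#'   [initialize_alpha()]).
#' @param beta0 Starting length-M probability vector (e.g. from
#'   [initialize_beta()]).
#' @param y Count vector over the aligned families.
#' @param tol Convergence threshold on the maximum absolute parameter
#'   change per iteration; default `1e-6`.
#' @param max_iter Iteration cap; default 1000.
#' @param fix_alpha Keep the confusion matrix fixed at `alpha0` and update
#'   only `beta`. With alpha fixed the log-likelihood is concave in beta,
#'   so the fit reaches the unique conditional maximizer; useful when the
#'   confusion structure is trusted from a learning sample.
#' @param universe Optional [family_universe()] attached to the fitted
#'   model.
#' @param verbose Log one line per iteration (iteration, log-likelihood,
#'   max parameter change) via [message()].
#' @return An object of class `em_result`: `model` (fitted
#'   [confusion_model()]), `loglik_trace`, `iterations`, `converged`.
#' @examples
#' y <- c(a = 30, b = 70)
#' fit <- fit_plsa(diag(2), c(0.5, 0.5), y)
#' fit$model$beta # exactly y / sum(y)
#' @export
fit_plsa <- function(alpha0, beta0, y, tol = 1e-6, max_iter = 1000L,
                     fix_alpha = FALSE, universe = NULL, verbose = FALSE) {
  stopifnot(tol > 0, max_iter >= 1L)
  model <- confusion_model(alpha0, beta0, universe)
  if (is.null(rownames(model$alpha)) && !is.null(names(y)) &&
    length(y) == nrow(model$alpha)) {
    dimnames(model$alpha) <- list(names(y), colnames(model$alpha))
  }
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (k in seq_len(max_iter)) {
    iter <- k
    ws <- e_step(model, y)
    upd <- m_step(ws, prev_alpha = model$alpha)
    if (fix_alpha) upd$alpha <- model$alpha
    delta <- max(abs(upd$alpha - model$alpha), abs(upd$beta - model$beta))
    model$alpha <- upd$alpha
    model$beta <- upd$beta
    trace[k] <- observed_log_likelihood(model, ws$y)
    if (verbose) {
      message(sprintf("iter %4d  loglik %.6f  max-change %.3e", k, trace[k], delta))
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(
      model = model, loglik_trace = trace, iterations = iter,
      converged = converged
    ),
    class = "em_result"
  )
}

#' @export
print.em_result <- function(x, ...) {
  cat(
    "em_result:", x$iterations, "iterations,",
    if (x$converged) "converged," else "NOT converged,",
    "loglik", format(utils::tail(x$loglik_trace, 1L)), "\n"
  )
  invisible(x)
}

#' Corrected functional profile from a fitted model
#'
#' The fitted origin proportions serve as the corrected profile; the
#' corrected read count for existing family `j` is the total observed
#' count times `beta_hat[j]`, rounded half away from zero. The rounded
#' counts need not sum exactly to the observed total (the decomposition is
#' approximate by construction); the discrepancy is at most M/2.
#'
#' @param result An `em_result` from [fit_plsa()].
#' @param y The count vector the model was fitted to.
#' @return An object of class `profile_estimate` with `existing_ids`,
#'   `beta_hat`, `count_hat` and `total_reads`.
#' @export
corrected_profile <- function(result, y) {
  stopifnot(inherits(result, "em_result"))
  total <- sum(y)
  beta_hat <- result$model$beta
  ids <- colnames(result$model$alpha)
  if (is.null(ids)) ids <- paste0("c", seq_along(beta_hat))
  profile_estimate(
    existing_ids = ids, beta_hat = as.numeric(beta_hat),
    count_hat = round_half_away(total * beta_hat), total_reads = total
  )
}

#' Construct a profile estimate
#'
#' @param existing_ids Character vector of M existing family ids.
#' @param beta_hat Length-M fitted origin proportions.
#' @param count_hat Length-M rounded corrected counts.
#' @param total_reads Total observed read count.
#' @return An object of class `profile_estimate`.
#' @export
profile_estimate <- function(existing_ids, beta_hat, count_hat, total_reads) {
  stopifnot(
    length(existing_ids) == length(beta_hat),
    length(beta_hat) == length(count_hat)
  )
  structure(
    list(
      existing_ids = as.character(existing_ids),
      beta_hat = as.numeric(beta_hat),
      count_hat = as.integer(round(count_hat)),
      total_reads = as.numeric(total_reads)
    ),
    class = "profile_estimate"
  )
}

#' @export
print.profile_estimate <- function(x, ...) {
  cat(
    "profile_estimate:", length(x$existing_ids), "existing families,",
    x$total_reads, "reads\n"
  )
  df <- data.frame(
    family_id = x$existing_ids, beta_hat = x$beta_hat,
    count_hat = x$count_hat
  )
  print(utils::head(df, 10L), row.names = FALSE)
  if (nrow(df) > 10L) cat("...", nrow(df) - 10L, "more rows\n")
  invisible(x)
}

# round() in R rounds half to even; counts use half away from zero
round_half_away <- function(x) {
  floor(abs(x) + 0.5) * sign(x)
}

align_to_model <- function(model, y) {
  ids <- rownames(model$alpha)
  if (is.null(ids) || is.null(names(y))) {
    if (length(y) != nrow(model$alpha)) {
      stop("count vector length does not match the model's aligned families",
        call. = FALSE
      )
    }
    return(as.numeric(y))
  }
  align_counts(y, ids)
}
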