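#' Configuration for synthetic cross-annotation simulations
#'
#' @param n_existing M, the number of existing families including the
#'   reserved `EXTRA` family; must satisfy `M <= N + 1`.
#' @param n_aligned N, the number of aligned families.
#' @param total_reads Number of reads to draw per sample.
#' @param concentration Dirichlet sharpness for the confusion-matrix
#'   columns and the origin proportions; larger values concentrate draws
#'   around their expectation.
#' @param cross_rate Expected probability mass a real family's reads place
#'   on aligned families other than its own (`[0, 1)`); 0 means no
#'   cross-annotation.
#' @param seed Integer seed; all draws are reproducible given the seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_existing, n_aligned, total_reads,
                              concentration = 50, cross_rate = 0.2,
                              seed = 1L) {
  stopifnot(
    n_existing >= 2L, n_aligned >= 1L, n_existing <= n_aligned + 1L,
    total_reads >= 1, concentration > 0,
    cross_rate >= 0, cross_rate < 1
  )
  structure(
    list(
      n_existing = as.integer(n_existing), n_aligned = as.integer(n_aligned),
      total_reads = as.integer(total_reads), concentration = concentration,
      cross_rate = cross_rate, seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

# Dirichlet draw via normalized gammas; a zero shape yields a structural
# zero in that coordinate (used for cross_rate = 0).
rdirichlet1 <- function(shape) {
  g <- stats::rgamma(length(shape), shape = shape, rate = 1)
  if (sum(g) == 0) {
    # all-shape-zero cannot happen for valid configs; guard for fp underflow
    g <- shape
  }
  g / sum(g)
}

#' Draw a ground-truth confusion model
#'
#' Each real existing family `j` is paired with a "self" aligned family
#' (the j-th aligned id); its confusion column is a Dirichlet draw whose
#' mean places `1 - cross_rate` on the self family and spreads the rest
#' uniformly over the other aligned families. The `EXTRA` family has no
#' self target: its column is a symmetric Dirichlet draw (mean uniform),
#' reflecting that unclassified and non-coding reads scatter broadly. The
#' origin proportions are a symmetric Dirichlet draw over the M existing
#' families.
#'
#' @param config A [simulation_config()].
#' @return A [confusion_model()] with a [family_universe()] of ids
#'   `FAM0001...` and existing ids the first `M - 1` aligned ids plus
#'   `EXTRA`. Deterministic given `config$seed`.
#' @export
sample_truth <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  N <- config$n_aligned
  M <- config$n_existing
  conc <- config$concentration
  aligned <- sprintf("FAM%04d", seq_len(N))
  existing <- c(aligned[seq_len(M - 1L)], "EXTRA")
  alpha <- matrix(0, N, M, dimnames = list(aligned, existing))
  for (j in seq_len(M - 1L)) {
    shape <- if (N == 1L) {
      conc
    } else {
      s <- rep(conc * config$cross_rate / (N - 1L), N)
      s[j] <- conc * (1 - config$cross_rate)
      s
    }
    alpha[, j] <- rdirichlet1(shape)
  }
  alpha[, M] <- rdirichlet1(rep(conc / N, N))
  beta <- rdirichlet1(rep(conc / M, M))
  names(beta) <- existing
  confusion_model(alpha, beta, family_universe(aligned, existing))
}

#' Sample read counts from a confusion model
#'
#' Draws `total_reads` reads from the joint law
#' `P(aligned = i, origin = j) = alpha[i, j] * beta[j]` by a single
#' multinomial draw over all (aligned, origin) cells. With
#' `labeled = TRUE` the full joint (origin x aligned) count matrix is
#' returned — a learning sample; with `labeled = FALSE` only the aligned
#' marginal count vector is returned, exactly the marginal of the labeled
#' draw the same seed would produce.
#'
#' @param model A [confusion_model()].
#' @param total_reads Number of reads (0 gives all-zero counts).
#' @param seed Integer seed.
#' @param labeled Return the joint matrix (`TRUE`) or the aligned marginal
#'   vector (`FALSE`, default).
#' @return Either an origin x aligned integer matrix or a named integer
#'   count vector over the aligned families.
#' @export
simulate_counts <- function(model, total_reads, seed, labeled = FALSE) {
  stopifnot(inherits(model, "confusion_model"), total_reads >= 0)
  set.seed(as.integer(seed))
  N <- nrow(model$alpha)
  M <- ncol(model$alpha)
  p <- as.vector(model$alpha * rep(model$beta, each = N))
  cells <- if (total_reads == 0) {
    rep(0L, N * M)
  } else {
    as.integer(stats::rmultinom(1L, size = total_reads, prob = p))
  }
  joint_aligned_by_origin <- matrix(cells, N, M, dimnames = dimnames(model$alpha))
  if (labeled) {
    t(joint_aligned_by_origin)
  } else {
    structure(as.integer(rowSums(joint_aligned_by_origin)),
      names = rownames(model$alpha)
    )
  }
}

#' Decide the true family annotation of a simulated read placement
#'
#' Applies the truth-labeling rule for simulated reads: a read whose
#' best placement on the reference has identity greater than
#' `min_identity` percent is labeled with the family of a coding-sequence
#' interval its location overlaps by at least `min_overlap` bases;
#' otherwise it has no truth label. Coordinates are 0-based half-open;
#' the overlap is the length of the interval intersection.
#'
#' When CDS intervals from different families both satisfy the rule, the
#' larger overlap wins; an exact tie between different families is an
#' error flagged for review.
#'
#' @param placement List with `start`, `end` (read location, 0-based
#'   half-open), `identity` (percent, 0-100) and `cds` — a data frame with
#'   columns `family_id`, `start`, `end`.
#' @param min_overlap Minimum overlap in bases (inclusive); default 60.
#' @param min_identity Identity threshold in percent (strict `>`);
#'   default 95.
#' @return The family id, or `NA_character_` when no rule applies.
#' @examples
#' p <- list(
#'   start = 100, end = 200, identity = 98,
#'   cds = data.frame(family_id = "F", start = 120, end = 400)
#' )
#' label_read_truth(p) # overlap 80 >= 60 -> "F"
#' @export
label_read_truth <- function(placement, min_overlap = 60, min_identity = 95) {
  stopifnot(
    min_overlap >= 1, min_identity >= 0, min_identity <= 100,
    placement$end > placement$start
  )
  if (placement$identity <= min_identity) {
    return(NA_character_)
  }
  cds <- placement$cds
  if (is.null(cds) || nrow(cds) == 0L) {
    return(NA_character_)
  }
  ov <- pmin(placement$end, cds$end) - pmax(placement$start, cds$start)
  ok <- ov >= min_overlap
  if (!any(ok)) {
    return(NA_character_)
  }
  best <- max(ov[ok])
  winners <- unique(cds$family_id[ok & ov == best])
  if (length(winners) > 1L) {
    stop(
      "ambiguous truth label: equal best overlap (", best, " bases) for families ",
      paste(winners, collapse = ", "),
      call. = FALSE
    )
  }
  winners
}
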