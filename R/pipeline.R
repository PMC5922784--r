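#' Run the full cross-annotation correction pipeline
#'
#' Wires the whole workflow together: parse the BLAST tabular alignments,
#' apply the score-cutoff best-hit assignment, tally per-family counts,
#' flag artificial families from the RPS-BLAST alignments, build the
#' family universe (non-artificial families plus `EXTRA`), set EM starting
#' values from the learning sample, fit the PLSA model, and write the
#' corrected profile and reports to `out_dir`.
#'
#' Without a learning sample the pipeline falls back (with a warning) to a
#' neutral initialization: uniform confusion columns, and starting origin
#' proportions taken from the observed counts of each real existing
#' family, with `EXTRA` starting at the share of reads assigned to
#' artificial families.
#'
#' @param blast Path to the BLAST tabular alignments of the sample, or
#'   `NULL` when `counts` is given instead.
#' @param family_map Path to the subject-to-family map TSV (required with
#'   `blast`).
#' @param counts Path to a pre-tallied per-family count TSV (see
#'   [read_count_vector()]); alternative entry point that skips parsing
#'   and best-hit assignment.
#' @param rps_counts Path to a pre-tallied RPS-BLAST count TSV used for
#'   artificial-family flagging with the `counts` entry point.
#' @param out_dir Output directory (created if needed). Files written:
#'   `corrected_profile.tsv`, `em_trace.tsv`, and when `truth` is given,
#'   `accuracy_report.tsv`.
#' @param rps Optional path to RPS-BLAST tabular alignments for
#'   artificial-family flagging; when `NULL` no family is flagged.
#' @param rps_family_map Optional separate map for RPS subject ids;
#'   defaults to `family_map`.
#' @param learning Optional path to the learning sample's joint count TSV
#'   (see [read_joint_counts()]).
#' @param truth Optional path to a TSV of true proportions over the
#'   existing families (columns `family_id`, `beta`); enables the
#'   accuracy report.
#' @param score_cutoff,rps_cutoff Bit-score cutoffs (strict `>`) for the
#'   BLAST and RPS-BLAST filters; defaults 66 and 61.
#' @param filter_mode,evalue_cutoff Alternative e-value filtering for the
#'   BLAST alignments; see [assign_best_hit()].
#' @param tol,max_iter EM convergence controls; see [fit_plsa()].
#' @param verbose Log pipeline stages and one line per EM iteration.
#' @return Invisibly, a list with `profile`, `fit`, `universe`, `counts`,
#'   `artificial` and (when truth was supplied) `accuracy`.
#' @export
run_correction <- function(blast = NULL, family_map = NULL, out_dir,
                           counts = NULL, rps = NULL, rps_family_map = NULL,
                           rps_counts = NULL,
                           learning = NULL, truth = NULL,
                           score_cutoff = 66, rps_cutoff = 61,
                           filter_mode = c("bitscore", "evalue"),
                           evalue_cutoff = 1e-3,
                           tol = 1e-6, max_iter = 1000L,
                           verbose = FALSE) {
  filter_mode <- match.arg(filter_mode)
  say <- function(...) if (verbose) message(...)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  if (is.null(blast) == is.null(counts)) {
    stop("supply exactly one of 'blast' (alignments) or 'counts' (pre-tallied)",
      call. = FALSE
    )
  }

  map <- NULL
  if (!is.null(blast)) {
    say("stage: parse + best-hit assignment")
    if (is.null(family_map)) {
      stop("'family_map' is required with alignment input", call. = FALSE)
    }
    map <- load_family_map(family_map)
    records <- parse_blast_tabular(blast)
    assignments <- assign_best_hit(records, map,
      score_cutoff = score_cutoff,
      mode = filter_mode, evalue_cutoff = evalue_cutoff
    )
    y <- tally_family_counts(assignments)
  } else {
    say("stage: load pre-tallied counts")
    y <- read_count_vector(counts)
  }
  if (!length(y) || sum(y) == 0) {
    stop("pipeline stage 'filtering': no reads survive the alignment filter",
      call. = FALSE
    )
  }

  artificial <- character(0)
  if (!is.null(rps)) {
    say("stage: artificial-family flagging")
    rps_map <- if (is.null(rps_family_map)) map else load_family_map(rps_family_map)
    if (is.null(rps_map)) {
      stop("a family map is required to process RPS-BLAST alignments", call. = FALSE)
    }
    rps_assign <- assign_best_hit(parse_blast_tabular(rps), rps_map,
      score_cutoff = rps_cutoff
    )
    artificial <- flag_artificial_families(y, tally_family_counts(rps_assign))
  } else if (!is.null(rps_counts)) {
    say("stage: artificial-family flagging (pre-tallied RPS counts)")
    artificial <- flag_artificial_families(y, read_count_vector(rps_counts))
  }
  universe <- build_family_universe(y, artificial)
  say(sprintf(
    "stage: universe built (N = %d aligned, M = %d existing)",
    length(universe$aligned_ids), length(universe$existing_ids)
  ))

  if (!is.null(learning)) {
    say("stage: learned initialization")
    priors <- estimate_learning_distributions(read_joint_counts(learning))
    alpha0 <- initialize_alpha(priors, universe)
    beta0 <- initialize_beta(priors, y, universe)
  } else {
    warning(
      "no learning sample supplied; falling back to uniform confusion ",
      "columns and count-based starting proportions"
    )
    init <- uniform_initialization(y, universe, artificial)
    alpha0 <- init$alpha0
    beta0 <- init$beta0
  }

  say("stage: EM fit")
  fit <- fit_plsa(alpha0, beta0, y,
    tol = tol, max_iter = max_iter,
    universe = universe, verbose = verbose
  )
  profile <- corrected_profile(fit, y)

  write_profile(profile, file.path(out_dir, "corrected_profile.tsv"))
  utils::write.table(
    data.frame(
      iteration = seq_along(fit$loglik_trace),
      loglik = sprintf("%.10f", fit$loglik_trace)
    ),
    file.path(out_dir, "em_trace.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )

  out <- list(
    profile = profile, fit = fit, universe = universe,
    counts = y, artificial = artificial
  )
  if (!is.null(truth)) {
    say("stage: accuracy evaluation")
    tr <- utils::read.delim(truth,
      header = TRUE, sep = "\t", quote = "",
      colClasses = c("character", "numeric")
    )
    beta_true <- structure(tr$beta, names = tr$family_id)
    missing <- setdiff(universe$existing_ids, names(beta_true))
    if (length(missing)) {
      stop(
        "pipeline stage 'evaluate': truth file missing families: ",
        paste(utils::head(missing, 5L), collapse = ", "),
        call. = FALSE
      )
    }
    acc <- profile_accuracy(profile$beta_hat, beta_true[universe$existing_ids])
    write_accuracy_report(acc, file.path(out_dir, "accuracy_report.tsv"))
    out$accuracy <- acc
  }
  invisible(out)
}

# Fallback starting values when no learning sample is available: uniform
# confusion columns; beta0 from the observed counts of each real existing
# family, EXTRA seeded with the artificial families' read share.
uniform_initialization <- function(y, universe, artificial, eps = 1e-12) {
  N <- length(universe$aligned_ids)
  M <- length(universe$existing_ids)
  alpha0 <- matrix(1 / N, N, M,
    dimnames = list(universe$aligned_ids, universe$existing_ids)
  )
  beta0 <- numeric(M)
  names(beta0) <- universe$existing_ids
  real <- setdiff(universe$existing_ids, "EXTRA")
  beta0[real] <- y[real] / sum(y)
  beta0["EXTRA"] <- if (length(artificial)) sum(y[artificial]) / sum(y) else 0
  beta0 <- pmax(beta0, eps)
  list(alpha0 = alpha0, beta0 = beta0 / sum(beta0))
}

#' Write synthetic fixture files in the package's on-disk formats
#'
#' Draws a ground-truth model, a labeled learning sample and an unlabeled
#' evaluation sample, and writes them (plus the true proportions) under
#' `out_dir`. Useful for demonstrations and for exercising the pipeline
#' without external alignments.
#'
#' @param config A [simulation_config()].
#' @param out_dir Output directory. Files: `learning_joint.tsv`,
#'   `observed_counts.tsv`, `rps_support_counts.tsv` (unit support for the
#'   real existing families, for artificial-family flagging) and
#'   `true_proportions.tsv`.
#' @param learning_reads Reads in the labeled learning sample; defaults to
#'   `config$total_reads`.
#' @return Invisibly, a list with the model and the generated objects.
#' @export
write_synthetic_fixtures <- function(config, out_dir,
                                     learning_reads = config$total_reads) {
  stopifnot(inherits(config, "simulation_config"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  model <- sample_truth(config)
  joint <- simulate_counts(model, learning_reads,
    seed = config$seed + 1L,
    labeled = TRUE
  )
  y <- simulate_counts(model, config$total_reads,
    seed = config$seed + 2L,
    labeled = FALSE
  )
  write_joint_counts(joint, file.path(out_dir, "learning_joint.tsv"))
  write_count_vector(y, file.path(out_dir, "observed_counts.tsv"))
  # RPS-style support: positive exactly for the real existing families, so
  # that artificial-family flagging recovers the generating universe
  real <- setdiff(model$universe$existing_ids, "EXTRA")
  rps <- structure(
    ifelse(model$universe$aligned_ids %in% real, 1L, 0L),
    names = model$universe$aligned_ids
  )
  write_count_vector(rps, file.path(out_dir, "rps_support_counts.tsv"))
  utils::write.table(
    data.frame(
      family_id = names(model$beta),
      beta = sprintf("%.17g", model$beta)
    ),
    file.path(out_dir, "true_proportions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(list(model = model, joint = joint, counts = y))
}
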