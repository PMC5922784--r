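#' Family universe: aligned and estimated existing families
#'
#' Holds the `N` aligned families (every family some read was best-hit
#' assigned to) and the `M` estimated existing families: the non-artificial
#' aligned families plus one reserved family, `"EXTRA"`, always last, which
#' absorbs reads originating from coding sequences outside the family
#' catalogue and from non-coding sequence.
#'
#' @param aligned_ids Character vector of N aligned family ids.
#' @param existing_ids Character vector of M existing family ids; the last
#'   element must be `"EXTRA"`, which may not appear in `aligned_ids`.
#' @return An object of class `family_universe` with elements `aligned_ids`
#'   and `existing_ids`.
#' @export
family_universe <- function(aligned_ids, existing_ids) {
  aligned_ids <- as.character(aligned_ids)
  existing_ids <- as.character(existing_ids)
  if (length(aligned_ids) < 1L || length(existing_ids) < 1L) {
    stop("family universe needs at least one aligned and one existing family",
      call. = FALSE
    )
  }
  if (anyDuplicated(aligned_ids) || anyDuplicated(existing_ids)) {
    stop("duplicate family ids in universe", call. = FALSE)
  }
  if (existing_ids[length(existing_ids)] != "EXTRA" ||
    sum(existing_ids == "EXTRA") != 1L) {
    stop("existing_ids must contain the reserved id 'EXTRA' exactly once, last",
      call. = FALSE
    )
  }
  if ("EXTRA" %in% aligned_ids) {
    stop("the reserved family id 'EXTRA' collides with an aligned family id",
      call. = FALSE
    )
  }
  structure(
    list(aligned_ids = aligned_ids, existing_ids = existing_ids),
    class = "family_universe"
  )
}

#' @export
print.family_universe <- function(x, ...) {
  cat(
    "family_universe:", length(x$aligned_ids), "aligned families,",
    length(x$existing_ids), "existing families (incl. EXTRA)\n"
  )
  invisible(x)
}

#' Assign each read to a family by its best retained alignment
#'
#' Applies the alignment score filter and assigns every surviving read to
#' the family of its highest-scoring alignment (best-hit association). In
#' the default `"bitscore"` mode, alignments with bit score strictly
#' greater than `score_cutoff` are retained (the score-based filter tuned
#' for ~100-base reads against the COG database; default cutoff 66). The
#' `"evalue"` mode instead retains alignments with e-value at most
#' `evalue_cutoff`, the conventional filter the score-based rule replaces;
#' it is provided for comparison runs.
#'
#' Ties on bit score are broken deterministically: lowest e-value, then
#' lexicographically smallest subject id.
#'
#' @param records Alignment data frame from [parse_blast_tabular()].
#' @param family_map Named character vector from [load_family_map()].
#' @param score_cutoff Bit-score cutoff (strict `>`); default 66.
#' @param mode `"bitscore"` (default) or `"evalue"`.
#' @param evalue_cutoff E-value cutoff (inclusive `<=`) for `"evalue"` mode.
#' @return Named character vector: names are read ids, values family ids.
#'   Reads with no retained alignment are absent.
#' @details A retained alignment whose subject id is missing from
#'   `family_map` is an error (a silent drop would bias the counts).
#' @export
assign_best_hit <- function(records, family_map, score_cutoff = 66,
                            mode = c("bitscore", "evalue"),
                            evalue_cutoff = 1e-3) {
  mode <- match.arg(mode)
  stopifnot(score_cutoff >= 0)
  keep <- if (mode == "bitscore") {
    records$bit_score > score_cutoff
  } else {
    records$e_value <= evalue_cutoff
  }
  rec <- records[keep, , drop = FALSE]
  if (nrow(rec) == 0L) {
    return(structure(character(0), names = character(0)))
  }
  unknown <- setdiff(unique(rec$subject_id), names(family_map))
  if (length(unknown)) {
    stop(
      "subject id(s) absent from family map: ",
      paste(utils::head(sort(unknown), 5L), collapse = ", "),
      if (length(unknown) > 5L) ", ..." else "",
      call. = FALSE
    )
  }
  ord <- order(rec$read_id, -rec$bit_score, rec$e_value, rec$subject_id,
    method = "radix"
  )
  rec <- rec[ord, , drop = FALSE]
  best <- rec[!duplicated(rec$read_id), , drop = FALSE]
  structure(unname(family_map[best$subject_id]), names = best$read_id)
}

#' Tally best-hit assignments into a per-family count vector
#'
#' @param assignments Named character vector (read id -> family id) from
#'   [assign_best_hit()].
#' @return Named integer vector of counts, family ids sorted
#'   lexicographically (C locale); the counts sum to the number of
#'   assigned reads. An empty assignment yields a zero-length vector.
#' @export
tally_family_counts <- function(assignments) {
  if (!length(assignments)) {
    return(structure(integer(0), names = character(0)))
  }
  fams <- sort(unique(unname(assignments)), method = "radix")
  counts <- vapply(fams, function(f) sum(assignments == f), integer(1))
  structure(unname(counts), names = fams)
}

#' Flag artificial families by absence of RPS-BLAST support
#'
#' A family appearing in the filtered BLAST profile is judged artificial
#' (not truly present) when it has zero read count in the RPS-BLAST output
#' after score filtration (cutoff 61 by default, applied upstream in
#' [assign_best_hit()] on the RPS alignments).
#'
#' @param blast_counts Count vector from the BLAST best-hit path.
#' @param rps_counts Count vector from the same assign/tally path run on
#'   RPS-BLAST alignments at the RPS score cutoff.
#' @return Sorted character vector of flagged (artificial) family ids:
#'   families present in `blast_counts` with zero or absent RPS count.
#' @export
flag_artificial_families <- function(blast_counts, rps_counts) {
  supported <- names(rps_counts)[rps_counts > 0L]
  sort(setdiff(names(blast_counts), supported), method = "radix")
}

#' Build the family universe from counts and flagged artifacts
#'
#' The aligned families are all families carrying best-hit reads; the
#' estimated existing families are the non-artificial aligned families,
#' sorted, with the reserved `"EXTRA"` family appended last. Thus
#' `M = N - |artificial| + 1`.
#'
#' @param blast_counts Count vector over aligned families.
#' @param artificial Character vector of flagged family ids (subset of the
#'   aligned families).
#' @return A [family_universe()].
#' @details Flagging every aligned family as artificial is an error: a
#'   universe whose only origin is EXTRA makes the mixture vacuous.
#' @export
build_family_universe <- function(blast_counts, artificial = character(0)) {
  aligned <- sort(names(blast_counts), method = "radix")
  if (!length(aligned)) {
    stop("no aligned families: empty count vector", call. = FALSE)
  }
  if ("EXTRA" %in% aligned) {
    stop("the reserved family id 'EXTRA' collides with an aligned family id",
      call. = FALSE
    )
  }
  extra_art <- setdiff(artificial, aligned)
  if (length(extra_art)) {
    stop(
      "artificial families not present among aligned families: ",
      paste(extra_art, collapse = ", "),
      call. = FALSE
    )
  }
  real <- sort(setdiff(aligned, artificial), method = "radix")
  if (!length(real)) {
    stop("all aligned families flagged artificial; no existing families besides EXTRA",
      call. = FALSE
    )
  }
  family_universe(aligned, c(real, "EXTRA"))
}
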