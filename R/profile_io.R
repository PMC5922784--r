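#' Parse a BLAST tabular (outfmt 6) alignment file
#'
#' Reads the standard 12-column tab-separated BLAST output
#' (query, subject, percent identity, alignment length, mismatches, gap
#' opens, query start/end, subject start/end, e-value, bit score). Columns
#' beyond the twelfth are ignored, since real blastx output often carries
#' extras. Lines starting with `#` and blank lines are skipped.
#'
#' @param path Path to a BLAST tabular file.
#' @return A data frame with one row per alignment, in file order, and
#'   columns `read_id`, `subject_id`, `percent_identity`,
#'   `alignment_length`, `e_value`, `bit_score`.
#' @details A malformed line (fewer than 12 fields, or a non-numeric score
#'   field) aborts with an error naming the offending line number. An empty
#'   file yields a zero-row data frame.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("r1\tP1\t98.0\t33\t0\t0\t1\t99\t10\t42\t1e-12\t70.1", tf)
#' parse_blast_tabular(tf)
#' @export
parse_blast_tabular <- function(path) {
  if (!file.exists(path)) {
    stop("BLAST tabular file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^#", lines) & nzchar(trimws(lines))
  line_no <- which(is_data)
  empty <- data.frame(
    read_id = character(0), subject_id = character(0),
    percent_identity = numeric(0), alignment_length = integer(0),
    e_value = numeric(0), bit_score = numeric(0),
    stringsAsFactors = FALSE
  )
  if (!any(is_data)) {
    return(empty)
  }
  fields <- strsplit(lines[is_data], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    bad <- which(nf < 12L)[1L]
    stop(sprintf(
      "malformed BLAST tabular line %d: expected >= 12 tab-separated fields, found %d",
      line_no[bad], nf[bad]
    ), call. = FALSE)
  }
  pick <- function(k) vapply(fields, `[[`, character(1), k)
  as_num <- function(x, what) {
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop(sprintf(
        "malformed BLAST tabular line %d: non-numeric %s '%s'",
        line_no[bad], what, x[bad]
      ), call. = FALSE)
    }
    v
  }
  rec <- data.frame(
    read_id = pick(1), subject_id = pick(2),
    percent_identity = as_num(pick(3), "percent identity"),
    alignment_length = as.integer(as_num(pick(4), "alignment length")),
    e_value = as_num(pick(11), "e-value"),
    bit_score = as_num(pick(12), "bit score"),
    stringsAsFactors = FALSE
  )
  check <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf(
        "malformed BLAST tabular line %d: %s out of range",
        line_no[which(!ok)[1L]], what
      ), call. = FALSE)
    }
  }
  check(rec$percent_identity >= 0 & rec$percent_identity <= 100, "percent identity")
  check(rec$alignment_length >= 1L, "alignment length")
  check(rec$e_value >= 0, "e-value")
  check(is.finite(rec$bit_score), "bit score")
  rec
}

#' Load a subject-to-family mapping table
#'
#' Reads a two-column tab-separated table mapping database subject ids
#' (e.g. protein accessions) to functional family ids (e.g. COG ids).
#' The mapping must be many-to-one: a subject id appearing twice with
#' conflicting families is an error. Identical duplicate rows are
#' collapsed silently.
#'
#' @param path Path to a headerless two-column TSV (subject_id, family_id).
#' @return A named character vector: `names()` are subject ids, values are
#'   family ids.
#' @seealso [write_family_map()]
#' @export
load_family_map <- function(path) {
  if (!file.exists(path)) {
    stop("family map file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (!length(lines)) {
    return(structure(character(0), names = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L)) {
    stop("family map requires two tab-separated columns (subject_id, family_id); line ",
      which(lengths(fields) < 2L)[1L], " has fewer",
      call. = FALSE
    )
  }
  subject <- vapply(fields, `[[`, character(1), 1L)
  family <- vapply(fields, `[[`, character(1), 2L)
  keep <- !duplicated(paste(subject, family, sep = "\r"))
  subject <- subject[keep]
  family <- family[keep]
  dup <- duplicated(subject)
  if (any(dup)) {
    stop(
      "conflicting family assignments for subject id(s): ",
      paste(unique(subject[dup]), collapse = ", "),
      call. = FALSE
    )
  }
  structure(family, names = subject)
}

#' Write a subject-to-family mapping table
#'
#' @param map Named character vector as returned by [load_family_map()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_family_map <- function(map, path) {
  writeLines(paste(names(map), unname(map), sep = "\t"), path)
  invisible(path)
}

#' Read and write per-family read-count vectors
#'
#' A count vector holds the observed best-hit read count for each aligned
#' family. On disk it is a TSV with header `family_id\tcount`. In memory it
#' is a named integer vector (names are family ids).
#'
#' @param counts Named non-negative integer vector.
#' @param path File path.
#' @return `read_count_vector()` returns a named integer vector;
#'   `write_count_vector()` returns `path` invisibly.
#' @export
write_count_vector <- function(counts, path) {
  stopifnot(is.numeric(counts), !is.null(names(counts)))
  df <- data.frame(
    family_id = names(counts), count = as.integer(counts),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @rdname write_count_vector
#' @export
read_count_vector <- function(path) {
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t", quote = "",
    colClasses = c("character", "integer"), comment.char = ""
  )
  if (!all(c("family_id", "count") %in% names(df))) {
    stop("count vector file must have columns family_id, count", call. = FALSE)
  }
  if (any(df$count < 0L)) {
    stop("negative count in ", path, call. = FALSE)
  }
  structure(df$count, names = df$family_id)
}

#' Read and write joint (origin x aligned) count matrices
#'
#' The learning sample is summarized as a matrix of read counts indexed by
#' (origin family, aligned family). On disk it is a long-format TSV with
#' header `origin_id\taligned_id\tcount`; every cell is written, including
#' zeros, so that reading the file back reconstructs the matrix and its
#' dimension ids exactly.
#'
#' @param joint Non-negative integer matrix, rows = origin families
#'   (including the reserved `EXTRA` origin when present), columns = aligned
#'   families; both dimensions named.
#' @param path File path.
#' @return `read_joint_counts()` returns the matrix with dimnames in file
#'   order of first appearance; `write_joint_counts()` returns `path`
#'   invisibly.
#' @export
write_joint_counts <- function(joint, path) {
  stopifnot(is.matrix(joint), !is.null(rownames(joint)), !is.null(colnames(joint)))
  df <- data.frame(
    origin_id = rep(rownames(joint), times = ncol(joint)),
    aligned_id = rep(colnames(joint), each = nrow(joint)),
    count = as.integer(joint),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = TRUE
  )
  invisible(path)
}

#' @rdname write_joint_counts
#' @export
read_joint_counts <- function(path) {
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t", quote = "",
    colClasses = c("character", "character", "integer"), comment.char = ""
  )
  if (!all(c("origin_id", "aligned_id", "count") %in% names(df))) {
    stop("joint count file must have columns origin_id, aligned_id, count",
      call. = FALSE
    )
  }
  if (any(df$count < 0L)) {
    stop("negative count in ", path, call. = FALSE)
  }
  origins <- unique(df$origin_id)
  aligned <- unique(df$aligned_id)
  joint <- matrix(0L, length(origins), length(aligned),
    dimnames = list(origins, aligned)
  )
  idx <- cbind(match(df$origin_id, origins), match(df$aligned_id, aligned))
  joint[idx] <- joint[idx] + df$count
  joint
}

#' Write a corrected functional profile
#'
#' Serializes the fitted origin proportions and rounded corrected counts,
#' one row per estimated existing family (the reserved `EXTRA` family
#' included), as a TSV with header `family_id\tbeta_hat\tcount_hat`.
#' `beta_hat` is written at full double precision so that a write/read
#' round trip is lossless.
#'
#' @param profile A `profile_estimate` object from [corrected_profile()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @seealso [read_profile()]
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "profile_estimate"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("family_id\tbeta_hat\tcount_hat", con)
  writeLines(
    sprintf(
      "%s\t%.17g\t%d", profile$existing_ids, profile$beta_hat,
      as.integer(profile$count_hat)
    ),
    con
  )
  invisible(path)
}

#' Read a corrected functional profile
#'
#' @param path Path to a TSV written by [write_profile()].
#' @return A `profile_estimate` object (`total_reads` is recovered as the
#'   sum of `count_hat`, the best available reconstruction from disk).
#' @export
read_profile <- function(path) {
  df <- utils::read.delim(path,
    header = TRUE, sep = "\t", quote = "",
    colClasses = c("character", "numeric", "integer"), comment.char = ""
  )
  if (!all(c("family_id", "beta_hat", "count_hat") %in% names(df))) {
    stop("profile file must have columns family_id, beta_hat, count_hat",
      call. = FALSE
    )
  }
  profile_estimate(
    existing_ids = df$family_id, beta_hat = df$beta_hat,
    count_hat = df$count_hat, total_reads = sum(df$count_hat)
  )
}
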