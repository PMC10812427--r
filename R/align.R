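the_matrix_cache <- new.env(parent = emptyenv())

#' The default protein substitution matrix
#'
#' BLOSUM62, extended to accept the RefSeq ambiguity and rare residues: any
#' residue pair not covered by the matrix (U, O, J against anything) scores
#' a fixed -1. Ambiguity codes already in the matrix (B, Z, X) use its own
#' rows.
#'
#' @return A numeric matrix with residue-letter dimnames.
#' @export
blosum62_matrix <- function() {
  if (!is.null(the_matrix_cache$blosum62)) return(the_matrix_cache$blosum62)
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  base <- env$BLOSUM62
  extra <- setdiff(c("U", "O", "J"), rownames(base))
  alphabet <- c(rownames(base), extra)
  full <- matrix(-1, nrow = length(alphabet), ncol = length(alphabet),
                 dimnames = list(alphabet, alphabet))
  full[rownames(base), colnames(base)] <- base
  the_matrix_cache$blosum62 <- full
  full
}

#' Alignment parameters
#'
#' Defaults are the protein-BLAST conventions: BLOSUM62 with gap open -11
#' and gap extension -1. A gap run of length `g` costs
#' `gap_open + (g - 1) * gap_extend`; end gaps are penalized like internal
#' gaps (true global alignment) unless `penalize_end_gaps = FALSE`
#' (semiglobal variant).
#'
#' @param substitution_matrix Numeric matrix with residue dimnames; default
#'   [blosum62_matrix()].
#' @param gap_open Gap opening penalty (applies to a gap's first column);
#'   must satisfy `gap_open <= gap_extend <= 0`.
#' @param gap_extend Penalty for each subsequent gap column.
#' @param mode Alignment mode; only `"global"` is supported.
#' @param penalize_end_gaps Penalize leading/trailing gaps.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = NULL,
                             gap_open = -11,
                             gap_extend = -1,
                             mode = c("global"),
                             penalize_end_gaps = TRUE) {
  mode <- match.arg(mode)
  if (is.null(substitution_matrix)) substitution_matrix <- blosum62_matrix()
  if (!(gap_open <= gap_extend && gap_extend <= 0)) {
    abort("alignment_params requires gap_open <= gap_extend <= 0",
          class = "surfscreen_config_error")
  }
  structure(
    list(
      substitution_matrix = substitution_matrix,
      gap_open = gap_open,
      gap_extend = gap_extend,
      mode = mode,
      penalize_end_gaps = penalize_end_gaps
    ),
    class = "alignment_params"
  )
}

#' @noRd
encode_residues <- function(seq, alphabet, which_seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  idx <- match(chars, alphabet)
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    abort(
      sprintf("Residue '%s' at position %d of the %s sequence is outside the substitution-matrix alphabet",
              chars[pos], pos, which_seq),
      class = "surfscreen_input_error"
    )
  }
  idx - 1L
}

#' Optimal global pairwise protein alignment
#'
#' Needleman-Wunsch alignment under affine gap scoring. The traceback is
#' deterministic: among co-optimal moves, diagonal is preferred over a gap
#' in the subject (up) over a gap in the query (left).
#'
#' @param a,b Protein sequences (non-empty character scalars).
#' @param params An [alignment_params()].
#' @param query_id,subject_id Identifiers carried into the result.
#' @return An object of class `alignment_result`: a list with `query_id`,
#'   `subject_id`, `score`, `aligned_query`, `aligned_subject` (gapped
#'   strings of equal length), `aln_length`, `matches` (columns with
#'   identical residues), `indel_columns` (columns containing a gap) and
#'   `similarity_pct` (see [similarity_score()]; `NA` if the alignment has
#'   no residue-residue column).
#' @examples
#' r <- global_align("MKTAYIAK", "MKTAYIAK")
#' r$similarity_pct # 100
#' @export
global_align <- function(a, b, params = alignment_params(),
                         query_id = "query", subject_id = "subject") {
  if (!nzchar(a) || !nzchar(b)) {
    abort("Sequences must be non-empty", class = "surfscreen_input_error")
  }
  sub <- params$substitution_matrix
  alphabet <- rownames(sub)
  ai <- encode_residues(a, alphabet, "query")
  bi <- encode_residues(b, alphabet, "subject")
  res <- nw_affine_cpp(ai, bi, sub, params$gap_open, params$gap_extend,
                       params$penalize_end_gaps)
  a_chars <- strsplit(toupper(a), "")[[1]]
  b_chars <- strsplit(toupper(b), "")[[1]]
  qa <- rep("-", length(res$a_idx))
  qb <- rep("-", length(res$b_idx))
  qa[res$a_idx >= 0] <- a_chars[res$a_idx[res$a_idx >= 0] + 1L]
  qb[res$b_idx >= 0] <- b_chars[res$b_idx[res$b_idx >= 0] + 1L]
  gap <- res$a_idx < 0 | res$b_idx < 0
  stopifnot(!any(res$a_idx < 0 & res$b_idx < 0)) # no gap-gap columns
  matches <- sum(!gap & qa == qb)
  indel <- sum(gap)
  aln_length <- length(qa)
  denom <- aln_length - indel
  out <- structure(
    list(
      query_id = query_id,
      subject_id = subject_id,
      score = res$score,
      aligned_query = paste(qa, collapse = ""),
      aligned_subject = paste(qb, collapse = ""),
      aln_length = aln_length,
      matches = as.integer(matches),
      indel_columns = as.integer(indel),
      similarity_pct = if (denom > 0) 100 * matches / denom else NA_real_
    ),
    class = "alignment_result"
  )
  out
}

#' Percent similarity of an aligned pair
#'
#' The number of identical aligned residue pairs divided by the alignment
#' length minus the number of indel columns, times 100 — i.e. percent
#' identity over the residue-residue columns of the alignment.
#'
#' @param r An `alignment_result` (see [global_align()]).
#' @return Similarity percentage in `[0, 100]`.
#' @export
similarity_score <- function(r) {
  denom <- r$aln_length - r$indel_columns
  if (denom <= 0) {
    abort("Degenerate alignment: no residue-residue columns",
          class = "surfscreen_domain_error")
  }
  100 * r$matches / denom
}

#' Brute-force reference score for short global alignments
#'
#' Enumerates every global alignment of two short sequences (length <= 10)
#' and returns the best affine-gap score. This is a validation utility for
#' checking the dynamic-programming aligner; it always penalizes end gaps.
#'
#' @inheritParams global_align
#' @return The optimal score as a double.
#' @export
enumerate_global_score <- function(a, b, params = alignment_params()) {
  sub <- params$substitution_matrix
  alphabet <- rownames(sub)
  ai <- encode_residues(a, alphabet, "query")
  bi <- encode_residues(b, alphabet, "subject")
  enumerate_global_score_cpp(ai, bi, sub, params$gap_open, params$gap_extend)
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("Global alignment %s vs %s\n", x$query_id, x$subject_id))
  cat(sprintf("  score: %.1f  length: %d  matches: %d  indel columns: %d\n",
              x$score, x$aln_length, x$matches, x$indel_columns))
  cat(sprintf("  similarity: %s%%\n",
              ifelse(is.na(x$similarity_pct), "NA",
                     formatC(x$similarity_pct, format = "f", digits = 1))))
  invisible(x)
}
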