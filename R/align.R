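#' Nucleotide scoring scheme
#'
#' Scoring for the local aligner. Defaults are standard nucleotide values:
#' match +2, mismatch -1, gap open -5, gap extend -1. A gap of length L costs
#' `gap_open + L * gap_extend` (the opening column pays both penalties).
#'
#' @param match positive match reward.
#' @param mismatch mismatch penalty (<= 0).
#' @param gap_open gap opening penalty (<= 0).
#' @param gap_extend gap extension penalty (<= 0).
#' @return A `scoring_scheme` list.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -1L,
                           gap_open = -5L, gap_extend = -1L) {
  stopifnot(match > 0, mismatch <= 0, gap_open <= 0, gap_extend <= 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend)),
            class = "scoring_scheme")
}

#' Optimal local alignment of two nucleotide strings
#'
#' Smith-Waterman local alignment with affine gaps (Gotoh recurrence) and a
#' deterministic traceback: score ties are resolved toward the diagonal,
#' then upward (gap in the subject), and the traceback starts from the first
#' maximal cell in row-major order. `N` counts as a mismatch against every
#' letter, including `N`.
#'
#' `identity_pct` is 100 x matches / aligned columns, where aligned columns
#' include gap columns. `overlap_nt` counts subject positions covered by the
#' alignment.
#'
#' @param a query nucleotide string.
#' @param b subject nucleotide string.
#' @param scheme a [scoring_scheme()].
#' @return A `local_alignment` list with fields `score`, `query_interval`
#'   and `subject_interval` (0-based half-open), `aligned_length`,
#'   `n_matches`, `identity_pct` and `overlap_nt`.
#' @examples
#' local_align("ACGTACGT", "ACGTTCGT")
#' @export
local_align <- function(a, b, scheme = scoring_scheme()) {
  if (!is.character(a) || length(a) != 1L || !nzchar(a) ||
      !is.character(b) || length(b) != 1L || !nzchar(b)) {
    stop("'a' and 'b' must be non-empty strings")
  }
  a <- clean_seq(a)
  b <- clean_seq(b)
  r <- .sw_align_cpp(a, b, scheme$match, scheme$mismatch,
                     scheme$gap_open, scheme$gap_extend)
  n_col <- r$n_col
  structure(list(
    score = r$score,
    query_interval = c(r$q_start, r$q_end),
    subject_interval = c(r$s_start, r$s_end),
    aligned_length = n_col,
    n_matches = r$n_match,
    identity_pct = if (n_col > 0) 100 * r$n_match / n_col else 0,
    overlap_nt = r$s_end - r$s_start
  ), class = "local_alignment")
}

#' Best head identity of a candidate against a reference set
#'
#' Aligns the 5'-terminal `head_len` nucleotides of a candidate element
#' against every record of a reference catalogue and returns the alignment
#' maximising `(identity_pct, overlap_nt)`; remaining ties go to the first
#' reference in catalogue order. This is the quantity behind the
#' 60%-identity / 60-nt-overlap rule used to call 5S rRNA- or tRNA-derived
#' heads.
#'
#' @param candidate a single-row [sine_catalogue()] subset or a nucleotide
#'   string.
#' @param refs reference [sine_catalogue()].
#' @param head_len length of the candidate head to align (nt).
#' @param scheme a [scoring_scheme()].
#' @return A `local_alignment` with extra fields `ref_id` and `ref_index`.
#' @export
best_head_identity <- function(candidate, refs, head_len = 100L,
                               scheme = scoring_scheme()) {
  stopifnot(head_len >= 1)
  seq <- candidate_seq(candidate)
  if (!inherits(refs, "sine_catalogue") || nrow(refs) == 0L) {
    stop("'refs' must be a non-empty sine_catalogue")
  }
  head <- substr(seq, 1L, min(head_len, nchar(seq)))
  best <- NULL
  for (k in seq_len(nrow(refs))) {
    aln <- local_align(head, refs$seq[k], scheme)
    if (is.null(best) ||
        aln$identity_pct > best$identity_pct ||
        (aln$identity_pct == best$identity_pct &&
         aln$overlap_nt > best$overlap_nt)) {
      best <- aln
      best$ref_id <- refs$id[k]
      best$ref_index <- k
    }
  }
  best
}

# internal: accept either a catalogue row or a bare string
candidate_seq <- function(candidate) {
  if (inherits(candidate, "sine_catalogue") || is.data.frame(candidate)) {
    if (nrow(candidate) != 1L) stop("expected a single record")
    return(candidate$seq)
  }
  if (is.character(candidate) && length(candidate) == 1L) {
    return(clean_seq(candidate))
  }
  stop("candidate must be a catalogue row or a nucleotide string")
}

candidate_id <- function(candidate) {
  if (is.data.frame(candidate) && nrow(candidate) == 1L) candidate$id
  else NA_character_
}

#' @export
print.local_alignment <- function(x, ...) {
  cat(sprintf(
    "local_alignment: score %s, identity %.1f%% over %d column(s), overlap %d nt\n",
    format(x$score), x$identity_pct, x$aligned_length, x$overlap_nt))
  cat(sprintf("  query [%d,%d)  subject [%d,%d)%s\n",
              x$query_interval[1], x$query_interval[2],
              x$subject_interval[1], x$subject_interval[2],
              if (!is.null(x$ref_id)) paste0("  ref ", x$ref_id) else ""))
  invisible(x)
}
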