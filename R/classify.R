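#' Classification thresholds
#'
#' The head-homology rule used throughout: a candidate head must align to a
#' reference gene at `id_threshold` percent identity or better over at
#' least `overlap_threshold` reference nucleotides. The published rule for
#' 5S-derived elements is 60% identity over a 60-nt overlap; it is reused
#' symmetrically for the tRNA side, where no explicit threshold was
#' published (an assumption, flagged in the documentation).
#'
#' @param id_threshold minimum percent identity.
#' @param overlap_threshold minimum subject overlap (nt).
#' @param head_len length of the candidate 5' head used for the search;
#'   100 nt bounds compute while covering the ~64-nt conserved 5S head
#'   plus divergence.
#' @return a `classification_thresholds` list.
#' @export
classification_thresholds <- function(id_threshold = 60,
                                      overlap_threshold = 60L,
                                      head_len = 100L) {
  stopifnot(id_threshold > 0, id_threshold <= 100, overlap_threshold >= 1)
  structure(list(id_threshold = id_threshold,
                 overlap_threshold = as.integer(overlap_threshold),
                 head_len = as.integer(head_len)),
            class = "classification_thresholds")
}

#' Classify a candidate element as SINE2, SINE3 or unclassified
#'
#' Applies the head-homology rule in fixed precedence: the 5S test runs
#' first (meeting it calls the element 5S rRNA-derived, `SINE3`); otherwise
#' a tRNA head match or a type-2 internal promoter (A box + B box) calls it
#' tRNA-derived (`SINE2`); otherwise the element stays `unclassified`. The
#' 5S-first precedence avoids spurious tRNA isotype calls on 5S heads. The
#' tRNA isotype reported is that of the single best-scoring tRNA reference;
#' exact ties give `"ambiguous"`.
#'
#' @param candidate a catalogue row or nucleotide string.
#' @param refs_trna reference tRNA gene [sine_catalogue()] (or `NULL`).
#' @param refs_5s reference 5S rRNA gene [sine_catalogue()] (or `NULL`).
#' @param thresholds a [classification_thresholds()].
#' @param motif_models named model list with `A_box` and `B_box` entries,
#'   used for the promoter fallback; `NULL` disables it. Defaults to the
#'   exact-consensus [strict_motif_models()]: a degenerate box pair is too
#'   weak to be the sole evidence for a family call.
#' @param scheme a [scoring_scheme()].
#' @param spacer_bounds A-to-B spacer bounds for the promoter fallback.
#' @return A `sine_classification` list: `family`, `origin_call`,
#'   `head_alignment`, `promoter`, `line_3prime_match` (filled by
#'   [line_3prime_similarity()], reported only).
#' @export
classify_element <- function(candidate, refs_trna = NULL, refs_5s = NULL,
                             thresholds = classification_thresholds(),
                             motif_models = strict_motif_models(),
                             scheme = scoring_scheme(),
                             spacer_bounds = c(10L, 150L)) {
  has_trna <- inherits(refs_trna, "sine_catalogue") && nrow(refs_trna) > 0
  has_5s <- inherits(refs_5s, "sine_catalogue") && nrow(refs_5s) > 0
  if (!has_trna && !has_5s && is.null(motif_models)) {
    stop(sine_condition("sinescout_config_error",
      "classification needs a tRNA or 5S reference set, or motif models"))
  }
  seq <- candidate_seq(candidate)
  meets <- function(aln) {
    !is.null(aln) && aln$identity_pct >= thresholds$id_threshold &&
      aln$overlap_nt >= thresholds$overlap_threshold
  }

  res <- structure(list(family = "unclassified", origin_call = NA_character_,
                        head_alignment = NULL, promoter = NULL,
                        line_3prime_match = NULL),
                   class = "sine_classification")

  if (has_5s) {
    aln5 <- best_head_identity(seq, refs_5s, thresholds$head_len, scheme)
    if (meets(aln5)) {
      res$family <- "SINE3"
      res$origin_call <- "5S"
      res$head_alignment <- aln5
      return(res)
    }
    res$head_alignment <- aln5
  }
  if (has_trna) {
    alnt <- best_head_identity(seq, refs_trna, thresholds$head_len, scheme)
    if (meets(alnt)) {
      res$family <- "SINE2"
      res$head_alignment <- alnt
      res$origin_call <- .isotype_call(alnt, seq, refs_trna,
                                       thresholds$head_len, scheme)
      return(res)
    }
    if (is.null(res$head_alignment)) res$head_alignment <- alnt
  }
  if (!is.null(motif_models)) {
    prom <- annotate_type2_promoter(seq, motif_models$A_box,
                                    motif_models$B_box,
                                    motif_models$Bprime_box,
                                    spacer_bounds = spacer_bounds)
    res$promoter <- prom
    if (prom$promoter_type == "type2") {
      res$family <- "SINE2"
      return(res)
    }
  }
  res
}

# internal: isotype = origin label (or id) of the best tRNA reference;
# ties on (identity, overlap) between different isotypes -> "ambiguous"
.isotype_call <- function(best, seq, refs, head_len, scheme) {
  label <- function(k) {
    lab <- refs$origin_label[k]
    if (is.na(lab)) refs$id[k] else lab
  }
  head <- substr(seq, 1L, min(head_len, nchar(seq)))
  ties <- character()
  for (k in seq_len(nrow(refs))) {
    aln <- local_align(head, refs$seq[k], scheme)
    if (aln$identity_pct == best$identity_pct &&
        aln$overlap_nt == best$overlap_nt) {
      ties <- c(ties, label(k))
    }
  }
  if (length(unique(ties)) > 1L) "ambiguous" else label(best$ref_index)
}

#' Filter out candidates that are true genes
#'
#' A candidate that aligns to a reference gene at `full_len_id_threshold`
#' percent identity or better while covering at least `coverage_threshold`
#' of both the reference length and its own length is the gene itself, not
#' a derived element, and is discarded. The candidate-coverage condition
#' keeps derived elements that contain a complete gene-derived head but
#' carry a long unrelated body and tail: such an element covers the gene
#' yet is several times its length, so it is not the gene.
#'
#' @param candidate a catalogue row or nucleotide string.
#' @param refs reference gene [sine_catalogue()] (tRNAs and/or 5S rRNAs).
#' @param full_len_id_threshold percent identity above which the candidate
#'   is considered the gene.
#' @param coverage_threshold minimum fraction of the reference covered.
#' @param scheme a [scoring_scheme()].
#' @return `TRUE` to keep the candidate, `FALSE` to discard it.
#' @export
true_gene_filter <- function(candidate, refs, full_len_id_threshold = 90,
                             coverage_threshold = 0.9,
                             scheme = scoring_scheme()) {
  if (!inherits(refs, "sine_catalogue") || nrow(refs) == 0L) {
    stop("'refs' must be a non-empty sine_catalogue")
  }
  seq <- candidate_seq(candidate)
  for (k in seq_len(nrow(refs))) {
    aln <- local_align(seq, refs$seq[k], scheme)
    ref_coverage <- aln$overlap_nt / nchar(refs$seq[k])
    cand_coverage <- (aln$query_interval[2] - aln$query_interval[1]) /
      nchar(seq)
    if (aln$identity_pct >= full_len_id_threshold &&
        ref_coverage >= coverage_threshold &&
        cand_coverage >= coverage_threshold) {
      return(FALSE)
    }
  }
  TRUE
}

#' Discard loci overlapping an exclusion list
#'
#' Coordinate-based companion to [true_gene_filter()]: drops loci (e.g.
#' candidate elements located on a genome) that overlap a known tRNA/rRNA
#' gene interval by at least `min_overlap_frac` of the locus length.
#'
#' @param loci loci data.frame (`contig`, `start`, `end`, 0-based
#'   half-open).
#' @param exclusion exclusion intervals data.frame with the same
#'   coordinate convention (e.g. read from a BED file).
#' @param min_overlap_frac minimum overlapping fraction of the locus that
#'   triggers removal.
#' @return the retained subset of `loci`.
#' @export
exclusion_filter <- function(loci, exclusion, min_overlap_frac = 0.5) {
  if (!nrow(loci) || !nrow(exclusion)) return(loci)
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    same <- exclusion[exclusion$contig == loci$contig[i], , drop = FALSE]
    if (!nrow(same)) next
    ov <- pmax(0, pmin(same$end, loci$end[i]) - pmax(same$start, loci$start[i]))
    if (any(ov / (loci$end[i] - loci$start[i]) >= min_overlap_frac)) {
      keep[i] <- FALSE
    }
  }
  loci[keep, , drop = FALSE]
}

#' Similarity of an element 3' terminus to LINE 3'-UTR references
#'
#' SINEs borrow the retrotransposition machinery of partner LINEs, and
#' sequence similarity between a SINE 3' terminus and a LINE 3'-UTR is read
#' as evidence for that partnership. This reports the best forward-strand
#' local alignment of the candidate's final `window` nucleotides against
#' each LINE reference. It never changes the family call.
#'
#' @param candidate a catalogue row or nucleotide string.
#' @param refs_line LINE 3'-UTR reference [sine_catalogue()].
#' @param window length of the candidate 3' terminus aligned (nt).
#' @param scheme a [scoring_scheme()].
#' @return the best `local_alignment` (with `ref_id`), or `NULL` when
#'   nothing aligns with a positive score.
#' @export
line_3prime_similarity <- function(candidate, refs_line, window = 150L,
                                   scheme = scoring_scheme()) {
  if (!inherits(refs_line, "sine_catalogue") || nrow(refs_line) == 0L) {
    stop("'refs_line' must be a non-empty sine_catalogue")
  }
  seq <- candidate_seq(candidate)
  n <- nchar(seq)
  tail3 <- substr(seq, max(1L, n - window + 1L), n)
  best <- NULL
  for (k in seq_len(nrow(refs_line))) {
    aln <- local_align(tail3, refs_line$seq[k], scheme)
    if (is.null(best) || aln$score > best$score) {
      best <- aln
      best$ref_id <- refs_line$id[k]
    }
  }
  if (!is.null(best) && best$score <= 0) return(NULL)
  best
}

#' @export
print.sine_classification <- function(x, ...) {
  cat("sine_classification:", x$family,
      if (!is.na(x$origin_call)) paste0("(", x$origin_call, ")") else "",
      "\n")
  if (!is.null(x$head_alignment)) {
    cat(sprintf("  head: %.1f%% identity over %d nt vs %s\n",
                x$head_alignment$identity_pct, x$head_alignment$overlap_nt,
                x$head_alignment$ref_id))
  }
  if (!is.null(x$promoter)) cat("  promoter:", x$promoter$promoter_type, "\n")
  invisible(x)
}
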