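#' Find a terminal target site duplication on a printed element
#'
#' Published SINE elements are often printed together with both copies of
#' their target site duplication (TSD), so the element starts and ends with
#' the same short direct repeat. This finder returns the longest `k` in
#' `[min_len, max_len]` such that a k-mer starting within `max_end_offset`
#' of the first position equals a k-mer ending within `max_end_offset` of
#' the last position. Matching is exact: degraded TSDs with substitutions
#' are treated as absent, since repeat decay is read as evidence of element
#' age rather than as a match.
#'
#' @param seq element nucleotide string.
#' @param min_len minimum TSD length (>= 2).
#' @param max_len maximum TSD length. The published range for these
#'   elements is 4-14 bp; the default keeps headroom and reported lengths
#'   are never clipped.
#' @param max_end_offset how far from the respective sequence ends the
#'   repeat copies may sit (0 = strictly terminal).
#' @return A `tsd_annotation` list (`tsd_seq`, `length_nt`, `mode`,
#'   `left_offset`, `right_offset`) or `NULL` when no repeat qualifies.
#'   Offset ties are broken toward the smallest offsets.
#' @examples
#' find_tsd_terminal("ACGTGAAATTTACGTG")
#' @export
find_tsd_terminal <- function(seq, min_len = 4L, max_len = 20L,
                              max_end_offset = 0L) {
  stopifnot(min_len >= 2L, max_len >= min_len, max_end_offset >= 0L)
  seq <- clean_seq(seq)
  n <- nchar(seq)
  if (n < 2L * min_len) return(NULL)
  for (k in seq(from = min(max_len, n %/% 2L), to = min_len)) {
    for (lo in 0:max_end_offset) {
      if (lo + k > n) next
      left <- substr(seq, lo + 1L, lo + k)
      for (ro in 0:max_end_offset) {
        s_end <- n - ro
        s_start <- s_end - k + 1L
        if (s_start <= lo + k) next  # copies must not overlap
        if (left == substr(seq, s_start, s_end)) {
          return(structure(list(tsd_seq = left, length_nt = k,
                                mode = "terminal",
                                left_offset = lo, right_offset = ro),
                           class = "tsd_annotation"))
        }
      }
    }
  }
  NULL
}

#' Find a target site duplication in the genomic flanks of an element
#'
#' Searches for the best exact direct repeat shared between the `window`
#' nucleotides upstream of an element locus and the `window` nucleotides
#' downstream of it. Because a genuine TSD abuts the insertion, candidate
#' repeats are scored as `length - left_gap - right_gap`, where the gaps are
#' the distances from the upstream copy's end to the element start and from
#' the element end to the downstream copy's start; only repeats scoring
#' above zero are reported (a repeat farther from the junction than its own
#' length is indistinguishable from background). Ties prefer longer
#' repeats, then smaller gaps.
#'
#' @param genome_seq contig nucleotide string.
#' @param element_interval 0-based half-open `c(start, end)` of the element
#'   on the contig.
#' @param window flank width searched on each side (nt).
#' @param min_len,max_len allowed TSD length range.
#' @return A `tsd_annotation` (`mode = "flanking"`; `left_offset` /
#'   `right_offset` are the junction gaps) or `NULL`. Elements touching a
#'   contig edge have no usable flank pair and return `NULL`.
#' @export
find_tsd_flanking <- function(genome_seq, element_interval, window = 30L,
                              min_len = 4L, max_len = 20L) {
  genome_seq <- clean_seq(genome_seq)
  n <- nchar(genome_seq)
  start <- element_interval[1]
  end <- element_interval[2]
  stopifnot(start >= 0, end > start, end <= n)
  up_start <- max(0L, start - window)
  up <- substr(genome_seq, up_start + 1L, start)          # [up_start, start)
  down <- substr(genome_seq, end + 1L, min(n, end + window))
  if (nchar(up) < min_len || nchar(down) < min_len) return(NULL)

  best <- NULL
  kmax <- min(max_len, nchar(up), nchar(down))
  for (k in seq(from = kmax, to = min_len)) {
    nu <- nchar(up) - k + 1L
    nd <- nchar(down) - k + 1L
    ukm <- substring(up, 1:nu, k:(nu + k - 1L))
    dkm <- substring(down, 1:nd, k:(nd + k - 1L))
    hit <- which(outer(ukm, dkm, "=="), arr.ind = TRUE)
    if (!nrow(hit)) next
    # left gap: distance from upstream copy end to the element start
    lg <- nchar(up) - (hit[, 1] - 1L) - k
    rg <- hit[, 2] - 1L
    score <- k - lg - rg
    o <- order(-score, lg, rg)[1]
    if (score[o] > 0 && (is.null(best) || score[o] > best$score)) {
      best <- list(seq = ukm[hit[o, 1]], k = k, lg = lg[o], rg = rg[o],
                   score = score[o])
    }
    # a shorter repeat can never outscore an already-found one of length k
    if (!is.null(best) && best$score >= k - 1L) break
  }
  if (is.null(best)) return(NULL)
  structure(list(tsd_seq = best$seq, length_nt = best$k, mode = "flanking",
                 left_offset = as.integer(best$lg),
                 right_offset = as.integer(best$rg)),
            class = "tsd_annotation")
}

# internal: tandem-repeat anchored at the 3' end of 'seq'; returns
# list(unit, count) with the primitive unit, or NULL if fewer than
# min_copies. Preference: maximal total length, then smallest unit.
.terminal_tandem <- function(seq, max_unit = 6L, min_copies = 3L) {
  n <- nchar(seq)
  best <- NULL
  for (u in seq_len(min(max_unit, n))) {
    unit <- substr(seq, n - u + 1L, n)
    count <- 1L
    while ((p <- n - (count + 1L) * u + 1L) >= 1L &&
           substr(seq, p, p + u - 1L) == unit) {
      count <- count + 1L
    }
    # reduce to the primitive unit (e.g. ACTACT x n -> ACT x 2n)
    for (d in seq_len(u - 1L)) {
      if (u %% d == 0L &&
          unit == strrep(substr(unit, 1L, d), u %/% d)) {
        count <- count * (u %/% d)
        unit <- substr(unit, 1L, d)
        u <- d
        break
      }
    }
    if (count >= min_copies) {
      total <- nchar(unit) * count
      if (is.null(best) || total > best$total ||
          (total == best$total && nchar(unit) < nchar(best$unit))) {
        best <- list(unit = unit, count = count, total = total)
      }
    }
  }
  best
}

#' Annotate the 3' tail of an element
#'
#' Inspects the 3'-terminal `tail_window` nucleotides for the hallmarks of a
#' SINE tail: an oligo-T tract, a terminal tandem simple repeat, a `TC`
#' motif immediately upstream of the A/T-rich stretch, and overall
#' A/T-richness. When the printed element carries a terminal TSD copy (see
#' [find_tsd_terminal()]), that copy is trimmed first (`trim_tsd = TRUE`),
#' since the biological tail precedes the 3' TSD.
#'
#' The oligo-T tract is the longest run of >= 4 T whose span intersects the
#' tail window; its full run length is reported even where the run starts
#' upstream of the window. The terminal tandem repeat is the maximal repeat
#' of a primitive unit of 1-6 nt anchored at the (trimmed) 3' terminus with
#' at least 3 copies; the smallest primitive unit is preferred.
#'
#' @param seq element nucleotide string.
#' @param tail_window window at the 3' end inspected (nt).
#' @param trim_tsd drop a detected terminal TSD copy before tail analysis.
#' @return A `tail_annotation` list: `oligo_t` (`NULL` or
#'   `list(start, run_length)`, 0-based on the trimmed sequence),
#'   `repeat_unit` / `repeat_count` (or `NA` / 0), `tc_motif_present`,
#'   `tc_position`, `at_fraction_3prime`, `trimmed_tsd_len`.
#' @export
annotate_tail <- function(seq, tail_window = 50L, trim_tsd = TRUE) {
  seq <- clean_seq(seq)
  trimmed_len <- 0L
  if (trim_tsd) {
    tsd <- find_tsd_terminal(seq)
    if (!is.null(tsd) && tsd$right_offset == 0L) {
      trimmed_len <- tsd$length_nt
      seq <- substr(seq, 1L, nchar(seq) - trimmed_len)
    }
  }
  n <- nchar(seq)
  win_start <- max(0L, n - tail_window)  # 0-based

  # longest oligo-T run intersecting the window (>= 4 T)
  oligo_t <- NULL
  runs <- gregexpr("T{4,}", seq)[[1]]
  if (runs[1] != -1L) {
    r_start <- as.integer(runs) - 1L
    r_len <- attr(runs, "match.length")
    keep <- r_start + r_len > win_start
    if (any(keep)) {
      r_start <- r_start[keep]; r_len <- r_len[keep]
      o <- order(-r_len, -r_start)[1]  # longest, then 3'-most
      oligo_t <- list(start = r_start[o], run_length = r_len[o])
    }
  }

  tandem <- .terminal_tandem(seq)
  repeat_unit <- if (is.null(tandem)) NA_character_ else tandem$unit
  repeat_count <- if (is.null(tandem)) 0L else tandem$count

  # TC dinucleotide immediately upstream of the A/T-rich stretch
  anchor <- if (!is.null(oligo_t)) oligo_t$start else
    if (!is.null(tandem)) n - tandem$total else NA_integer_
  tc_present <- FALSE
  tc_position <- NA_integer_
  if (!is.na(anchor) && anchor >= 2L &&
      substr(seq, anchor - 1L, anchor) == "TC") {
    tc_present <- TRUE
    tc_position <- anchor - 2L
  }

  tail_chars <- strsplit(substr(seq, win_start + 1L, n), "")[[1]]
  at_fraction <- if (length(tail_chars)) {
    mean(tail_chars %in% c("A", "T"))
  } else NA_real_

  structure(list(oligo_t = oligo_t, repeat_unit = repeat_unit,
                 repeat_count = repeat_count, tc_motif_present = tc_present,
                 tc_position = tc_position,
                 at_fraction_3prime = at_fraction,
                 trimmed_tsd_len = trimmed_len),
            class = "tail_annotation")
}

#' Check descriptive terminal motifs
#'
#' Flags the presence and positions of the tRNA-style `CCA` end within the
#' 5' 120 nt and of the `ACATT` motif anywhere in the element. These are
#' descriptive annotations only; they play no role in classification.
#'
#' @param seq element nucleotide string.
#' @return list with `cca_present`, `cca_positions` (0-based starts within
#'   the 5' region), `acatt_present`, `acatt_positions`.
#' @export
check_terminal_motifs <- function(seq) {
  seq <- clean_seq(seq)
  head5 <- substr(seq, 1L, min(120L, nchar(seq)))
  cca <- gregexpr("CCA", head5, fixed = TRUE)[[1]]
  acatt <- gregexpr("ACATT", seq, fixed = TRUE)[[1]]
  list(
    cca_present = cca[1] != -1L,
    cca_positions = if (cca[1] == -1L) integer() else as.integer(cca) - 1L,
    acatt_present = acatt[1] != -1L,
    acatt_positions = if (acatt[1] == -1L) integer() else
      as.integer(acatt) - 1L
  )
}

#' @export
print.tsd_annotation <- function(x, ...) {
  cat(sprintf("tsd_annotation (%s): %s (%d bp), offsets %d/%d\n",
              x$mode, x$tsd_seq, x$length_nt, x$left_offset,
              x$right_offset))
  invisible(x)
}

#' @export
print.tail_annotation <- function(x, ...) {
  cat("tail_annotation:\n")
  if (!is.null(x$oligo_t)) {
    cat(sprintf("  oligo-T: %d nt at %d\n", x$oligo_t$run_length,
                x$oligo_t$start))
  }
  if (!is.na(x$repeat_unit)) {
    cat(sprintf("  terminal repeat: %s x %d\n", x$repeat_unit,
                x$repeat_count))
  }
  cat(sprintf("  TC motif: %s; A/T fraction: %.2f\n",
              if (x$tc_motif_present) "yes" else "no",
              x$at_fraction_3prime))
  invisible(x)
}
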