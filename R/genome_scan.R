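#' Genome scan parameters
#'
#' Parameters for seed-and-extend copy mapping and boundary extension.
#' Seeding uses exact 12-mers: elements are 140-500 nt, so at least one
#' intact 12-mer survives 10% divergence with high probability. Overlapping
#' or near-adjacent loci are merged so that copy counts refer to whole,
#' non-fragmented insertions. The boundary-extension defaults of 1,000 nt
#' upstream and 2,000 nt downstream follow the candidate-curation practice
#' of widening a masked repeat before re-inspection.
#'
#' @param seed_len exact k-mer seed length (>= 8).
#' @param min_identity minimum percent identity of an accepted locus.
#' @param min_coverage minimum fraction of the query element aligned.
#' @param merge_gap loci up to this many nt apart are merged.
#' @param extend_up,extend_down boundary extension (nt) used by
#'   [extend_boundaries()].
#' @return A `scan_params` list.
#' @export
scan_params <- function(seed_len = 12L, min_identity = 80,
                        min_coverage = 0.8, merge_gap = 50L,
                        extend_up = 1000L, extend_down = 2000L) {
  stopifnot(seed_len >= 8L, min_identity >= 0, min_identity <= 100,
            min_coverage >= 0, min_coverage <= 1, merge_gap >= 0)
  structure(list(seed_len = as.integer(seed_len),
                 min_identity = min_identity, min_coverage = min_coverage,
                 merge_gap = as.integer(merge_gap),
                 extend_up = as.integer(extend_up),
                 extend_down = as.integer(extend_down)),
            class = "scan_params")
}

# internal: 0-based start positions of all k-mers of 'seq' present in the
# k-mer set of 'query'
.seed_positions <- function(seq, query_kmers, k) {
  n <- nchar(seq)
  if (n < k) return(integer())
  starts <- 1:(n - k + 1L)
  kmers <- substring(seq, starts, starts + k - 1L)
  which(kmers %in% query_kmers) - 1L
}

.query_kmers <- function(query, k) {
  n <- nchar(query)
  if (n < k) return(character())
  starts <- 1:(n - k + 1L)
  unique(substring(query, starts, starts + k - 1L))
}

# internal: group sorted 0-based seed positions into clusters whose
# consecutive members are at most 'gap' apart
.cluster_seeds <- function(pos, gap) {
  if (!length(pos)) return(list())
  brk <- c(0L, which(diff(pos) > gap), length(pos))
  lapply(seq_len(length(brk) - 1L), function(i) {
    pos[(brk[i] + 1L):brk[i + 1L]]
  })
}

#' Map copies of an element across genome contigs
#'
#' Seed-and-extend homology search: exact k-mer seeds are collected on both
#' strands, clustered, and each cluster is extended by local alignment of
#' the element against a window around the cluster. Loci passing the
#' identity and query-coverage thresholds are kept; same-strand loci that
#' overlap or lie within `merge_gap` nt of each other are merged, keeping
#' the best identity and the union interval. Output is sorted by
#' `(contig, start)`.
#'
#' @param element a catalogue row or nucleotide string (the query).
#' @param genome a [sine_catalogue()] of contigs.
#' @param params a [scan_params()].
#' @param scheme a [scoring_scheme()].
#' @return loci data.frame: `contig`, `start`, `end` (0-based half-open),
#'   `strand`, `element_id`, `identity_pct`, `query_coverage`.
#' @export
map_copies <- function(element, genome, params = scan_params(),
                       scheme = scoring_scheme()) {
  stopifnot(inherits(genome, "sine_catalogue"))
  query <- candidate_seq(element)
  qid <- candidate_id(element)
  if (is.na(qid)) qid <- "query"
  k <- params$seed_len
  elen <- nchar(query)
  if (elen < k) stop("element shorter than the seed length")

  queries <- c("+" = query, "-" = revcomp(query))
  out <- locus_df()
  for (ci in seq_len(nrow(genome))) {
    cseq <- genome$seq[ci]
    clen <- nchar(cseq)
    for (strand in c("+", "-")) {
      q <- queries[[strand]]
      qk <- .query_kmers(q, k)
      if (!length(qk)) next
      seeds <- .seed_positions(cseq, qk, k)
      for (cl in .cluster_seeds(seeds, gap = elen)) {
        w_start <- max(0L, min(cl) - elen)
        w_end <- min(clen, max(cl) + k + elen)
        window <- substr(cseq, w_start + 1L, w_end)
        aln <- local_align(q, window, scheme)
        if (aln$aligned_length == 0L) next
        coverage <- (aln$query_interval[2] - aln$query_interval[1]) / elen
        if (aln$identity_pct >= params$min_identity &&
            coverage >= params$min_coverage) {
          out <- rbind(out, locus_df(
            contig = genome$id[ci],
            start = w_start + aln$subject_interval[1],
            end = w_start + aln$subject_interval[2],
            strand = strand, element_id = qid,
            identity_pct = aln$identity_pct, query_coverage = coverage))
        }
      }
    }
  }
  merge_loci(out, merge_gap = params$merge_gap)
}

#' Merge overlapping or near-adjacent loci
#'
#' Same-contig, same-strand loci whose intervals overlap or lie within
#' `merge_gap` nt are merged into one locus spanning their union; the
#' merged locus keeps the best identity and coverage among its members.
#'
#' @param loci loci data.frame.
#' @param merge_gap maximum gap (nt) across which loci are merged.
#' @return merged loci data.frame, sorted by `(contig, start)`.
#' @export
merge_loci <- function(loci, merge_gap = 50L) {
  if (!nrow(loci)) return(loci)
  validate_loci(loci)
  loci <- loci[order(loci$contig, loci$strand, loci$start), , drop = FALSE]
  merged <- list()
  cur <- loci[1, , drop = FALSE]
  for (i in seq_len(nrow(loci))[-1]) {
    row <- loci[i, , drop = FALSE]
    if (row$contig == cur$contig && row$strand == cur$strand &&
        row$start <= cur$end + merge_gap) {
      cur$end <- max(cur$end, row$end)
      cur$identity_pct <- max(cur$identity_pct, row$identity_pct)
      cur$query_coverage <- max(cur$query_coverage, row$query_coverage)
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- row
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, merged)
  out <- out[order(out$contig, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Extend the boundaries of a locus
#'
#' Widens a locus by `extend_up` nt upstream and `extend_down` nt
#' downstream in the element's own orientation: on the minus strand,
#' upstream means genomic rightward. The window is clipped to the contig.
#'
#' @param locus single-row loci data.frame.
#' @param genome a [sine_catalogue()] of contigs.
#' @param extend_up,extend_down extension lengths (nt).
#' @return list with `contig`, `start`, `end` (0-based half-open window on
#'   the forward strand), `strand`, `seq` (forward-strand window sequence)
#'   and `element_offset` (0-based offset of the original locus start
#'   within the window).
#' @export
extend_boundaries <- function(locus, genome, extend_up = 1000L,
                              extend_down = 2000L) {
  stopifnot(nrow(locus) == 1L)
  validate_loci(locus)
  ci <- match(locus$contig, genome$id)
  if (is.na(ci)) stop("locus contig not present in the genome")
  clen <- nchar(genome$seq[ci])
  stopifnot(locus$end <= clen)
  if (locus$strand == "+") {
    w_start <- max(0L, locus$start - extend_up)
    w_end <- min(clen, locus$end + extend_down)
  } else {
    w_start <- max(0L, locus$start - extend_down)
    w_end <- min(clen, locus$end + extend_up)
  }
  list(contig = locus$contig, start = w_start, end = w_end,
       strand = locus$strand,
       seq = substr(genome$seq[ci], w_start + 1L, w_end),
       element_offset = locus$start - w_start)
}

# internal: best-scoring tail signal in s within [from, to): oligo-T run
# (>= min_t T) or tandem simple repeat (unit 1-6, >= 3 copies, total >= 9).
# The most prominent signal (largest span, ties earliest) is taken as the
# element terminus; returns 0-based half-open interval or NULL.
.find_tail_signal <- function(s, from, to, min_t = 4L) {
  sub <- substr(s, from + 1L, to)
  cand <- list()
  runs <- gregexpr(sprintf("T{%d,}", min_t), sub)[[1]]
  if (runs[1] != -1L) {
    for (i in seq_along(runs)) {
      cand[[length(cand) + 1L]] <- c(start = as.integer(runs[i]) - 1L,
                                     len = attr(runs, "match.length")[i])
    }
  }
  reps <- gregexpr("(.{1,6}?)\\1{2,}", sub, perl = TRUE)[[1]]
  if (reps[1] != -1L) {
    for (i in seq_along(reps)) {
      len <- attr(reps, "match.length")[i]
      if (len >= 9L) {
        cand[[length(cand) + 1L]] <- c(start = as.integer(reps[i]) - 1L,
                                       len = len)
      }
    }
  }
  if (!length(cand)) return(NULL)
  m <- do.call(rbind, cand)
  o <- order(-m[, "len"], m[, "start"])[1]
  c(start = from + unname(m[o, "start"]),
    end = from + unname(m[o, "start"]) + unname(m[o, "len"]))
}

#' Discover candidate elements de novo by promoter-pair scanning
#'
#' Scans contigs (both strands) for type-2 promoter pairs: an A-box hit
#' followed by a B-box hit with a spacer within `spacer_bounds`. Each pair
#' nominates a candidate running from the A-box start to the end of the
#' most prominent downstream tail signal (an oligo-T tract of >= 4 T or a
#' tandem simple repeat) within `max_len` nt of the A-box start; pairs with
#' no tail signal are dropped. Flanks are then searched for a TSD with
#' [find_tsd_flanking()]. Candidates therefore always carry at least two
#' hallmarks (promoter pair plus tail, usually plus TSD). Overlapping
#' same-strand candidates are collapsed, keeping the first.
#'
#' @param genome a [sine_catalogue()] of contigs.
#' @param motif_models named list with `A_box` and `B_box`
#'   [motif_model()]s; defaults to the exact-consensus
#'   [strict_motif_models()], since degenerate models produce spurious
#'   pairs every few hundred bp on genome-scale input.
#' @param spacer_bounds A-to-B spacer range (nt).
#' @param max_len maximal candidate length measured from the A-box start;
#'   600 nt exceeds the longest described element (493 bp).
#' @param tsd_window flank width passed to [find_tsd_flanking()].
#' @return A [sine_catalogue()] of candidates (ids
#'   `cand_<contig>_<start>_<strand>`) with a `loci` attribute holding the
#'   candidate coordinates and hallmark summary (`tsd_seq`, `tsd_len`,
#'   `tail_start`, `tail_end` in forward-strand coordinates).
#' @export
discover_candidates <- function(genome, motif_models = strict_motif_models(),
                                spacer_bounds = c(10L, 150L),
                                max_len = 600L, tsd_window = 30L) {
  stopifnot(inherits(genome, "sine_catalogue"))
  rows <- list()
  for (ci in seq_len(nrow(genome))) {
    fwd <- genome$seq[ci]
    clen <- nchar(fwd)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") fwd else revcomp(fwd)
      a_hits <- scan_motif(s, motif_models$A_box, strands = "+")
      if (!nrow(a_hits)) next
      b_hits <- scan_motif(s, motif_models$B_box, strands = "+")
      if (!nrow(b_hits)) next
      for (ai in seq_len(nrow(a_hits))) {
        a <- a_hits[ai, ]
        sp <- b_hits$start - a$end
        bok <- which(sp >= spacer_bounds[1] & sp <= spacer_bounds[2])
        if (!length(bok)) next
        b <- b_hits[bok[1], ]
        tail <- .find_tail_signal(s, from = b$end,
                                  to = min(nchar(s), a$start + max_len))
        if (is.null(tail)) next
        c_start <- a$start
        c_end <- unname(tail["end"])
        # back to forward-strand coordinates
        if (strand == "+") {
          f_start <- c_start; f_end <- c_end
        } else {
          f_start <- clen - c_end; f_end <- clen - c_start
        }
        tsd <- find_tsd_flanking(fwd, c(f_start, f_end),
                                 window = tsd_window)
        rows[[length(rows) + 1L]] <- data.frame(
          contig = genome$id[ci], start = f_start, end = f_end,
          strand = strand,
          seq = substr(s, c_start + 1L, c_end),
          tsd_seq = if (is.null(tsd)) NA_character_ else tsd$tsd_seq,
          tsd_len = if (is.null(tsd)) NA_integer_ else tsd$length_nt,
          tail_start = if (strand == "+") unname(tail["start"]) else
            clen - unname(tail["end"]),
          tail_end = if (strand == "+") unname(tail["end"]) else
            clen - unname(tail["start"]),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    cat0 <- sine_catalogue(character(), character())
    attr(cat0, "loci") <- locus_df()
    return(cat0)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$contig, df$start, df$strand), , drop = FALSE]
  # collapse overlapping same-strand candidates, keeping the first
  keep <- rep(TRUE, nrow(df))
  last_end <- -1L
  last <- list(contig = "", strand = "", end = -1L)
  for (i in seq_len(nrow(df))) {
    if (df$contig[i] == last$contig && df$strand[i] == last$strand &&
        df$start[i] < last$end) {
      keep[i] <- FALSE
    } else {
      last <- list(contig = df$contig[i], strand = df$strand[i],
                   end = df$end[i])
    }
  }
  df <- df[keep, , drop = FALSE]
  ids <- sprintf("cand_%s_%d_%s", df$contig, df$start, df$strand)
  out <- sine_catalogue(ids, df$seq,
                        chromosome_tag = sprintf("%s:%d-%d(%s)", df$contig,
                                                 df$start, df$end,
                                                 df$strand))
  attr(out, "loci") <- df[, c("contig", "start", "end", "strand",
                              "tsd_seq", "tsd_len", "tail_start",
                              "tail_end")]
  out
}

#' Summarise the chromosomal distribution of mapped loci
#'
#' Counts loci per contig and, when a region labelling is supplied (e.g.
#' pericentromeric / subtelomeric / other), per label, together with a
#' one-sided binomial enrichment test per label: under the null each locus
#' falls into a label with probability equal to the label's share of the
#' total labelled length.
#'
#' @param loci loci data.frame.
#' @param region_bed optional data.frame of labelled regions (`contig`,
#'   `start`, `end`, `label`, 0-based half-open). Regions must not overlap.
#' @return list with `per_contig` (data.frame `contig`, `n`) and, when
#'   labels are given, `per_label` (data.frame `label`, `n`,
#'   `length_fraction`, `expected`, `p_enrichment`). Loci are assigned to
#'   the label containing their midpoint.
#' @export
distribution_report <- function(loci, region_bed = NULL) {
  validate_loci(loci)
  per_contig <- as.data.frame(table(contig = loci$contig),
                              stringsAsFactors = FALSE)
  names(per_contig) <- c("contig", "n")
  out <- list(per_contig = per_contig)
  if (is.null(region_bed)) return(out)

  stopifnot(all(c("contig", "start", "end", "label") %in% names(region_bed)))
  for (ct in unique(region_bed$contig)) {
    r <- region_bed[region_bed$contig == ct, , drop = FALSE]
    r <- r[order(r$start), , drop = FALSE]
    if (nrow(r) > 1L && any(r$start[-1] < r$end[-nrow(r)])) {
      stop("region intervals overlap on contig ", ct)
    }
  }
  lab_len <- tapply(region_bed$end - region_bed$start, region_bed$label, sum)
  total_len <- sum(lab_len)

  mid <- (loci$start + loci$end) / 2
  locus_label <- rep(NA_character_, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    r <- region_bed[region_bed$contig == loci$contig[i] &
                      region_bed$start <= mid[i] &
                      region_bed$end > mid[i], , drop = FALSE]
    if (nrow(r)) locus_label[i] <- r$label[1]
  }
  n_total <- sum(!is.na(locus_label))
  labels <- sort(unique(region_bed$label))
  per_label <- do.call(rbind, lapply(labels, function(lb) {
    n <- sum(locus_label == lb, na.rm = TRUE)
    frac <- unname(lab_len[lb]) / total_len
    p <- if (n_total > 0) {
      binom.test(n, n_total, p = frac, alternative = "greater")$p.value
    } else NA_real_
    data.frame(label = lb, n = n, length_fraction = frac,
               expected = n_total * frac, p_enrichment = p,
               stringsAsFactors = FALSE)
  }))
  out$per_label <- per_label
  out
}
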