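#' Motif model for RNA polymerase III promoter and terminator elements
#'
#' A motif model couples an IUPAC consensus with a mismatch allowance and an
#' optional search window. Windows are 0-based half-open intervals relative
#' to the element start and constrain where the motif *start* may fall;
#' windowed scans are forward-strand only (the window is defined on the
#' element's own orientation).
#'
#' @param name motif name, e.g. `"A_box"`, `"B_box"`, `"Bprime_box"`,
#'   `"type1_A"`, `"type1_IE"`, `"type1_C"`, `"terminator"`.
#' @param consensus IUPAC consensus string (length >= 4).
#' @param max_mismatch maximum number of mismatching positions
#'   (< consensus length).
#' @param search_window optional integer pair, 0-based half-open, relative
#'   to the element start.
#' @return A `motif_model` list.
#' @export
motif_model <- function(name, consensus, max_mismatch = 0L,
                        search_window = NULL) {
  consensus <- toupper(consensus)
  if (nchar(consensus) < 4L) stop("consensus must be at least 4 nt")
  if (grepl("[^ACGTRYSWKMBDHVN]", consensus)) {
    stop("consensus contains non-IUPAC characters")
  }
  if (max_mismatch >= nchar(consensus)) {
    stop("max_mismatch must be smaller than the consensus length")
  }
  if (!is.null(search_window)) {
    stopifnot(length(search_window) == 2L,
              search_window[1] >= 0, search_window[2] > search_window[1])
    search_window <- as.integer(search_window)
  }
  structure(list(name = name, consensus = consensus,
                 max_mismatch = as.integer(max_mismatch),
                 search_window = search_window),
            class = "motif_model")
}

# IUPAC nucleotide bit masks; two letters match when their masks intersect.
.iupac_masks <- local({
  m <- integer(128)
  codes <- c(A = 1L, C = 2L, G = 4L, T = 8L, R = 5L, Y = 10L, S = 6L,
             W = 9L, K = 12L, M = 3L, B = 14L, D = 13L, H = 11L, V = 7L,
             N = 15L)
  m[utf8ToInt(paste(names(codes), collapse = "")) ] <- unname(codes)
  m
})

seq_masks <- function(seq) {
  .iupac_masks[utf8ToInt(seq)]
}

# internal: forward-strand scan, returns data.frame(start, mismatches),
# 0-based starts. Degeneracy is one-way: a consensus ambiguity code matches
# any compatible subject base (N matches everything), but a subject N only
# matches a consensus N -- an unknown base is never evidence for a motif.
.scan_forward <- function(seq, consensus, max_mismatch) {
  n <- nchar(seq)
  m <- nchar(consensus)
  if (n < m) return(data.frame(start = integer(), mismatches = integer()))
  sm <- seq_masks(seq)
  sm[sm == 15L] <- 0L  # subject N
  cm <- seq_masks(consensus)
  npos <- n - m + 1L
  mm <- integer(npos)
  for (j in seq_len(m)) {
    if (cm[j] == 15L) next  # consensus N matches anything, even subject N
    mm <- mm + as.integer(bitwAnd(sm[j:(j + npos - 1L)], cm[j]) == 0L)
  }
  keep <- which(mm <= max_mismatch)
  data.frame(start = keep - 1L, mismatches = mm[keep])
}

#' Scan a sequence for a motif
#'
#' Reports every position where the consensus matches under IUPAC semantics
#' with at most `max_mismatch` mismatching positions. Without a search
#' window both strands are scanned (restrict with `strands`); a model with a
#' `search_window` is scanned on the forward strand only, within the window.
#' Overlapping hits are all reported; hits are sorted by `(start, strand)`.
#'
#' Minus-strand hits are reported in forward-strand coordinates;
#' `matched_seq` is always the strand-oriented sequence that matched the
#' consensus.
#'
#' @param seq nucleotide string to scan.
#' @param model a [motif_model()].
#' @param strands strands to scan (ignored when the model has a window).
#' @return data.frame with columns `model_name`, `start`, `end` (0-based
#'   half-open), `strand`, `mismatches`, `matched_seq`.
#' @examples
#' scan_motif("ACGTACGT", motif_model("any4", "NNNN"), strands = "+")
#' @export
scan_motif <- function(seq, model, strands = c("+", "-")) {
  stopifnot(inherits(model, "motif_model"))
  seq <- clean_seq(seq)
  m <- nchar(model$consensus)
  empty <- data.frame(model_name = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), matched_seq = character(),
                      stringsAsFactors = FALSE)
  if (!nzchar(seq) || nchar(seq) < m) return(empty)

  res <- list()
  if (!is.null(model$search_window)) {
    fw <- .scan_forward(seq, model$consensus, model$max_mismatch)
    w <- model$search_window
    fw <- fw[fw$start >= w[1] & fw$start < w[2], , drop = FALSE]
    if (nrow(fw)) {
      res[[1]] <- data.frame(model_name = model$name, start = fw$start,
                             end = fw$start + m, strand = "+",
                             mismatches = fw$mismatches,
                             stringsAsFactors = FALSE)
    }
  } else {
    if ("+" %in% strands) {
      fw <- .scan_forward(seq, model$consensus, model$max_mismatch)
      if (nrow(fw)) {
        res[["+"]] <- data.frame(model_name = model$name, start = fw$start,
                                 end = fw$start + m, strand = "+",
                                 mismatches = fw$mismatches,
                                 stringsAsFactors = FALSE)
      }
    }
    if ("-" %in% strands) {
      rc <- revcomp(seq)
      rv <- .scan_forward(rc, model$consensus, model$max_mismatch)
      if (nrow(rv)) {
        n <- nchar(seq)
        start <- n - (rv$start + m)
        res[["-"]] <- data.frame(model_name = model$name, start = start,
                                 end = start + m, strand = "-",
                                 mismatches = rv$mismatches,
                                 stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out <- out[order(out$start, out$strand), , drop = FALSE]
  fwd <- substr(rep(seq, nrow(out)), out$start + 1L, out$end)
  out$matched_seq <- ifelse(out$strand == "+", fwd, revcomp(fwd))
  rownames(out) <- NULL
  out
}

#' Default motif model sets
#'
#' Degenerate defaults for the internal RNA polymerase III promoter boxes
#' and terminator:
#' * type-2 (tRNA-type) A box `TRGCNNARYNNG` and B box `GKTTCGANNC`, each
#'   allowing 2 mismatches — generalisations of the tRNA internal-promoter
#'   consensus, since the boxes of tRNA-derived SINEs are degenerate;
#' * a B' box `GGTTCGATTCC` (exact), as observed downstream of the B box in
#'   AfuSINE2-1a;
#' * type-1 (5S-type) A, IE and C boxes with search windows `[45,75)`,
#'   `[65,90)` and `[75,110)` following canonical 5S internal-control-region
#'   geometry; their consensus strings `AYTYAARCCA`, `NTRGT` and
#'   `TAKAWRSNCC` are derived from the annotated boxes of the five packaged
#'   5S-derived elements (the published per-family logos are graphical and
#'   not machine-readable, so these serve as explicit stand-ins);
#' * the pol III termination signal `GCTTTTCG` (exact).
#'
#' All models are plain data and can be overridden per call.
#'
#' @return named list of [motif_model()] objects.
#' @export
default_motif_models <- function() {
  list(
    A_box = motif_model("A_box", "TRGCNNARYNNG", max_mismatch = 2L),
    B_box = motif_model("B_box", "GKTTCGANNC", max_mismatch = 2L),
    Bprime_box = motif_model("Bprime_box", "GGTTCGATTCC", max_mismatch = 0L),
    type1_A = motif_model("type1_A", "AYTYAARCCA", max_mismatch = 1L,
                          search_window = c(45L, 75L)),
    type1_IE = motif_model("type1_IE", "NTRGT", max_mismatch = 1L,
                           search_window = c(65L, 90L)),
    type1_C = motif_model("type1_C", "TAKAWRSNCC", max_mismatch = 2L,
                          search_window = c(75L, 110L)),
    terminator = motif_model("terminator", "GCTTTTCG", max_mismatch = 0L)
  )
}

#' Strict motif models for de-novo evidence
#'
#' The same type-2 consensus strings as [default_motif_models()] but with
#' no mismatch allowance. Degenerate models are appropriate for annotating
#' elements already supported by other evidence, but as *sole* evidence a
#' permissive A/B pair is worthless: with two mismatches allowed, chance
#' pairs arise every few hundred bp of random sequence. Classification's
#' promoter fallback and de-novo discovery therefore default to exact
#' matching.
#'
#' @return named list of [motif_model()] objects (`A_box`, `B_box`,
#'   `Bprime_box`, `terminator`).
#' @export
strict_motif_models <- function() {
  list(
    A_box = motif_model("A_box", "TRGCNNARYNNG", max_mismatch = 0L),
    B_box = motif_model("B_box", "GKTTCGANNC", max_mismatch = 0L),
    Bprime_box = motif_model("Bprime_box", "GGTTCGATTCC", max_mismatch = 0L),
    terminator = motif_model("terminator", "GCTTTTCG", max_mismatch = 0L)
  )
}

#' Published per-element promoter box sequences
#'
#' The exact A/B (and, for AfuSINE2-1a, B') box strings annotated on the
#' eight packaged tRNA-derived elements, and the A/IE/C box strings
#' annotated on the five 5S rRNA-derived elements. Useful as strict motif
#' models when re-annotating the packaged catalogue.
#'
#' @return nested named list: `$type2[[element]]` with `a`, `b` (and
#'   optionally `bprime`); `$type1[[element]]` with `a`, `ie`, `c`.
#' @export
table1_box_strings <- function() {
  list(
    type2 = list(
      "AfuSINE2-1a" = list(a = "TAGCGTAGTGG", b = "GATTGGTGACC",
                           bprime = "GGTTCGATTCC"),
      "AfuSINE2-3a" = list(a = "TGGAGGGACTGG", b = "GGTTGGATAAC"),
      "AfuSINE2-4a" = list(a = "TGCGGCCTGG", b = "GTAAGTATTCC"),
      "AfuSINE2-7a" = list(a = "TGGCGGAATGG", b = "TGTTCGAATAG"),
      "AfuSINE2-5d" = list(a = "AGGCTTAATGG", b = "TGTTCAATCCC"),
      "AfuSINE2-3c" = list(a = "TGGCAAAGCCGT", b = "AGTTCAAATCT"),
      "AfuSINE2-4c" = list(a = "TCCTGCAATGG", b = "GGATCGATTCC"),
      "AfuSINE2-7e" = list(a = "TAGCAGAGTGG", b = "GATTCGATTTC")
    ),
    type1 = list(
      "AfuSINE3-1a" = list(a = "ACTTAAGCCAGGTG", ie = "GTGGT",
                           c = "TAGAAAGCCCTTTTGCCT"),
      "AfuSINE3-3a" = list(a = "ACTTAAGCCACATG", ie = "GTGGT",
                           c = "TATATGCGCCCTTAATGG"),
      "AfuSINE3-3c" = list(a = "ACTTAAGCCACACG", ie = "GTGGT",
                           c = "TAGAAAGCCTTTTTGCTT"),
      "AfuSINE3-4a" = list(a = "ATTCAAACCAGTAT", ie = "TTGGT",
                           c = "TATATGCGTCCCTAAAGG"),
      "AfuSINE3-5c" = list(a = "ACTTAAGCCAGTAT", ie = "ATAGT",
                           c = "TATATGCACCCTTAAAGG")
    )
  )
}

# internal: best hit = fewest mismatches, then smallest start
.best_hit <- function(hits) {
  if (!nrow(hits)) return(NULL)
  hits[order(hits$mismatches, hits$start), , drop = FALSE][1, , drop = FALSE]
}

#' Annotate a type-2 (tRNA-type) internal pol III promoter
#'
#' Selects the highest-quality A-box and B-box hits (fewest mismatches,
#' then leftmost) such that the A box precedes the B box with a spacer
#' within `spacer_bounds`, then searches downstream of the chosen B box for
#' a B' box. Spacers count the nucleotides strictly between the end of the
#' upstream hit and the start of the downstream hit. Scanning is
#' forward-strand (element orientation).
#'
#' @param seq element nucleotide string.
#' @param a_model,b_model [motif_model()]s for the A and B boxes.
#' @param bprime_model optional [motif_model()] for the B' box.
#' @param spacer_bounds allowed A-to-B spacer range (nt), inclusive.
#' @return A `promoter_annotation` list with fields `promoter_type`
#'   (`"type2"` or `"none"`), `hits` (data.frame), `ab_spacer_nt`,
#'   `b_bprime_spacer_nt`.
#' @export
annotate_type2_promoter <- function(seq, a_model, b_model,
                                    bprime_model = NULL,
                                    spacer_bounds = c(10L, 150L)) {
  stopifnot(length(spacer_bounds) == 2L, spacer_bounds[1] <= spacer_bounds[2])
  seq <- clean_seq(seq)
  a_hits <- scan_motif(seq, a_model, strands = "+")
  b_hits <- scan_motif(seq, b_model, strands = "+")
  none <- structure(list(promoter_type = "none", hits = a_hits[0, ],
                         ab_spacer_nt = NA_integer_,
                         b_bprime_spacer_nt = NA_integer_),
                    class = "promoter_annotation")
  if (!nrow(a_hits) || !nrow(b_hits)) return(none)

  # enumerate valid pairs; rank by total mismatches, then leftmost A, then B
  pairs <- expand.grid(ai = seq_len(nrow(a_hits)), bi = seq_len(nrow(b_hits)))
  spacer <- b_hits$start[pairs$bi] - a_hits$end[pairs$ai]
  ok <- spacer >= spacer_bounds[1] & spacer <= spacer_bounds[2]
  if (!any(ok)) return(none)
  pairs <- pairs[ok, , drop = FALSE]
  spacer <- spacer[ok]
  mmsum <- a_hits$mismatches[pairs$ai] + b_hits$mismatches[pairs$bi]
  pick <- order(mmsum, a_hits$start[pairs$ai], b_hits$start[pairs$bi])[1]
  a <- a_hits[pairs$ai[pick], , drop = FALSE]
  b <- b_hits[pairs$bi[pick], , drop = FALSE]

  hits <- rbind(a, b)
  b_bprime <- NA_integer_
  if (!is.null(bprime_model)) {
    bp_hits <- scan_motif(seq, bprime_model, strands = "+")
    bp_hits <- bp_hits[bp_hits$start >= b$end, , drop = FALSE]
    bp <- .best_hit(bp_hits)
    if (!is.null(bp)) {
      hits <- rbind(hits, bp)
      b_bprime <- bp$start - b$end
    }
  }
  rownames(hits) <- NULL
  structure(list(promoter_type = "type2", hits = hits,
                 ab_spacer_nt = as.integer(spacer[pick]),
                 b_bprime_spacer_nt = as.integer(b_bprime)),
            class = "promoter_annotation")
}

#' Annotate a type-1 (5S-type) internal pol III promoter
#'
#' Takes the best hit per box (A, IE, C) within its search window and calls
#' `type1` when at least two of the three boxes are found in order
#' A < IE < C (comparing the boxes that were found).
#'
#' @param seq element nucleotide string.
#' @param a_model,ie_model,c_model [motif_model()]s; each needs a
#'   `search_window` unless `window_layout` supplies one.
#' @param window_layout optional named list (`A`, `IE`, `C`) of 0-based
#'   half-open windows overriding the models' own windows.
#' @return A `promoter_annotation` with `promoter_type` `"type1"` or
#'   `"none"` and the per-box hits found.
#' @export
annotate_type1_promoter <- function(seq, a_model, ie_model, c_model,
                                    window_layout = NULL) {
  seq <- clean_seq(seq)
  models <- list(A = a_model, IE = ie_model, C = c_model)
  if (!is.null(window_layout)) {
    for (nm in names(models)) {
      if (!is.null(window_layout[[nm]])) {
        models[[nm]] <- motif_model(models[[nm]]$name,
                                    models[[nm]]$consensus,
                                    models[[nm]]$max_mismatch,
                                    window_layout[[nm]])
      }
    }
  }
  if (any(vapply(models, function(m) is.null(m$search_window), logical(1)))) {
    stop("each type-1 box model needs a search window")
  }
  best <- lapply(models, function(m) .best_hit(scan_motif(seq, m)))
  found <- !vapply(best, is.null, logical(1))
  hits <- do.call(rbind, best[found])
  if (is.null(hits)) hits <- scan_motif(seq, models$A)[0, ]
  rownames(hits) <- NULL
  ordered <- TRUE
  if (sum(found) >= 2L) {
    starts <- vapply(best[found], function(h) h$start, numeric(1))
    ordered <- all(diff(starts) > 0)  # box windows are ordered A, IE, C
  }
  type <- if (sum(found) >= 2L && ordered) "type1" else "none"
  structure(list(promoter_type = type, hits = hits,
                 ab_spacer_nt = NA_integer_,
                 b_bprime_spacer_nt = NA_integer_),
            class = "promoter_annotation")
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat("promoter_annotation:", x$promoter_type, "\n")
  if (nrow(x$hits)) print(x$hits, row.names = FALSE)
  if (!is.na(x$ab_spacer_nt)) cat("A-B spacer:", x$ab_spacer_nt, "nt\n")
  if (!is.na(x$b_bprime_spacer_nt)) {
    cat("B-B' spacer:", x$b_bprime_spacer_nt, "nt\n")
  }
  invisible(x)
}
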