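#' Pipeline configuration
#'
#' One declarative object holding every threshold the pipeline uses, with
#' the published values as defaults: the 60%-identity / 60-nt-overlap head
#' rule, 4-20 bp terminal TSD search, a 50-nt tail window, 10-150 nt A-to-B
#' spacer bounds, the true-gene filter at 90% identity / 90% coverage, and
#' the seed-and-extend scan parameters. Every parameter is echoed to the
#' run log, so a run is fully auditable.
#'
#' @param thresholds a [classification_thresholds()].
#' @param scheme a [scoring_scheme()].
#' @param scan a [scan_params()].
#' @param motif_models named [motif_model()] list used for hallmark
#'   annotation, see [default_motif_models()].
#' @param classify_motif_models model list used as promoter evidence in
#'   classification; defaults to the exact-consensus
#'   [strict_motif_models()].
#' @param tsd list with `min_len`, `max_len`, `max_end_offset` for
#'   [find_tsd_terminal()].
#' @param tail_window 3' window for [annotate_tail()].
#' @param spacer_bounds A-to-B spacer bounds (nt).
#' @param true_gene list with `id_threshold` (percent) and
#'   `coverage_threshold` (fraction) for [true_gene_filter()].
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(thresholds = classification_thresholds(),
                            scheme = scoring_scheme(),
                            scan = scan_params(),
                            motif_models = default_motif_models(),
                            classify_motif_models = strict_motif_models(),
                            tsd = list(min_len = 4L, max_len = 20L,
                                       max_end_offset = 0L),
                            tail_window = 50L,
                            spacer_bounds = c(10L, 150L),
                            true_gene = list(id_threshold = 90,
                                             coverage_threshold = 0.9)) {
  structure(list(thresholds = thresholds, scheme = scheme, scan = scan,
                 motif_models = motif_models,
                 classify_motif_models = classify_motif_models, tsd = tsd,
                 tail_window = tail_window, spacer_bounds = spacer_bounds,
                 true_gene = true_gene),
            class = "pipeline_config")
}

# internal: flatten the configuration into "key = value" log lines
.config_log_lines <- function(config) {
  th <- config$thresholds
  sc <- config$scheme
  sp <- config$scan
  c(sprintf("id_threshold = %s", th$id_threshold),
    sprintf("overlap_threshold = %s", th$overlap_threshold),
    sprintf("head_len = %s", th$head_len),
    sprintf("match = %s; mismatch = %s; gap_open = %s; gap_extend = %s",
            sc$match, sc$mismatch, sc$gap_open, sc$gap_extend),
    sprintf("seed_len = %s; min_identity = %s; min_coverage = %s; merge_gap = %s",
            sp$seed_len, sp$min_identity, sp$min_coverage, sp$merge_gap),
    sprintf("extend_up = %s; extend_down = %s", sp$extend_up, sp$extend_down),
    sprintf("tsd_min_len = %s; tsd_max_len = %s; tsd_max_end_offset = %s",
            config$tsd$min_len, config$tsd$max_len,
            config$tsd$max_end_offset),
    sprintf("tail_window = %s", config$tail_window),
    sprintf("spacer_bounds = %s..%s", config$spacer_bounds[1],
            config$spacer_bounds[2]),
    sprintf("true_gene_id_threshold = %s; true_gene_coverage_threshold = %s",
            config$true_gene$id_threshold,
            config$true_gene$coverage_threshold),
    vapply(config$motif_models, function(m) {
      sprintf("motif %s = %s (max_mismatch %d%s)", m$name, m$consensus,
              m$max_mismatch,
              if (is.null(m$search_window)) "" else
                sprintf(", window [%d,%d)", m$search_window[1],
                        m$search_window[2]))
    }, character(1), USE.NAMES = FALSE),
    vapply(config$classify_motif_models, function(m) {
      sprintf("classify motif %s = %s (max_mismatch %d)", m$name,
              m$consensus, m$max_mismatch)
    }, character(1), USE.NAMES = FALSE))
}

#' Run the full annotation pipeline
#'
#' Orchestrates the desk analysis of a candidate set: discard true genes
#' ([true_gene_filter()]), annotate structural hallmarks (terminal TSD,
#' type-2 and type-1 promoters, terminator, tail, terminal motifs),
#' classify each element ([classify_element()]) and, when a genome is
#' supplied, map its copies ([map_copies()]). The run is deterministic
#' given its inputs and configuration, and every threshold used is written
#' to the log.
#'
#' @param candidates candidate [sine_catalogue()] (non-empty).
#' @param refs named list of reference catalogues: `trna`, `r5s`,
#'   optionally `line`. At least one of `trna` / `r5s` is required.
#' @param genome optional [sine_catalogue()] of contigs for copy mapping.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, writes
#'   `annotations.tsv`, `classification.tsv` and (with a genome)
#'   `loci.gff3` + `loci.bed`.
#' @param log_file optional path for the run log (always also emitted as
#'   messages).
#' @return invisibly, a `sine_annotation_set`: list with `annotations` (one
#'   `sine_annotation` per retained candidate), `discarded` (ids removed by
#'   the true-gene filter), `loci` (combined loci data.frame) and `table`
#'   (the flat annotation data.frame, see [annotation_table()]).
#' @export
run_pipeline <- function(candidates, refs = list(), genome = NULL,
                         config = pipeline_config(), out_dir = NULL,
                         log_file = NULL) {
  if (!inherits(candidates, "sine_catalogue") || nrow(candidates) == 0L) {
    stop(sine_condition("sinescout_config_error",
                        "candidates must be a non-empty sine_catalogue"))
  }
  has_trna <- inherits(refs$trna, "sine_catalogue") && nrow(refs$trna) > 0
  has_5s <- inherits(refs$r5s, "sine_catalogue") && nrow(refs$r5s) > 0
  if (!has_trna && !has_5s) {
    stop(sine_condition("sinescout_config_error",
      paste("classification requested without reference sets;",
            "supply refs$trna and/or refs$r5s (FASTA via read_fasta())")))
  }

  log_lines <- c("sinescout run", .config_log_lines(config))
  emit <- function(msg) {
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  for (l in .config_log_lines(config)) message(l)

  gene_refs <- do.call(rbind, Filter(Negate(is.null),
                                     list(refs$trna, refs$r5s)))
  class(gene_refs) <- c("sine_catalogue", "data.frame")

  keep <- vapply(seq_len(nrow(candidates)), function(i) {
    true_gene_filter(candidates[i, ], gene_refs,
                     full_len_id_threshold = config$true_gene$id_threshold,
                     coverage_threshold = config$true_gene$coverage_threshold,
                     scheme = config$scheme)
  }, logical(1))
  discarded <- candidates$id[!keep]
  if (length(discarded)) {
    emit(paste("true-gene filter discarded:",
               paste(discarded, collapse = ", ")))
  }
  retained <- candidates[keep, , drop = FALSE]

  if (nrow(retained) == 0L) {
    warning("no candidates left after the true-gene filter")
    emit("0 candidates retained")
    result <- structure(list(annotations = list(), discarded = discarded,
                             loci = locus_df(),
                             table = annotation_table(list())),
                        class = "sine_annotation_set")
    .write_outputs(result, out_dir, genome)
    .write_log(log_lines, log_file)
    return(invisible(result))
  }

  mm <- config$motif_models
  annotations <- lapply(seq_len(nrow(retained)), function(i) {
    rec <- retained[i, , drop = FALSE]
    seq <- rec$seq
    tsd <- find_tsd_terminal(seq, min_len = config$tsd$min_len,
                             max_len = config$tsd$max_len,
                             max_end_offset = config$tsd$max_end_offset)
    prom2 <- annotate_type2_promoter(seq, mm$A_box, mm$B_box, mm$Bprime_box,
                                     spacer_bounds = config$spacer_bounds)
    prom1 <- annotate_type1_promoter(seq, mm$type1_A, mm$type1_IE,
                                     mm$type1_C)
    promoter <- if (prom2$promoter_type == "type2") prom2 else
      if (prom1$promoter_type == "type1") prom1 else prom2
    term_hits <- scan_motif(seq, mm$terminator, strands = "+")
    tail <- annotate_tail(seq, tail_window = config$tail_window)
    motifs <- check_terminal_motifs(seq)
    cls <- classify_element(rec, refs_trna = refs$trna, refs_5s = refs$r5s,
                            thresholds = config$thresholds,
                            motif_models = config$classify_motif_models,
                            scheme = config$scheme,
                            spacer_bounds = config$spacer_bounds)
    if (!is.null(refs$line) && nrow(refs$line) > 0) {
      cls$line_3prime_match <- line_3prime_similarity(rec, refs$line,
                                                      scheme = config$scheme)
    }
    loci <- if (!is.null(genome)) {
      map_copies(rec, genome, params = config$scan, scheme = config$scheme)
    } else {
      locus_df()
    }
    structure(list(record = rec, tsd = tsd, promoter = promoter,
                   tail = tail,
                   terminator_hit = .best_hit(term_hits),
                   classification = cls, loci = loci),
              class = "sine_annotation")
  })
  names(annotations) <- retained$id

  loci <- do.call(rbind, c(list(locus_df()),
                           lapply(annotations, `[[`, "loci")))
  rownames(loci) <- NULL
  tab <- annotation_table(annotations)
  emit(sprintf("%d candidate(s) annotated; %d classified SINE3, %d SINE2",
               nrow(tab), sum(tab$family == "SINE3"),
               sum(tab$family == "SINE2")))

  result <- structure(list(annotations = annotations, discarded = discarded,
                           loci = loci, table = tab),
                      class = "sine_annotation_set")
  .write_outputs(result, out_dir, genome)
  .write_log(log_lines, log_file)
  invisible(result)
}

.write_log <- function(lines, log_file) {
  if (!is.null(log_file)) writeLines(lines, log_file)
  invisible(NULL)
}

.write_outputs <- function(result, out_dir, genome) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write.table(result$table, file.path(out_dir, "annotations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cls_tab <- result$table[, c("id", "family", "origin_call", "head_id_pct",
                              "overlap_nt", "promoter_type")]
  write.table(cls_tab, file.path(out_dir, "classification.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(genome)) {
    write_gff3(result$loci, file.path(out_dir, "loci.gff3"))
    write_bed(result$loci, file.path(out_dir, "loci.bed"))
  }
  invisible(NULL)
}

#' Flatten annotations into a report table
#'
#' One row per annotated element with the TSV report columns: id, length,
#' family and origin call, head identity and overlap, promoter type, TSD
#' length and sequence, tail repeat unit and count, oligo-T length, TC
#' motif flag, 3' A/T fraction, terminator presence and copy count.
#'
#' @param annotations list of `sine_annotation` objects (or a
#'   `sine_annotation_set`).
#' @return data.frame.
#' @export
annotation_table <- function(annotations) {
  if (inherits(annotations, "sine_annotation_set")) {
    annotations <- annotations$annotations
  }
  if (!length(annotations)) {
    return(data.frame(id = character(), length_bp = integer(),
                      family = character(), origin_call = character(),
                      head_id_pct = numeric(), overlap_nt = integer(),
                      promoter_type = character(), tsd_len = integer(),
                      tsd_seq = character(), tail_unit = character(),
                      tail_count = integer(), oligoT_len = integer(),
                      tc_motif = logical(), at_fraction = numeric(),
                      terminator = logical(), n_loci = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(annotations, function(a) {
    cls <- a$classification
    head_aln <- cls$head_alignment
    data.frame(
      id = a$record$id,
      length_bp = a$record$length_bp,
      family = cls$family,
      origin_call = cls$origin_call,
      head_id_pct = if (is.null(head_aln)) NA_real_ else
        round(head_aln$identity_pct, 2),
      overlap_nt = if (is.null(head_aln)) NA_integer_ else head_aln$overlap_nt,
      promoter_type = a$promoter$promoter_type,
      tsd_len = if (is.null(a$tsd)) NA_integer_ else a$tsd$length_nt,
      tsd_seq = if (is.null(a$tsd)) NA_character_ else a$tsd$tsd_seq,
      tail_unit = a$tail$repeat_unit,
      tail_count = a$tail$repeat_count,
      oligoT_len = if (is.null(a$tail$oligo_t)) NA_integer_ else
        a$tail$oligo_t$run_length,
      tc_motif = a$tail$tc_motif_present,
      at_fraction = round(a$tail$at_fraction_3prime, 3),
      terminator = !is.null(a$terminator_hit),
      n_loci = nrow(a$loci),
      stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' @export
print.sine_annotation_set <- function(x, ...) {
  cat("sine_annotation_set:", length(x$annotations), "annotated,",
      length(x$discarded), "discarded\n")
  if (nrow(x$table)) {
    print(x$table[, c("id", "family", "origin_call", "promoter_type",
                      "tsd_len", "n_loci")], row.names = FALSE)
  }
  invisible(x)
}

#' @export
print.sine_annotation <- function(x, ...) {
  cat("sine_annotation:", x$record$id, "(", x$record$length_bp, "bp )\n")
  print(x$classification)
  if (!is.null(x$tsd)) print(x$tsd)
  print(x$tail)
  cat("loci mapped:", nrow(x$loci), "\n")
  invisible(x)
}
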