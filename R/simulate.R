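#' Element template for the genome simulator
#'
#' Describes the master copy of a planted element:
#' `[pad][A box][spacer][B box][body][tail]`, i.e. a type-2 internal
#' promoter near the 5' end followed by an unrelated body and a tail
#' signal. The default box strings are the intact boxes observed on the
#' youngest fully-featured element of the packaged catalogue. Alternatively
#' a `head_seq` (e.g. a tRNA gene) can replace the pad/box block entirely.
#'
#' @param a_box,b_box concrete box sequences planted into the element.
#' @param a_offset 0-based offset of the A box from the element start; kept
#'   small so that a discovered candidate anchored at the A box starts
#'   within a few nt of the true element start.
#' @param spacer nucleotides strictly between the A-box end and B-box
#'   start.
#' @param body_len length of the random body between the B box and tail.
#' @param tail tail specification: `list(kind = "polyT", length = 10)` or
#'   `list(kind = "repeat", unit = "ACT", n = 7)`.
#' @param head_seq optional fixed head sequence replacing pad + boxes.
#' @return an `element_template` list.
#' @export
element_template <- function(a_box = "TAGCGTAGTGG", b_box = "GATTGGTGACC",
                             a_offset = 6L, spacer = 30L, body_len = 120L,
                             tail = list(kind = "polyT", length = 10L),
                             head_seq = NULL) {
  stopifnot(a_offset >= 0L, spacer >= 0L, body_len >= 0L)
  stopifnot(tail$kind %in% c("polyT", "repeat"))
  structure(list(a_box = toupper(a_box), b_box = toupper(b_box),
                 a_offset = as.integer(a_offset), spacer = as.integer(spacer),
                 body_len = as.integer(body_len), tail = tail,
                 head_seq = head_seq),
            class = "element_template")
}

#' Simulation configuration
#'
#' Conditions for [simulate_genome()]. Defaults mirror the biology the
#' annotation stages assume: i.i.d. background at a given GC content,
#' elements with an intact type-2 promoter and an oligo-T tail, target site
#' duplications of 4-14 bp (the published range), and point-substitution
#' divergence between copies of a family. Indels are not simulated.
#'
#' @param seed integer RNG seed; identical seeds give byte-identical
#'   output.
#' @param contig_lengths integer vector of contig lengths (nt).
#' @param gc_content background GC fraction.
#' @param n_elements number of distinct element families (master copies).
#' @param copies_per_element copies planted per family.
#' @param tsd_len_range inclusive range of TSD lengths.
#' @param divergence per-site substitution probability applied to each
#'   planted copy.
#' @param template an [element_template()].
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L, contig_lengths = 50000L,
                       gc_content = 0.5, n_elements = 5L,
                       copies_per_element = 1L,
                       tsd_len_range = c(4L, 14L), divergence = 0,
                       template = element_template()) {
  stopifnot(gc_content >= 0, gc_content <= 1,
            divergence >= 0, divergence <= 1,
            all(contig_lengths > 0), n_elements >= 0,
            copies_per_element >= 1,
            tsd_len_range[1] >= 1, tsd_len_range[2] >= tsd_len_range[1])
  structure(list(seed = as.integer(seed),
                 contig_lengths = as.integer(contig_lengths),
                 gc_content = gc_content, n_elements = as.integer(n_elements),
                 copies_per_element = as.integer(copies_per_element),
                 tsd_len_range = as.integer(tsd_len_range),
                 divergence = divergence, template = template),
            class = "sim_config")
}

# internal: i.i.d. background sequence at the requested GC content
.random_seq <- function(n, gc = 0.5) {
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# internal: instantiate the master element of one family
.build_master <- function(template, gc) {
  tail_seq <- switch(template$tail$kind,
    polyT = strrep("T", template$tail$length),
    "repeat" = strrep(template$tail$unit, template$tail$n))
  if (!is.null(template$head_seq)) {
    head <- toupper(template$head_seq)
    a_off <- NA_integer_
    b_off <- NA_integer_
  } else {
    head <- paste0(.random_seq(template$a_offset, gc), template$a_box,
                   .random_seq(template$spacer, gc), template$b_box)
    a_off <- template$a_offset
    b_off <- template$a_offset + nchar(template$a_box) + template$spacer
  }
  seq <- paste0(head, .random_seq(template$body_len, gc), tail_seq)
  list(seq = seq, a_offset = a_off, b_offset = b_off,
       tail_len = nchar(tail_seq))
}

#' Point-mutate a sequence
#'
#' Substitutes each position independently with probability `rate`, always
#' to a different base (uniform over the three alternatives). No indels.
#'
#' @param seq nucleotide string.
#' @param rate per-site substitution probability in `[0, 1]`.
#' @param seed optional seed making the call self-contained and
#'   reproducible; `NULL` draws from the current RNG stream.
#' @return the mutated sequence.
#' @export
mutate_seq <- function(seq, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) {
    return(withr::with_seed(seed, mutate_seq(seq, rate, seed = NULL)))
  }
  chars <- strsplit(clean_seq(seq), "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      alt <- bases[bases != chars[i]]
      chars[i] <- alt[sample.int(length(alt), 1L)]
    }
  }
  paste(chars, collapse = "")
}

#' Simulate a genome with planted elements and ground truth
#'
#' Generates i.i.d. background contigs and plants element copies with the
#' full hallmark set: each insertion duplicates its target site, so the
#' planted copy is flanked by two identical direct repeats drawn from the
#' background (the TSD); promoter boxes sit at the template offsets; the
#' tail follows the template specification. Copies are point-mutated at the
#' configured divergence; at divergence 0 every hallmark is intact by
#' construction. Minus-strand insertions plant the reverse complement of
#' the copy (the TSD remains a direct repeat, as in real insertions).
#'
#' @param config a [sim_config()].
#' @return list with `genome` (a [sine_catalogue()] of contigs, ids
#'   `contig1`, `contig2`, ...), `masters` (a [sine_catalogue()] of the
#'   undiverged master element of each family, ids `elem1`, `elem2`, ...;
#'   the natural query for copy mapping) and `truth`, a data.frame with
#'   one row per planted copy: `element_id`, `copy`, `contig`, `start`, `end` (0-based
#'   half-open, element only, TSDs excluded), `strand`, `tsd_seq`,
#'   `a_offset`, `b_offset` (element-strand offsets of the planted boxes),
#'   `tail_len` and `seq` (the planted, possibly mutated, element-strand
#'   sequence).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_genome_impl(config))
}

.simulate_genome_impl <- function(config) {
  tmpl <- config$template
  gc <- config$gc_content
  masters <- lapply(seq_len(config$n_elements), function(i) {
    .build_master(tmpl, gc)
  })
  elem_lens <- vapply(masters, function(m) nchar(m$seq), integer(1))
  if (length(elem_lens) && any(elem_lens >= min(config$contig_lengths))) {
    stop(sine_condition("sinescout_config_error",
                        "element longer than the shortest contig"))
  }

  backgrounds <- lapply(config$contig_lengths, .random_seq, gc = gc)
  n_contig <- length(backgrounds)

  # one insertion job per copy
  jobs <- if (config$n_elements > 0) {
    expand.grid(elem = seq_len(config$n_elements),
                copy = seq_len(config$copies_per_element))
  } else {
    data.frame(elem = integer(), copy = integer())
  }
  jobs$contig <- if (nrow(jobs)) {
    sample.int(n_contig, nrow(jobs), replace = TRUE)
  } else integer()

  truth <- list()
  contigs <- character(n_contig)
  for (ci in seq_len(n_contig)) {
    bg <- backgrounds[[ci]]
    bg_len <- nchar(bg)
    mine <- jobs[jobs$contig == ci, , drop = FALSE]
    if (!nrow(mine)) {
      contigs[ci] <- bg
      next
    }
    max_elen <- max(elem_lens[mine$elem])
    margin <- max_elen + 2L * config$tsd_len_range[2] + 100L
    # rejection-sample insertion points with a safety margin
    pts <- NULL
    for (try in 1:200) {
      cand <- sort(sample.int(bg_len - margin, nrow(mine)))
      if (nrow(mine) == 1L || all(diff(cand) >= margin)) {
        pts <- cand
        break
      }
    }
    if (is.null(pts)) {
      stop(sine_condition("sinescout_config_error",
                          "cannot place elements: contig too crowded"))
    }
    pieces <- character()
    cursor <- 0L  # 0-based position in the background consumed so far
    shift <- 0L
    for (ji in seq_len(nrow(mine))) {
      p <- pts[ji]  # TSD source = background [p, p + L)
      L <- if (config$tsd_len_range[1] == config$tsd_len_range[2]) {
        config$tsd_len_range[1]
      } else {
        sample(seq(config$tsd_len_range[1], config$tsd_len_range[2]), 1L)
      }
      tsd <- substr(bg, p + 1L, p + L)
      strand <- sample(c("+", "-"), 1L)
      m <- masters[[mine$elem[ji]]]
      copy_seq <- mutate_seq(m$seq, config$divergence)
      planted <- if (strand == "+") copy_seq else revcomp(copy_seq)
      # background up to and including the first TSD copy, then the
      # element, then resume from p so the TSD is emitted again
      pieces <- c(pieces, substr(bg, cursor + 1L, p + L), planted)
      cursor <- p
      start <- p + L + shift
      truth[[length(truth) + 1L]] <- data.frame(
        element_id = paste0("elem", mine$elem[ji]), copy = mine$copy[ji],
        contig = paste0("contig", ci), start = start,
        end = start + nchar(planted), strand = strand, tsd_seq = tsd,
        a_offset = m$a_offset, b_offset = m$b_offset,
        tail_len = m$tail_len, seq = copy_seq, stringsAsFactors = FALSE)
      shift <- shift + nchar(planted) + L
    }
    pieces <- c(pieces, substr(bg, cursor + 1L, bg_len))
    contigs[ci] <- paste(pieces, collapse = "")
  }

  genome <- sine_catalogue(paste0("contig", seq_len(n_contig)), contigs)
  truth <- if (length(truth)) {
    do.call(rbind, truth)
  } else {
    data.frame(element_id = character(), copy = integer(),
               contig = character(), start = integer(), end = integer(),
               strand = character(), tsd_seq = character(),
               a_offset = integer(), b_offset = integer(),
               tail_len = integer(), seq = character(),
               stringsAsFactors = FALSE)
  }
  truth <- truth[order(truth$contig, truth$start), , drop = FALSE]
  rownames(truth) <- NULL
  master_ids <- if (config$n_elements > 0) {
    paste0("elem", seq_len(config$n_elements))
  } else {
    character()
  }
  masters_cat <- sine_catalogue(master_ids,
                                vapply(masters, `[[`, character(1), "seq"))
  list(genome = genome, masters = masters_cat, truth = truth)
}

#' Write simulation outputs to files
#'
#' Serialises a [simulate_genome()] result as a genome FASTA plus a truth
#' GFF3 of the planted element intervals.
#'
#' @param sim result of [simulate_genome()].
#' @param fasta_path,gff3_path output paths.
#' @return invisibly, a list of the two paths.
#' @export
write_simulation <- function(sim, fasta_path, gff3_path) {
  write_fasta(sim$genome, fasta_path)
  loci <- locus_df(contig = sim$truth$contig, start = sim$truth$start,
                   end = sim$truth$end, strand = sim$truth$strand,
                   element_id = sim$truth$element_id,
                   identity_pct = rep(100, nrow(sim$truth)),
                   query_coverage = rep(1, nrow(sim$truth)))
  write_gff3(loci, gff3_path)
  invisible(list(fasta = fasta_path, gff3 = gff3_path))
}
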