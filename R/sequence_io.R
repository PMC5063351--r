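#' Build an element catalogue
#'
#' A catalogue is the package's container for a set of nucleotide records:
#' candidate elements, reference genes (tRNAs, 5S rRNAs, LINE 3'-UTRs) or
#' genome contigs. It is a plain `data.frame` with class `sine_catalogue`
#' and columns `id`, `seq`, `origin_label`, `chromosome_tag`, `length_bp`.
#'
#' Sequences are normalised to uppercase and any character outside
#' `A`, `C`, `G`, `T` is coerced to `N`. `N` never matches a motif position
#' (except through IUPAC degeneracy) and counts as a mismatch in alignments.
#'
#' @param id character vector of unique record names.
#' @param seq character vector of nucleotide sequences.
#' @param origin_label optional origin annotation per record, e.g.
#'   `"tRNA/Arg"` or `"5S rRNA"`; `NA` when unknown.
#' @param chromosome_tag optional free-text location tag per record.
#' @return A `sine_catalogue` data.frame.
#' @examples
#' sine_catalogue(c("a", "b"), c("ACGT", "ggna"))
#' @export
sine_catalogue <- function(id, seq, origin_label = NA_character_,
                           chromosome_tag = NA_character_) {
  id <- as.character(id)
  seq <- clean_seq(as.character(seq))
  if (length(id) != length(seq)) {
    stop("'id' and 'seq' must have equal length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate record id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (length(seq) && any(!nzchar(seq))) {
    stop("empty sequence for record(s): ",
         paste(id[!nzchar(seq)], collapse = ", "))
  }
  out <- data.frame(
    id = id,
    seq = seq,
    origin_label = rep_len(as.character(origin_label), length(id)),
    chromosome_tag = rep_len(as.character(chromosome_tag), length(id)),
    length_bp = nchar(seq),
    stringsAsFactors = FALSE
  )
  class(out) <- c("sine_catalogue", "data.frame")
  out
}

#' Normalise a nucleotide string
#'
#' Uppercases and maps every character outside `{A,C,G,T}` to `N`.
#'
#' @param x character vector of sequences.
#' @return character vector of cleaned sequences.
#' @export
clean_seq <- function(x) {
  x <- toupper(x)
  gsub("[^ACGT]", "N", x)
}

#' Reverse-complement a nucleotide string
#'
#' @param x character vector over `{A,C,G,T,N}`.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

#' Read a FASTA file into a catalogue
#'
#' The record id is the header token up to the first whitespace; the rest of
#' the description line is kept as `chromosome_tag`. Lowercase letters are
#' uppercased and non-ACGT characters become `N`.
#'
#' @param path path to a FASTA file.
#' @return A [sine_catalogue()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop(sine_condition("sinescout_parse_error",
                          paste0("cannot parse FASTA '", path, "': ",
                                 conditionMessage(e))))
    }
  )
  headers <- names(set)
  if (is.null(headers) || any(!nzchar(trimws(headers)))) {
    stop(sine_condition("sinescout_parse_error",
                        paste0("malformed (empty) FASTA header in ", path)))
  }
  id <- sub("\\s.*$", "", headers)
  tag <- ifelse(grepl("\\s", headers),
                trimws(sub("^\\S+\\s+", "", headers)), NA_character_)
  seqs <- as.character(set)
  if (any(!nzchar(seqs))) {
    stop(sine_condition("sinescout_parse_error",
                        paste0("empty sequence for record '",
                               id[!nzchar(seqs)][1], "' in ", path)))
  }
  sine_catalogue(id, seqs, chromosome_tag = tag)
}

#' Write a catalogue to FASTA
#'
#' Headers are `id` followed by the `chromosome_tag` when present; lines wrap
#' at 60 columns. Writing then reading preserves ids, sequences and order.
#'
#' @param catalogue a [sine_catalogue()].
#' @param path output file path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(catalogue, path, width = 60L) {
  stopifnot(inherits(catalogue, "sine_catalogue"))
  set <- Biostrings::BStringSet(catalogue$seq)
  names(set) <- ifelse(is.na(catalogue$chromosome_tag), catalogue$id,
                       paste(catalogue$id, catalogue$chromosome_tag))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Load the packaged AfuSINE catalogue
#'
#' Returns the thirteen AfuSINE elements described from the *Aspergillus
#' fumigatus* Af293 genome: eight tRNA-derived (AfuSINE2) and five
#' 5S rRNA-derived (AfuSINE3) elements, with their published origin
#' annotations and chromosome assignments. Sequences are stored verbatim as
#' published, i.e. including the flanking target-site-duplication copies
#' where those were annotated as part of the element.
#'
#' @return A [sine_catalogue()] of 13 records.
#' @examples
#' cat13 <- load_fixture_catalogue()
#' table(substr(cat13$origin_label, 1, 4))
#' @export
load_fixture_catalogue <- function() {
  path <- system.file("extdata", "afusine_table1.fasta",
                      package = "sinescout", mustWork = TRUE)
  cat13 <- read_fasta(path)
  tag <- cat13$chromosome_tag
  origin <- sub("^.*origin=(\\S+).*$", "\\1", tag)
  cat13$origin_label <- gsub("_", " ", origin)
  cat13$chromosome_tag <- sub("^.*chr=(\\S+).*$", "\\1", tag)
  cat13
}

# internal: loci data.frame constructor (0-based half-open intervals)
locus_df <- function(contig = character(), start = integer(),
                     end = integer(), strand = character(),
                     element_id = character(),
                     identity_pct = numeric(), query_coverage = numeric()) {
  data.frame(contig = as.character(contig), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             element_id = as.character(element_id),
             identity_pct = as.numeric(identity_pct),
             query_coverage = as.numeric(query_coverage),
             stringsAsFactors = FALSE)
}

validate_loci <- function(loci) {
  needed <- c("contig", "start", "end", "strand")
  if (!all(needed %in% names(loci))) {
    stop("loci must have columns: ", paste(needed, collapse = ", "))
  }
  if (nrow(loci) && any(loci$end < loci$start)) {
    stop("invalid locus: end < start")
  }
  if (nrow(loci) && any(!loci$strand %in% c("+", "-"))) {
    stop("locus strand must be '+' or '-'")
  }
  invisible(loci)
}

loci_to_granges <- function(loci) {
  validate_loci(loci)
  gr <- GenomicRanges::GRanges(
    seqnames = loci$contig,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = loci$strand
  )
  if (!is.null(loci$element_id)) {
    S4Vectors::mcols(gr)$Name <- loci$element_id
    S4Vectors::mcols(gr)$ID <- paste0(loci$element_id, "_",
                                      seq_len(nrow(loci)))
  }
  if (!is.null(loci$identity_pct)) {
    S4Vectors::mcols(gr)$identity_pct <- round(loci$identity_pct, 2)
  }
  gr
}

#' Write mapped loci as GFF3
#'
#' Internal coordinates are 0-based half-open; the GFF3 output is 1-based
#' inclusive. The feature type is `dispersed_repeat` and attributes carry the
#' element id and percent identity.
#'
#' @param loci a loci data.frame as returned by [map_copies()] (columns
#'   `contig`, `start`, `end`, `strand` and optionally `element_id`,
#'   `identity_pct`).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(loci, path) {
  gr <- loci_to_granges(loci)
  S4Vectors::mcols(gr)$type <- rep("dispersed_repeat", length(gr))
  S4Vectors::mcols(gr)$source <- rep("sinescout", length(gr))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write mapped loci as BED6
#'
#' BED output stays 0-based half-open. The score column carries percent
#' identity scaled to 0-1000.
#'
#' @inheritParams write_gff3
#' @return `path`, invisibly.
#' @export
write_bed <- function(loci, path) {
  gr <- loci_to_granges(loci)
  nm <- S4Vectors::mcols(gr)$Name
  S4Vectors::mcols(gr) <- NULL
  S4Vectors::mcols(gr)$name <- if (is.null(nm)) rep(".", length(gr)) else nm
  idp <- loci$identity_pct
  S4Vectors::mcols(gr)$score <- if (is.null(idp)) rep(0L, length(gr)) else
    as.integer(round(pmin(100, pmax(0, idp)) * 10))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

# internal: typed conditions so callers can distinguish configuration
# problems (exit 2) from parse problems (exit 3)
sine_condition <- function(class, message) {
  structure(class = c(class, "error", "condition"),
            list(message = message, call = sys.call(-1)))
}

#' @export
print.sine_catalogue <- function(x, ...) {
  cat("sine_catalogue with", nrow(x), "record(s)\n")
  if (nrow(x)) {
    show <- utils::head(data.frame(
      id = x$id, length_bp = x$length_bp, origin = x$origin_label,
      stringsAsFactors = FALSE), 10)
    print(show, row.names = FALSE)
    if (nrow(x) > 10) cat("...", nrow(x) - 10, "more\n")
  }
  invisible(x)
}
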