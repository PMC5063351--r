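test_that("FASTA parsing normalises case and alphabet, keeps descriptions", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">rec1 some description", "acgtACGT", ">rec2", "GGRYNTT"), f)
  cat2 <- read_fasta(f)
  expect_s3_class(cat2, "sine_catalogue")
  expect_equal(nrow(cat2), 2L)
  expect_equal(cat2$id, c("rec1", "rec2"))
  expect_equal(cat2$seq[1], "ACGTACGT")
  expect_equal(cat2$seq[2], "GGNNNTT")  # IUPAC degeneracy codes become N
  expect_equal(cat2$chromosome_tag, c("some description", NA))
  expect_equal(cat2$length_bp, nchar(cat2$seq))
})

test_that("malformed records are rejected with informative errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">empty_rec", ">ok", "ACGT"), f)
  expect_error(read_fasta(f), "empty_rec")
  expect_error(sine_catalogue(c("a", "a"), c("ACGT", "ACGT")), "duplicate")
  expect_error(sine_catalogue("a", ""), "empty")
  expect_error(read_fasta(withr::local_tempfile(fileext = ".fa")),
               "no such file")
})

test_that("write/read round-trip preserves ids, sequences and order", {
  cat3 <- sine_catalogue(c("z", "a", "m"),
                         c(strrep("ACGT", 40), "GATTACA", strrep("T", 61)),
                         chromosome_tag = c("tag z", NA, "tag m"))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(cat3, f)  # wraps at 60 columns
  back <- read_fasta(f)
  expect_equal(back$id, cat3$id)
  expect_equal(back$seq, cat3$seq)
  expect_equal(back$chromosome_tag, cat3$chromosome_tag)
})

test_that("the packaged catalogue has the published composition", {
  cat13 <- fixture()
  expect_equal(nrow(cat13), 13L)
  expect_equal(sum(grepl("^AfuSINE3", cat13$id)), 5L)
  expect_equal(sum(grepl("^AfuSINE2", cat13$id)), 8L)
  expect_equal(sum(startsWith(cat13$origin_label, "tRNA/")), 8L)
  expect_equal(sum(cat13$origin_label == "5S rRNA"), 5L)
  # published per-element lengths
  expected <- c("AfuSINE3-1a" = 280L, "AfuSINE3-3a" = 275L,
                "AfuSINE3-3c" = 343L, "AfuSINE3-4a" = 259L,
                "AfuSINE3-5c" = 297L, "AfuSINE2-1a" = 370L,
                "AfuSINE2-3a" = 493L, "AfuSINE2-4a" = 349L,
                "AfuSINE2-7a" = 401L, "AfuSINE2-5d" = 230L,
                "AfuSINE2-3c" = 201L, "AfuSINE2-4c" = 253L,
                "AfuSINE2-7e" = 140L)
  expect_equal(cat13$length_bp[match(names(expected), cat13$id)],
               unname(expected))
  expect_equal(cat13$length_bp, nchar(cat13$seq))
})

test_that("GFF3 output is 1-based inclusive with the right attributes", {
  loci <- data.frame(contig = "contig1", start = 99L, end = 240L,
                     strand = "+", element_id = "elemA",
                     identity_pct = 91.25, query_coverage = 1)
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(loci, f)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "##gff-version 3"))
  feat <- strsplit(grep("dispersed_repeat", lines, value = TRUE), "\t")[[1]]
  expect_equal(as.integer(feat[4]), 100L)  # 0-based 99 -> 1-based 100
  expect_equal(as.integer(feat[5]), 240L)
  expect_match(feat[9], "elemA")
  # round-trip through a standard reader
  gr <- rtracklayer::import(f)
  expect_equal(GenomicRanges::start(gr), 100L)
  expect_equal(GenomicRanges::end(gr), 240L)
})

test_that("GFF3/BED writers handle empty and multi-record input", {
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(data.frame(contig = character(), start = integer(),
                        end = integer(), strand = character()), f)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "##gff-version 3"))
  expect_false(any(grepl("dispersed_repeat", lines)))

  loci5 <- data.frame(contig = "c1", start = seq(0, 4000, by = 1000),
                      end = seq(300, 4300, by = 1000), strand = "+",
                      element_id = paste0("e", 1:5),
                      identity_pct = 100, query_coverage = 1)
  write_gff3(loci5, f)
  expect_equal(sum(grepl("dispersed_repeat", readLines(f))), 5L)

  b <- withr::local_tempfile(fileext = ".bed")
  write_bed(loci5, b)
  bed <- read.table(b, sep = "\t")
  expect_equal(nrow(bed), 5L)
  expect_equal(bed$V2, loci5$start)  # BED stays 0-based half-open
  expect_equal(bed$V3, loci5$end)

  expect_error(write_gff3(data.frame(contig = "c", start = 10L, end = 5L,
                                     strand = "+"), f), "end < start")
})
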