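test_that("the 60/60 head rule cleanly separates the packaged families", {
  cat13 <- fixture()
  refs <- head_refs_5s()
  fams <- vapply(seq_len(nrow(cat13)), function(i) {
    classify_element(cat13[i, ], refs_5s = refs,
                     motif_models = NULL)$family
  }, character(1))
  is3 <- grepl("SINE3", cat13$id)
  expect_equal(sum(fams == "SINE3"), 5L)
  expect_true(all(fams[is3] == "SINE3"))
  expect_true(all(fams[!is3] != "SINE3"))
})

test_that("random sequence stays unclassified; planted tRNA heads classify
           SINE2 with the right isotype", {
  withr::local_seed(71)
  refs_trna <- sine_catalogue(
    c("trna_arg", "trna_gly", "trna_met"),
    c(random_dna(72), random_dna(72), random_dna(72)),
    origin_label = c("tRNA/Arg", "tRNA/Gly", "tRNA/Met"))
  refs_5s <- sine_catalogue("r5s", random_dna(120),
                            origin_label = "5S rRNA")

  rand <- random_dna(300)
  cls0 <- classify_element(rand, refs_trna = refs_trna, refs_5s = refs_5s)
  expect_equal(cls0$family, "unclassified")

  cand <- paste0(mutate_seq(refs_trna$seq[2], 0.05), random_dna(200))
  cls <- classify_element(cand, refs_trna = refs_trna, refs_5s = refs_5s)
  expect_equal(cls$family, "SINE2")
  expect_equal(cls$origin_call, "tRNA/Gly")

  expect_error(classify_element(rand, motif_models = NULL),
               class = "sinescout_config_error")
})

test_that("a type-2 promoter alone supports a SINE2 call", {
  withr::local_seed(73)
  refs_5s <- sine_catalogue("r5s", random_dna(120))
  elem <- paste0(random_dna(8), "TAGCGTAGTGG", random_dna(25),
                 "GATTGGTGACC", random_dna(150))
  models <- list(A_box = motif_model("A_box", "TAGCGTAGTGG"),
                 B_box = motif_model("B_box", "GATTGGTGACC"))
  cls <- classify_element(elem, refs_5s = refs_5s, motif_models = models)
  expect_equal(cls$family, "SINE2")
  expect_true(is.na(cls$origin_call))
})

test_that("raising the identity threshold never classifies more", {
  cat13 <- fixture()
  refs <- head_refs_5s()
  classified_at <- function(th) {
    vapply(seq_len(nrow(cat13)), function(i) {
      classify_element(cat13[i, ], refs_5s = refs, motif_models = NULL,
                       thresholds = classification_thresholds(
                         id_threshold = th))$family != "unclassified"
    }, logical(1))
  }
  lo <- classified_at(60)
  hi <- classified_at(80)
  expect_true(all(lo | !hi))  # classified at 80 implies classified at 60
  expect_lte(sum(hi), sum(lo))
})

test_that("classification is invariant to reference order", {
  cat13 <- fixture()
  refs <- head_refs_5s()
  refs_rev <- refs[rev(seq_len(nrow(refs))), , drop = FALSE]
  for (i in c(1, 6, 13)) {
    a <- classify_element(cat13[i, ], refs_5s = refs, motif_models = NULL)
    b <- classify_element(cat13[i, ], refs_5s = refs_rev,
                          motif_models = NULL)
    expect_equal(a$family, b$family)
    expect_equal(a$head_alignment$identity_pct,
                 b$head_alignment$identity_pct)
  }
})

test_that("true-gene filter discards genes and keeps derived elements", {
  withr::local_seed(79)
  gene <- random_dna(120)
  refs <- sine_catalogue("r5s_gene", gene)
  # a candidate identical to the gene IS the gene
  expect_false(true_gene_filter(gene, refs))
  # a derived element: conserved head, divergent body and tail
  derived <- paste0(substr(gene, 1, 64), random_dna(200))
  expect_true(true_gene_filter(derived, refs))

  # packaged 5S-derived records survive against a synthetic full-length
  # 5S gene built from the conserved head plus a canonical-length body
  cat13 <- fixture()
  head64 <- substr(fixture_seq("AfuSINE3-1a"), 1, 64)
  gene5s <- paste0(head64, random_dna(55))  # ~119 nt, 5S rRNA scale
  refs5s <- sine_catalogue("r5s_synth", gene5s)
  s3 <- cat13[grepl("SINE3", cat13$id), , drop = FALSE]
  for (i in seq_len(nrow(s3))) {
    expect_true(true_gene_filter(s3[i, ], refs5s), info = s3$id[i])
  }
})

test_that("exclusion intervals remove overlapping loci by coordinate", {
  loci <- data.frame(contig = c("c1", "c1", "c2"),
                     start = c(100L, 500L, 0L), end = c(200L, 600L, 100L),
                     strand = "+")
  excl <- data.frame(contig = "c1", start = 150L, end = 400L)
  kept <- exclusion_filter(loci, excl, min_overlap_frac = 0.5)
  expect_equal(nrow(kept), 2L)  # first locus overlaps 50/100 -> dropped
  expect_equal(kept$start, c(500L, 0L))
})

test_that("LINE 3' similarity is reported but strand- and orientation-aware", {
  withr::local_seed(83)
  line_utr <- random_dna(200)
  refs_line <- sine_catalogue("line_utr", line_utr)
  cand <- paste0(random_dna(150), substr(line_utr, 50, 149))
  aln <- line_3prime_similarity(cand, refs_line, window = 100)
  expect_equal(aln$identity_pct, 100)
  expect_equal(aln$overlap_nt, 100)
  expect_equal(aln$ref_id, "line_utr")

  # a reversed (not complemented) copy should not align forward
  revd <- paste(rev(strsplit(substr(line_utr, 50, 149), "")[[1]]),
                collapse = "")
  cand2 <- paste0(random_dna(150), revd)
  aln2 <- line_3prime_similarity(cand2, refs_line)
  if (!is.null(aln2)) {
    expect_lt(aln2$overlap_nt * aln2$identity_pct / 100, 60)
  }

  # planted diverged tail at ~85% identity gives a long reported overlap
  tail120 <- mutate_seq(substr(line_utr, 1, 120), 0.15)
  cand3 <- paste0(random_dna(150), tail120)
  aln3 <- line_3prime_similarity(cand3, refs_line)
  expect_gte(aln3$overlap_nt, 100)
})
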