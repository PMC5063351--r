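test_that("map_copies finds nothing in element-free genomes and recovers
           planted copies exactly at zero divergence", {
  null_genome <- simulate_genome(sim_config(seed = 2, contig_lengths = 20000,
                                            n_elements = 0))$genome
  withr::local_seed(3)
  elem <- sine_catalogue("q", random_dna(200))
  expect_equal(nrow(map_copies(elem[1, ], null_genome)), 0L)

  sim <- simulate_genome(sim_config(seed = 5, contig_lengths = 50000,
                                    n_elements = 1, copies_per_element = 5,
                                    divergence = 0))
  query <- sine_catalogue("elem1", sim$truth$seq[1])
  loci <- map_copies(query[1, ], sim$genome)
  expect_equal(nrow(loci), 5L)
  expect_equal(loci$start, sim$truth$start)
  expect_equal(loci$end, sim$truth$end)
  expect_equal(loci$strand, sim$truth$strand)
  expect_true(all(loci$identity_pct == 100))
})

test_that("a fixture element maps only to itself in a concatenated decoy
           genome", {
  withr::local_seed(89)
  cat13 <- fixture()
  spacers <- replicate(14, random_dna(500))
  genome_seq <- paste0(spacers[1],
                       paste0(cat13$seq, spacers[-1], collapse = ""))
  genome <- sine_catalogue("cat_contig", genome_seq)
  loci <- map_copies(cat13[cat13$id == "AfuSINE2-7e", ], genome)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$identity_pct, 100)
  expect_equal(loci$query_coverage, 1)
})

test_that("strict mapping equals naive exact-substring search", {
  withr::local_seed(97)
  elem <- random_dna(60)
  genome_seq <- paste0(random_dna(3000), elem, random_dna(2000), elem,
                       random_dna(1500), revcomp(elem), random_dna(1000))
  genome <- sine_catalogue("g", genome_seq)
  params <- scan_params(min_identity = 100, min_coverage = 1)
  loci <- map_copies(elem, genome, params = params)
  # oracle: fixed-string search on both strands
  fwd <- gregexpr(elem, genome_seq, fixed = TRUE)[[1]]
  rev <- gregexpr(revcomp(elem), genome_seq, fixed = TRUE)[[1]]
  expect_equal(loci$start[loci$strand == "+"], as.integer(fwd) - 1L)
  expect_equal(loci$start[loci$strand == "-"], as.integer(rev) - 1L)
  expect_equal(nrow(loci), 3L)
})

test_that("copy recall holds under divergence on simulated genomes", {
  sim0 <- simulate_genome(sim_config(seed = 13, contig_lengths = 50000,
                                     n_elements = 2, copies_per_element = 6,
                                     divergence = 0))
  sim10 <- simulate_genome(sim_config(seed = 17, contig_lengths = 50000,
                                      n_elements = 2, copies_per_element = 6,
                                      divergence = 0.10))
  recall <- function(sim) {
    found <- 0L
    for (eid in unique(sim$truth$element_id)) {
      tr <- sim$truth[sim$truth$element_id == eid, , drop = FALSE]
      loci <- map_copies(sim$masters[sim$masters$id == eid, ], sim$genome)
      for (i in seq_len(nrow(tr))) {
        hit <- loci$contig == tr$contig[i] & loci$start < tr$end[i] &
          loci$end > tr$start[i]
        if (any(hit)) found <- found + 1L
      }
    }
    found / nrow(sim$truth)
  }
  expect_gte(recall(sim0), 0.99)
  expect_gte(recall(sim10), 0.95)
})

test_that("mapping the reverse-complemented genome mirrors loci", {
  sim <- simulate_genome(sim_config(seed = 19, contig_lengths = 30000,
                                    n_elements = 1, copies_per_element = 4,
                                    divergence = 0.02))
  query <- sine_catalogue("elem1", sim$truth$seq[1])
  loci <- map_copies(query[1, ], sim$genome)
  rc_genome <- sine_catalogue(sim$genome$id, revcomp(sim$genome$seq))
  loci_rc <- map_copies(query[1, ], rc_genome)
  n <- nchar(sim$genome$seq[1])
  mirrored <- data.frame(start = n - loci_rc$end, end = n - loci_rc$start,
                         strand = ifelse(loci_rc$strand == "+", "-", "+"))
  mirrored <- mirrored[order(mirrored$start), ]
  expect_equal(loci$start, mirrored$start)
  expect_equal(loci$end, mirrored$end)
  expect_equal(loci$strand, mirrored$strand)
})

test_that("boundary extension applies the 1000/2000 rule with clipping and
           strand awareness", {
  withr::local_seed(23)
  genome <- sine_catalogue("c1", random_dna(100000))
  locus <- data.frame(contig = "c1", start = 5000L, end = 5300L,
                      strand = "+")
  ext <- extend_boundaries(locus, genome)
  expect_equal(c(ext$start, ext$end), c(4000L, 7300L))
  expect_equal(ext$element_offset, 1000L)
  expect_equal(nchar(ext$seq), 3300L)

  locus0 <- data.frame(contig = "c1", start = 0L, end = 300L, strand = "+")
  ext0 <- extend_boundaries(locus0, genome)
  expect_equal(c(ext0$start, ext0$end), c(0L, 2300L))

  # minus strand: upstream is genomic rightward; check by mirror symmetry
  n <- nchar(genome$seq)
  locus_m <- data.frame(contig = "c1", start = 5000L, end = 5300L,
                        strand = "-")
  ext_m <- extend_boundaries(locus_m, genome)
  rc_genome <- sine_catalogue("c1", revcomp(genome$seq))
  locus_p <- data.frame(contig = "c1", start = n - 5300L, end = n - 5000L,
                        strand = "+")
  ext_p <- extend_boundaries(locus_p, rc_genome)
  expect_equal(ext_m$start, n - ext_p$end)
  expect_equal(ext_m$end, n - ext_p$start)
  expect_equal(ext_m$seq, revcomp(ext_p$seq))
})

test_that("de-novo discovery controls false positives and recovers planted
           elements with tight boundaries", {
  strict <- list(A_box = motif_model("A_box", "TAGCGTAGTGG"),
                 B_box = motif_model("B_box", "GATTGGTGACC"))
  null_genome <- simulate_genome(sim_config(seed = 8,
                                            contig_lengths = 100000,
                                            n_elements = 0))$genome
  expect_lte(nrow(discover_candidates(null_genome, motif_models = strict)),
             1L)

  sim <- simulate_genome(sim_config(seed = 7, contig_lengths = 100000,
                                    n_elements = 10,
                                    copies_per_element = 1, divergence = 0))
  cand <- discover_candidates(sim$genome, motif_models = strict)
  found <- attr(cand, "loci")
  n_good <- 0L
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    match <- found$contig == tr$contig & found$strand == tr$strand &
      abs(found$start - tr$start) <= 10L & abs(found$end - tr$end) <= 10L
    if (any(match)) n_good <- n_good + 1L
  }
  expect_gte(n_good, 9L)

  # unscannable input
  genome_n <- sine_catalogue("nn", strrep("N", 5000))
  expect_equal(nrow(discover_candidates(genome_n, motif_models = strict)),
               0L)
})

test_that("distribution report counts per contig and tests label
           enrichment against a binomial oracle", {
  loci5 <- data.frame(contig = "chr3", start = seq(100, 4100, by = 1000),
                      end = seq(400, 4400, by = 1000), strand = "+")
  rep0 <- distribution_report(loci5)
  expect_equal(rep0$per_contig$contig, "chr3")
  expect_equal(rep0$per_contig$n, 5L)

  regions <- data.frame(
    contig = "chr3",
    start = c(0L, 10000L, 90000L),
    end = c(10000L, 90000L, 100000L),
    label = c("subtelomeric", "other", "pericentromeric"))
  overlapping <- regions
  overlapping$end[1] <- 20000L
  expect_error(distribution_report(loci5, overlapping), "overlap")

  # all 20 loci inside the 10% subtelomeric label
  withr::local_seed(29)
  starts <- sort(sample(0:9500, 20))
  loci20 <- data.frame(contig = "chr3", start = starts, end = starts + 100L,
                       strand = "+")
  rep1 <- distribution_report(loci20, regions)
  sub <- rep1$per_label[rep1$per_label$label == "subtelomeric", ]
  expect_equal(sub$n, 20L)
  # oracle: exact binomial tail, P(X >= 20 | n = 20, p = 0.1)
  oracle_p <- sum(dbinom(20:20, 20, 0.1))
  expect_equal(sub$p_enrichment, oracle_p, tolerance = 1e-12)
  expect_lt(sub$p_enrichment, 0.01)
})

test_that("uniformly planted loci give well-calibrated enrichment p-values", {
  withr::local_seed(31)
  regions <- data.frame(contig = "c", start = c(0L, 20000L),
                        end = c(20000L, 100000L),
                        label = c("subtelomeric", "other"))
  pvals <- replicate(40, {
    starts <- sample(0:99900, 15)
    loci <- data.frame(contig = "c", start = starts, end = starts + 50L,
                       strand = "+")
    rep <- distribution_report(loci, regions)
    rep$per_label$p_enrichment[rep$per_label$label == "subtelomeric"]
  })
  # under the null the p-value should not be systematically small
  expect_gt(mean(pvals > 0.05), 0.7)
})
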