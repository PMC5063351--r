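# Independent oracles used to validate the package's own algorithms.
# These deliberately use different algorithmic routes (enumeration, naive
# string scans) from the implementations they check.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

# Exhaustive local-alignment oracle: enumerates every choice of aligned
# position subsets (i1<...<ik from a, j1<...<jk from b). Columns between
# consecutive aligned pairs are gap runs costed affinely
# (gap_open + len * gap_extend per run). The optimum over all such
# configurations is the optimal local alignment score (optimal alignments
# never start or end in a gap, and never interleave gap runs).
enum_local_score <- function(a, b, scheme = scoring_scheme()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  subst <- function(x, y) {
    if (x == "N" || y == "N") scheme$mismatch
    else if (x == y) scheme$match else scheme$mismatch
  }
  gap_cost <- function(len) {
    if (len == 0) 0 else scheme$gap_open + len * scheme$gap_extend
  }
  best <- 0
  for (k in seq_len(min(n, m))) {
    ia <- utils::combn(n, k, simplify = FALSE)
    jb <- utils::combn(m, k, simplify = FALSE)
    for (is in ia) {
      for (js in jb) {
        sc <- sum(mapply(subst, av[is], bv[js]))
        if (k > 1) {
          sc <- sc + sum(vapply(seq_len(k - 1), function(t) {
            gap_cost(is[t + 1] - is[t] - 1L) +
              gap_cost(js[t + 1] - js[t] - 1L)
          }, numeric(1)))
        }
        if (sc > best) best <- sc
      }
    }
  }
  best
}

# Independent pure-R Gotoh recurrence (score only); same gap model as the
# enumeration oracle, but polynomial, for larger sampled pairs.
gotoh_score <- function(a, b, scheme = scoring_scheme()) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 1:n) {
    for (j in 1:m) {
      s <- if (av[i] == "N" || bv[j] == "N") scheme$mismatch
           else if (av[i] == bv[j]) scheme$match else scheme$mismatch
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + scheme$gap_open,
                             X[i, j + 1],
                             Y[i, j + 1] + scheme$gap_open) +
        scheme$gap_extend
      Y[i + 1, j + 1] <- max(M[i + 1, j] + scheme$gap_open,
                             Y[i + 1, j],
                             X[i + 1, j] + scheme$gap_open) +
        scheme$gap_extend
      best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
    }
  }
  best
}

# Naive IUPAC motif scan: per-position character-set membership, one-way
# degeneracy (consensus codes expand; subject N only matches consensus N).
naive_iupac_scan <- function(seq, consensus, max_mismatch) {
  sets <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
               Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
               K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
               D = c("A", "G", "T"), H = c("A", "C", "T"),
               V = c("A", "C", "G"), N = c("A", "C", "G", "T", "N"))
  sv <- strsplit(seq, "")[[1]]
  cv <- strsplit(consensus, "")[[1]]
  m <- length(cv)
  n <- length(sv)
  hits <- integer()
  mms <- integer()
  if (n < m) return(data.frame(start = hits, mismatches = mms))
  for (p in 1:(n - m + 1)) {
    mm <- sum(vapply(1:m, function(q) {
      !(sv[p + q - 1] %in% sets[[cv[q]]])
    }, logical(1)))
    if (mm <= max_mismatch) {
      hits <- c(hits, p - 1L)
      mms <- c(mms, mm)
    }
  }
  data.frame(start = hits, mismatches = mms)
}

# Brute-force 3'-anchored tandem repeat search on short strings: tries all
# (unit, count) pairs directly, returns the best by (total length,
# smallest primitive unit) with count >= 3, or NULL.
brute_terminal_tandem <- function(seq, max_unit = 6L) {
  n <- nchar(seq)
  is_primitive <- function(u) {
    lu <- nchar(u)
    for (d in seq_len(lu - 1)) {
      if (lu %% d == 0 && u == strrep(substr(u, 1, d), lu / d)) return(FALSE)
    }
    TRUE
  }
  best <- NULL
  for (u_len in seq_len(min(max_unit, n))) {
    unit <- substr(seq, n - u_len + 1L, n)
    if (!is_primitive(unit)) next
    count <- 0L
    while ((count + 1L) * u_len <= n &&
           substr(seq, n - (count + 1L) * u_len + 1L,
                  n - count * u_len) == unit) {
      count <- count + 1L
    }
    if (count >= 3L) {
      total <- count * u_len
      if (is.null(best) || total > best$total ||
          (total == best$total && u_len < nchar(best$unit))) {
        best <- list(unit = unit, count = count, total = total)
      }
    }
  }
  best
}

fixture <- local({
  cached <- NULL
  function() {
    if (is.null(cached)) cached <<- load_fixture_catalogue()
    cached
  }
})

fixture_seq <- function(id) {
  cat13 <- fixture()
  cat13$seq[cat13$id == id]
}

# 5S reference set built from the conserved heads (positions 1-64) of the
# five packaged 5S-derived elements
head_refs_5s <- function(head_len = 64L) {
  cat13 <- fixture()
  s3 <- cat13[grepl("SINE3", cat13$id), , drop = FALSE]
  sine_catalogue(paste0(s3$id, "_head"), substr(s3$seq, 1, head_len),
                 origin_label = "5S rRNA")
}
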