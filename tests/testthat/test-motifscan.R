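test_that("PSSM construction matches hand arithmetic", {
  # column (10,0,0,0), total pseudocount 1 split over a uniform background
  # -> A entry log2((10.25/11)/0.25); with pseudocount 4 -> log2((11/14)/0.25)
  p <- pssm_from_counts(matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 4)
  expect_equal(unname(p$matrix["A", 1]), log2((11 / 14) / 0.25),
               tolerance = 1e-12)
  expect_equal(unname(p$matrix["C", 1]), log2((1 / 14) / 0.25),
               tolerance = 1e-12)
  # uniform counts on a uniform background give all-zero scores
  u <- pssm_from_counts(matrix(5, 4, 3))
  expect_equal(unname(u$matrix), matrix(0, 4, 3))
  expect_identical(dim(u$matrix), c(4L, 3L))
  expect_error(pssm_from_counts(matrix(0, 4, 1), pseudocount = 0),
               "degenerate")
})

test_that("window scoring sums matrix entries and flags non-ACGT windows", {
  hand <- manual_pssm(matrix(c(1, -1, 0, 0), 4, 2))
  expect_equal(score_window(hand, "AC"), 0)
  expect_equal(score_window(hand, "AA"), 2)
  expect_true(is.na(score_window(hand, "AN")))
  expect_error(score_window(hand, "A"), "length")
  zero <- manual_pssm(matrix(0, 4, 3))
  expect_equal(score_window(zero, "GTA"), 0)
})

test_that("scanner equals the naive per-window loop on random cases", {
  set.seed(101)
  for (case in 1:50) {
    L <- sample(3:8, 1)
    counts <- matrix(sample(0:20, 4 * L, replace = TRUE), 4, L)
    counts[1, colSums(counts) == 0] <- 1
    pssm <- pssm_from_counts(counts, motif_id = "rnd")
    seq <- random_dna(sample(15:50, 1))
    thr <- sample(c(-Inf, 0, 2), 1)
    got <- scan_sequences(pssm, seq, score_threshold = thr,
                          collapse_strands = FALSE)
    want <- naive_scan(pssm, seq, thr)
    if (is.null(want)) {
      expect_identical(nrow(got), 0L)
    } else {
      o1 <- order(got$start, got$strand)
      o2 <- order(want$start, want$strand)
      expect_identical(got$start[o1], as.integer(want$start[o2]))
      expect_identical(got$strand[o1], want$strand[o2])
      expect_equal(got$score[o1], want$score[o2], tolerance = 1e-12)
    }
  }
})

test_that("threshold -Inf reports every window on both strands", {
  pssm <- pssm_from_counts(matrix(sample(1:9, 12, replace = TRUE), 4, 3))
  seq <- random_dna(20)
  m <- scan_sequences(pssm, seq, score_threshold = -Inf,
                      collapse_strands = FALSE)
  expect_identical(nrow(m), (20L - 3L + 1L) * 2L)
  # with strand collapsing, one match per locus
  m1 <- scan_sequences(pssm, seq, score_threshold = -Inf)
  expect_identical(nrow(m1), 20L - 3L + 1L)
})

test_that("double-stranded best score is reverse-complement invariant", {
  set.seed(77)
  for (i in 1:10) {
    pssm <- pssm_from_counts(matrix(sample(0:30, 24, replace = TRUE) + 1, 4, 6))
    seq <- random_dna(30)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    a <- scan_sequences(pssm, seq, score_threshold = -Inf,
                        collapse_strands = FALSE)
    b <- scan_sequences(pssm, rc, score_threshold = -Inf,
                        collapse_strands = FALSE)
    expect_equal(max(a$score), max(b$score), tolerance = 1e-12)
  }
})

test_that("a planted motif is recovered at its offset under a stringent threshold", {
  # information-rich 3-mer; background elsewhere is its worst letters
  counts <- matrix(1, 4, 3)
  counts[cbind(c(1, 3, 4), 1:3)] <- 60   # consensus AGT
  pssm <- pssm_from_counts(counts, motif_id = "planted")
  seq <- paste0(strrep("C", 8), "AGT", strrep("C", 9))
  # a 3-mer's rarest outcome has probability 1/64, so ask for p = 0.02:
  # only the exact consensus clears the resulting threshold
  thr <- pssm_score_threshold(pssm, p = 0.02)
  m <- scan_sequences(pssm, seq, score_threshold = thr)
  expect_identical(nrow(m), 1L)
  expect_identical(m$start, 8L)
  expect_identical(m$strand, "+")
})

test_that("enumeration threshold bounds the background match probability", {
  set.seed(5)
  counts <- matrix(sample(0:50, 4 * 6, replace = TRUE) + 1, 4, 6)
  pssm <- pssm_from_counts(counts)
  for (p in c(1e-2, 1e-3)) {
    thr <- pssm_score_threshold(pssm, p = p)
    # empirical exceedance under the uniform background
    sc <- replicate(4000, score_window(pssm, random_dna(6)))
    expect_lte(mean(sc >= thr), p + 3 * sqrt(p / 4000) + 2e-3)
  }
})

test_that("delta PSSM is the haplotype score difference and antisymmetric", {
  # SNP column scores ref base 2.0, alt base -1.0; other columns identical
  mat <- matrix(0, 4, 3)
  mat[1, 2] <- 2; mat[3, 2] <- -1   # A -> 2, G -> -1 in column 2
  hand <- manual_pssm(mat)
  d <- delta_pssm(hand, "CAC", "CGC")
  expect_equal(d$delta, 3)
  d_swapped <- delta_pssm(hand, "CGC", "CAC")
  expect_equal(d_swapped$delta, -3)
  expect_equal(delta_pssm(hand, "CAC", "CAC")$delta, 0)
  expect_warning(expect_null(delta_pssm(hand, "CNC", "CGC")), "unscorable")
})

test_that("candidates arise exactly where a SNP lies inside a match span", {
  counts <- matrix(1, 4, 4)
  counts[cbind(c(1, 2, 3, 4), 1:4)] <- 60  # consensus ACGT
  pssm <- pssm_from_counts(counts, motif_id = "m1")
  genome <- c(chr1 = paste0(strrep("T", 10), "ACGT", strrep("T", 10)))
  matches <- data.frame(motif_id = "m1", chrom = "chr1", start = 10L,
                        end = 14L, strand = "+", score = 10,
                        haplotype = "REF", stringsAsFactors = FALSE)
  inside <- data.frame(snp_id = "in", chrom = "chr1", pos = 12L,
                       ref_base = "G", alt_base = "A", DP = 50L, MQ = 60L)
  outside <- data.frame(snp_id = "out", chrom = "chr1", pos = 14L,
                        ref_base = "T", alt_base = "C", DP = 50L, MQ = 60L)
  cand <- call_candidate_sites(matches, rbind(inside, outside),
                               list(m1 = pssm), genome,
                               shoulder = 2, flank = 3)
  expect_length(cand, 1L)
  expect_identical(cand[[1]]$disruption$snp_id, "in")
  expect_gt(cand[[1]]$disruption$delta, 0)  # alt weakens the consensus
  # the same SNP inside two motifs yields one candidate per motif
  matches2 <- rbind(matches,
                    transform(matches, motif_id = "m2"))
  cand2 <- call_candidate_sites(matches2, inside,
                                list(m1 = pssm, m2 = pssm), genome,
                                shoulder = 2, flank = 3)
  expect_length(cand2, 2L)
  expect_setequal(vapply(cand2, function(x) x$disruption$motif_id,
                         character(1)), c("m1", "m2"))
})

test_that("jaspar pfm files round-trip through write and read", {
  m <- matrix(sample(0:50, 4 * 7, replace = TRUE), 4, 7,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  path <- withr::local_tempfile(fileext = ".pfm")
  write_jaspar_pfm(list(MA0001.1 = m), path)
  back <- read_jaspar_pfm(path)
  expect_identical(names(back), "MA0001.1")
  expect_equal(unname(back[[1]]), unname(m))
})
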