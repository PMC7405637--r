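# Independent oracles used across tests. These deliberately use the most
# naive correct formulation so they stay independent of the package code.

# step-up Benjamini-Hochberg by direct definition
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m))
    q_sorted[i] <- min(1, min(m * sort(p)[i:m] / (i:m)))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# two-sided exact binomial p by enumeration (minimum-likelihood ordering)
binom_two_sided_enum <- function(a, b) {
  n <- a + b
  if (n == 0) return(NA_real_)
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[a + 1] * (1 + 1e-07)])
}

# naive double-stranded PSSM scan: score every window explicitly
naive_scan <- function(pssm, seq, threshold) {
  L <- pssm$length
  n <- nchar(seq) - L + 1
  out <- NULL
  revcomp <- function(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (i in seq_len(max(n, 0))) {
    w <- substr(seq, i, i + L - 1)
    for (strand in c("+", "-")) {
      s <- score_window(pssm, if (strand == "+") w else revcomp(w))
      if (!is.na(s) && s >= threshold)
        out <- rbind(out, data.frame(start = i - 1, strand = strand,
                                     score = s, stringsAsFactors = FALSE))
    }
  }
  out
}

# Pearson chi-square on a 2x2 from expected counts, no correction
chisq_brute <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# random 2x2x1 count table in CountTable layout
random_count_table <- function(min_count = 5, max_count = 100) {
  data.frame(replicate = 1L,
             allele = rep(c("REF", "ALT"), 2),
             region = rep(c("footprint", "flank"), each = 2),
             count = sample(min_count:max_count, 4, replace = TRUE),
             stringsAsFactors = FALSE)
}

# CountTable from the four cell totals (single replicate)
cells_to_table <- function(a_ref, c_ref, a_alt, c_alt) {
  data.frame(replicate = 1L,
             allele = c("REF", "ALT", "REF", "ALT"),
             region = c("footprint", "footprint", "flank", "flank"),
             count = c(a_ref, a_alt, c_ref, c_alt),
             stringsAsFactors = FALSE)
}

# tiny hand-built PSSM with per-column scores given as a 4 x L matrix
manual_pssm <- function(mat, motif_id = "hand") {
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(motif_id = motif_id, matrix = mat,
                 background = rep(0.25, 4), pseudocount = 0,
                 length = ncol(mat)), class = "pssm")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")
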