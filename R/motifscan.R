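BASES <- c("A", "C", "G", "T")

#' Build a position-specific scoring matrix from base counts
#'
#' Converts a 4 x L position frequency matrix into log2 odds against a
#' background composition, with a pseudocount split across bases in
#' proportion to the background (the common JASPAR convention).
#'
#' @param counts 4 x L numeric matrix of non-negative base counts, rows in
#'   A, C, G, T order.
#' @param pseudocount Total pseudocount added per column (default 0.8),
#'   distributed over bases proportionally to `background`.
#' @param background Background base probabilities summing to 1
#'   (default uniform).
#' @param motif_id Identifier stored on the result.
#' @return A `pssm` object: list with `motif_id`, `matrix` (4 x L log2
#'   odds), `background`, `pseudocount`, `length`.
#' @examples
#' pssm_from_counts(matrix(c(10, 0, 0, 0), 4, 1), pseudocount = 4)
#' @export
pssm_from_counts <- function(counts, pseudocount = 0.8,
                             background = rep(0.25, 4), motif_id = "motif") {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == 4, ncol(counts) >= 1, all(counts >= 0),
            abs(sum(background) - 1) < 1e-8, pseudocount >= 0)
  if (pseudocount == 0 && any(colSums(counts) == 0))
    stop("degenerate column: all-zero counts with pseudocount 0")
  pc <- pseudocount * background
  prob <- sweep(counts + pc, 2, colSums(counts) + pseudocount, "/")
  if (any(prob == 0))
    stop("degenerate column: zero probability with pseudocount 0")
  m <- log2(prob / background)
  rownames(m) <- BASES
  structure(list(motif_id = motif_id, matrix = m, background = background,
                 pseudocount = pseudocount, length = ncol(m)),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat("pssm", x$motif_id, "length", x$length, "\n")
  print(round(x$matrix, 2))
  invisible(x)
}

#' Score one sequence window against a PSSM
#'
#' @param pssm A [pssm_from_counts()] object.
#' @param seq Nucleotide string of exactly the motif length.
#' @return The log2-odds score (sum of matrix entries), or `NA` if the window
#'   contains a non-ACGT character ("unscorable").
#' @export
score_window <- function(pssm, seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  if (length(b) != pssm$length)
    stop("window length ", length(b), " != motif length ", pssm$length)
  idx <- match(b, BASES)
  if (anyNA(idx)) return(NA_real_)
  sum(pssm$matrix[cbind(idx, seq_along(idx))])
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# score all windows of one strand; returns numeric vector, NA = unscorable
.scan_one <- function(pssm, seq) {
  b <- strsplit(toupper(seq), "")[[1]]
  L <- pssm$length
  n <- length(b) - L + 1L
  if (n < 1L) return(numeric(0))
  idx <- match(b, BASES)
  vapply(seq_len(n), function(i) {
    j <- idx[i:(i + L - 1L)]
    if (anyNA(j)) NA_real_ else sum(pssm$matrix[cbind(j, seq_len(L))])
  }, numeric(1))
}

#' Log-odds threshold for a target match p-value
#'
#' Computes, by exact dynamic-programming enumeration of the PSSM score
#' distribution under the background model (scores discretised to a fine
#' grid), the smallest threshold whose exceedance probability is at most
#' `p`. This mirrors FIMO's p-value semantics for match calling.
#'
#' @param pssm A PSSM.
#' @param p Target per-window match probability (default 1e-4).
#' @param granularity Score discretisation step (default 1e-3 log2 units).
#' @return The score threshold.
#' @export
pssm_score_threshold <- function(pssm, p = 1e-4, granularity = 1e-3) {
  stopifnot(p > 0, p <= 1)
  scaled <- round(pssm$matrix / granularity)
  # distribution of the integer score as a named prob table, column by column
  dist <- c("0" = 1)
  for (j in seq_len(pssm$length)) {
    vals <- as.integer(names(dist))
    new <- list()
    for (b in 1:4) {
      v <- vals + scaled[b, j]
      new[[b]] <- setNames(as.numeric(dist) * pssm$background[b],
                           as.character(v))
    }
    all <- unlist(new)
    dist <- tapply(all, names(all), sum)
  }
  sc <- as.integer(names(dist))
  o <- order(sc, decreasing = TRUE)
  exceed <- cumsum(as.numeric(dist)[o])
  ok <- which(exceed <= p + 1e-12)
  if (length(ok) == 0L) return(Inf)
  sc[o][max(ok)] * granularity
}

#' Scan both haplotypes of a region for motif matches
#'
#' Slides the PSSM over every window and both strands of the reference and
#' alternative haplotype sequences, reporting matches scoring at or above the
#' threshold. Reverse-strand windows are scored on the reverse complement and
#' reported in forward-strand coordinates. When both strands match at the
#' same locus only the higher-scoring strand is kept (ties go to `+`), so one
#' physical site is counted once.
#'
#' @param pssm A PSSM.
#' @param region_seq_ref,region_seq_alt Haplotype sequences of the region
#'   (equal length, differing only at variant positions). `region_seq_alt`
#'   may be `NULL` to scan a single sequence.
#' @param score_threshold Minimum log2-odds score; default is the exact
#'   enumeration threshold at p = 1e-4 from [pssm_score_threshold()].
#' @param chrom,offset Coordinates of the region start (0-based), used to
#'   report genomic positions.
#' @param collapse_strands If `TRUE` (default) report one match per locus,
#'   keeping the higher-scoring strand; if `FALSE` report every strand's
#'   passing window separately.
#' @return `data.frame` of matches: `motif_id`, `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `score`, `haplotype`.
#' @export
scan_sequences <- function(pssm, region_seq_ref, region_seq_alt = NULL,
                           score_threshold = NULL, chrom = "chr1",
                           offset = 0L, collapse_strands = TRUE) {
  if (is.null(score_threshold))
    score_threshold <- pssm_score_threshold(pssm)
  haps <- list(REF = region_seq_ref)
  if (!is.null(region_seq_alt)) {
    stopifnot(nchar(region_seq_alt) == nchar(region_seq_ref))
    haps$ALT <- region_seq_alt
  }
  L <- pssm$length
  out <- lapply(names(haps), function(h) {
    seq <- haps[[h]]
    fwd <- .scan_one(pssm, seq)
    rev <- rev(.scan_one(pssm, .revcomp(seq)))  # align to forward coordinates
    n <- length(fwd)
    if (n == 0L) return(NULL)
    if (collapse_strands) {
      # per-locus strand choice: higher score wins, tie -> "+"
      use_rev <- !is.na(rev) & (is.na(fwd) | rev > fwd)
      score <- ifelse(use_rev, rev, fwd)
      strand <- ifelse(use_rev, "-", "+")
      pos <- seq_len(n)
    } else {
      score <- c(fwd, rev)
      strand <- rep(c("+", "-"), each = n)
      pos <- rep(seq_len(n), 2L)
    }
    keep <- !is.na(score) & score >= score_threshold
    if (!any(keep)) return(NULL)
    i <- which(keep)
    data.frame(motif_id = pssm$motif_id, chrom = chrom,
               start = offset + pos[i] - 1L, end = offset + pos[i] - 1L + L,
               strand = strand[i],
               score = score[i], haplotype = h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(motif_id = character(), chrom = character(),
                      start = integer(), end = integer(), strand = character(),
                      score = numeric(), haplotype = character(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Allelic motif disruption score
#'
#' deltaPSSM = PSSM(ref) - PSSM(alt): positive values mean the alternative
#' allele weakens the motif (loss of binding on the variant), negative values
#' a gain.
#'
#' @param pssm A PSSM.
#' @param ref_window,alt_window Motif-aligned haplotype windows (already
#'   reverse-complemented for minus-strand matches).
#' @return List with `pssm_ref`, `pssm_alt`, `delta`, or `NULL` (with a
#'   warning) if either window is unscorable.
#' @export
delta_pssm <- function(pssm, ref_window, alt_window) {
  s_ref <- score_window(pssm, ref_window)
  s_alt <- score_window(pssm, alt_window)
  if (is.na(s_ref) || is.na(s_alt)) {
    warning("unscorable window; candidate dropped")
    return(NULL)
  }
  list(pssm_ref = s_ref, pssm_alt = s_alt, delta = s_ref - s_alt)
}

#' Intersect motif matches with heterozygous SNPs into candidate sites
#'
#' Every (SNP, motif match) pair where the SNP position falls inside the
#' match span becomes a candidate allele-specific binding site: a SNP inside
#' two motifs yields two candidates. The disruption score is computed from
#' the two haplotype windows at the matched locus, so a match found on only
#' one haplotype still scores both.
#'
#' @param matches `data.frame` from [scan_sequences()] (genomic coordinates).
#' @param snps `data.frame` from [filter_variants()].
#' @param pssms Named list of PSSMs keyed by `motif_id`.
#' @param genome Named character vector (or `DNAStringSet`) of chromosome
#'   sequences holding the reference haplotype.
#' @param shoulder,flank Widths passed to [site_layout()].
#' @return List of candidates; each element has `layout` (a [site_layout()])
#'   and `disruption` (`motif_id`, `strand`, `pssm_ref`, `pssm_alt`, `delta`).
#'   Duplicate (SNP, motif, locus) combinations arising from matches on both
#'   haplotypes are collapsed.
#' @export
call_candidate_sites <- function(matches, snps, pssms, genome,
                                 shoulder = 10, flank = 50) {
  if (is(genome, "DNAStringSet"))
    genome <- setNames(as.character(genome), names(genome))
  out <- list()
  seen <- character()
  for (i in seq_len(nrow(snps))) {
    snp <- snps[i, , drop = FALSE]
    hit <- which(matches$chrom == snp$chrom & matches$start <= snp$pos &
                   matches$end > snp$pos)
    for (j in hit) {
      m <- matches[j, ]
      key <- paste(snp$snp_id, m$motif_id, m$start, m$strand)
      if (key %in% seen) next
      seen <- c(seen, key)
      pssm <- pssms[[m$motif_id]]
      chrseq <- genome[[snp$chrom]]
      ref_win <- substr(chrseq, m$start + 1L, m$end)
      rel <- snp$pos - m$start + 1L
      if (toupper(substr(ref_win, rel, rel)) != snp$ref_base) next # ref mismatch
      alt_win <- ref_win
      substr(alt_win, rel, rel) <- snp$alt_base
      if (m$strand == "-") {
        ref_win <- .revcomp(ref_win)
        alt_win <- .revcomp(alt_win)
      }
      d <- delta_pssm(pssm, ref_win, alt_win)
      if (is.null(d)) next
      layout <- site_layout(snp$chrom, m$start, m$end, snp,
                            shoulder = shoulder, flank = flank)
      out[[length(out) + 1L]] <- list(
        layout = layout,
        disruption = data.frame(snp_id = snp$snp_id, motif_id = m$motif_id,
                                strand = m$strand, pssm_ref = d$pssm_ref,
                                pssm_alt = d$pssm_alt, delta = d$delta,
                                stringsAsFactors = FALSE))
    }
  }
  out
}
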