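#' Classify a regulatory SNP as promoter or enhancer candidate
#'
#' A SNP within `window` bp (inclusive) of any transcription start site is a
#' promoter SNP and its target is the closest gene (ties broken by smaller
#' distance, then lexicographic gene id); all others are enhancer candidates
#' to be resolved through chromatin-interaction pairs.
#'
#' @param snps `data.frame` with `snp_id`, `chrom`, `pos` (0-based).
#' @param tss_table `data.frame` with `gene_id`, `chrom`, `strand`, `tss`
#'   (0-based position). Distance is measured to the TSS regardless of
#'   strand.
#' @param window Promoter half-width in bp (default 1000, inclusive).
#' @return `data.frame`: `snp_id`, `class` (`"promoter"` /
#'   `"enhancer_candidate"`), `target_gene` (`NA` for enhancer candidates),
#'   `tss_distance`.
#' @export
classify_snp_location <- function(snps, tss_table, window = 1000) {
  if (nrow(tss_table) == 0L) stop("empty TSS table")
  out <- lapply(seq_len(nrow(snps)), function(i) {
    s <- snps[i, ]
    cand <- tss_table[tss_table$chrom == s$chrom, , drop = FALSE]
    if (nrow(cand) == 0L)
      return(data.frame(snp_id = s$snp_id, class = "enhancer_candidate",
                        target_gene = NA_character_, tss_distance = NA_real_,
                        stringsAsFactors = FALSE))
    d <- abs(cand$tss - s$pos)
    o <- order(d, cand$gene_id)
    best <- o[1]
    if (d[best] <= window)
      data.frame(snp_id = s$snp_id, class = "promoter",
                 target_gene = cand$gene_id[best], tss_distance = d[best],
                 stringsAsFactors = FALSE)
    else
      data.frame(snp_id = s$snp_id, class = "enhancer_candidate",
                 target_gene = NA_character_, tss_distance = d[best],
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Map enhancer-candidate SNPs to target genes via chromatin interactions
#'
#' For each interaction record, a SNP falling in one anchor gains the genes
#' resident in the paired anchor; targets are unioned over all records.
#'
#' @param snps `data.frame` with `snp_id`, `chrom`, `pos` (0-based).
#' @param interactions `data.frame` with columns `chrom1`, `start1`, `end1`,
#'   `genes1`, `chrom2`, `start2`, `end2`, `genes2`; intervals 0-based
#'   half-open, gene lists comma-separated (possibly empty).
#' @return Named list mapping `snp_id` to a character vector of target genes
#'   (possibly empty).
#' @export
map_enhancer_targets <- function(snps, interactions) {
  split_genes <- function(x) {
    if (is.na(x) || !nzchar(x)) character() else strsplit(x, ",")[[1]]
  }
  out <- setNames(vector("list", nrow(snps)), snps$snp_id)
  for (i in seq_len(nrow(snps))) {
    s <- snps[i, ]
    hits <- character()
    for (j in seq_len(nrow(interactions))) {
      r <- interactions[j, ]
      in1 <- r$chrom1 == s$chrom & s$pos >= r$start1 & s$pos < r$end1
      in2 <- r$chrom2 == s$chrom & s$pos >= r$start2 & s$pos < r$end2
      if (in1) hits <- c(hits, split_genes(r$genes2))
      if (in2) hits <- c(hits, split_genes(r$genes1))
    }
    out[[i]] <- sort(unique(hits))
  }
  out
}

#' Flag SNPs overlapping known eQTLs
#'
#' A SNP overlaps an eQTL if its rsID matches, or — when no rsID is
#' available on either side — its chromosome and position match exactly.
#'
#' @param snps `data.frame` with `snp_id`, `chrom`, `pos` (0-based) and
#'   optionally `rsid`.
#' @param eqtls `data.frame` with `rsid` and/or `chrom`, `pos` (0-based),
#'   plus `gene`, `tissue`.
#' @return Logical vector, one flag per SNP row.
#' @export
overlap_eqtl <- function(snps, eqtls) {
  has_rsid <- "rsid" %in% names(snps) && "rsid" %in% names(eqtls)
  vapply(seq_len(nrow(snps)), function(i) {
    s <- snps[i, ]
    if (has_rsid && !is.na(s$rsid) && nzchar(s$rsid) &&
        s$rsid %in% stats::na.omit(eqtls$rsid))
      return(TRUE)
    if (all(c("chrom", "pos") %in% names(eqtls)))
      return(any(eqtls$chrom == s$chrom & eqtls$pos == s$pos, na.rm = TRUE))
    FALSE
  }, logical(1))
}

#' Chi-square enrichment test on a 2x2 table
#'
#' Pearson chi-square with one degree of freedom, by default without the
#' Yates continuity correction.
#'
#' @param table 2x2 matrix of counts, e.g. regulatory/non-regulatory SNPs by
#'   eQTL/non-eQTL status.
#' @param correct Apply the Yates correction (default `FALSE`).
#' @return List with `statistic` and `pvalue`.
#' @export
enrichment_test <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero margin")
  ct <- suppressWarnings(chisq.test(table, correct = correct))
  list(statistic = unname(ct$statistic), pvalue = unname(ct$p.value))
}
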