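#' Exact binomial test for allele-specific expression at one SNP
#'
#' Under balanced expression the reference-allele read count at a coding
#' heterozygous SNP follows Binomial(N, 0.5). The two-sided p-value uses the
#' minimum-likelihood ordering: the sum of probabilities of all outcomes no
#' more likely than the observed one.
#'
#' @param ref_count,alt_count Non-negative allelic read counts.
#' @return Two-sided p-value, or `NA` if both counts are zero (untestable).
#' @examples
#' ase_binomial_test(5, 5)   # 1
#' ase_binomial_test(0, 10)  # 2 * 0.5^10
#' @export
ase_binomial_test <- function(ref_count, alt_count) {
  stopifnot(ref_count >= 0, alt_count >= 0)
  n <- ref_count + alt_count
  if (n == 0) return(NA_real_)
  binom.test(ref_count, n, p = 0.5)$p.value
}

#' Gene-level allele-specific expression calls
#'
#' Tests every coding heterozygous SNP of each gene with
#' [ase_binomial_test()]; a gene is ASE-positive if any of its SNPs rejects
#' the balanced null at `alpha`. No multiple-testing correction is applied by
#' default; `adjust = "BH"` switches the per-SNP threshold to q-values.
#'
#' @param counts `data.frame` with columns `gene`, `snp`, `ref_count`,
#'   `alt_count` (summed across replicate libraries).
#' @param alpha Per-SNP significance threshold (default 0.05, strict `<`).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return List with `snps` (per-SNP `data.frame` incl. `pvalue`) and
#'   `genes` (`gene`, `status` in `ase`/`balanced`/`untested`, `min_pvalue`,
#'   `n_snps_tested`).
#' @export
call_ase_genes <- function(counts, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  pv <- mapply(ase_binomial_test, counts$ref_count, counts$alt_count)
  counts$pvalue <- pv
  crit <- if (adjust == "BH") {
    q <- rep(NA_real_, length(pv))
    q[!is.na(pv)] <- adjust_fdr(pv[!is.na(pv)])
    counts$qvalue <- q
    q
  } else pv
  genes <- do.call(rbind, lapply(split(seq_len(nrow(counts)), counts$gene),
    function(idx) {
      p <- crit[idx]
      tested <- sum(!is.na(p))
      status <- if (tested == 0L) "untested"
        else if (any(p < alpha, na.rm = TRUE)) "ase" else "balanced"
      data.frame(gene = counts$gene[idx[1]], status = status,
                 min_pvalue = if (tested) min(counts$pvalue[idx], na.rm = TRUE)
                              else NA_real_,
                 n_snps_tested = tested, stringsAsFactors = FALSE)
    }))
  rownames(genes) <- NULL
  list(snps = counts, genes = genes[order(genes$gene), , drop = FALSE])
}
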