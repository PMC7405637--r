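#' Shift an aligned read end to its Tn5 cut site
#'
#' ATAC-seq read starts are offset from the transposition event centre:
#' forward-strand alignments are shifted by +4 bp and reverse-strand
#' alignments by -5 bp from their 3'-most base, the standard correction for
#' the 9-bp Tn5 duplication.
#'
#' @param alignment_start 0-based leftmost aligned position.
#' @param alignment_end 0-based exclusive rightmost aligned position.
#' @param strand `"+"` or `"-"` (vector recycled against the coordinates).
#' @return Integer vector of 0-based cut-site coordinates. Positions that
#'   would fall before the contig start are returned as `NA` with a warning;
#'   callers drop them.
#' @examples
#' shift_cut_site(1000L, 1050L, "+") # 1004
#' shift_cut_site(1950L, 2001L, "-") # 1995
#' @export
shift_cut_site <- function(alignment_start, alignment_end, strand) {
  stopifnot(all(strand %in% c("+", "-")))
  cut <- ifelse(strand == "+",
                alignment_start + 4L,
                (alignment_end - 1L) - 5L)
  bad <- cut < 0L
  if (any(bad)) {
    warning(sum(bad), " cut site(s) before contig start discarded")
    cut[bad] <- NA_integer_
  }
  as.integer(cut)
}

#' Assign a read to an allele at a heterozygous SNP
#'
#' @param base Observed base in the read at the SNP position (character
#'   vector; `NA` for reads not covering the position).
#' @param qual Phred base quality at that position (numeric, same length).
#' @param ref_base,alt_base The two alleles of the SNP.
#' @param min_base_quality Minimum base quality for an assignment (default 20).
#' @return Character vector in `c("REF", "ALT", "UNASSIGNED")`.
#' @export
assign_allele <- function(base, qual, ref_base, alt_base, min_base_quality = 20) {
  stopifnot(length(ref_base) == 1L, length(alt_base) == 1L,
            ref_base != alt_base)
  out <- rep("UNASSIGNED", length(base))
  ok <- !is.na(base) & !is.na(qual) & qual >= min_base_quality
  out[ok & base == ref_base] <- "REF"
  out[ok & base == alt_base] <- "ALT"
  out
}

#' Filter open-chromatin peaks by total cut-site count
#'
#' Peaks supported by few transposase cut sites are dominated by
#' nucleosome-bound signal and are removed before footprint analysis.
#'
#' @param peaks `GRanges` with a `cut_count` metadata column, as produced by
#'   [count_peak_cuts()].
#' @param min_cuts Minimum number of cut sites for a peak to be retained
#'   (default 200; peaks with fewer are removed, so a peak at exactly
#'   `min_cuts` is kept).
#' @return The retained peaks, input order preserved.
#' @export
filter_peaks <- function(peaks, min_cuts = 200) {
  stopifnot(is(peaks, "GRanges"), !is.null(peaks$cut_count))
  peaks[peaks$cut_count >= min_cuts]
}

#' Count cut sites per peak
#'
#' @param cuts A `data.frame` of cut sites (columns `chrom`, `pos`) pooled
#'   over replicates, or a `GRanges`.
#' @param peaks `GRanges` of peaks.
#' @return `peaks` with a `cut_count` metadata column.
#' @export
count_peak_cuts <- function(cuts, peaks) {
  gr <- if (is(cuts, "GRanges")) cuts else
    GenomicRanges::GRanges(cuts$chrom,
                           IRanges::IRanges(cuts$pos + 1L, width = 1L))
  peaks$cut_count <- GenomicRanges::countOverlaps(peaks, gr)
  peaks
}

#' Read and filter heterozygous SNPs from a VCF
#'
#' Keeps biallelic heterozygous single-nucleotide records with `DP` strictly
#' above `min_dp` and `MQ` strictly above `min_mq` that fall inside a retained
#' peak. Records missing `DP` or `MQ` are rejected and tallied.
#'
#' @param vcf_path Path to an (optionally bgzipped) VCF with one sample.
#' @param peaks `GRanges` of retained peaks, or `NULL` to skip the overlap
#'   requirement.
#' @param min_dp,min_mq Strict lower bounds on read depth and mapping quality
#'   (defaults 10 and 20).
#' @return A `data.frame` of heterozygous SNPs with columns `snp_id`, `chrom`,
#'   `pos` (0-based), `ref_base`, `alt_base`, `DP`, `MQ`. The number of
#'   records dropped for missing fields is attached as
#'   `attr(, "n_missing_field")`.
#' @export
filter_variants <- function(vcf_path, peaks = NULL, min_dp = 10, min_mq = 20) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(rr$REF)
  alt <- vapply(rr$ALT, function(a)
    if (length(a) == 1L) as.character(a) else NA_character_, character(1))
  gt <- if ("GT" %in% names(VariantAnnotation::geno(vcf)))
    VariantAnnotation::geno(vcf)$GT[, 1L] else rep("0/1", length(rr))
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")

  info <- VariantAnnotation::info(vcf)
  dp <- if ("DP" %in% colnames(info)) info$DP else rep(NA_integer_, length(rr))
  mq <- if ("MQ" %in% colnames(info)) info$MQ else rep(NA_real_, length(rr))
  missing_field <- is.na(dp) | is.na(mq)

  snv <- !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  keep <- het & snv & !missing_field & dp > min_dp & mq > min_mq
  keep[is.na(keep)] <- FALSE
  if (!is.null(peaks)) {
    inpeak <- IRanges::overlapsAny(rr, peaks)
    keep <- keep & inpeak
  }
  out <- data.frame(
    snp_id = rownames(vcf)[keep],
    chrom = as.character(GenomicRanges::seqnames(rr))[keep],
    pos = GenomicRanges::start(rr)[keep] - 1L,   # VCF 1-based -> 0-based
    ref_base = ref[keep],
    alt_base = alt[keep],
    DP = as.integer(dp[keep]),
    MQ = as.numeric(mq[keep]),
    stringsAsFactors = FALSE
  )
  attr(out, "n_missing_field") <- sum(missing_field)
  out
}

#' Region layout around a candidate binding site
#'
#' Partitions the neighbourhood of a motif match into the footprint (the
#' motif-match span), two shoulder intervals absorbing the fuzzy footprint
#' edges, and two flanking intervals of accessible background. Shoulder cut
#' sites are excluded from the model; the test contrasts footprint and flanks.
#' All coordinates are 0-based half-open.
#'
#' @param chrom Chromosome name.
#' @param match_start,match_end Motif-match span (0-based half-open).
#' @param snp One-row `data.frame` as from [filter_variants()]; its position
#'   must lie inside the match span.
#' @param shoulder,flank Shoulder and flank widths in bp (defaults 10 and 50).
#' @return A `site_layout` list with elements `chrom`, `footprint`,
#'   `shoulders`, `flanks` (each interval a `c(start, end)` pair), `snp`,
#'   `window` (the full span).
#' @export
site_layout <- function(chrom, match_start, match_end, snp,
                        shoulder = 10, flank = 50) {
  stopifnot(match_start < match_end, shoulder >= 1, flank >= 1)
  stopifnot(snp$pos >= match_start, snp$pos < match_end, snp$chrom == chrom)
  s <- as.integer(shoulder); f <- as.integer(flank)
  layout <- list(
    chrom = chrom,
    footprint = c(match_start, match_end),
    shoulders = list(left = c(match_start - s, match_start),
                     right = c(match_end, match_end + s)),
    flanks = list(left = c(match_start - s - f, match_start - s),
                  right = c(match_end + s, match_end + s + f)),
    snp = snp,
    window = c(match_start - s - f, match_end + s + f)
  )
  if (layout$window[1] < 0)
    stop("layout extends before contig start")
  class(layout) <- "site_layout"
  layout
}

#' @export
print.site_layout <- function(x, ...) {
  cat("site_layout on", x$chrom,
      sprintf("footprint [%d,%d) snp %s@%d %s>%s\n",
              x$footprint[1], x$footprint[2], x$snp$snp_id, x$snp$pos,
              x$snp$ref_base, x$snp$alt_base))
  invisible(x)
}

.in_interval <- function(pos, iv) pos >= iv[1] & pos < iv[2]

.region_of <- function(pos, layout) {
  out <- rep(NA_character_, length(pos))
  out[.in_interval(pos, layout$footprint)] <- "footprint"
  out[.in_interval(pos, layout$shoulders$left) |
        .in_interval(pos, layout$shoulders$right)] <- "shoulder"
  out[.in_interval(pos, layout$flanks$left) |
        .in_interval(pos, layout$flanks$right)] <- "flank"
  out
}

#' Extract allele-tagged cut sites around a candidate site
#'
#' Reads each replicate's alignments over the layout window, drops duplicate
#' and mapping-quality-0 reads, shifts read ends to Tn5 cut sites, and assigns
#' each read to an allele from its base at the SNP position.
#'
#' @param bam_files Character vector of coordinate-sorted, indexed BAM files,
#'   one per replicate (replicate id = position in the vector).
#' @param layout A [site_layout()].
#' @param min_base_quality Minimum base quality for allele assignment.
#' @param min_mapq Reads at or below this mapping quality are discarded
#'   (default 0, i.e. only MAPQ 0 is dropped).
#' @return `data.frame` of cut sites with columns `chrom`, `pos`, `strand`,
#'   `allele`, `replicate`, restricted to the layout window.
#' @export
extract_cut_sites <- function(bam_files, layout, min_base_quality = 20,
                              min_mapq = 1) {
  win <- GenomicRanges::GRanges(
    layout$chrom,
    IRanges::IRanges(layout$window[1] + 1L - 150L,
                     layout$window[2] + 150L))
  res <- lapply(seq_along(bam_files), function(r) {
    flags <- Rsamtools::scanBamFlag(isDuplicate = FALSE,
                                    isUnmappedQuery = FALSE)
    param <- Rsamtools::ScanBamParam(which = win, flag = flags,
                                     what = c("seq", "qual", "mapq"),
                                     mapqFilter = min_mapq)
    gal <- GenomicAlignments::readGAlignments(bam_files[r], param = param)
    if (length(gal) == 0L)
      return(NULL)
    strand <- as.character(GenomicAlignments::strand(gal))
    cut <- shift_cut_site(GenomicAlignments::start(gal) - 1L,
                          GenomicAlignments::end(gal), strand)
    base <- rep(NA_character_, length(gal))
    qual <- rep(NA_real_, length(gal))
    names(gal) <- seq_along(gal)
    snp_gr <- GenomicRanges::GRanges(
      layout$chrom, IRanges::IRanges(layout$snp$pos + 1L, width = 1L))
    hits <- GenomicAlignments::mapToAlignments(snp_gr, gal)
    ok <- GenomicRanges::width(hits) == 1L
    if (any(ok)) {
      idx <- S4Vectors::mcols(hits)$alignmentsHits[ok]
      qpos <- GenomicRanges::start(hits)[ok]
      seqs <- S4Vectors::mcols(gal)$seq[idx]
      quals <- S4Vectors::mcols(gal)$qual[idx]
      base[idx] <- substr(as.character(seqs), qpos, qpos)
      qual[idx] <- vapply(seq_along(idx), function(i)
        utf8ToInt(substr(as.character(quals[i]), qpos[i], qpos[i])) - 33L,
        numeric(1))
    }
    allele <- assign_allele(base, qual, layout$snp$ref_base,
                            layout$snp$alt_base, min_base_quality)
    keep <- !is.na(cut) & .in_interval(cut, layout$window)
    if (!any(keep)) return(NULL)
    data.frame(chrom = layout$chrom, pos = cut[keep], strand = strand[keep],
               allele = allele[keep], replicate = r,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(chrom = character(), pos = integer(),
                      strand = character(), allele = character(),
                      replicate = integer(), stringsAsFactors = FALSE)
  out
}

#' Count cut sites by allele and region
#'
#' Builds the response table for the interaction model: counts of allele-
#' assigned cut sites in the footprint and flank regions, per replicate.
#' Shoulder and unassigned cut sites are excluded from the counts but tallied.
#'
#' @param cuts `data.frame` from [extract_cut_sites()].
#' @param layout A [site_layout()].
#' @param n_replicates Number of replicates in the experiment; defaults to the
#'   maximum replicate id seen (pass explicitly when a replicate may have zero
#'   cuts).
#' @return `data.frame` (a "CountTable") with columns `replicate`, `allele`,
#'   `region`, `count`, containing all `2 x 2 x R` cells. Tallies of excluded
#'   cut sites are attached as `attr(, "n_shoulder")` and
#'   `attr(, "n_unassigned")`.
#' @export
count_cuts_by_region <- function(cuts, layout, n_replicates = NULL) {
  if (is.null(n_replicates))
    n_replicates <- if (nrow(cuts)) max(cuts$replicate) else 1L
  region <- .region_of(cuts$pos, layout)
  in_model <- region %in% c("footprint", "flank") & cuts$allele %in% c("REF", "ALT")
  n_shoulder <- sum(region %in% "shoulder", na.rm = TRUE)
  n_unassigned <- sum(!(cuts$allele %in% c("REF", "ALT")) &
                        region %in% c("footprint", "flank"))
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      allele = c("REF", "ALT"),
                      region = c("footprint", "flank"),
                      stringsAsFactors = FALSE)
  key <- paste(grid$replicate, grid$allele, grid$region)
  obs <- table(paste(cuts$replicate[in_model], cuts$allele[in_model],
                     region[in_model]))
  grid$count <- as.integer(obs[key])
  grid$count[is.na(grid$count)] <- 0L
  attr(grid, "n_shoulder") <- n_shoulder
  attr(grid, "n_unassigned") <- n_unassigned
  grid
}
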