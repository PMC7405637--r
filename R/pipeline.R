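PIPELINE_KEYS <- c(
  "bam_files", "sam_files", "peaks", "vcf", "fasta", "motifs",
  "tss_table", "interactions", "eqtls", "ase_counts", "output_dir",
  "min_cuts", "min_dp", "min_mq", "min_base_quality", "score_threshold",
  "fdr_max", "min_abs_delta", "min_abs_log2_magnitude", "shoulder", "flank",
  "alpha_ase", "dispersion_mode", "seed")

#' Read a pipeline configuration file
#'
#' Plain `key = value` lines (`#` comments allowed). Unknown keys are
#' rejected. File-list values (`bam_files`, `sam_files`) are comma-separated.
#'
#' @param path Path to the config file.
#' @return Named list of settings merged over the defaults of
#'   [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  out <- list()
  for (l in lines) {
    kv <- strsplit(l, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", l)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    if (!key %in% PIPELINE_KEYS) stop("unknown config key: ", key)
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
      else if (grepl(",", val)) trimws(strsplit(val, ",")[[1]])
      else val
  }
  out
}

.cut_sites_genomewide <- function(bam_files, min_mapq = 1) {
  do.call(rbind, lapply(seq_along(bam_files), function(r) {
    flags <- Rsamtools::scanBamFlag(isDuplicate = FALSE,
                                    isUnmappedQuery = FALSE)
    param <- Rsamtools::ScanBamParam(flag = flags, mapqFilter = min_mapq)
    gal <- GenomicAlignments::readGAlignments(bam_files[r], param = param)
    if (length(gal) == 0L) return(NULL)
    strand <- as.character(GenomicAlignments::strand(gal))
    cut <- shift_cut_site(GenomicAlignments::start(gal) - 1L,
                          GenomicAlignments::end(gal), strand)
    ok <- !is.na(cut)
    data.frame(chrom = as.character(GenomicAlignments::seqnames(gal))[ok],
               pos = cut[ok], replicate = r, stringsAsFactors = FALSE)
  }))
}

#' Run the full ASB detection workflow
#'
#' Executes the six stages — cut-site extraction and first-round filters,
#' motif scanning and candidate calling, the negative-binomial interaction
#' model with FDR control, the second-round empirical filter, target-gene
#' annotation with eQTL overlap, and allele-specific expression — writing
#' per-stage TSVs, a funnel summary of record counts, and a JSON run
#' manifest to `output_dir`.
#'
#' @param config Path to a [read_pipeline_config()] file or an equivalent
#'   named list. Required entries: `bam_files` (or `sam_files`, converted
#'   on the fly), `peaks`, `vcf`, `fasta`, `motifs`. Optional: `tss_table`,
#'   `interactions`, `eqtls`, `ase_counts`, thresholds (`min_cuts`,
#'   `min_dp`, `min_mq`, `min_base_quality`, `score_threshold`, `fdr_max`,
#'   `min_abs_delta`, `min_abs_log2_magnitude`, `shoulder`, `flank`,
#'   `alpha_ase`, `dispersion_mode`, `seed`).
#' @param output_dir Output directory; overrides `config$output_dir`.
#' @return List with `calls` (the full per-candidate table), `snp_summary`,
#'   `annotation`, `ase`, `enrichment`, `summary` (the filter funnel), and
#'   `paths` of the written files.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- read_pipeline_config(config)
  defaults <- list(min_cuts = 200, min_dp = 10, min_mq = 20,
                   min_base_quality = 20, score_threshold = NA,
                   fdr_max = 0.05, min_abs_delta = 5,
                   min_abs_log2_magnitude = 1, shoulder = 10, flank = 50,
                   alpha_ase = 0.05, dispersion_mode = "common", seed = 1)
  cfg <- utils::modifyList(defaults, config)
  if (is.null(output_dir)) output_dir <- cfg$output_dir
  if (is.null(output_dir)) stop("input error: no output_dir", call. = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(as.integer(cfg$seed))

  for (key in c("peaks", "vcf", "fasta", "motifs"))
    if (is.null(cfg[[key]]) || !file.exists(cfg[[key]]))
      stop("input error [", key, "]: missing file", call. = FALSE)
  if (is.null(cfg$bam_files)) {
    if (is.null(cfg$sam_files)) stop("input error: no alignments",
                                     call. = FALSE)
    cfg$bam_files <- vapply(cfg$sam_files, sam_to_bam, character(1))
  }

  msg <- function(...) message("[atacASB] ", ...)

  # -- stage 1: cut sites, peak + variant filters ---------------------------
  msg("stage cutsites: extracting genome-wide cut sites")
  cuts_all <- .cut_sites_genomewide(cfg$bam_files)
  peaks <- rtracklayer::import(cfg$peaks)
  peaks <- count_peak_cuts(cuts_all, peaks)
  n_peaks_in <- length(peaks)
  peaks <- filter_peaks(peaks, min_cuts = cfg$min_cuts)
  snps <- filter_variants(cfg$vcf, peaks, min_dp = cfg$min_dp,
                          min_mq = cfg$min_mq)
  msg(sprintf("peaks %d -> %d; het SNPs retained %d",
              n_peaks_in, length(peaks), nrow(snps)))

  # -- stage 2: motif scan + candidates -------------------------------------
  genome <- Biostrings::readDNAStringSet(cfg$fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome_chr <- setNames(as.character(genome), names(genome))
  pfms <- read_jaspar_pfm(cfg$motifs)
  pssms <- lapply(names(pfms), function(id)
    pssm_from_counts(pfms[[id]], motif_id = id))
  names(pssms) <- names(pfms)

  matches <- NULL
  for (id in names(pssms)) {
    pssm <- pssms[[id]]
    thr <- if (is.na(cfg$score_threshold)) pssm_score_threshold(pssm)
           else cfg$score_threshold
    L <- pssm$length
    for (p in seq_along(peaks)) {
      chrom <- as.character(GenomicRanges::seqnames(peaks))[p]
      s0 <- GenomicRanges::start(peaks)[p] - 1L
      e0 <- GenomicRanges::end(peaks)[p]
      ref_seq <- substr(genome_chr[[chrom]], s0 + 1L, e0)
      insnp <- snps[snps$chrom == chrom & snps$pos >= s0 & snps$pos < e0, ,
                    drop = FALSE]
      alt_seq <- ref_seq
      for (k in seq_len(nrow(insnp))) {
        rel <- insnp$pos[k] - s0 + 1L
        if (toupper(substr(alt_seq, rel, rel)) == insnp$ref_base[k])
          substr(alt_seq, rel, rel) <- insnp$alt_base[k]
      }
      m <- scan_sequences(pssm, ref_seq,
                          if (nrow(insnp)) alt_seq else NULL,
                          score_threshold = thr, chrom = chrom, offset = s0)
      matches <- rbind(matches, m)
    }
  }
  candidates <- call_candidate_sites(matches, snps, pssms, genome_chr,
                                     shoulder = cfg$shoulder,
                                     flank = cfg$flank)
  msg(sprintf("motif matches %d; candidate (SNP x motif) sites %d",
              if (is.null(matches)) 0L else nrow(matches),
              length(candidates)))

  # -- stage 3: counts + model ----------------------------------------------
  n_reps <- length(cfg$bam_files)
  count_tables <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    lay <- candidates[[i]]$layout
    cuts <- extract_cut_sites(cfg$bam_files, lay,
                              min_base_quality = cfg$min_base_quality)
    count_tables[[i]] <- count_cuts_by_region(cuts, lay,
                                              n_replicates = n_reps)
  }
  disruption <- do.call(rbind, lapply(candidates, `[[`, "disruption"))
  names(count_tables) <- sprintf("cand%04d", seq_along(candidates))
  fits <- fit_asb_sites(count_tables, dispersion = cfg$dispersion_mode)
  calls <- cbind(disruption, fits[, setdiff(names(fits), "site_id")])
  n_sig <- sum(calls$qvalue < cfg$fdr_max, na.rm = TRUE)

  # -- stage 4: empirical filter --------------------------------------------
  calls <- empirical_filter(calls, fdr_max = cfg$fdr_max,
                            min_abs_delta = cfg$min_abs_delta,
                            min_abs_log2_magnitude = cfg$min_abs_log2_magnitude)
  snp_summary <- summarize_snps(calls)
  msg(sprintf("significant sites %d; retained after empirical filter %d; regulatory SNPs %d",
              n_sig, sum(calls$verdict == "significant"), nrow(snp_summary)))

  # -- stage 5: annotation --------------------------------------------------
  annotation <- NULL; enrichment <- NULL
  reg_snps <- snps[snps$snp_id %in% snp_summary$snp_id, , drop = FALSE]
  if (!is.null(cfg$tss_table) && nrow(reg_snps)) {
    tss <- read.delim(cfg$tss_table, stringsAsFactors = FALSE)
    annotation <- classify_snp_location(reg_snps, tss)
    if (!is.null(cfg$interactions)) {
      inter <- read.delim(cfg$interactions, stringsAsFactors = FALSE)
      enh <- annotation$snp_id[annotation$class == "enhancer_candidate"]
      tg <- map_enhancer_targets(
        reg_snps[reg_snps$snp_id %in% enh, , drop = FALSE], inter)
      annotation$enhancer_targets <- vapply(annotation$snp_id, function(id)
        if (id %in% names(tg)) paste(tg[[id]], collapse = ",") else "",
        character(1))
    }
  }
  if (!is.null(cfg$eqtls) && nrow(snps)) {
    eq <- read.delim(cfg$eqtls, stringsAsFactors = FALSE)
    flag <- overlap_eqtl(snps, eq)
    isreg <- snps$snp_id %in% snp_summary$snp_id
    if (!is.null(annotation))
      annotation$eqtl_flag <- flag[match(annotation$snp_id, snps$snp_id)]
    tab <- rbind(regulatory = c(sum(isreg & flag), sum(isreg & !flag)),
                 other = c(sum(!isreg & flag), sum(!isreg & !flag)))
    enrichment <- tryCatch(enrichment_test(tab), error = function(e) NULL)
  }

  # -- stage 6: allele-specific expression ----------------------------------
  ase <- NULL
  if (!is.null(cfg$ase_counts)) {
    ac <- read.delim(cfg$ase_counts, stringsAsFactors = FALSE)
    ase <- call_ase_genes(ac, alpha = cfg$alpha_ase)
  }

  funnel <- data.frame(
    open_regions = length(peaks), het_snps = nrow(snps),
    potential_sites = length(candidates),
    tested_sites = sum(calls$converged),
    significant = n_sig,
    retained = sum(calls$verdict == "significant"),
    regulatory_snps = nrow(snp_summary))

  counts_df <- do.call(rbind, lapply(seq_along(candidates), function(i)
    cbind(candidate = names(count_tables)[i],
          snp_id = candidates[[i]]$disruption$snp_id,
          count_tables[[i]])))

  paths <- list(
    calls = file.path(output_dir, "asb_calls.tsv"),
    counts = file.path(output_dir, "allele_counts.tsv"),
    snp_summary = file.path(output_dir, "regulatory_snps.tsv"),
    summary = file.path(output_dir, "summary.tsv"),
    manifest = file.path(output_dir, "manifest.json"))
  .write_tsv(calls, paths$calls)
  if (!is.null(counts_df)) .write_tsv(counts_df, paths$counts)
  .write_tsv(snp_summary, paths$snp_summary)
  .write_tsv(funnel, paths$summary)
  if (!is.null(annotation)) {
    paths$annotation <- file.path(output_dir, "annotation.tsv")
    .write_tsv(annotation, paths$annotation)
  }
  if (!is.null(ase)) {
    paths$ase_snps <- file.path(output_dir, "ase_snps.tsv")
    paths$ase_genes <- file.path(output_dir, "ase_genes.tsv")
    .write_tsv(ase$snps, paths$ase_snps)
    .write_tsv(ase$genes, paths$ase_genes)
  }
  manifest <- list(
    package = "atacASB",
    version = as.character(utils::packageVersion("atacASB")),
    r_version = R.version.string,
    seed = cfg$seed,
    thresholds = cfg[c("min_cuts", "min_dp", "min_mq", "min_base_quality",
                       "fdr_max", "min_abs_delta", "min_abs_log2_magnitude",
                       "shoulder", "flank", "alpha_ase", "dispersion_mode")],
    funnel = as.list(funnel))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             paths$manifest)

  list(calls = calls, snp_summary = snp_summary, annotation = annotation,
       ase = ase, enrichment = enrichment, summary = funnel, paths = paths)
}
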