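#' Simulation configuration
#'
#' Bundles the parameters of the synthetic data generator. The defaults
#' describe the study conditions the model targets: three replicate
#' libraries, an expected flank count of 50 cuts per allele per replicate, a
#' two-fold footprint depletion under binding, negative-binomial dispersion
#' 0.1, and an interaction effect of 1.5 on the log scale at ASB sites.
#'
#' @param n_sites Number of candidate sites.
#' @param fraction_asb Fraction of sites with a true allele-specific effect.
#' @param beta_int_effect Absolute true interaction coefficient at ASB sites
#'   (log scale); its sign per site is set opposite to the planted motif
#'   disruption, so simulated effects are sign-consistent.
#' @param cell_mean Expected flank count per allele per replicate.
#' @param footprint_depth Flank/footprint mean ratio under binding (>= 1).
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param replicates Number of replicate libraries.
#' @param seed Master seed fixing every downstream draw.
#' @param motif_length Length of the planted motif.
#' @param shoulder,flank Region geometry used for read placement.
#' @param read_length Read length for read-level output.
#' @param gc_skew Optional background GC skew in `(-0.25, 0.25)`; 0 gives a
#'   uniform background.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_sites = 100, fraction_asb = 0.3,
                       beta_int_effect = 1.5, cell_mean = 50,
                       footprint_depth = 2, dispersion = 0.1,
                       replicates = 3, seed = 42, motif_length = 12,
                       shoulder = 10, flank = 50, read_length = 100,
                       gc_skew = 0) {
  stopifnot(n_sites >= 1, fraction_asb >= 0, fraction_asb <= 1,
            cell_mean > 0, footprint_depth >= 1, dispersion >= 0,
            replicates >= 1, motif_length >= 4, abs(gc_skew) < 0.25)
  structure(list(n_sites = as.integer(n_sites), fraction_asb = fraction_asb,
                 beta_int_effect = beta_int_effect, cell_mean = cell_mean,
                 footprint_depth = footprint_depth, dispersion = dispersion,
                 replicates = as.integer(replicates), seed = as.integer(seed),
                 motif_length = as.integer(motif_length),
                 shoulder = as.integer(shoulder), flank = as.integer(flank),
                 read_length = as.integer(read_length), gc_skew = gc_skew),
            class = "sim_config")
}

.rnb <- function(n, mu, dispersion) {
  if (dispersion <= 0) rpois(n, mu) else rnbinom(n, size = 1 / dispersion, mu = mu)
}

#' Simulate the count table of one candidate site
#'
#' Draws `y(allele, region, replicate)` from the negative-binomial
#' log-linear model `log mu = b0 + b_r x_r + b_a x_a + b_int x_r x_a` with
#' `b0 = log(cell_mean / footprint_depth)`, `b_r = log(footprint_depth)`,
#' `b_a = 0`, and `b_int = +/- beta_int_effect` at ASB sites, 0 otherwise.
#'
#' @param config A [sim_config()].
#' @param is_asb Whether the site carries a true effect.
#' @param sign Sign of the effect at an ASB site (+1 gain on variant,
#'   -1 loss).
#' @param seed Optional seed set before drawing (`NULL` to draw from the
#'   current RNG stream).
#' @return List with `counts` (CountTable `data.frame`) and `truth`
#'   (the four true coefficients and `is_asb`).
#' @export
simulate_site <- function(config, is_asb = FALSE, sign = -1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b0 <- log(config$cell_mean / config$footprint_depth)
  b <- c(b0, log(config$footprint_depth), 0,
         if (is_asb) sign * config$beta_int_effect else 0)
  grid <- expand.grid(replicate = seq_len(config$replicates),
                      allele = c("REF", "ALT"),
                      region = c("footprint", "flank"),
                      stringsAsFactors = FALSE)
  x_r <- as.integer(grid$region == "flank")
  x_a <- as.integer(grid$allele == "ALT")
  mu <- exp(b[1] + b[2] * x_r + b[3] * x_a + b[4] * x_r * x_a)
  grid$count <- .rnb(nrow(grid), mu, config$dispersion)
  list(counts = grid,
       truth = list(beta0 = b[1], beta_r = b[2], beta_a = b[3],
                    beta_int = b[4], is_asb = is_asb))
}

.random_seq <- function(n, gc_skew = 0) {
  p <- c(0.25 - gc_skew, 0.25 + gc_skew, 0.25 + gc_skew, 0.25 - gc_skew)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# strong planted motif: 97/1/1/1 counts per column around a random consensus
.sim_motif <- function(motif_length) {
  consensus <- sample(BASES, motif_length, replace = TRUE)
  m <- matrix(1, 4, motif_length, dimnames = list(BASES, NULL))
  m[cbind(match(consensus, BASES), seq_len(motif_length))] <- 97
  m
}

#' Simulate a complete input bundle with known ground truth
#'
#' Generates a synthetic chromosome with one planted motif instance per
#' candidate site, injects a heterozygous SNP into every motif span, draws
#' per-site count tables from the interaction model, and writes all files in
#' their standard formats: genome FASTA, VCF (with DP/MQ), peak BED, JASPAR
#' pfm, a per-site CountTable TSV, a truth TSV, and (optionally) one
#' coordinate-sorted SAM per replicate whose shifted, allele-assigned cut
#' sites reproduce the drawn counts exactly.
#'
#' At ASB sites the sign of the true interaction is opposite to the planted
#' deltaPSSM (gain of binding on the allele that scores higher), alternating
#' between gain and loss across sites.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param read_level Also emit SAM alignments realising the counts.
#' @return List with file paths (`fasta`, `vcf`, `peaks`, `pfm`, `counts`,
#'   `truth`, `sams`), plus in-memory `genome`, `snps`, `truth`,
#'   `count_tables`, `layouts`, and `motif_id`.
#' @export
simulate_dataset <- function(config = sim_config(), dir = tempfile("simasb"),
                             read_level = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  L <- config$motif_length
  spacing <- 1000L
  margin <- 500L
  chrom <- "chrSim"
  chrom_len <- margin * 2L + spacing * config$n_sites
  genome_seq <- .random_seq(chrom_len, config$gc_skew)

  pfm <- .sim_motif(L)
  motif_id <- "SIMTF1"
  pssm <- pssm_from_counts(pfm, motif_id = motif_id)
  consensus <- BASES[apply(pfm, 2, which.max)]
  snp_col <- which.max(apply(pssm$matrix, 2, function(s) max(s) - min(s)))

  n_asb <- round(config$n_sites * config$fraction_asb)
  is_asb <- c(rep(TRUE, n_asb), rep(FALSE, config$n_sites - n_asb))

  snps <- NULL; truth <- NULL
  count_tables <- list(); layouts <- list()
  gain <- FALSE  # alternate loss/gain across ASB sites
  for (i in seq_len(config$n_sites)) {
    start <- margin + (i - 1L) * spacing          # 0-based motif start
    # plant the motif consensus
    planted <- consensus
    weak <- BASES[which.min(pssm$matrix[, snp_col])]
    if (is_asb[i]) gain <- !gain
    gain_i <- if (is_asb[i]) gain else (i %% 2 == 0)
    # gain site: reference carries the weak base, variant restores consensus
    ref_base <- if (gain_i) weak else consensus[snp_col]
    alt_base <- if (gain_i) consensus[snp_col] else weak
    planted[snp_col] <- ref_base
    substr(genome_seq, start + 1L, start + L) <-
      paste(planted, collapse = "")
    snp_pos <- start + snp_col - 1L
    snp <- data.frame(snp_id = sprintf("snp%03d", i), chrom = chrom,
                      pos = snp_pos, ref_base = ref_base,
                      alt_base = alt_base, DP = 60L, MQ = 60L,
                      stringsAsFactors = FALSE)
    snps <- rbind(snps, snp)
    sgn <- if (gain_i) 1 else -1
    site <- simulate_site(config, is_asb = is_asb[i], sign = sgn)
    id <- snp$snp_id
    count_tables[[id]] <- site$counts
    layouts[[id]] <- site_layout(chrom, start, start + L, snp,
                                 shoulder = config$shoulder,
                                 flank = config$flank)
    truth <- rbind(truth, data.frame(
      site_id = id, snp_id = id, chrom = chrom, motif_start = start,
      snp_pos = snp_pos, is_asb = is_asb[i],
      beta_int_true = site$truth$beta_int,
      delta_sign = if (gain_i) -1 else 1, stringsAsFactors = FALSE))
  }

  fasta <- file.path(dir, "genome.fa")
  gen <- Biostrings::DNAStringSet(setNames(genome_seq, chrom))
  Biostrings::writeXStringSet(gen, fasta)
  vcf <- file.path(dir, "variants.vcf")
  .write_sim_vcf(snps, vcf)
  pfm_path <- file.path(dir, "motif.pfm")
  write_jaspar_pfm(setNames(list(pfm), motif_id), pfm_path)
  peaks_gr <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(start = truth$motif_start + 1L - 200L,
                            end = truth$motif_start + L + 200L))
  peaks <- file.path(dir, "peaks.bed")
  rtracklayer::export(peaks_gr, peaks, format = "BED")
  counts_df <- do.call(rbind, lapply(names(count_tables), function(id)
    cbind(site_id = id, count_tables[[id]])))
  counts_path <- file.path(dir, "counts.tsv")
  .write_tsv(counts_df, counts_path)
  truth_path <- file.path(dir, "truth.tsv")
  .write_tsv(truth, truth_path)

  sams <- NULL
  if (read_level)
    sams <- .emit_reads(config, genome_seq, chrom, chrom_len, snps,
                        layouts, count_tables, dir)

  list(fasta = fasta, vcf = vcf, peaks = peaks, pfm = pfm_path,
       counts = counts_path, truth = truth_path, sams = sams,
       genome = setNames(genome_seq, chrom), snps = snps, truth_table = truth,
       count_tables = count_tables, layouts = layouts, motif_id = motif_id)
}

# place cut sites uniformly within their region and wrap each in a read that
# covers the SNP (forward read for cuts left of the SNP, reverse otherwise)
.emit_reads <- function(config, genome_seq, chrom, chrom_len, snps,
                        layouts, count_tables, dir) {
  rl <- config$read_length
  reads_by_rep <- replicate(config$replicates,
                            list(pos0 = integer(), flag = integer(),
                                 seq = character()), simplify = FALSE)
  for (id in names(count_tables)) {
    lay <- layouts[[id]]
    snp <- lay$snp
    tab <- count_tables[[id]]
    region_pos <- function(region, n) {
      if (n == 0L) return(integer())
      if (region == "footprint") {
        lay$footprint[1] + sample.int(diff(lay$footprint), n, replace = TRUE) - 1L
      } else {
        lens <- c(diff(lay$flanks$left), diff(lay$flanks$right))
        side <- sample.int(2L, n, replace = TRUE, prob = lens / sum(lens))
        starts <- c(lay$flanks$left[1], lay$flanks$right[1])
        starts[side] + sample.int(lens[1], n, replace = TRUE) - 1L
      }
    }
    for (r in seq_len(config$replicates)) {
      sub <- tab[tab$replicate == r, ]
      # a few unphasable shoulder cuts exercise the exclusion tallies
      sh_n <- rpois(1, config$cell_mean / 10)
      sh_pos <- if (sh_n > 0)
        lay$shoulders$left[1] +
          sample.int(2L * config$shoulder, sh_n, replace = TRUE) - 1L
      else integer()
      sh_pos <- ifelse(sh_pos >= lay$footprint[1],
                       sh_pos + diff(lay$footprint), sh_pos)
      cuts <- data.frame(pos = integer(), allele = character())
      for (k in seq_len(nrow(sub)))
        cuts <- rbind(cuts, data.frame(
          pos = region_pos(sub$region[k], sub$count[k]),
          allele = sub$allele[k], stringsAsFactors = FALSE))
      if (sh_n > 0)
        cuts <- rbind(cuts, data.frame(
          pos = sh_pos, allele = sample(c("REF", "ALT"), sh_n, replace = TRUE),
          stringsAsFactors = FALSE))
      if (nrow(cuts) == 0L) next
      fwd <- cuts$pos <= snp$pos
      pos0 <- ifelse(fwd, cuts$pos - 4L, cuts$pos + 5L - rl + 1L)
      flag <- ifelse(fwd, 0L, 16L)
      seqs <- substring(genome_seq, pos0 + 1L, pos0 + rl)
      off <- snp$pos - pos0 + 1L
      base <- ifelse(cuts$allele == "ALT", snp$alt_base, snp$ref_base)
      covered <- off >= 1L & off <= rl
      stopifnot(all(covered))
      substr(seqs, off, off) <- base
      reads_by_rep[[r]]$pos0 <- c(reads_by_rep[[r]]$pos0, pos0)
      reads_by_rep[[r]]$flag <- c(reads_by_rep[[r]]$flag, flag)
      reads_by_rep[[r]]$seq <- c(reads_by_rep[[r]]$seq, seqs)
    }
  }
  sams <- character(config$replicates)
  for (r in seq_len(config$replicates)) {
    df <- data.frame(name = sprintf("read_r%d_%06d", r,
                                    seq_along(reads_by_rep[[r]]$pos0)),
                     pos0 = reads_by_rep[[r]]$pos0,
                     flag = reads_by_rep[[r]]$flag,
                     seq = reads_by_rep[[r]]$seq, stringsAsFactors = FALSE)
    sams[r] <- file.path(dir, sprintf("replicate%d.sam", r))
    .write_sim_sam(df, chrom, chrom_len, sams[r])
  }
  sams
}

#' Simulate allelic expression counts with known ground truth
#'
#' Each gene carries one coding heterozygous SNP; a fraction of genes is
#' imbalanced at the stated allele fraction, the rest are balanced at 0.5.
#'
#' @param n_genes Number of genes.
#' @param imbalance Reference-allele fraction at imbalanced genes
#'   (in `(0, 1)`).
#' @param depth Total allelic read count per SNP (0 gives untestable genes).
#' @param seed Seed for the draws.
#' @param fraction_imbalanced Fraction of genes that are imbalanced
#'   (default 0.5).
#' @return List with `counts` (`gene`, `snp`, `ref_count`, `alt_count`) and
#'   `truth` (`gene`, `imbalanced`).
#' @export
simulate_ase <- function(n_genes = 50, imbalance = 0.9, depth = 50,
                         seed = 42, fraction_imbalanced = 0.5) {
  stopifnot(imbalance > 0, imbalance < 1, depth >= 0)
  set.seed(seed)
  n_imb <- round(n_genes * fraction_imbalanced)
  imb <- c(rep(TRUE, n_imb), rep(FALSE, n_genes - n_imb))
  p <- ifelse(imb, imbalance, 0.5)
  ref <- rbinom(n_genes, depth, p)
  counts <- data.frame(gene = sprintf("gene%03d", seq_len(n_genes)),
                       snp = sprintf("csnp%03d", seq_len(n_genes)),
                       ref_count = ref, alt_count = depth - ref,
                       stringsAsFactors = FALSE)
  truth <- data.frame(gene = counts$gene, imbalanced = imb,
                      stringsAsFactors = FALSE)
  list(counts = counts, truth = truth)
}
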