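#' Read motifs from a JASPAR pfm file
#'
#' Accepts the JASPAR 2016+ format (`>ID name` header followed by four
#' `A [ ... ]` count rows) and the bare four-row variant, possibly with
#' several motifs per file.
#'
#' @param path Path to the pfm file.
#' @return Named list of 4 x L count matrices (rows A, C, G, T).
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (startsWith(lines[i], ">")) {
      id <- strsplit(sub("^>", "", lines[i]), "[ \t]+")[[1]][1]
      rows <- lines[(i + 1L):(i + 4L)]
      i <- i + 5L
    } else {
      id <- paste0("motif", length(out) + 1L)
      rows <- lines[i:(i + 3L)]
      i <- i + 4L
    }
    parsed <- lapply(rows, function(r) {
      r <- sub("^[ACGTacgt][ :|]*", "", trimws(r))
      r <- gsub("[][]", " ", r)
      as.numeric(strsplit(trimws(r), "[ \t]+")[[1]])
    })
    if (length(unique(lengths(parsed))) != 1L)
      stop("malformed pfm record: ", id)
    mat <- do.call(rbind, parsed)
    rownames(mat) <- BASES
    out[[id]] <- mat
  }
  out
}

#' Write motifs to a JASPAR pfm file
#'
#' @param motifs Named list of 4 x L count matrices.
#' @param path Output path.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(motifs)) {
    writeLines(paste0(">", id), con)
    m <- motifs[[id]]
    for (b in 1:4)
      writeLines(sprintf("%s  [ %s ]", BASES[b],
                         paste(format(m[b, ], trim = TRUE), collapse = " ")),
                 con)
  }
}

# minimal single-sample VCF emitter for simulated variants (text fixture)
.write_sim_vcf <- function(snps, path, sample = "SIM") {
  head <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##contig=<ID=", unique(snps$chrom), ">"),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample, sep = "\t"))
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t100\tPASS\tDP=%d;MQ=%d\tGT\t0/1",
                  snps$chrom, snps$pos + 1L, snps$snp_id, snps$ref_base,
                  snps$alt_base, snps$DP, snps$MQ)
  writeLines(c(head, body), path)
}

# minimal coordinate-sorted SAM emitter; reads is a data.frame with
# pos0 (leftmost, 0-based), flag, seq
.write_sim_sam <- function(reads, chrom, chrom_len, path) {
  head <- c("@HD\tVN:1.6\tSO:coordinate",
            sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  reads <- reads[order(reads$pos0), , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                  reads$name, reads$flag, chrom, reads$pos0 + 1L,
                  nchar(reads$seq), reads$seq,
                  strrep("I", nchar(reads$seq[1])))
  writeLines(c(head, body), path)
}

#' Convert a SAM fixture to an indexed BAM
#'
#' @param sam_path Path to a SAM file.
#' @return Path to the sorted, indexed BAM.
#' @export
sam_to_bam <- function(sam_path) {
  dest <- sub("\\.sam$", "", sam_path)
  bam <- Rsamtools::asBam(sam_path, dest, overwrite = TRUE,
                          indexDestination = TRUE)
  bam
}

.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
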