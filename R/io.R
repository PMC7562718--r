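# Sequence and table I/O. FASTA/FASTQ go through Biostrings; the collapsed
# small-RNA FASTA convention (">id_xN" headers carrying the read count) is a
# micro-format handled here.

revcomp_chr <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read small-RNA reads from FASTA/FASTQ
#'
#' Collapsed FASTA headers of the form `id_xN` (or `id:N`, `id-N` as a
#' fallback when `_xN` is absent) carry the read count N; FASTQ and plain
#' FASTA records count 1 each and are collapsed by sequence.
#'
#' @param path Input file.
#' @param format `"fasta"` or `"fastq"` (guessed from the extension by default).
#' @return `data.frame(sequence, count)`, unique sequences, U normalized to T.
#' @export
read_srna_fasta <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  ss <- Biostrings::readDNAStringSet(path, format = format)
  cnt <- rep(1, length(ss))
  if (format == "fasta") {
    m <- regmatches(names(ss), regexec("_x([0-9]+)\\s*$", names(ss)))
    has <- lengths(m) == 2L
    cnt[has] <- as.numeric(vapply(m[has], `[`, character(1), 2L))
  }
  collapse_reads(data.frame(sequence = normalize_seq(as.character(ss)),
                            count = cnt, stringsAsFactors = FALSE))
}

#' Write reads as collapsed FASTA
#'
#' @param reads `data.frame(sequence, count)`.
#' @param path Output path.
#' @param prefix Read-id prefix.
#' @export
write_srna_fasta <- function(reads, path, prefix = "read") {
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- sprintf("%s%d_x%d", prefix, seq_len(nrow(reads)),
                       as.integer(round(reads$count)))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

collapse_reads <- function(reads) {
  if (!nrow(reads))
    return(data.frame(sequence = character(0), count = numeric(0),
                      stringsAsFactors = FALSE))
  agg <- rowsum(as.numeric(reads$count), group = reads$sequence)
  out <- data.frame(sequence = rownames(agg), count = as.numeric(agg[, 1L]),
             stringsAsFactors = FALSE)
  out[order(out$sequence, method = "radix"), , drop = FALSE]
}

#' Read a reference FASTA
#' @param path FASTA file.
#' @return Named [Biostrings::DNAStringSet].
#' @export
read_reference <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  names(ss) <- sub("\\s.*$", "", names(ss))
  ss
}

#' Read degradome tags
#'
#' Accepts a TSV with columns (transcript, pos1, count) or a collapsed FASTA
#' of tag sequences.
#' @param path Input file.
#' @return A data frame with either (transcript, pos1, count) or
#'   (sequence, count) columns.
#' @export
read_degradome_tags <- function(path) {
  if (grepl("\\.(fa|fasta)(\\.gz)?$", path, ignore.case = TRUE))
    return(read_srna_fasta(path))
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("transcript", "pos1", "count") %in% names(df)))
  df
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called loci as GFF3
#'
#' One `siRNA_locus` feature per locus with period, register, phase score and
#' any trigger annotation in the attributes column.
#'
#' @param loci Locus table from [scan_phas_loci()] (optionally annotated by
#'   [annotate_trigger()]).
#' @param path Output path.
#' @export
write_loci_gff3 <- function(loci, path) {
  if (!nrow(loci)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = loci$ref,
    ranges = IRanges::IRanges(start = loci$start1, end = loci$end1),
    strand = "+")
  S4Vectors::mcols(gr)$source <- "phasir"
  S4Vectors::mcols(gr)$type <- "siRNA_locus"
  S4Vectors::mcols(gr)$score <- round(loci$score, 4)
  S4Vectors::mcols(gr)$ID <- loci$locus_id
  S4Vectors::mcols(gr)$period <- loci$period
  S4Vectors::mcols(gr)$phase_register <- loci$register
  if ("trigger" %in% names(loci)) {
    S4Vectors::mcols(gr)$trigger <- loci$trigger
    S4Vectors::mcols(gr)$trigger_cleavage <- loci$trigger_cleavage1
  }
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
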