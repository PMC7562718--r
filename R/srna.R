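#' Filter collapsed reads by length
#'
#' Keeps reads whose length lies in the standard clean-read size window
#' (18-30 nt by default); counts are preserved.
#'
#' @param reads `data.frame(sequence, count)`.
#' @param min_len,max_len Inclusive length bounds (nt).
#' @return Filtered reads.
#' @export
filter_reads <- function(reads, min_len = 18L, max_len = 30L) {
  if (min_len > max_len) stop("min_len must not exceed max_len")
  len <- nchar(reads$sequence)
  reads[len >= min_len & len <= max_len, , drop = FALSE]
}

#' Exactly map collapsed reads to a reference
#'
#' Reports every exact occurrence of each read (forward strand) and of its
#' reverse complement (minus strand) on the reference; no mismatches are
#' allowed. Multi-mapping reads are handled by policy: `"count-all"` places
#' weight 1 at every locus, `"fractional"` spreads weight 1/n over the n
#' placements. Reads containing ambiguity codes are skipped with a warning;
#' reads with zero placements are recorded in the `"unmapped"` attribute.
#'
#' @param reads `data.frame(sequence, count)` of collapsed reads.
#' @param reference Named [Biostrings::DNAStringSet] (or named character).
#' @param policy Multi-mapping weight policy.
#' @return `data.frame(sequence, ref, start0, strand, length, five0, count,
#'   weight)` where `start0` is the 0-based leftmost coordinate and `five0`
#'   the 0-based forward coordinate of the biological 5' end (leftmost base
#'   on `+`, rightmost on `-`).
#' @export
align_exact <- function(reads, reference, policy = c("count-all", "fractional")) {
  policy <- match.arg(policy)
  if (is.character(reference)) reference <- Biostrings::DNAStringSet(reference)
  if (is.null(names(reference)) || anyNA(names(reference)))
    stop("reference sequences must be named")
  reads$sequence <- normalize_seq(reads$sequence)
  bad <- grepl("[^ACGT]", reads$sequence)
  if (any(bad)) {
    warning(sprintf("skipping %d read(s) with ambiguous nucleotide codes", sum(bad)))
    reads <- reads[!bad, , drop = FALSE]
  }
  empty <- data.frame(sequence = character(0), ref = character(0),
                      start0 = integer(0), strand = character(0),
                      length = integer(0), five0 = integer(0),
                      count = numeric(0), weight = numeric(0),
                      stringsAsFactors = FALSE)
  if (!nrow(reads)) { attr(empty, "unmapped") <- reads; return(empty) }

  widths <- Biostrings::width(reference)
  spacer <- 40L
  off0 <- cumsum(c(0L, head(widths + spacer, -1L)))  # 0-based ref starts in concat
  sep <- strrep("N", spacer)
  subj_f <- Biostrings::DNAString(paste(as.character(reference), collapse = sep))
  subj_r <- Biostrings::DNAString(paste(
    as.character(Biostrings::reverseComplement(reference)), collapse = sep))

  hits <- list()
  for (len in sort(unique(nchar(reads$sequence)))) {
    idx <- which(nchar(reads$sequence) == len)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(reads$sequence[idx]))
    for (orient in c("+", "-")) {
      m <- Biostrings::matchPDict(pd, if (orient == "+") subj_f else subj_r)
      nh <- S4Vectors::elementNROWS(m)
      if (!sum(nh)) next
      gstart0 <- BiocGenerics::start(BiocGenerics::unlist(m)) - 1L
      ri <- findInterval(gstart0, off0)
      local0 <- gstart0 - off0[ri]
      start0 <- if (orient == "+") local0 else widths[ri] - local0 - len
      hits[[length(hits) + 1L]] <- data.frame(
        read = idx[rep(seq_along(nh), nh)], ref = names(reference)[ri],
        start0 = as.integer(start0), strand = orient,
        length = len, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    attr(empty, "unmapped") <- reads
    return(empty)
  }
  h <- do.call(rbind, hits)
  nplace <- tabulate(h$read, nbins = nrow(reads))
  out <- data.frame(
    sequence = reads$sequence[h$read], ref = h$ref, start0 = h$start0,
    strand = h$strand, length = h$length,
    five0 = ifelse(h$strand == "+", h$start0, h$start0 + h$length - 1L),
    count = reads$count[h$read],
    weight = if (policy == "count-all") 1 else 1 / nplace[h$read],
    stringsAsFactors = FALSE)
  out <- out[order(out$ref, out$start0, out$strand, out$sequence,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unmapped") <- reads[nplace == 0L, , drop = FALSE]
  out
}

#' Build a position profile of sRNA 5' ends
#'
#' Accumulates weighted read counts at 5' positions, keyed by reference,
#' strand and read length. For phasing arithmetic every entry also carries
#' its effective position: the 5' position itself on the plus strand, the
#' leftmost coordinate + 2 on the minus strand (the canonical 2-nt
#' 3'-overhang correction that maps both strands of a DCL duplex onto the
#' same register).
#'
#' @param aligned Output of [align_exact()].
#' @param reference The reference used for alignment (for sequence lengths),
#'   or a named integer vector of lengths.
#' @param library_total Optional RPM denominator override; defaults to the
#'   total mapped weighted count.
#' @return A `position_profile`: list of `entries` (data frame),
#'   `library_total`, `ref_lengths`.
#' @export
build_position_profile <- function(aligned, reference, library_total = NULL) {
  ref_lengths <- if (is.numeric(reference)) reference
    else setNames(Biostrings::width(reference), names(reference))
  if (nrow(aligned)) {
    key <- paste(aligned$ref, aligned$strand, aligned$five0, aligned$length,
                 sep = "\r")
    w <- aligned$count * aligned$weight
    agg <- rowsum(w, group = key)
    parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    entries <- data.frame(
      ref = parts[, 1L], strand = parts[, 2L],
      five0 = as.integer(parts[, 3L]), length = as.integer(parts[, 4L]),
      count = as.numeric(agg[, 1L]), stringsAsFactors = FALSE)
  } else {
    entries <- data.frame(ref = character(0), strand = character(0),
                          five0 = integer(0), length = integer(0),
                          count = numeric(0), stringsAsFactors = FALSE)
  }
  entries$eff0 <- ifelse(entries$strand == "+", entries$five0,
                         entries$five0 - entries$length + 3L)
  entries <- entries[order(entries$ref, entries$eff0, entries$strand,
                           entries$length, method = "radix"), , drop = FALSE]
  rownames(entries) <- NULL
  if (is.null(library_total))
    library_total <- sum(entries$count)
  structure(list(entries = entries, library_total = library_total,
                 ref_lengths = ref_lengths),
            class = "position_profile")
}

#' Read-length distribution
#'
#' Count-weighted fraction of reads per length over the clean-read window.
#'
#' @param reads `data.frame(sequence, count)`.
#' @param min_len,max_len Length window.
#' @return `data.frame(length, count, fraction)`; fractions sum to 1.
#' @export
size_distribution <- function(reads, min_len = 18L, max_len = 30L) {
  reads <- filter_reads(reads, min_len, max_len)
  if (!nrow(reads))
    return(data.frame(length = integer(0), count = numeric(0),
                      fraction = numeric(0)))
  agg <- rowsum(as.numeric(reads$count), group = nchar(reads$sequence))
  out <- data.frame(length = as.integer(rownames(agg)), count = agg[, 1L])
  out <- out[order(out$length), , drop = FALSE]
  out$fraction <- out$count / sum(out$count)
  rownames(out) <- NULL
  out
}

#' 5'-nucleotide composition of a length class
#'
#' Count-weighted fractions of the first nucleotide among reads of the given
#' length; T is reported as U (RNA convention).
#'
#' @param reads `data.frame(sequence, count)`.
#' @param length_class Read length (nt), e.g. 21.
#' @return Named numeric vector over A, C, G, U summing to 1; empty if no
#'   reads in the class.
#' @export
five_prime_composition <- function(reads, length_class) {
  reads <- reads[nchar(reads$sequence) == length_class, , drop = FALSE]
  if (!nrow(reads)) return(setNames(numeric(0), character(0)))
  first <- substr(normalize_seq(reads$sequence), 1L, 1L)
  first <- chartr("T", "U", first)
  agg <- rowsum(as.numeric(reads$count), group = first)
  frac <- setNames(rep(0, 4L), c("A", "C", "G", "U"))
  frac[rownames(agg)] <- agg[, 1L] / sum(agg)
  frac
}

#' Reads-per-million / per-ten-million normalization
#'
#' @param count Raw count(s).
#' @param library_total Library size (mapped clean-read total); must be > 0.
#' @return Normalized value(s).
#' @export
normalize_rpm <- function(count, library_total) {
  if (length(library_total) != 1L || is.na(library_total) || library_total <= 0)
    stop("library_total must be a single positive number")
  count / library_total * 1e6
}

#' @rdname normalize_rpm
#' @export
normalize_rp10m <- function(count, library_total) {
  if (length(library_total) != 1L || is.na(library_total) || library_total <= 0)
    stop("library_total must be a single positive number")
  count / library_total * 1e7
}

#' Export a position profile as a BED-like table
#'
#' @param profile A `position_profile`.
#' @return `data.frame(ref, start1, end1, strand, length, count, rpm)` keyed
#'   by read 5' position (1-based, single-base interval).
#' @export
profile_table <- function(profile) {
  e <- profile$entries
  data.frame(ref = e$ref, start1 = e$five0 + 1L, end1 = e$five0 + 1L,
             strand = e$strand, length = e$length, count = e$count,
             rpm = if (profile$library_total > 0)
               normalize_rpm(e$count, profile$library_total) else rep(0, nrow(e)),
             stringsAsFactors = FALSE)
}
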