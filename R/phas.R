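#' Phase score
#'
#' The windowed phasing statistic: with k occupied phase cells, P the summed
#' in-register read count and U the summed off-register count,
#' `score = (k - 2) * ln(1 + 10 * P / (1 + U))` for `k >= 3`, else 0.
#'
#' @param P,U,k Window statistics (vectorized).
#' @return Numeric score(s) in natural-log units, >= 0.
#' @export
phase_score <- function(P, U, k) {
  ifelse(k >= 3, (k - 2) * log1p(10 * P / (1 + U)), 0)
}

check_period <- function(period) {
  if (!period %in% c(21L, 24L))
    stop("period must be 21 or 24")
  as.integer(period)
}

#' Phase score of one nine-cycle window
#'
#' Counts only reads whose length equals the period. A (position, strand)
#' cell is occupied when it carries at least one such read; minus-strand
#' reads enter at their effective position (leftmost coordinate + 2, the
#' canonical duplex-overhang correction), so both strands of a phased duplex
#' fall in the same register. The register is the absolute residue class
#' (effective position mod period).
#'
#' @param profile A `position_profile`.
#' @param ref Reference name.
#' @param start0 0-based window start; the window spans `cycles * period` nt.
#' @param period 21 or 24.
#' @param register Residue in `[0, period)`.
#' @param cycles Window size in cycles (9 by default).
#' @return List of class `phase_window` with `ref, start0, period, register,
#'   k, P, U, score`.
#' @export
phase_score_window <- function(profile, ref, start0, period, register,
                               cycles = 9L) {
  period <- check_period(period)
  L <- profile$ref_lengths[[ref]]
  w <- cycles * period
  if (start0 < 0 || start0 + w > L)
    stop("window overruns the reference")
  if (register < 0 || register >= period) stop("register must be in [0, period)")
  e <- profile$entries
  e <- e[e$ref == ref & e$length == period &
           e$eff0 >= start0 & e$eff0 < start0 + w, , drop = FALSE]
  inreg <- e$eff0 %% period == register
  k <- sum(inreg & e$count > 0)
  P <- sum(e$count[inreg])
  U <- sum(e$count[!inreg])
  structure(list(ref = ref, start0 = start0, period = period,
                 register = as.integer(register), k = as.integer(k),
                 P = P, U = U, score = phase_score(P, U, k)),
            class = "phase_window")
}

#' Scan a position profile for *PHAS* loci
#'
#' Slides the nine-cycle window one nt at a time over read-supported regions
#' of every reference, takes the best register per window, keeps windows
#' with `score >= score_threshold` and `k >= min_phased_positions`, and
#' merges overlapping passing windows sharing a register into loci. Each
#' locus spans its first to last in-register read and is named
#' `<period>PHAS<number>` in reference order.
#'
#' @param profile A `position_profile`.
#' @param period 21 or 24.
#' @param score_threshold Minimum window phase score (natural-log units).
#' @param min_phased_positions Minimum occupied phase cells k in a window.
#' @param cycles Window size in cycles.
#' @return `data.frame(locus_id, ref, start0, end0, start1, end1, period,
#'   register, score, k, P, U)`; loci shorter than three periods are
#'   discarded as degenerate.
#' @export
scan_phas_loci <- function(profile, period, score_threshold = 15,
                           min_phased_positions = 4L, cycles = 9L) {
  period <- check_period(period)
  w <- cycles * period
  empty <- data.frame(locus_id = character(0), ref = character(0),
                      start0 = integer(0), end0 = integer(0),
                      start1 = integer(0), end1 = integer(0),
                      period = integer(0), register = integer(0),
                      score = numeric(0), k = integer(0), P = numeric(0),
                      U = numeric(0), stringsAsFactors = FALSE)
  ent <- profile$entries
  ent <- ent[ent$length == period & ent$count > 0, , drop = FALSE]
  if (!nrow(ent)) return(empty)
  by_ref <- split(ent, ent$ref)
  loci <- list()
  for (ref in intersect(names(profile$ref_lengths), names(by_ref))) {
    e <- by_ref[[ref]]
    L <- profile$ref_lengths[[ref]]
    # aggregate to occupied (effective position, strand) cells
    key <- paste(e$eff0, e$strand, sep = "\r")
    agg <- rowsum(e$count, group = key)
    parts <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    cell <- data.frame(eff0 = as.integer(parts[, 1L]),
                       count = as.numeric(agg[, 1L]))
    cell <- cell[order(cell$eff0), , drop = FALSE]
    cell <- cell[cell$eff0 >= 0 & cell$eff0 < L, , drop = FALSE]
    if (!nrow(cell)) next
    win <- cpp_phase_scan(cell$eff0, cell$count, L, period, as.integer(cycles),
                          as.integer(min_phased_positions), score_threshold)
    if (!nrow(win)) next
    for (reg in sort(unique(win$register))) {
      wr <- win[win$register == reg, , drop = FALSE]
      wr <- wr[order(wr$start0), , drop = FALSE]
      grp <- cumsum(c(1L, as.integer(wr$start0[-1L] > head(wr$start0, -1L) + w - 1L)))
      for (g in unique(grp)) {
        wg <- wr[grp == g, , drop = FALSE]
        lo <- min(wg$start0)
        hi <- max(wg$start0) + w - 1L
        memb <- cell[cell$eff0 >= lo & cell$eff0 <= hi &
                       cell$eff0 %% period == reg, , drop = FALSE]
        if (!nrow(memb)) next
        start0 <- min(memb$eff0)
        end0 <- max(memb$eff0) + period - 1L
        if (end0 - start0 + 1L < 3L * period) next   # degenerate call
        best <- which.max(wg$score)
        loci[[length(loci) + 1L]] <- data.frame(
          ref = ref, start0 = start0, end0 = end0,
          start1 = start0 + 1L, end1 = end0 + 1L, period = period,
          register = as.integer(reg), score = wg$score[best],
          k = as.integer(wg$k[best]), P = wg$P[best], U = wg$U[best],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(loci)) return(empty)
  out <- do.call(rbind, loci)
  ord <- order(match(out$ref, names(profile$ref_lengths)), out$start0)
  out <- out[ord, , drop = FALSE]
  out <- cbind(locus_id = sprintf("%dPHAS%04d", period, seq_len(nrow(out))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Enumerate the phasiRNAs of a called locus
#'
#' Every period-length read whose effective 5' position is in-register
#' within the locus becomes a phasiRNA named `<locus>_<offset><strand>`,
#' where offset is the nt distance of the read's biological 5' end (forward
#' coordinate) from the locus start. In-register reads of other lengths are
#' excluded and counted in the `"off_period_excluded"` attribute.
#'
#' @param locus One row of the [scan_phas_loci()] table.
#' @param profile A `position_profile`.
#' @param reference Named `DNAStringSet` (or named character) for sequence
#'   extraction.
#' @return `data.frame(name, locus_id, offset, strand, five0, start1, end1,
#'   sequence, count)`.
#' @export
enumerate_phasirnas <- function(locus, profile, reference) {
  p <- locus$period
  e <- profile$entries
  e <- e[e$ref == locus$ref & e$eff0 >= locus$start0 & e$eff0 <= locus$end0 &
           e$eff0 %% p == locus$register & e$count > 0, , drop = FALSE]
  off_period <- sum(e$count[e$length != p])
  e <- e[e$length == p, , drop = FALSE]
  out <- if (nrow(e)) {
    refseq <- as.character(reference)[[locus$ref]]
    left0 <- ifelse(e$strand == "+", e$eff0, e$eff0 - 2L)
    sq <- substring(refseq, left0 + 1L, left0 + p)
    sq[e$strand == "-"] <- revcomp_chr(sq[e$strand == "-"])
    offset <- e$five0 - locus$start0
    data.frame(name = sprintf("%s_%d%s", locus$locus_id, offset, e$strand),
               locus_id = locus$locus_id, offset = offset, strand = e$strand,
               five0 = e$five0, start1 = left0 + 1L, end1 = left0 + p,
               sequence = sq, count = e$count, stringsAsFactors = FALSE)
  } else {
    data.frame(name = character(0), locus_id = character(0),
               offset = integer(0), strand = character(0), five0 = integer(0),
               start1 = integer(0), end1 = integer(0), sequence = character(0),
               count = numeric(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "off_period_excluded") <- off_period
  out
}

#' Annotate the trigger miRNA site of a locus
#'
#' Scores each candidate trigger against the precursor with the duplex
#' scheme; if the best site scores <= `max_score`, the locus is annotated
#' with the trigger, its site, and the implied cleavage position (the
#' precursor coordinate paired with trigger nucleotide 10, i.e. the +1
#' position of the downstream fragment). Consistency of the locus phase
#' register with that cleavage position is reported. Further triggers
#' passing the ceiling are listed as secondary.
#'
#' @param locus One row of the [scan_phas_loci()] table.
#' @param precursor_sequence The locus reference sequence.
#' @param trigger_mirnas Named character vector of trigger sequences.
#' @param scheme A [penalty_scheme()].
#' @param max_score Trigger-site score ceiling.
#' @return A list with `trigger, site_start1, site_end1, score, cleavage1,
#'   register_consistent, secondary` or `NULL` when no site qualifies.
#' @export
annotate_trigger <- function(locus, precursor_sequence, trigger_mirnas,
                             scheme = penalty_scheme(), max_score = 3.5) {
  if (is.null(names(trigger_mirnas)))
    names(trigger_mirnas) <- sprintf("trigger%d", seq_along(trigger_mirnas))
  best <- list()
  for (tn in names(trigger_mirnas)) {
    sites <- find_candidate_sites(trigger_mirnas[[tn]], precursor_sequence,
                                  scheme, max_score)
    if (nrow(sites))
      best[[length(best) + 1L]] <- cbind(trigger = tn, sites[1L, , drop = FALSE],
                                         stringsAsFactors = FALSE)
  }
  if (!length(best)) return(NULL)
  tab <- do.call(rbind, best)
  tab <- tab[order(tab$score, tab$start1), , drop = FALSE]
  top <- tab[1L, ]
  list(trigger = top$trigger, site_start1 = top$start1, site_end1 = top$end1,
       score = top$score, cleavage1 = top$cleavage1,
       register_consistent =
         !is.na(top$cleavage1) &&
         ((top$cleavage1 - 1L) %% locus$period == locus$register),
       secondary = if (nrow(tab) > 1L) tab[-1L, , drop = FALSE] else NULL)
}
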