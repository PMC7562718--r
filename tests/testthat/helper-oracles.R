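# Independent brute-force oracles and small fixtures used across the suite.

mk_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")

rc_chr <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

# Exhaustive minimum mispair score over all alignments with at most
# `bulge_cap` bulged nucleotides: explicit path enumeration (branch and
# bound on the running sum, which is exact for a minimum of non-negative
# penalties). Independent of the package DP.
oracle_duplex_score <- function(srna, window, scheme = penalty_scheme()) {
  s <- strsplit(srna, "")[[1]]
  w <- rev(strsplit(window, "")[[1]])
  m <- length(s)
  n <- length(w)
  B <- scheme$bulge_cap
  mlt <- function(i) if (i >= scheme$core_start && i <= scheme$core_end) 1
    else scheme$outside_multiplier
  wc <- c(AT = TRUE, TA = TRUE, GC = TRUE, CG = TRUE)
  gu <- c(GT = TRUE, TG = TRUE)
  pp <- function(a, b) {
    if (!a %in% c("A", "C", "G", "T") || !b %in% c("A", "C", "G", "T"))
      return(scheme$mismatch)
    key <- paste0(a, b)
    if (isTRUE(wc[key])) return(0)
    if (isTRUE(gu[key])) return(scheme$gu_wobble)
    scheme$mismatch
  }
  best <- Inf
  rec <- function(i, j, b, acc) {
    if (acc >= best) return(invisible())
    if (i == m && j == n) {
      best <<- acc
      return(invisible())
    }
    if (i < m && j < n) rec(i + 1L, j + 1L, b, acc + pp(s[i + 1L], w[j + 1L]) * mlt(i + 1L))
    if (b < B && i < m) rec(i + 1L, j, b + 1L, acc + scheme$bulge * mlt(i + 1L))
    if (b < B && j < n && i >= 1L && i <= m - 1L)
      rec(i, j + 1L, b + 1L, acc + scheme$bulge * mlt(i))
    invisible()
  }
  rec(0L, 0L, 0L, 0)
  best
}

# Direct application of the category rules to a vector of occupied-position
# counts; `site` indexes into that vector.
oracle_category <- function(counts, site) {
  t <- counts[site]
  stopifnot(t >= 1)
  if (t == 1) return(4L)
  mx <- max(counts)
  if (t == mx) {
    if (sum(counts == mx) == 1L) return(0L) else return(1L)
  }
  if (t > mean(counts)) return(2L)
  3L
}

# Direct recount of the windowed phase statistic from raw cells.
oracle_phase_window <- function(eff0, counts, start0, period, register,
                                cycles = 9L) {
  inwin <- eff0 >= start0 & eff0 < start0 + cycles * period
  inreg <- inwin & (eff0 %% period == register)
  k <- sum(inreg & counts > 0)
  P <- sum(counts[inreg])
  U <- sum(counts[inwin & !inreg])
  if (k >= 3) (k - 2) * log(1 + 10 * P / (1 + U)) else 0
}

# Naive substring scan for exact read placements (forward + reverse
# complement), independent of the PDict machinery.
oracle_align <- function(read, reference) {
  refs <- as.character(reference)
  out <- list()
  for (nm in names(refs)) {
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") read else rc_chr(read)
      hit <- gregexpr(pat, refs[[nm]], fixed = TRUE)[[1]]
      if (hit[1] != -1L)
        out[[length(out) + 1L]] <- data.frame(
          ref = nm, start0 = as.integer(hit) - 1L, strand = strand,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(ref = character(0), start0 = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

tiny_config <- function(seed = 7, ...) {
  args <- list(seed = seed, n_transcripts = 12L,
               transcript_len_range = c(350L, 550L), n_phas21 = 2L,
               n_phas24 = 1L, n_planted_targets = 2L)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(synthetic_config, args)
}

# a degradome_profile object from parallel vectors
mk_profile <- function(pos1, count, length = 1000L, transcript = "TX") {
  structure(list(transcript = transcript, pos1 = as.integer(pos1),
                 count = as.numeric(count), total = sum(count),
                 length = as.integer(length)),
            class = "degradome_profile")
}
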