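#' Mispair penalty scheme
#'
#' The duplex scoring rules for sRNA:target complementarity: mismatches,
#' gaps or bulges cost 1, G:U wobble pairs cost 0.5, and every penalty is
#' halved outside the core base-paired region, sRNA positions 2-17 (1-based
#' from the sRNA 5' end). Candidate target sites are those scoring at most
#' `max_score` (3.5). At most `bulge_cap` nucleotides may be bulged in total;
#' a target-strand bulge takes the position index of the 5'-adjacent consumed
#' sRNA nucleotide.
#'
#' @param mismatch,gu_wobble,bulge Per-nucleotide penalties.
#' @param core_start,core_end Core region bounds (sRNA positions, 1-based).
#' @param outside_multiplier Penalty multiplier outside the core.
#' @param max_score Candidate-site score ceiling (inclusive).
#' @param bulge_cap Maximum total bulged nucleotides per duplex.
#' @return A validated list of class `penalty_scheme`.
#' @export
penalty_scheme <- function(mismatch = 1, gu_wobble = 0.5, bulge = 1,
                           core_start = 2L, core_end = 17L,
                           outside_multiplier = 0.5, max_score = 3.5,
                           bulge_cap = 2L) {
  s <- list(mismatch = as.numeric(mismatch), gu_wobble = as.numeric(gu_wobble),
            bulge = as.numeric(bulge), core_start = as.integer(core_start),
            core_end = as.integer(core_end),
            outside_multiplier = as.numeric(outside_multiplier),
            max_score = as.numeric(max_score), bulge_cap = as.integer(bulge_cap))
  if (any(c(s$mismatch, s$gu_wobble, s$bulge, s$outside_multiplier) < 0))
    stop("penalties must be >= 0")
  if (s$core_start < 1L || s$core_start > s$core_end)
    stop("core region must satisfy 1 <= core_start <= core_end")
  if (s$bulge_cap < 0L) stop("bulge_cap must be >= 0")
  class(s) <- "penalty_scheme"
  s
}

#' Score one sRNA:target duplex
#'
#' Finds the minimum-penalty antiparallel alignment of the sRNA (5'->3')
#' against a target window (given 5'->3'; its 3'-most base pairs sRNA
#' position 1) by banded dynamic programming under the penalty scheme.
#'
#' @param srna sRNA sequence (5'->3'; U accepted).
#' @param target_window Target subsequence (5'->3'); its length must be
#'   within the sRNA length +/- `bulge_cap`.
#' @param scheme A [penalty_scheme()].
#' @return A `duplex_alignment`: list with `score`, `states` (one character
#'   per alignment column along the sRNA: M = Watson-Crick, W = G:U wobble,
#'   X = mismatch, S = bulged sRNA nt, T = bulged target nt), `pair_window1`
#'   (for each sRNA position, the 1-based window coordinate it pairs with,
#'   NA if bulged), and `cleavage_window1`, the window coordinate paired
#'   with sRNA position 10 (the cleavage +1 position), NA if unpaired.
#' @export
score_duplex <- function(srna, target_window, scheme = penalty_scheme()) {
  srna <- unname(normalize_seq(srna))
  target_window <- unname(normalize_seq(target_window))
  m <- nchar(srna)
  n <- nchar(target_window)
  if (abs(n - m) > scheme$bulge_cap)
    stop("target window length outside sRNA length +/- bulge_cap")
  res <- cpp_duplex_align(srna, target_window, scheme)
  pair_window1 <- ifelse(is.na(res$pair_j), NA_integer_,
                         n - res$pair_j + 1L)  # wrev index -> window coord
  structure(list(srna = srna, window = target_window, score = res$score,
                 states = res$states, n_bulges = res$n_bulges,
                 pair_window1 = as.integer(pair_window1),
                 cleavage_window1 = if (m >= 10L) pair_window1[10L] else NA_integer_),
            class = "duplex_alignment")
}

#' Recompute a duplex score from its paired-state string
#'
#' Re-derives the mispair score by walking the alignment columns and applying
#' the scheme, independently of the DP that produced it.
#'
#' @param states State string from [score_duplex()] (characters M, W, X, S, T).
#' @param scheme A [penalty_scheme()].
#' @return Numeric score.
#' @export
recompute_duplex_score <- function(states, scheme = penalty_scheme()) {
  cols <- strsplit(states, "")[[1]]
  i <- 0L
  score <- 0
  mult <- function(i) if (i >= scheme$core_start && i <= scheme$core_end) 1
    else scheme$outside_multiplier
  for (st in cols) {
    if (st %in% c("M", "W", "X", "S")) i <- i + 1L
    pos <- if (st == "T") max(i, 1L) else i
    score <- score + switch(st, M = 0, W = scheme$gu_wobble,
                            X = scheme$mismatch, S = scheme$bulge,
                            T = scheme$bulge,
                            stop("unknown state: ", st)) * mult(pos)
  }
  score
}

#' Find candidate target sites of one sRNA on a transcript
#'
#' Scores every alignment end position on the transcript (window lengths
#' within the sRNA length +/- `bulge_cap`) and returns non-overlapping sites
#' with score <= `max_score` (inclusive), overlap resolved in favour of the
#' lower score (leftmost on ties), sorted ascending by score.
#'
#' @param srna sRNA sequence (5'->3').
#' @param transcript Target transcript sequence (or a length-1 named
#'   character / `DNAStringSet` element).
#' @param scheme A [penalty_scheme()].
#' @param max_score Score ceiling; defaults to the scheme's.
#' @return `data.frame(start1, end1, score, cleavage1, alignment)` with
#'   1-based inclusive target coordinates; `cleavage1` is the target
#'   coordinate paired with sRNA position 10.
#' @export
find_candidate_sites <- function(srna, transcript, scheme = penalty_scheme(),
                                 max_score = scheme$max_score) {
  srna <- unname(normalize_seq(srna))
  transcript <- unname(normalize_seq(as.character(transcript)))
  m <- nchar(srna)
  empty <- data.frame(start1 = integer(0), end1 = integer(0),
                      score = numeric(0), cleavage1 = integer(0),
                      alignment = character(0), stringsAsFactors = FALSE)
  L <- nchar(transcript)
  if (L < m - scheme$bulge_cap) return(empty)
  span <- m + 2L * scheme$bulge_cap
  if (L > 4L * span) {
    # long transcript: exact semi-global prefilter finds the rare candidate
    # regions, the per-end scan then enumerates sites locally
    starts <- sort(cpp_duplex_prescan(srna, transcript, scheme, max_score))
    hits <- hits_from_starts(srna, transcript, starts, scheme, max_score, m)
  } else {
    hits <- cpp_duplex_scan(srna, transcript, scheme, max_score)
  }
  resolve_candidate_hits(srna, transcript, hits, scheme, max_score, empty)
}

# confirm prefilter start positions by local per-end scans over merged regions
hits_from_starts <- function(srna, transcript, starts, scheme, max_score, m) {
  if (!length(starts)) return(NULL)
  span <- m + 2L * scheme$bulge_cap
  L <- nchar(transcript)
  grp <- cumsum(c(1L, as.integer(diff(starts) > span)))
  hits <- do.call(rbind, lapply(split(starts, grp), function(ss) {
    lo <- min(ss)
    hi <- min(L, max(ss) + span)
    h <- cpp_duplex_scan(srna, substr(transcript, lo + 1L, hi), scheme,
                         max_score)
    h$end0 <- h$end0 + lo
    h
  }))
  if (!is.null(hits) && nrow(hits)) {
    # regions may overlap: keep the best record per end (min score, then
    # window length closest to the sRNA length, then shorter)
    hits <- hits[order(hits$end0, hits$score, abs(hits$len - m), hits$len), ,
                 drop = FALSE]
    hits <- hits[!duplicated(hits$end0), , drop = FALSE]
  }
  hits
}

# overlap resolution (lowest score, leftmost on ties) and traceback
resolve_candidate_hits <- function(srna, transcript, hits, scheme, max_score,
                                   empty) {
  if (is.null(hits) || !nrow(hits)) return(empty)
  hits$start0 <- hits$end0 - hits$len + 1L
  hits <- hits[hits$start0 >= 0L, , drop = FALSE]
  if (!nrow(hits)) return(empty)
  hits <- hits[order(hits$score, hits$start0), , drop = FALSE]
  taken <- integer(0)
  keep <- logical(nrow(hits))
  for (k in seq_len(nrow(hits))) {
    span <- hits$start0[k]:hits$end0[k]
    if (!any(span %in% taken)) {
      keep[k] <- TRUE
      taken <- c(taken, span)
    }
  }
  hits <- hits[keep, , drop = FALSE]
  out <- lapply(seq_len(nrow(hits)), function(k) {
    win <- substr(transcript, hits$start0[k] + 1L, hits$end0[k] + 1L)
    al <- score_duplex(srna, win, scheme)
    data.frame(start1 = hits$start0[k] + 1L, end1 = hits$end0[k] + 1L,
               score = al$score,
               cleavage1 = if (is.na(al$cleavage_window1)) NA_integer_
                 else hits$start0[k] + al$cleavage_window1,
               alignment = al$states, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$score <= max_score + 1e-9, , drop = FALSE]
  out[order(out$score, out$start1), , drop = FALSE]
}

#' Predict candidate targets for a set of sRNAs
#'
#' Applies [find_candidate_sites()] to every sRNA x transcript pair and
#' assembles the initial candidate pool (mispair score <= `max_score`).
#'
#' @param srnas Named character vector of sRNA sequences.
#' @param transcriptome Named [Biostrings::DNAStringSet] (or named character).
#' @param scheme A [penalty_scheme()].
#' @param max_score Score ceiling.
#' @return `data.frame(srna_id, srna_seq, transcript, start1, end1, score,
#'   cleavage1, alignment)`.
#' @export
predict_targets <- function(srnas, transcriptome, scheme = penalty_scheme(),
                            max_score = scheme$max_score) {
  if (is.null(names(srnas))) names(srnas) <- sprintf("sRNA%04d", seq_along(srnas))
  srnas <- normalize_seq(srnas)
  txchar <- setNames(normalize_seq(as.character(transcriptome)),
                     names(transcriptome))
  if (is.null(names(txchar))) stop("transcriptome sequences must be named")
  # one prefilter pass per sRNA over the X-separated concatenated
  # transcriptome; separators cannot take part in an alignment
  spacer <- 40L
  widths <- nchar(txchar)
  off0 <- cumsum(c(0L, head(widths + spacer, -1L)))
  concat <- paste(txchar, collapse = strrep("X", spacer))
  rows <- list()
  empty_sites <- data.frame(start1 = integer(0), end1 = integer(0),
                            score = numeric(0), cleavage1 = integer(0),
                            alignment = character(0), stringsAsFactors = FALSE)
  for (si in seq_along(srnas)) {
    srna <- srnas[[si]]
    m <- nchar(srna)
    starts <- sort(cpp_duplex_prescan(srna, concat, scheme, max_score))
    if (!length(starts)) next
    ti_of <- findInterval(starts, off0)
    for (ti in unique(ti_of)) {
      local <- starts[ti_of == ti] - off0[ti]
      local <- local[local >= 0L & local < widths[ti]]
      if (!length(local)) next
      hits <- hits_from_starts(srna, txchar[[ti]], local, scheme, max_score, m)
      sites <- resolve_candidate_hits(srna, txchar[[ti]], hits, scheme,
                                      max_score, empty_sites)
      if (nrow(sites)) {
        sites$srna_id <- names(srnas)[si]
        sites$srna_seq <- unname(srna)
        sites$transcript <- names(txchar)[ti]
        rows[[length(rows) + 1L]] <- sites
      }
    }
  }
  if (!length(rows))
    return(data.frame(srna_id = character(0), srna_seq = character(0),
                      transcript = character(0), start1 = integer(0),
                      end1 = integer(0), score = numeric(0),
                      cleavage1 = integer(0), alignment = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out <- out[, c("srna_id", "srna_seq", "transcript", "start1", "end1",
                 "score", "cleavage1", "alignment")]
  out <- out[order(out$srna_id, out$transcript, out$start1,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
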