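#' Generate a synthetic reference with planted *PHAS* loci and targets
#'
#' Builds a reference of random background transcripts plus one precursor per
#' planted locus. Each precursor carries an exact reverse-complement site for
#' its trigger miRNA; the implied cleavage position (between the target bases
#' paired with trigger nucleotides 10 and 11) sets the phase register, and
#' phasiRNA duplexes are laid head-to-tail downstream of it with the 2-nt 3'
#' overhang geometry of DCL products. The 5' nucleotide of each 21-nt
#' phasiRNA is forced to C with probability `five_prime_c_bias` by editing
#' the underlying precursor base, so reads remain exact matches. A subset of
#' 21-nt phasiRNAs gets a perfect complementary site planted in a background
#' transcript; the cleavage coordinate paired with phasiRNA nucleotide 10 is
#' recorded as ground truth.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_reference` with elements `reference`
#'   (named [Biostrings::DNAStringSet]), `truth` (lists `loci`, `phasirnas`,
#'   `targets` as data frames) and `config`.
#' @export
generate_reference <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  validate_config(config)
  set.seed(stage_seed(config$seed, 0L))
  bases <- c("A", "C", "G", "T")
  rand_seq <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")

  # background transcripts
  n_tx <- config$n_transcripts
  tx_len <- if (n_tx > 0)
    sample(seq(config$transcript_len_range[1], config$transcript_len_range[2]),
           n_tx, replace = TRUE) else integer(0)
  tx_seq <- vapply(tx_len, rand_seq, character(1))
  tx_names <- sprintf("TX%04d", seq_len(n_tx))

  loci <- list(); phas <- list(); pre_seq <- character(0); pre_names <- character(0)
  idx <- 0L
  for (period in c(21L, 24L)) {
    n_loci <- if (period == 21L) config$n_phas21 else config$n_phas24
    if (n_loci == 0L) next
    which_trig <- if (period == 21L) 1L else 2L
    trig <- config$trigger_sequences[[which_trig]]
    trig_name <- names(config$trigger_sequences)[which_trig]
    if (is.null(trig_name) || trig_name == "")
      trig_name <- paste0("trigger", which_trig)
    gl <- nchar(trig)
    cyc <- config$cycles_per_locus
    for (i in seq_len(n_loci)) {
      idx <- idx + 1L
      if (!is.null(config$precursor_len)) {
        Lpre <- config$precursor_len
        t1 <- min(41L, Lpre - cyc * period - gl + 11L)
      } else {
        t1 <- 41L
        Lpre <- (t1 + gl - 11L) + cyc * period + 30L
      }
      s <- strsplit(rand_seq(Lpre), "")[[1]]
      s[t1:(t1 + gl - 1L)] <- strsplit(revcomp_chr(trig), "")[[1]]
      c1 <- t1 + gl - 10L   # 1-based coordinate paired with trigger nt 10
      c0 <- c1 - 1L
      # 5'-C bias: edit the precursor base under each biased 21-nt phasiRNA 5' end
      if (period == 21L && config$five_prime_c_bias > 0) {
        for (j in seq_len(cyc) - 1L) {
          if (runif(1) < config$five_prime_c_bias) s[c1 + j * period] <- "C"
          if (runif(1) < config$five_prime_c_bias)
            s[c0 + j * period + period - 2L] <- "G"   # minus-strand 5' base
        }
      }
      seq <- paste(s, collapse = "")
      name <- sprintf("PRE%d_%03d", period, i)
      pre_names <- c(pre_names, name)
      pre_seq <- c(pre_seq, seq)
      loci[[idx]] <- data.frame(
        locus = idx, ref = name, period = period, cycles = cyc,
        trigger = trig_name, trigger_start1 = t1, trigger_end1 = t1 + gl - 1L,
        cleavage1 = c1, register = c0 %% period,
        region_start1 = c1, region_end1 = c0 + cyc * period,
        validatable = TRUE, stringsAsFactors = FALSE)
      j <- rep(seq_len(cyc) - 1L, each = 2L)
      strand <- rep(c("+", "-"), cyc)
      start0 <- ifelse(strand == "+", c0 + j * period, c0 + j * period - 2L)
      five0 <- ifelse(strand == "+", start0, start0 + period - 1L)
      eff0 <- ifelse(strand == "+", start0, start0 + 2L)
      sq <- substring(seq, start0 + 1L, start0 + period)
      sq[strand == "-"] <- revcomp_chr(sq[strand == "-"])
      phas[[idx]] <- data.frame(
        ref = name, locus = idx, period = period, cycle = j, strand = strand,
        start0 = start0, five0 = five0, eff0 = eff0, sequence = sq,
        wt_mean = config$phased_read_mean,
        mut_mean = config$phased_read_mean / config$mutant_depletion_factor,
        stringsAsFactors = FALSE)
    }
  }
  loci <- if (length(loci)) do.call(rbind, loci) else empty_loci_truth()
  phas <- if (length(phas)) do.call(rbind, phas) else empty_phas_truth()

  # plant perfect target sites for a sample of 21-nt phasiRNAs
  targets <- empty_target_truth()
  if (config$n_planted_targets > 0L) {
    cand <- which(phas$period == 21L)
    if (length(cand) < config$n_planted_targets)
      stop("not enough 21-nt phasiRNAs to plant the requested targets")
    pick <- sort(sample(cand, config$n_planted_targets))
    host <- sample(seq_len(n_tx), config$n_planted_targets)
    rows <- vector("list", length(pick))
    for (k in seq_along(pick)) {
      sq <- phas$sequence[pick[k]]
      len <- nchar(sq)
      L <- tx_len[host[k]]
      whi <- L - len - 39L
      if (whi < 31L) stop("transcripts too short to host planted target sites")
      w1 <- (31:whi)[sample.int(whi - 30L, 1L)]
      site <- revcomp_chr(sq)
      tx_seq[host[k]] <- paste0(substr(tx_seq[host[k]], 1L, w1 - 1L), site,
                                substr(tx_seq[host[k]], w1 + len, L))
      rows[[k]] <- data.frame(
        transcript = tx_names[host[k]], srna_ref = phas$ref[pick[k]],
        srna_locus = phas$locus[pick[k]], srna_strand = phas$strand[pick[k]],
        srna_five0 = phas$five0[pick[k]], srna_sequence = sq,
        site_start1 = w1, site_end1 = w1 + len - 1L,
        cleavage1 = w1 + len - 10L, validatable = TRUE,
        stringsAsFactors = FALSE)
    }
    targets <- do.call(rbind, rows)
  }

  reference <- Biostrings::DNAStringSet(c(setNames(tx_seq, tx_names),
                                          setNames(pre_seq, pre_names)))
  structure(list(reference = reference,
                 truth = list(loci = loci, phasirnas = phas, targets = targets),
                 config = config),
            class = "synthetic_reference")
}

empty_loci_truth <- function() {
  data.frame(locus = integer(0), ref = character(0), period = integer(0),
             cycles = integer(0), trigger = character(0),
             trigger_start1 = integer(0), trigger_end1 = integer(0),
             cleavage1 = integer(0), register = integer(0),
             region_start1 = integer(0), region_end1 = integer(0),
             validatable = logical(0), stringsAsFactors = FALSE)
}
empty_phas_truth <- function() {
  data.frame(ref = character(0), locus = integer(0), period = integer(0),
             cycle = integer(0), strand = character(0), start0 = integer(0),
             five0 = integer(0), eff0 = integer(0), sequence = character(0),
             wt_mean = numeric(0), mut_mean = numeric(0),
             stringsAsFactors = FALSE)
}
empty_target_truth <- function() {
  data.frame(transcript = character(0), srna_ref = character(0),
             srna_locus = integer(0), srna_strand = character(0),
             srna_five0 = integer(0), srna_sequence = character(0),
             site_start1 = integer(0), site_end1 = integer(0),
             cleavage1 = integer(0), validatable = logical(0),
             stringsAsFactors = FALSE)
}

#' Simulate collapsed small-RNA libraries for one condition
#'
#' Draws, for each replicate, a Poisson count for every planted phasiRNA
#' (mean `phased_read_mean`, divided by `mutant_depletion_factor` in the
#' mutant) plus unphased background reads: lengths uniform on 18-30 nt,
#' uniform positions on either strand, `background_read_rate` expected reads
#' per reference nt. Reads are returned collapsed (unique sequence, summed
#' count), sorted by sequence.
#'
#' @param ref A `synthetic_reference`.
#' @param condition `"wildtype"` or `"mutant"`.
#' @return A list with one `data.frame(sequence, count)` per replicate.
#' @export
simulate_srna_library <- function(ref, condition = c("wildtype", "mutant")) {
  stopifnot(inherits(ref, "synthetic_reference"))
  condition <- match.arg(condition)
  cfg <- ref$config
  phas <- ref$truth$phasirnas
  means <- if (condition == "wildtype") phas$wt_mean else phas$mut_mean
  refchar <- as.character(ref$reference)
  widths <- Biostrings::width(ref$reference)
  total_len <- sum(widths)
  stage <- if (condition == "wildtype") 1L else 2L
  out <- vector("list", cfg$replicates)
  for (r in seq_len(cfg$replicates)) {
    set.seed(stage_seed(cfg$seed, stage, r))
    cnt <- if (nrow(phas)) rpois(nrow(phas), means) else integer(0)
    seqs <- phas$sequence[cnt > 0]
    cnts <- cnt[cnt > 0]
    if (cfg$background_read_rate > 0 && total_len > 0) {
      nbg <- rpois(1L, cfg$background_read_rate * total_len)
      if (nbg > 0) {
        ridx <- sample.int(length(widths), nbg, replace = TRUE,
                           prob = widths / total_len)
        len <- sample(18:30, nbg, replace = TRUE)
        len <- pmin(len, widths[ridx])
        pos0 <- floor(runif(nbg) * (widths[ridx] - len + 1L))
        strand <- sample(c("+", "-"), nbg, replace = TRUE)
        sq <- substring(refchar[ridx], pos0 + 1L, pos0 + len)
        if (any(strand == "-"))
          sq[strand == "-"] <- revcomp_chr(sq[strand == "-"])
        seqs <- c(seqs, sq)
        cnts <- c(cnts, rep(1L, nbg))
      }
    }
    if (length(seqs)) {
      agg <- rowsum(as.numeric(cnts), group = seqs)
      df <- data.frame(sequence = rownames(agg),
                       count = as.numeric(agg[, 1L]),
                       stringsAsFactors = FALSE)
      out[[r]] <- df[order(df$sequence, method = "radix"), , drop = FALSE]
    } else {
      out[[r]] <- data.frame(sequence = character(0), count = numeric(0),
                             stringsAsFactors = FALSE)
    }
    rownames(out[[r]]) <- NULL
  }
  names(out) <- sprintf("%s_rep%d", ifelse(condition == "wildtype", "wt", "mut"),
                        seq_len(cfg$replicates))
  out
}

#' Simulate a degradome (PARE) tag library
#'
#' Background tags are drawn per transcript position with Poisson means
#' decaying geometrically from the 5' end
#' (`degradome_background_mean * degradome_decay_rate^(pos-1)`), emulating
#' exonucleolytic background. At every planted cleavage coordinate — both
#' trigger sites on precursors and phasiRNA target sites on transcripts — a
#' spike of Poisson(`degradome_spike_mean`) tags is added. Tags are 20-nt
#' transcript substrings starting at their 5' position; positions within
#' 20 nt of the 3' end cannot yield a full tag, and a planted site falling
#' there is skipped with a warning and marked unvalidatable in the returned
#' truth.
#'
#' @param ref A `synthetic_reference`.
#' @return A list with `tags` (`data.frame(transcript, pos1, count,
#'   sequence)`), `library_total` and `truth` (the input truth with
#'   `validatable` updated).
#' @export
simulate_degradome_library <- function(ref) {
  stopifnot(inherits(ref, "synthetic_reference"))
  cfg <- ref$config
  set.seed(stage_seed(cfg$seed, 3L))
  refchar <- as.character(ref$reference)
  widths <- Biostrings::width(ref$reference)
  names(widths) <- names(ref$reference)
  truth <- ref$truth

  counts <- vector("list", length(refchar))
  names(counts) <- names(refchar)
  for (i in seq_along(refchar)) {
    npos <- widths[i] - 19L
    if (npos < 1L) { counts[[i]] <- numeric(0); next }
    mu <- cfg$degradome_background_mean *
      cfg$degradome_decay_rate^(seq_len(npos) - 1L)
    counts[[i]] <- rpois(npos, mu)
  }
  add_spike <- function(tx, pos1, what) {
    npos <- widths[[tx]] - 19L
    if (pos1 > npos || pos1 < 1L) {
      warning(sprintf("planted %s cleavage site %s:%d within 20 nt of the 3' end; skipped",
                      what, tx, pos1))
      return(FALSE)
    }
    counts[[tx]][pos1] <<- counts[[tx]][pos1] + rpois(1L, cfg$degradome_spike_mean)
    TRUE
  }
  if (nrow(truth$loci))
    for (k in seq_len(nrow(truth$loci)))
      truth$loci$validatable[k] <-
        add_spike(truth$loci$ref[k], truth$loci$cleavage1[k], "trigger")
  if (nrow(truth$targets))
    for (k in seq_len(nrow(truth$targets)))
      truth$targets$validatable[k] <-
        add_spike(truth$targets$transcript[k], truth$targets$cleavage1[k], "target")

  tx <- rep(names(counts), vapply(counts, length, integer(1)))
  pos1 <- unlist(lapply(counts, seq_along), use.names = FALSE)
  cnt <- unlist(counts, use.names = FALSE)
  keep <- which(cnt > 0)
  tags <- data.frame(transcript = tx[keep], pos1 = pos1[keep],
                     count = cnt[keep], stringsAsFactors = FALSE)
  tags$sequence <- substring(refchar[tags$transcript], tags$pos1,
                             tags$pos1 + 19L)
  rownames(tags) <- NULL
  list(tags = tags, library_total = sum(tags$count), truth = truth)
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles each sequence so that its dinucleotide (and hence mononucleotide)
#' composition is exactly preserved, by random Eulerian walks on the
#' dinucleotide transition multigraph. Used to build decoy sRNAs whose
#' target-site background mimics the real composition.
#'
#' @param seqs Character vector of sequences.
#' @param max_tries Rejection-sampling attempts per sequence.
#' @return Character vector of shuffled sequences.
#' @export
shuffle_dinucleotide <- function(seqs, max_tries = 500L) {
  vapply(normalize_seq(seqs), function(s) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    if (n < 3L) return(s)
    for (try in seq_len(max_tries)) {
      edges <- split(ch[-1L], ch[-n])             # out-edges per vertex
      edges <- lapply(edges, function(e) sample(e, length(e)))
      ptr <- setNames(rep(1L, length(edges)), names(edges))
      walk <- character(n)
      walk[1L] <- ch[1L]
      ok <- TRUE
      for (i in 2L:n) {
        v <- walk[i - 1L]
        if (is.null(edges[[v]])) { ok <- FALSE; break }
        p <- ptr[[v]]
        if (p > length(edges[[v]])) { ok <- FALSE; break }
        walk[i] <- edges[[v]][p]
        ptr[[v]] <- p + 1L
      }
      if (ok) return(paste(walk, collapse = ""))
    }
    s  # degenerate composition: walk always fails, return unshuffled
  }, character(1), USE.NAMES = FALSE)
}
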