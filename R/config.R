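#' Default trigger miRNA sequences
#'
#' Synthetic stand-in trigger sequences used by the generator, named after
#' the biological roles they emulate: the 21-nt *PHAS* trigger (miR2118
#' family) and the 24-nt *PHAS* trigger (miR2275 family). Both carry G at
#' position 10, so the target base paired with trigger nucleotide 10 (the
#' cleavage-diagnostic +1 position) is a C, compatible with the 5'-C bias of
#' the first phasiRNA in each register. Real mature miRNA sequences can be
#' supplied instead via `trigger_sequences`.
#'
#' @return Named character vector of two 22-nt sequences.
#' @export
default_triggers <- function() {
  c(miR2118 = "TACGCTAGAGTGGATCATCGAT",
    miR2275 = "GATTACAGCGTTAGCCTAGTGA")
}

#' Synthetic study configuration
#'
#' Bundles every tunable of the synthetic-data generator: reference layout,
#' planted locus structure, library composition, degradome model and the
#' wild-type/mutant replicate design. The defaults describe the benchmark
#' conditions used throughout the package: 20 planted 21-nt loci and 5
#' 24-nt loci of 10 cycles each, a mean of 20 reads per phased position,
#' unphased background at 0.05 reads per reference nt, 50 planted targets
#' with degradome spikes of mean 50 tags, three replicates per condition and
#' a 4-fold depletion of phased reads in the mutant.
#'
#' @param seed Integer seed; a fixed seed makes every generator output
#'   byte-identical.
#' @param n_transcripts Number of random background transcripts (the
#'   "transcriptome" scanned for targets).
#' @param transcript_len_range Length range (nt) of background transcripts.
#' @param n_phas21,n_phas24 Number of planted 21-nt / 24-nt *PHAS* precursors.
#' @param cycles_per_locus Phased duplex cycles per locus (>= 10 by default).
#' @param precursor_len Optional fixed precursor length; must be at least
#'   trigger length + cycles_per_locus * period, otherwise a configuration
#'   error is raised. `NULL` sizes precursors automatically.
#' @param trigger_sequences Named character vector of two trigger miRNA
#'   sequences (first triggers 21-nt loci, second 24-nt loci); U is accepted.
#' @param five_prime_c_bias Probability that a 21-nt phasiRNA 5' nucleotide
#'   is forced to C (realized by editing the precursor base so reads remain
#'   exact matches to the reference).
#' @param phased_read_mean Expected read count per phased position and
#'   replicate (Poisson mean) in the wild type.
#' @param background_read_rate Expected unphased read count per reference nt
#'   per library; background reads have lengths 18-30 nt at uniform positions
#'   on either strand.
#' @param n_planted_targets Number of transcripts carrying a planted perfect
#'   complementary site for a 21-nt phasiRNA.
#' @param degradome_spike_mean Poisson mean of the degradome tag spike at a
#'   planted cleavage coordinate.
#' @param degradome_background_mean Mean background degradome tag count per
#'   position at the transcript 5' end.
#' @param degradome_decay_rate Per-nt geometric decay of the background
#'   degradome tag mean along the transcript (5' to 3').
#' @param replicates Replicates per condition.
#' @param mutant_depletion_factor Factor (>= 1) dividing phased-read means in
#'   the mutant condition.
#'
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_transcripts = 250L,
                             transcript_len_range = c(1500L, 2500L),
                             n_phas21 = 20L,
                             n_phas24 = 5L,
                             cycles_per_locus = 10L,
                             precursor_len = NULL,
                             trigger_sequences = default_triggers(),
                             five_prime_c_bias = 0.9,
                             phased_read_mean = 20,
                             background_read_rate = 0.05,
                             n_planted_targets = 50L,
                             degradome_spike_mean = 50,
                             degradome_background_mean = 0.5,
                             degradome_decay_rate = 0.998,
                             replicates = 3L,
                             mutant_depletion_factor = 4) {
  cfg <- list(seed = as.integer(seed),
              n_transcripts = as.integer(n_transcripts),
              transcript_len_range = as.integer(transcript_len_range),
              n_phas21 = as.integer(n_phas21),
              n_phas24 = as.integer(n_phas24),
              cycles_per_locus = as.integer(cycles_per_locus),
              precursor_len = if (is.null(precursor_len)) NULL else as.integer(precursor_len),
              trigger_sequences = normalize_seq(trigger_sequences),
              five_prime_c_bias = as.numeric(five_prime_c_bias),
              phased_read_mean = as.numeric(phased_read_mean),
              background_read_rate = as.numeric(background_read_rate),
              n_planted_targets = as.integer(n_planted_targets),
              degradome_spike_mean = as.numeric(degradome_spike_mean),
              degradome_background_mean = as.numeric(degradome_background_mean),
              degradome_decay_rate = as.numeric(degradome_decay_rate),
              replicates = as.integer(replicates),
              mutant_depletion_factor = as.numeric(mutant_depletion_factor))
  class(cfg) <- "synthetic_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(length(cfg$seed) == 1L, !is.na(cfg$seed))
  if (cfg$seed < 0 || cfg$seed >= 2^30) stop("seed must be in [0, 2^30)")
  counts <- c(cfg$n_transcripts, cfg$n_phas21, cfg$n_phas24,
              cfg$cycles_per_locus, cfg$n_planted_targets, cfg$replicates)
  if (any(is.na(counts)) || any(counts < 0)) stop("counts must be >= 0")
  if (cfg$cycles_per_locus < 1) stop("cycles_per_locus must be >= 1")
  if (length(cfg$transcript_len_range) != 2L ||
      cfg$transcript_len_range[1] > cfg$transcript_len_range[2] ||
      cfg$transcript_len_range[1] < 100L)
    stop("transcript_len_range must be an increasing pair >= 100 nt")
  if (cfg$five_prime_c_bias < 0 || cfg$five_prime_c_bias > 1)
    stop("five_prime_c_bias must be a probability in [0, 1]")
  if (cfg$degradome_decay_rate <= 0 || cfg$degradome_decay_rate > 1)
    stop("degradome_decay_rate must be in (0, 1]")
  rates <- c(cfg$phased_read_mean, cfg$background_read_rate,
             cfg$degradome_spike_mean, cfg$degradome_background_mean)
  if (any(rates < 0)) stop("rates and means must be >= 0")
  if (cfg$mutant_depletion_factor < 1)
    stop("mutant_depletion_factor must be >= 1")
  if (length(cfg$trigger_sequences) != 2L)
    stop("trigger_sequences must name exactly two triggers (21-nt, 24-nt)")
  if (!all(strsplit(paste(cfg$trigger_sequences, collapse = ""), "")[[1]] %in%
           c("A", "C", "G", "T")))
    stop("trigger sequences must be unambiguous nucleotides")
  for (period in c(21L, 24L)) {
    n_loci <- if (period == 21L) cfg$n_phas21 else cfg$n_phas24
    if (n_loci > 0 && !is.null(cfg$precursor_len)) {
      trig <- cfg$trigger_sequences[[if (period == 21L) 1L else 2L]]
      if (cfg$precursor_len < nchar(trig) + cfg$cycles_per_locus * period)
        stop(sprintf(paste0("precursor_len %d too short for a trigger site plus ",
                            "%d cycles of period %d"),
                     cfg$precursor_len, cfg$cycles_per_locus, period))
    }
  }
  if (cfg$n_planted_targets > cfg$n_transcripts)
    stop("n_planted_targets cannot exceed n_transcripts")
  invisible(cfg)
}

#' Read / write a synthetic configuration as YAML
#'
#' @param path File path.
#' @param cfg A `synthetic_config`.
#' @return `read_config` returns a validated `synthetic_config`.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$trigger_sequences <- unlist(raw$trigger_sequences)
  do.call(synthetic_config, raw)
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "synthetic_config"))
  out <- unclass(cfg)
  out$trigger_sequences <- as.list(out$trigger_sequences)
  yaml::write_yaml(out, path)
  invisible(path)
}

# T/U-normalized, uppercased character sequences (names kept)
normalize_seq <- function(x) {
  y <- chartr("acgtuU", "ACGTTT", as.character(x))
  names(y) <- names(x)
  y
}

# seed offsets per generator stage so each stage has its own deterministic
# stream derived from the config seed
stage_seed <- function(seed, stage, index = 0L) {
  as.integer(seed) + 1000L * as.integer(stage) + as.integer(index)
}
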