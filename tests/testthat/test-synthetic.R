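test_that("configuration validation rejects impossible designs", {
  expect_error(synthetic_config(precursor_len = 150, cycles_per_locus = 10),
               "too short")
  expect_error(synthetic_config(five_prime_c_bias = 1.2), "probability")
  expect_error(synthetic_config(mutant_depletion_factor = 0.5), ">= 1")
  expect_error(synthetic_config(transcript_len_range = c(500, 300)),
               "increasing")
  expect_error(synthetic_config(n_transcripts = 5, n_planted_targets = 10),
               "exceed")
  expect_s3_class(synthetic_config(), "synthetic_config")
})

test_that("config survives a YAML round trip", {
  cfg <- tiny_config(seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(unclass(cfg2), unclass(cfg))
})

test_that("generated precursors carry an exact trigger complement and truth is coherent", {
  cfg <- tiny_config(seed = 1)
  gen <- generate_reference(cfg)
  refs <- as.character(gen$reference)
  loci <- gen$truth$loci
  expect_equal(nrow(loci), 3L)
  for (k in seq_len(nrow(loci))) {
    trig <- cfg$trigger_sequences[[if (loci$period[k] == 21) 1L else 2L]]
    site <- substr(refs[[loci$ref[k]]], loci$trigger_start1[k],
                   loci$trigger_end1[k])
    expect_identical(site, rc_chr(trig))
    # cleavage position pairs trigger nucleotide 10
    expect_equal(loci$cleavage1[k], loci$trigger_end1[k] - 9L)
    expect_equal(loci$register[k], (loci$cleavage1[k] - 1L) %% loci$period[k])
  }
  # every phasiRNA is an exact (reverse-complemented on minus) substring and
  # sits in its locus register under the duplex-overhang convention
  ph <- gen$truth$phasirnas
  for (k in seq_len(nrow(ph))) {
    sq <- substr(refs[[ph$ref[k]]], ph$start0[k] + 1L, ph$start0[k] + ph$period[k])
    if (ph$strand[k] == "-") sq <- rc_chr(sq)
    expect_identical(ph$sequence[k], sq)
    reg <- loci$register[match(ph$locus[k], loci$locus)]
    expect_equal(ph$eff0[k] %% ph$period[k], reg)
  }
  # planted target sites are exact reverse complements with cleavage at the
  # base paired with phasiRNA nucleotide 10
  tg <- gen$truth$targets
  expect_equal(nrow(tg), 2L)
  for (k in seq_len(nrow(tg))) {
    expect_identical(substr(refs[[tg$transcript[k]]], tg$site_start1[k],
                            tg$site_end1[k]),
                     rc_chr(tg$srna_sequence[k]))
    expect_equal(tg$cleavage1[k], tg$site_end1[k] - 9L)
  }
})

test_that("fixed seed gives byte-identical outputs; different seeds differ", {
  cfg <- tiny_config(seed = 5)
  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(generate_reference(cfg)$reference, f1)
  Biostrings::writeXStringSet(generate_reference(cfg)$reference, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  g1 <- simulate_srna_library(generate_reference(cfg), "wildtype")
  g2 <- simulate_srna_library(generate_reference(cfg), "wildtype")
  expect_identical(g1, g2)
  d1 <- simulate_degradome_library(generate_reference(cfg))
  d2 <- simulate_degradome_library(generate_reference(cfg))
  expect_identical(d1$tags, d2$tags)
  other <- generate_reference(tiny_config(seed = 6))$reference
  expect_false(identical(as.character(other),
                         as.character(generate_reference(cfg)$reference)))
})

test_that("five_prime_c_bias = 1 forces a C on every 21-nt phasiRNA 5' end", {
  gen <- generate_reference(tiny_config(seed = 2, five_prime_c_bias = 1))
  ph <- gen$truth$phasirnas
  expect_true(all(substr(ph$sequence[ph$period == 21], 1, 1) == "C"))
  lib <- simulate_srna_library(gen, "wildtype")[[1]]
  reads21 <- lib$sequence[nchar(lib$sequence) == 21 &
                            lib$sequence %in% ph$sequence]
  expect_true(length(reads21) > 0)
  expect_true(all(substr(reads21, 1, 1) == "C"))
})

test_that("with zero background every simulated read sits in a planted register", {
  gen <- generate_reference(tiny_config(seed = 3, background_read_rate = 0))
  lib <- simulate_srna_library(gen, "wildtype")[[1]]
  expect_true(all(lib$sequence %in% gen$truth$phasirnas$sequence))
})

test_that("mutant depletion and abundance calibration follow the Poisson model", {
  cfg <- synthetic_config(seed = 11, n_transcripts = 10,
                          transcript_len_range = c(300, 400), n_phas21 = 30,
                          n_phas24 = 0, n_planted_targets = 0,
                          phased_read_mean = 40, mutant_depletion_factor = 4,
                          background_read_rate = 0)
  gen <- generate_reference(cfg)
  ph <- gen$truth$phasirnas  # 30 loci x 10 cycles x 2 strands = 600 positions
  expect_gte(nrow(ph), 100)
  counts_of <- function(lib) {
    v <- setNames(lib$count, lib$sequence)
    x <- v[ph$sequence]
    ifelse(is.na(x), 0, x)
  }
  mut <- rowMeans(sapply(simulate_srna_library(gen, "mutant"), counts_of))
  expect_equal(mean(mut), 10, tolerance = 0.05)
  wt <- rowMeans(sapply(simulate_srna_library(gen, "wildtype"), counts_of))
  expect_equal(mean(wt), 40, tolerance = 0.05)  # relative error < 5%
})

test_that("degradome tags are transcript substrings with planted spikes", {
  cfg <- tiny_config(seed = 4)
  gen <- generate_reference(cfg)
  deg <- simulate_degradome_library(gen)
  refs <- as.character(gen$reference)
  expect_true(all(nchar(deg$tags$sequence) == 20L))
  idx <- sample(nrow(deg$tags), 50)
  expect_identical(
    deg$tags$sequence[idx],
    unname(substr(refs[deg$tags$transcript[idx]], deg$tags$pos1[idx],
                  deg$tags$pos1[idx] + 19L)))
  # the planted spike dominates its transcript
  for (k in seq_len(nrow(deg$truth$targets))) {
    tg <- deg$truth$targets[k, ]
    tx <- deg$tags[deg$tags$transcript == tg$transcript, ]
    expect_equal(tx$pos1[which.max(tx$count)], tg$cleavage1)
  }
})

test_that("zero spike and zero background give an empty tag set", {
  cfg <- tiny_config(seed = 4, degradome_spike_mean = 0,
                     degradome_background_mean = 0)
  deg <- simulate_degradome_library(generate_reference(cfg))
  expect_equal(nrow(deg$tags), 0L)
})

test_that("dinucleotide shuffle preserves composition", {
  set.seed(9)
  for (r in 1:10) {
    s <- mk_seq(21)
    sh <- shuffle_dinucleotide(s)
    di <- function(x) sort(table(substring(x, 1:(nchar(x) - 1), 2:nchar(x))))
    expect_identical(di(sh), di(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
  }
})
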