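make_profile_from_cells <- function(cells, ref_len = 1000L, period = 21L,
                                    ref = "pre") {
  # cells: data.frame(eff0, strand, count); build a position_profile directly
  entries <- data.frame(ref = ref, strand = cells$strand,
                        five0 = ifelse(cells$strand == "+", cells$eff0,
                                       cells$eff0 + period - 3L),
                        length = period, count = cells$count,
                        stringsAsFactors = FALSE)
  entries$eff0 <- cells$eff0
  structure(list(entries = entries, library_total = sum(entries$count),
                 ref_lengths = setNames(ref_len, ref)),
            class = "position_profile")
}

test_that("phase score arithmetic matches the closed form", {
  expect_equal(phase_score(12, 0, 3), log(121))
  expect_equal(phase_score(12, 12, 3), log(1 + 120 / 13))
  expect_equal(phase_score(12, 12, 3), 2.32540, tolerance = 1e-5)
  expect_equal(phase_score(5, 1, 2), 0)   # k < 3 gives score 0
  expect_equal(phase_score(0, 0, 0), 0)
})

test_that("phase score is monotone: increasing in P, decreasing in U", {
  P <- seq(1, 50, by = 1)
  s <- phase_score(P, U = 5, k = 6)
  expect_true(all(diff(s) > 0))
  U <- seq(0, 50, by = 1)
  s <- phase_score(P = 30, U = U, k = 6)
  expect_true(all(diff(s) < 0))
  expect_true(all(phase_score(30, 5, 4:18) >= 0))
})

test_that("windowed statistic matches a direct recount on fuzzed profiles", {
  set.seed(61)
  for (r in 1:30) {
    n <- sample(5:40, 1)
    cells <- data.frame(eff0 = sample(0:800, n),
                        strand = sample(c("+", "-"), n, TRUE),
                        count = rpois(n, 8) + 1)
    cells <- cells[!duplicated(cells[, c("eff0", "strand")]), ]
    prof <- make_profile_from_cells(cells)
    start0 <- sample(0:(1000 - 9 * 21), 1)
    reg <- sample(0:20, 1)
    pw <- phase_score_window(prof, "pre", start0, 21, reg)
    expect_equal(pw$score,
                 oracle_phase_window(cells$eff0, cells$count, start0, 21, reg))
  }
})

test_that("window scan agrees with phase_score_window at reported windows", {
  set.seed(62)
  cells <- data.frame(eff0 = 50 + 21 * 0:9, strand = "+", count = 10)
  extra <- data.frame(eff0 = c(55, 140, 300), strand = "+", count = c(2, 1, 3))
  prof <- make_profile_from_cells(rbind(cells, extra))
  loci <- scan_phas_loci(prof, 21, score_threshold = 10,
                         min_phased_positions = 4)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$register, 50 %% 21)
  pw <- phase_score_window(prof, "pre", loci$start0, 21, loci$register)
  expect_gte(pw$score, 10)
  expect_error(phase_score_window(prof, "pre", 980, 21, 0), "overruns")
  expect_error(phase_score_window(prof, "pre", 0, 22, 0), "21 or 24")
})

test_that("a planted locus is recovered with its exact register; period 24 finds nothing there", {
  gen <- generate_reference(tiny_config(seed = 13, background_read_rate = 0))
  libs <- simulate_srna_library(gen, "wildtype")
  pooled <- phasir:::collapse_reads(do.call(rbind, libs))
  aln <- align_exact(pooled, gen$reference)
  prof <- build_position_profile(aln, gen$reference)
  loci21 <- scan_phas_loci(prof, 21)
  truth21 <- gen$truth$loci[gen$truth$loci$period == 21, ]
  expect_equal(nrow(loci21), nrow(truth21))
  expect_setequal(paste(loci21$ref, loci21$register),
                  paste(truth21$ref, truth21$register))
  loci24 <- scan_phas_loci(prof, 24)
  expect_false(any(loci24$ref %in% truth21$ref))
})

test_that("loci separated by more than one window with no reads between stay separate", {
  cells <- rbind(
    data.frame(eff0 = 42 + 21 * 0:9, strand = "+", count = 10),
    data.frame(eff0 = 42 + 21 * 30:39, strand = "+", count = 10))
  prof <- make_profile_from_cells(cells, ref_len = 1500L)
  loci <- scan_phas_loci(prof, 21, score_threshold = 10)
  expect_equal(nrow(loci), 2L)   # same register, but a > 9-cycle gap between
})

test_that("random unphased background yields no loci at default thresholds", {
  set.seed(63)
  fp <- 0L
  for (r in 1:20) {
    n <- rpois(1, 60)
    cells <- data.frame(eff0 = sample(0:4000, n),
                        strand = sample(c("+", "-"), n, TRUE), count = 1)
    cells <- cells[!duplicated(cells[, c("eff0", "strand")]), ]
    prof <- make_profile_from_cells(cells, ref_len = 5000L)
    fp <- fp + nrow(scan_phas_loci(prof, 21))
  }
  expect_lte(fp, 1L)
})

test_that("phasiRNA names encode locus, 5' offset and strand", {
  # plus reads at offsets 0, 21, ..., 168; one duplex-partner minus read whose
  # biological 5' end sits at forward offset 165 (effective position 147)
  cells <- rbind(data.frame(eff0 = 1000 + 21 * 0:8, strand = "+", count = 5),
                 data.frame(eff0 = 1147, strand = "-", count = 5))
  prof <- make_profile_from_cells(cells, ref_len = 2000L)
  seqs <- Biostrings::DNAStringSet(setNames(paste(rep("ACGT", 500),
                                                  collapse = ""), "pre"))
  loci <- scan_phas_loci(prof, 21, score_threshold = 5)
  expect_equal(loci$start0, 1000)
  ph <- enumerate_phasirnas(loci[1, ], prof, seqs)
  expect_true(sprintf("%s_165-", loci$locus_id) %in% ph$name)
  expect_true(sprintf("%s_168+", loci$locus_id) %in% ph$name)
  expect_true(all(grepl("^21PHAS[0-9]{4}_[0-9]+[+-]$", ph$name)))
  # offsets of in-register plus reads are multiples of the period
  expect_true(all(ph$offset[ph$strand == "+"] %% 21 == 0))
  # names parse back
  parsed <- regmatches(ph$name, regexec("^(.*)_([0-9]+)([+-])$", ph$name))
  expect_true(all(vapply(parsed, `[`, character(1), 2) == loci$locus_id))
  expect_equal(as.integer(vapply(parsed, `[`, character(1), 3)), ph$offset)
})

test_that("degenerate locus calls with no in-register reads give no phasiRNAs", {
  cells <- data.frame(eff0 = 100 + 21 * 0:9, strand = "+", count = 5)
  prof <- make_profile_from_cells(cells, ref_len = 1000L)
  loci <- scan_phas_loci(prof, 21, score_threshold = 5)
  fake <- loci[1, ]
  fake$register <- (loci$register + 1) %% 21
  seqs <- Biostrings::DNAStringSet(setNames(paste(rep("ACGT", 250),
                                                  collapse = ""), "pre"))
  expect_equal(nrow(enumerate_phasirnas(fake, prof, seqs)), 0L)
})

test_that("trigger annotation finds the planted site and checks the register", {
  gen <- generate_reference(tiny_config(seed = 14))
  cfg <- gen$config
  loci_truth <- gen$truth$loci[1, ]
  locus <- data.frame(locus_id = "21PHAS0001", ref = loci_truth$ref,
                      period = 21L, register = loci_truth$register)
  ann <- annotate_trigger(locus, as.character(gen$reference)[[loci_truth$ref]],
                          cfg$trigger_sequences)
  expect_equal(ann$score, 0)
  expect_equal(ann$trigger, "miR2118")
  expect_equal(ann$cleavage1, loci_truth$cleavage1)
  expect_true(ann$register_consistent)
  # a random precursor with no qualifying site yields NULL
  set.seed(64)
  expect_null(annotate_trigger(locus, mk_seq(300), cfg$trigger_sequences))
  # with two qualifying triggers the lower score wins, the other is secondary
  trig2 <- cfg$trigger_sequences
  names(trig2) <- c("tA", "tB")
  pre <- paste0(mk_seq(50), rc_chr(trig2[["tA"]]), mk_seq(30),
                rc_chr(trig2[["tB"]]), mk_seq(30))
  # make the tA site imperfect so tB wins
  substr(pre, 55, 55) <- chartr("ACGT", "CAGT",
                                substr(pre, 55, 55))
  ann2 <- annotate_trigger(locus, pre, trig2)
  expect_equal(ann2$trigger, "tB")
  expect_equal(ann2$score, 0)
  expect_equal(nrow(ann2$secondary), 1L)
})
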