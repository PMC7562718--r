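test_that("length filter keeps the 18-30 nt clean-read window inclusively", {
  reads <- data.frame(sequence = vapply(c(17, 18, 30, 31), mk_seq, character(1)),
                      count = c(5, 6, 7, 8))
  kept <- filter_reads(reads)
  expect_setequal(nchar(kept$sequence), c(18, 30))
  expect_equal(sum(kept$count), 13)
  expect_equal(nrow(filter_reads(reads[0, ])), 0L)
  all21 <- data.frame(sequence = replicate(4, mk_seq(21)), count = 1)
  expect_identical(filter_reads(all21), all21)
  expect_error(filter_reads(reads, min_len = 25, max_len = 20), "min_len")
})

test_that("exact alignment reports every placement with correct coordinates", {
  set.seed(21)
  ref <- Biostrings::DNAStringSet(c(chr1 = mk_seq(300)))
  refc <- as.character(ref)[[1]]
  read_p <- substr(refc, 101, 121)              # + strand at start0 = 100
  read_m <- rc_chr(substr(refc, 41, 61))        # - strand, leftmost0 = 40
  aln <- align_exact(data.frame(sequence = c(read_p, read_m), count = c(3, 4)),
                     ref)
  p <- aln[aln$sequence == read_p & aln$strand == "+", ]
  expect_true(any(p$start0 == 100))
  m <- aln[aln$sequence == read_m & aln$strand == "-", ]
  expect_equal(m$start0, 40)
  expect_equal(m$five0, 40 + 21 - 1)   # biological 5' end on the forward axis
  # minus-strand round trip: extract at the placement and reverse-complement
  expect_identical(rc_chr(substr(refc, m$start0 + 1, m$start0 + m$length)),
                   read_m)
})

test_that("multi-mapping weights follow the chosen policy", {
  seg <- mk_seq(21)
  ref <- Biostrings::DNAStringSet(c(a = paste0(mk_seq(30), seg, mk_seq(30), seg,
                                               mk_seq(30))))
  reads <- data.frame(sequence = seg, count = 10)
  all <- align_exact(reads, ref, policy = "count-all")
  expect_equal(nrow(all), 2L)
  expect_equal(all$weight, c(1, 1))
  frac <- align_exact(reads, ref, policy = "fractional")
  expect_equal(frac$weight, c(0.5, 0.5))
})

test_that("alignment equals a naive substring scan on fuzzed references", {
  set.seed(31)
  for (r in 1:15) {
    ref <- Biostrings::DNAStringSet(setNames(
      vapply(c(200, 150), mk_seq, character(1)), c("r1", "r2")))
    refc <- as.character(ref)
    reads <- data.frame(
      sequence = c(substr(refc[[1]], 10, 29),
                   rc_chr(substr(refc[[2]], 50, 70)), mk_seq(20)),
      count = 1)
    aln <- align_exact(reads, ref)
    for (sq in reads$sequence) {
      got <- aln[aln$sequence == sq, c("ref", "start0", "strand")]
      got <- got[order(got$ref, got$start0, got$strand), ]
      want <- oracle_align(sq, ref)
      want <- want[order(want$ref, want$start0, want$strand), ]
      expect_equal(unname(as.matrix(got)), unname(as.matrix(want)))
    }
    unm <- attr(aln, "unmapped")
    expect_true(all(vapply(unm$sequence,
                           function(s) nrow(oracle_align(s, ref)) == 0L,
                           logical(1))))
  }
})

test_that("reads with ambiguity codes are skipped with a warning", {
  ref <- Biostrings::DNAStringSet(c(a = mk_seq(100)))
  expect_warning(aln <- align_exact(
    data.frame(sequence = c("ACGTNACGTACGTACGTACGT", mk_seq(21)), count = 1),
    ref), "ambiguous")
  expect_false(any(grepl("N", aln$sequence)))
})

test_that("position profiles conserve counts and aggregate 5' positions", {
  set.seed(41)
  ref <- Biostrings::DNAStringSet(c(a = mk_seq(500)))
  refc <- as.character(ref)[[1]]
  reads <- data.frame(
    sequence = c(substr(refc, 100, 120), substr(refc, 100, 123),
                 substr(refc, 200, 220)),
    count = c(3, 4, 5))
  aln <- align_exact(reads, ref)
  prof <- build_position_profile(aln, ref)
  expect_equal(prof$library_total, sum(aln$count * aln$weight))
  # two reads of different length share the 5' position 99 (0-based)
  at99 <- prof$entries[prof$entries$five0 == 99, ]
  expect_equal(sum(at99$count), 7)
  empty <- build_position_profile(aln[0, ], ref)
  expect_equal(empty$library_total, 0)
  expect_equal(nrow(empty$entries), 0L)
})

test_that("effective positions apply the 2-nt overhang correction on minus reads", {
  ref <- Biostrings::DNAStringSet(c(a = mk_seq(200)))
  refc <- as.character(ref)[[1]]
  # plus read at x and its duplex partner (leftmost x-2) share the register
  x <- 60
  plus <- substr(refc, x + 1, x + 21)
  minus <- rc_chr(substr(refc, x - 1, x + 19))
  aln <- align_exact(data.frame(sequence = c(plus, minus), count = 1), ref)
  prof <- build_position_profile(aln, ref)
  e <- prof$entries[prof$entries$length == 21, ]
  expect_equal(sort(unique(e$eff0 %% 21)), x %% 21)
})

test_that("size distribution and 5' composition are count-weighted fractions", {
  reads <- data.frame(
    sequence = c(paste0("C", mk_seq(20)), paste0("C", mk_seq(20)),
                 paste0("A", mk_seq(20)), mk_seq(24)),
    count = c(1, 1, 1, 1))
  sd <- size_distribution(reads)
  expect_equal(sd$fraction[sd$length == 21], 0.75)
  expect_equal(sum(sd$fraction), 1)
  comp <- five_prime_composition(
    data.frame(sequence = c(paste0("C", mk_seq(20)), paste0("A", mk_seq(20))),
               count = c(2, 1)), 21)
  expect_equal(unname(comp["C"]), 2 / 3)
  expect_equal(sum(comp), 1)
  expect_length(five_prime_composition(reads, 19), 0L)
})

test_that("RPM normalization follows count / total * 1e6", {
  expect_equal(normalize_rpm(50, 1e6), 50)
  expect_equal(normalize_rpm(0, 123), 0)
  expect_equal(normalize_rpm(7, 3.5e6), 2)
  expect_equal(normalize_rp10m(7, 3.5e6), 20)
  expect_error(normalize_rpm(1, 0), "positive")
})
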