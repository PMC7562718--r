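test_that("hand-computable duplex scores match the penalty rules", {
  set.seed(51)
  s <- mk_seq(21)
  expect_equal(score_duplex(s, rc_chr(s))$score, 0)

  # single G:U at core position 10 (sRNA G opposite target T)
  s10 <- s
  substr(s10, 10, 10) <- "G"
  w <- rc_chr(s10)
  substr(w, 12, 12) <- "T"   # window coordinate pairing sRNA position 10
  expect_equal(score_duplex(s10, w)$score, 0.5)

  # mismatch at position 1 plus G:U at position 18, both outside the core:
  # 1 * 0.5 + 0.5 * 0.5 = 0.75
  s18 <- s
  substr(s18, 18, 18) <- "G"
  w <- rc_chr(s18)
  substr(w, 21, 21) <- "C"            # position 1 partner -> mismatch (T:C)
  substr(s18, 1, 1) <- "T"
  substr(w, 21 - 17, 21 - 17) <- "T"  # position 18 partner -> G:U
  al <- score_duplex(s18, w)
  expect_equal(al$score, 0.75)
  expect_equal(recompute_duplex_score(al$states), 0.75)
})

test_that("a site scoring exactly 3.5 is retained (inclusive bound)", {
  set.seed(52)
  # three core mismatches plus one core G:U = 3 * 1 + 0.5 = 3.5; resample
  # until no bulged alignment undercuts the intended score
  repeat {
    s <- mk_seq(21)
    w <- rc_chr(s)
    mismatch_at <- function(w, p) {
      a <- substr(s, p, p)
      wob <- if (a == "G") "T" else if (a == "T") "G" else "Z"
      b <- setdiff(c("A", "C", "G", "T"), c(rc_chr(a), wob))[1]
      substr(w, 22 - p, 22 - p) <- b
      w
    }
    for (p in c(3, 6, 9)) w <- mismatch_at(w, p)
    substr(s, 13, 13) <- "G"
    substr(w, 22 - 13, 22 - 13) <- "T"
    al <- score_duplex(s, w)
    if (al$score == 3.5) break
  }
  sites <- find_candidate_sites(s, paste0(mk_seq(60), w, mk_seq(60)),
                                max_score = 3.5)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$score, 3.5)
  expect_equal(sites$start1, 61)
})

test_that("DP score equals exhaustive enumeration on fuzzed short pairs", {
  set.seed(53)
  scheme <- penalty_scheme()
  for (r in 1:150) {
    m <- sample(7:15, 1)
    d <- sample(-2:2, 1)
    s <- mk_seq(m)
    w <- if (r %% 3 == 0) {
      w0 <- rc_chr(s)
      n_mut <- sample(0:4, 1)
      for (q in sample(m, n_mut)) substr(w0, q, q) <- mk_seq(1)
      if (d > 0) paste0(mk_seq(d), w0) else substr(w0, 1 - d, m)
    } else mk_seq(m + d)
    expect_equal(score_duplex(s, w, scheme)$score,
                 oracle_duplex_score(s, w, scheme),
                 info = paste(s, w))
  }
})

test_that("G:U substitution never scores below Watson-Crick, mismatch never below G:U", {
  set.seed(54)
  for (r in 1:25) {
    s <- mk_seq(21)
    w <- rc_chr(s)
    p <- sample(21, 1)
    base_score <- score_duplex(s, w)$score
    s_gu <- s
    # make position p a G:U: sRNA base T opposite target G
    substr(s_gu, p, p) <- "T"
    w_gu <- w
    substr(w_gu, 22 - p, 22 - p) <- "G"
    gu_score <- score_duplex(s_gu, w_gu)$score
    w_mm <- w
    substr(w_mm, 22 - p, 22 - p) <- "C"  # T:C mismatch
    s_mm <- s
    substr(s_mm, p, p) <- "T"
    mm_score <- score_duplex(s_mm, w_mm)$score
    expect_gte(gu_score, base_score)
    expect_gte(mm_score, gu_score)
  }
})

test_that("every reported alignment's score re-derives from its state string", {
  set.seed(55)
  for (r in 1:40) {
    m <- sample(12:24, 1)
    s <- mk_seq(m)
    w0 <- rc_chr(s)
    for (q in sample(m, sample(0:5, 1))) substr(w0, q, q) <- mk_seq(1)
    d <- sample(-2:2, 1)
    w <- if (d > 0) paste0(mk_seq(d), w0) else substr(w0, 1 - d, m)
    al <- score_duplex(s, w)
    expect_equal(recompute_duplex_score(al$states), al$score)
    expect_equal(sum(strsplit(al$states, "")[[1]] %in% c("M", "W", "X", "S")),
                 m)
  }
})

test_that("candidate sites equal brute-force window enumeration on a short transcript", {
  set.seed(56)
  scheme <- penalty_scheme()
  s <- mk_seq(13)
  tx <- mk_seq(400)
  substr(tx, 150, 162) <- rc_chr(s)
  sites <- find_candidate_sites(s, tx, scheme)
  # brute force: best score per end over window lengths 11..15
  m <- 13L
  brute <- list()
  for (e in seq_len(400)) {
    best <- Inf
    for (len in (m - 2):(m + 2)) {
      st <- e - len + 1L
      if (st < 1) next
      sc <- oracle_duplex_score(s, substr(tx, st, e), scheme)
      if (sc < best) best <- sc
    }
    if (best <= scheme$max_score)
      brute[[length(brute) + 1L]] <- data.frame(end1 = e, score = best)
  }
  brute <- do.call(rbind, brute)
  # every returned site matches the brute-force optimum at its end
  for (k in seq_len(nrow(sites))) {
    b <- brute[brute$end1 == sites$end1[k], ]
    expect_equal(sites$score[k], b$score)
  }
  # every brute-force end either belongs to a returned site or was displaced
  # by an overlapping site of no worse score
  for (e in brute$end1) {
    b <- brute$score[brute$end1 == e]
    expect_true(any(sites$start1 <= e & sites$end1 >= e - 14 &
                      sites$score <= b + 1e-9))
  }
  # the planted site is recovered exactly, score 0, cleavage at position 10 partner
  expect_true(any(sites$start1 == 150 & sites$score == 0))
  expect_equal(sites$cleavage1[sites$start1 == 150], 162 - 9)
})

test_that("predict_targets is deterministic and finds planted perfect sites", {
  set.seed(57)
  txs <- setNames(vapply(rep(300, 4), mk_seq, character(1)),
                  paste0("t", 1:4))
  srnas <- setNames(vapply(rep(21, 3), mk_seq, character(1)),
                    paste0("s", 1:3))
  substr(txs[["t2"]], 100, 120) <- rc_chr(srnas[["s1"]])
  tab1 <- predict_targets(srnas, txs)
  tab2 <- predict_targets(srnas, txs)
  expect_identical(tab1, tab2)
  hit <- tab1[tab1$srna_id == "s1" & tab1$transcript == "t2" & tab1$score == 0, ]
  expect_equal(hit$start1, 100)
  expect_equal(hit$cleavage1, 120 - 9)
  expect_equal(nrow(predict_targets(character(0), txs)), 0L)
})
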