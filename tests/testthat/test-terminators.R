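test_that("hairpin enumeration matches the brute-force oracle", {
  set.seed(41)
  params <- terminator_params()
  for (rep in 1:8) {
    seq <- random_dna(120)
    got <- find_hairpins(seq, params)
    want <- brute_hairpins(seq, params)
    expect_equal(got[, c("start", "end", "stem_len", "loop_len",
                         "mismatches", "hairpin_score")],
                 want, info = sprintf("rep %d", rep))
  }
  # no complementarity, no candidates
  expect_equal(nrow(find_hairpins(strrep("A", 200))), 0L)
})

test_that("the worked hairpin is scored by first principles", {
  seq <- "AATATGGCAGCTTCGGCTGCCTTTTTTTT"
  params <- terminator_params()
  cands <- find_hairpins(seq, params)
  main <- cands[cands$stem_len == 6 & cands$loop_len == 4, ]
  expect_equal(nrow(main), 1L)
  expect_equal(main$start, 5L)
  expect_equal(main$end, 21L)
  expect_equal(main$mismatches, 0L)
  # pairs G:C,G:C,C:G,A:T,G:C,C:G = 17, minus 0.5 * loop 4
  expect_equal(main$hairpin_score, 17 - 2)
  expect_equal(brute_hairpins(seq, params)[
    brute_hairpins(seq, params)$loop_len == 4 &
      brute_hairpins(seq, params)$stem_len == 6, ]$hairpin_score, 15)

  # perfect 4-bp GC stem with a 3-nt loop: 12 - 1.5
  gc <- find_hairpins("TTGGCCAAAGGCCTT", terminator_params())
  best <- gc[which.max(gc$hairpin_score), ]
  expect_equal(best$hairpin_score, 12 - 1.5)
})

test_that("tail scoring uses decreasing weights and the logistic confidence map", {
  seq <- "AATATGGCAGCTTCGGCTGCCTTTTTTTT"
  params <- terminator_params()
  cands <- find_hairpins(seq, params)
  main <- cands[cands$stem_len == 6 & cands$loop_len == 4, ]
  scored <- score_tail(seq, main, params)
  # 8 T's: full weight sum 1.0 + 0.9 + ... + 0.3
  expect_equal(scored$tail_score, sum(1 - 0.1 * (0:7)))
  expect_equal(scored$confidence,
               100 / (1 + exp(-0.35 * (15 + 3 * 5.2 - 18))))

  # T-less tail: zero score, confidence below 50 whenever hairpin <= 18
  noT <- paste0(substr(seq, 1, 21), "GAGCACAG")
  scored0 <- score_tail(noT, main, params)
  expect_equal(scored0$tail_score, 0)
  expect_lt(scored0$confidence, 50)

  # truncated tail at the contig end is scored over available bases
  trunc <- substr(seq, 1, 24)                 # only 3 tail bases remain
  scoredt <- score_tail(trunc, main, params)
  expect_equal(scoredt$tail_score, 1 + 0.9 + 0.8)
})

test_that("confidence is monotone in stem strength and tail T count", {
  params <- terminator_params()
  loop <- "AAAA"          # non-pairing against G/C arms
  best_conf <- function(seq) {
    hp <- find_hairpins(seq, params)
    score_tail(seq, hp[which.max(hp$hairpin_score), ], params)$confidence
  }
  # growing the GC stem never lowers confidence ("CC" guard cannot pair T)
  confs <- vapply(4:8, function(s) {
    best_conf(paste0("CC", strrep("G", s), loop, strrep("C", s), "TTTTTTTT", "AA"))
  }, numeric(1))
  expect_true(all(diff(confs) >= 0))
  # each added tail T never lowers the confidence of the same hairpin
  base <- paste0("CC", "GGGGG", loop, "CCCCC", strrep("A", 8), "CC")
  hp <- find_hairpins(base, params)
  cand <- hp[hp$stem_len == 5 & hp$loop_len == 4, ][1, ]
  confs2 <- vapply(0:8, function(k) {
    seqk <- paste0("CC", "GGGGG", loop, "CCCCC",
                   strrep("T", k), strrep("A", 8 - k), "CC")
    score_tail(seqk, cand, params)$confidence
  }, numeric(1))
  expect_true(all(diff(confs2) >= 0))
})

test_that("planted canonical terminators are found at their coordinates", {
  term <- canonical_terminator()
  set.seed(53)
  for (rep in 1:3) {
    chars <- strsplit(random_dna(10000), "")[[1]]
    plant <- data.frame(at = c(2000L, 5000L, 8000L), strand = c("+", "-", "+"))
    rows <- list()
    for (i in seq_len(nrow(plant))) {
      gl <- nchar(term$guard)
      hl <- nchar(term$full) - gl - nchar(term$tail)
      if (plant$strand[i] == "+") {
        s <- strsplit(term$full, "")[[1]]
        chars[(plant$at[i] + 1):(plant$at[i] + length(s))] <- s
        rows[[i]] <- data.frame(start = plant$at[i] + gl,
                                end = plant$at[i] + gl + hl, strand = "+")
      } else {
        s <- strsplit(revcomp(term$full), "")[[1]]
        chars[(plant$at[i] + 1):(plant$at[i] + length(s))] <- s
        rows[[i]] <- data.frame(start = plant$at[i] + nchar(term$tail),
                                end = plant$at[i] + nchar(term$tail) + hl,
                                strand = "-")
      }
    }
    truth <- do.call(rbind, rows)
    rec <- genome_record("t", paste(chars, collapse = ""))
    found <- find_terminators(rec)
    for (i in seq_len(nrow(truth))) {
      expect_true(any(found$start == truth$start[i] &
                        found$end == truth$end[i] &
                        found$strand == truth$strand[i]),
                  info = sprintf("rep %d terminator %d", rep, i))
    }
  }
  expect_equal(nrow(find_terminators(genome_record("a", strrep("A", 10000)))), 0L)
})

test_that("terminator detection is strand-reflection symmetric", {
  set.seed(59)
  term <- canonical_terminator()
  chars <- strsplit(random_dna(5000), "")[[1]]
  s <- strsplit(term$full, "")[[1]]
  chars[1001:(1000 + length(s))] <- s
  seqs <- paste(chars, collapse = "")
  fwd <- find_terminators(genome_record("x", seqs))
  rev_ <- find_terminators(genome_record("x", revcomp(seqs)))
  n <- nchar(seqs)
  refl <- data.frame(start = n - rev_$end, end = n - rev_$start,
                     strand = ifelse(rev_$strand == "+", "-", "+"),
                     hairpin_score = rev_$hairpin_score,
                     tail_score = rev_$tail_score,
                     confidence = rev_$confidence)
  refl <- refl[order(refl$start, refl$end, refl$strand), ]
  fcmp <- fwd[order(fwd$start, fwd$end, fwd$strand),
              c("start", "end", "strand", "hairpin_score", "tail_score", "confidence")]
  rownames(refl) <- rownames(fcmp) <- NULL
  expect_equal(fcmp, refl)
})

test_that("raising min_confidence never adds candidates", {
  set.seed(61)
  rec <- genome_record("m", random_dna(8000))
  lo <- find_terminators(rec, terminator_params(min_confidence = 70))
  hi <- find_terminators(rec, terminator_params(min_confidence = 85))
  expect_true(all(paste(hi$start, hi$strand) %in% paste(lo$start, lo$strand)))
  expect_lte(nrow(hi), nrow(lo))
})

test_that("terminator parameter invariants are enforced", {
  expect_error(terminator_params(stem_min = 10, stem_max = 4),
               class = "regsig_argument_error")
  expect_error(terminator_params(loop_min = 8, loop_max = 3),
               class = "regsig_argument_error")
  expect_error(terminator_params(tail_len = 0), class = "regsig_argument_error")
})
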