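test_that("profile construction follows the smoothed log-odds definition", {
  aln <- rbind(
    strsplit("ACGT", "")[[1]],
    strsplit("ACGT", "")[[1]],
    strsplit("ACGA", "")[[1]]
  )
  p <- build_profile(aln, pseudocount = 1)
  expect_equal(p$L, 4L)
  expect_equal(p$consensus, "ACGT")
  # position 1: count(A) = 3 -> log2(((3+1)/(3+4))/0.25)
  expect_equal(unname(p$emissions[1, "A"]), log2((4 / 7) / 0.25))
  expect_equal(unname(p$emissions[1, "C"]), log2((1 / 7) / 0.25))
  # position 4: T twice, A once
  expect_equal(unname(p$emissions[4, "T"]), log2((3 / 7) / 0.25))
  expect_equal(unname(p$emissions[4, "A"]), log2((2 / 7) / 0.25))
  expect_true(all(is.finite(p$emissions)))
  # consensus emissions all positive for an identity-dominated alignment
  cons <- strsplit(p$consensus, "")[[1]]
  cons_scores <- vapply(1:4, function(i) p$emissions[i, cons[i]], numeric(1))
  expect_true(all(cons_scores > 0))
})

test_that("gappy columns are dropped by the threshold and N spreads over bases", {
  aln <- rbind(
    strsplit("A-GT", "")[[1]],
    strsplit("A-GT", "")[[1]],
    strsplit("A-GT", "")[[1]],
    strsplit("ACGT", "")[[1]]
  )
  p <- build_profile(aln, gap_col_threshold = 0.5)
  expect_equal(p$L, 3L) # column 2 gapped in 3/4 rows
  expect_equal(p$consensus, "AGT")

  alnN <- rbind(strsplit("AN", "")[[1]], strsplit("AN", "")[[1]])
  pN <- build_profile(alnN)
  # N contributes 1/4 count to each base: emissions equal across bases
  expect_equal(length(unique(round(pN$emissions[2, c("A", "C", "G", "T")], 12))), 1L)

  expect_error(build_profile(aln[1, , drop = FALSE]), "at least 2 rows")
  all_gap <- rbind(c("-", "-"), c("-", "-"))
  expect_error(build_profile(all_gap), "gap threshold")
})

test_that("profile construction is invariant to row order and monotone in counts", {
  set.seed(11)
  rows <- replicate(6, paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = ""))
  m <- do.call(rbind, strsplit(rows, ""))
  p1 <- build_profile(m)
  p2 <- build_profile(m[sample(nrow(m)), ])
  expect_equal(p1$emissions, p2$emissions)
  # adding one more A at a position never decreases the A emission
  m2 <- m
  m2[1, 5] <- "A"
  p3 <- build_profile(m2)
  expect_gte(p3$emissions[5, "A"], p1$emissions[5, "A"])
})

test_that("glocal scoring attains the per-position maximum on the consensus", {
  p <- tiny_profile()
  sc <- score_glocal(p, p$consensus)
  expect_equal(sc$score, p$self_score)
  expect_equal(sc$aligned, p$consensus)
  expect_equal(sc$seq_start, 0L)
  expect_equal(sc$seq_end, nchar(p$consensus))
  # flanking background is free
  flank <- paste(rep("A", 25), collapse = "")
  sc2 <- score_glocal(p, paste0(flank, p$consensus, flank))
  expect_equal(sc2$score, p$self_score)
  expect_equal(sc2$seq_start, 25L)
  expect_equal(sc2$seq_end, 25L + nchar(p$consensus))
})

test_that("a substitution lowers the score by exactly the emission difference", {
  p <- tiny_profile()
  cons <- strsplit(p$consensus, "")[[1]]
  pos <- 17L
  other <- setdiff(c("A", "C", "G", "T"), cons[pos])[1]
  mut <- cons
  mut[pos] <- other
  sc <- score_glocal(p, paste(mut, collapse = ""))
  drop <- unname(p$emissions[pos, cons[pos]] - p$emissions[pos, other])
  expect_equal(p$self_score - sc$score, drop)
  expect_error(score_glocal(p, ""), "non-empty")
})

test_that("no random background sequence approaches the consensus score", {
  p <- tiny_profile()
  set.seed(402)
  null_max <- max(vapply(seq_len(1000), function(i) {
    s <- paste(sample(c("A", "C", "G", "T"), p$L, TRUE), collapse = "")
    score_glocal(p, s)$score
  }, numeric(1)))
  expect_lt(null_max, 0.5 * p$self_score)
})

test_that("reverse complement is the standard involution with N fixed", {
  expect_equal(reverse_complement("ACGT"), "ACGT")
  expect_equal(reverse_complement("AACN"), "NGTT")
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T", "N"), 100, TRUE), collapse = "")
  expect_equal(reverse_complement(reverse_complement(s)), s)
})

test_that("profile TSV serialisation round-trips", {
  p <- tiny_profile()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_profile_tsv(p, f)
  q <- read_profile_tsv(f)
  expect_equal(q$consensus, p$consensus)
  expect_equal(q$L, p$L)
  expect_equal(q$emissions[, 1:4], p$emissions[, 1:4], tolerance = 1e-9)
  expect_equal(q$self_score, p$self_score, tolerance = 1e-9)
  expect_equal(q$gap_open, p$gap_open)
})
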