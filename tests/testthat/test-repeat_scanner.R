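test_that("an exact planted monomer is recovered on either strand", {
  p <- tiny_profile()
  set.seed(403)
  bg <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  plant <- function(seq) {
    paste0(substr(bg, 1, 10000), seq, substr(bg, 10001 + nchar(seq), 20000))
  }
  g_fwd <- Biostrings::DNAStringSet(c(chr = plant(p$consensus)))
  h <- scan_genome(g_fwd, p)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 10000L)
  expect_equal(h$end, 10000L + p$L)
  expect_equal(h$strand, "+")
  expect_equal(h$sequence, p$consensus)

  g_rev <- Biostrings::DNAStringSet(c(chr = plant(reverse_complement(p$consensus))))
  h2 <- scan_genome(g_rev, p)
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$start, 10000L)
  expect_equal(h2$end, 10000L + p$L)
  expect_equal(h2$strand, "-")
  expect_equal(h2$sequence, p$consensus)

  expect_equal(nrow(scan_genome(Biostrings::DNAStringSet(), p)), 0L)
})

test_that("diverged planted copies are recovered with tight boundaries", {
  ss <- small_scan()
  cmp <- truth_compare(ss$sim$truth, ss$hits)
  expect_equal(cmp$recall, 1)
  expect_equal(cmp$precision, 1)
  expect_lte(cmp$boundary_mae, 5)
})

test_that("scanning the reverse-complemented genome mirrors coordinates", {
  ss <- small_scan()
  g <- ss$sim$genome
  rc <- Biostrings::reverseComplement(g)
  names(rc) <- names(g)
  h_f <- ss$hits
  h_r <- scan_genome(rc, ss$profile)
  lens <- stats::setNames(Biostrings::width(g), names(g))
  mirrored <- h_r |>
    dplyr::mutate(
      m_start = lens[.data$seq_id] - .data$end,
      m_end = lens[.data$seq_id] - .data$start,
      m_strand = ifelse(.data$strand == "+", "-", "+")
    ) |>
    dplyr::arrange(.data$seq_id, .data$m_start)
  expect_equal(mirrored$m_start, h_f$start, ignore_attr = TRUE)
  expect_equal(mirrored$m_end, h_f$end, ignore_attr = TRUE)
  expect_equal(mirrored$m_strand, h_f$strand)
  expect_equal(mirrored$sequence, h_f$sequence)
})

test_that("raw blocks group by the max-gap rule within chromosomes only", {
  mk <- function(seq_id, start) {
    tibble::tibble(
      unit_key = paste0(seq_id, "_", start), seq_id = seq_id,
      start = start, end = start + 528L, strand = "+", score = 400,
      sequence = "A", aligned = "A"
    )
  }
  hits <- dplyr::bind_rows(
    mk("c1", 0L), mk("c1", 628L),      # gap 100 -> same block
    mk("c1", 11156L),                  # gap 10 kb -> new block
    mk("c2", 0L)                       # other chromosome
  )
  b <- call_raw_blocks(hits, max_gap = 600)
  expect_equal(length(unique(b$block_id)), 3L)
  expect_equal(b$block_id[1], b$block_id[2])
  expect_false(b$block_id[2] == b$block_id[3])
  expect_false(any(b$block_id[b$seq_id == "c1"] %in% b$block_id[b$seq_id == "c2"]))
  expect_error(call_raw_blocks(hits[c(2, 1, 3, 4), ]), "sorted")
})

test_that("filters remove block termini, short units and ambiguous units in order", {
  mk <- function(start, len = 528L, seq = NULL) {
    tibble::tibble(
      unit_key = paste0("u", start), seq_id = "c1", start = start,
      end = start + len, strand = "+", score = 400,
      sequence = seq %||% paste(rep("A", len), collapse = ""),
      aligned = "A"
    )
  }
  `%||%` <- function(x, y) if (is.null(x)) y else x
  # one clean block of five 528-bp units -> interior 3 retained
  five <- dplyr::bind_rows(lapply(0:4, function(i) mk(i * 528L)))
  five <- call_raw_blocks(five, 600)
  res <- filter_units(five, min_len = 500)
  expect_equal(res$report$n_raw, 5L)
  expect_equal(res$report$n_terminal_removed, 2L)
  expect_equal(res$report$n_retained, 3L)

  # 1-unit block loses its unit; 2-unit block loses both
  b1 <- call_raw_blocks(mk(0L), 600)
  expect_equal(filter_units(b1)$report$n_retained, 0L)
  b2 <- call_raw_blocks(dplyr::bind_rows(mk(0L), mk(528L)), 600)
  r2 <- filter_units(b2)
  expect_equal(r2$report$n_terminal_removed, 2L)
  expect_equal(r2$report$n_retained, 0L)

  # strict length retention: 501 kept, 500 and 499 removed
  lens <- c(528L, 501L, 500L, 499L, 528L)
  starts <- cumsum(c(0L, head(lens, -1)))
  blk <- call_raw_blocks(
    dplyr::bind_rows(mapply(mk, starts, lens, SIMPLIFY = FALSE)), 600)
  rl <- filter_units(blk, min_len = 500)
  expect_equal(rl$report$n_terminal_removed, 2L)
  expect_equal(rl$report$n_short_removed, 2L)
  expect_equal(rl$units$end - rl$units$start, 501L)

  # interior unit with one N is removed and tallied as ambiguous
  seqN <- paste0(paste(rep("A", 300), collapse = ""), "N",
                 paste(rep("A", 227), collapse = ""))
  blkN <- call_raw_blocks(dplyr::bind_rows(
    mk(0L), mk(528L, seq = seqN), mk(1056L)), 600)
  rn <- filter_units(blkN)
  expect_equal(rn$report$n_ambiguous_removed, 1L)
  expect_equal(rn$report$n_retained, 0L)
  # report is conserved
  expect_equal(rn$report$n_retained,
               rn$report$n_raw - rn$report$n_terminal_removed -
                 rn$report$n_short_removed - rn$report$n_ambiguous_removed)
})

test_that("retained set is independent of input hit order", {
  ss <- small_scan()
  blocks <- call_raw_blocks(ss$hits, 600)
  r1 <- filter_units(blocks)
  set.seed(1)
  shuffled <- blocks[sample(nrow(blocks)), ] |>
    dplyr::arrange(.data$seq_id, .data$start)
  r2 <- filter_units(shuffled)
  expect_equal(r1$units$unit_key, r2$units$unit_key)
  expect_equal(r1$report, r2$report)
})

test_that("names number units in tens, 5' to 3', restarting per chromosome", {
  units <- tibble::tibble(
    unit_key = c("a", "b", "c", "d"),
    seq_id = c("Chr01", "Chr01", "Chr11", "Chr11"),
    start = c(100L, 1000L, 50L, 900L),
    end = c(628L, 1528L, 578L, 1428L),
    strand = "+", score = 400, sequence = "A", aligned = "A",
    arm = c("S", "S", "L", "L")
  )
  named <- assign_names(units)
  expect_equal(named$name, c("Pv01Sk00010", "Pv01Sk00020",
                             "Pv11Lk00010", "Pv11Lk00020"))
  units3 <- dplyr::bind_rows(
    units[3:4, ],
    dplyr::mutate(units[3, ], unit_key = "e", start = 2000L, end = 2528L))
  named3 <- assign_names(dplyr::arrange(units3, .data$seq_id, .data$start))
  expect_equal(named3$name[3], "Pv11Lk00030")
  expect_error(assign_names(dplyr::mutate(units, arm = NA_character_)),
               "arm assignment")
})
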