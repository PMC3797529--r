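test_that("an exact substring contig is placed to the base in both orientations", {
  fx <- qc_fixture()
  pl <- place_contig(c(bacA = fx$contig), fx$genome)
  expect_equal(pl$seq_id, "Chr02")
  expect_equal(pl$start, fx$lo)
  expect_equal(pl$end, fx$hi)
  expect_equal(pl$orientation, "+")
  expect_false(pl$flagged)

  rc <- reverse_complement(fx$contig)
  pl2 <- place_contig(c(bacA_rc = rc), fx$genome)
  expect_equal(pl2$start, fx$lo)
  expect_equal(pl2$end, fx$hi)
  expect_equal(pl2$orientation, "-")

  set.seed(408)
  junk <- paste(sample(c("A", "C", "G", "T"), 5000, TRUE), collapse = "")
  expect_error(place_contig(c(x = junk), fx$genome), "unplaceable")
})

test_that("identical unit sets pair one-to-one at identity 1", {
  fx <- qc_fixture()
  qc <- assembly_qc(c(bacA = fx$contig), fx$chits, fx$genome, fx$ghits)
  expect_equal(qc$report$n_contig_only, 0L)
  expect_equal(qc$report$n_paired, nrow(fx$chits))
  paired <- qc$pairing[!is.na(qc$pairing$contig_unit) &
                         !is.na(qc$pairing$genome_unit), ]
  expect_true(all(paired$identity == 1))
  expect_equal(nrow(qc$cross_location), 0L)
  expect_equal(nrow(qc$gaps), 0L)
})

test_that("swapping the unit lists swaps the contig-only and genome-only roles", {
  fx <- qc_fixture()
  local <- fx$ghits[fx$ghits$seq_id == "Chr02" &
                      fx$ghits$end > fx$lo & fx$ghits$start < fx$hi, ]
  drop2 <- local[-(1:2), ]
  p1 <- pair_units(fx$chits, drop2)
  p2 <- pair_units(drop2, fx$chits)
  n_c_only <- sum(!is.na(p1$contig_unit) & is.na(p1$genome_unit))
  n_g_only <- sum(is.na(p2$contig_unit) & !is.na(p2$genome_unit))
  expect_equal(n_c_only, 2L)
  expect_equal(n_g_only, 2L)
})

test_that("units missing from the assembly produce a gap span in the report", {
  fx <- qc_fixture()
  local <- fx$ghits[fx$ghits$seq_id == "Chr02" &
                      fx$ghits$end > fx$lo & fx$ghits$start < fx$hi, ]
  # drop two adjacent genome units, as if the assembly collapsed the array
  blk <- local[order(local$start), ][3:4, ]
  ghits2 <- fx$ghits[!fx$ghits$unit_key %in% blk$unit_key, ]
  qc <- assembly_qc(c(bacA = fx$contig), fx$chits, fx$genome, ghits2)
  expect_equal(qc$report$n_contig_only, 2L)
  expect_equal(nrow(qc$gaps), 1L)
  expect_equal(qc$gaps$n_missing_units, 2L)
  # the projected gap covers the dropped units
  expect_lte(qc$gaps$start, min(blk$start) + 5)
  expect_gte(qc$gaps$end, max(blk$end) - 5)
})

test_that("relocated blocks are flagged as cross-location hits with no false flags", {
  fx <- qc_fixture()
  sim <- fx$sim
  g2 <- as.character(sim$genome)
  blk_id <- sim$blocks$block_id[sim$blocks$seq_id == "Chr02" &
                                  sim$blocks$region == "S"][2]
  blk <- sim$truth[sim$truth$block_id == blk_id, ]
  bseq <- substr(g2[["Chr02"]], min(blk$start) + 1, max(blk$end))
  # paste the block into Chr01 background far from any planted array,
  # then overwrite the original location with random sequence
  at <- 2.5e5
  substr(g2[["Chr01"]], at + 1, at + nchar(bseq)) <- bseq
  set.seed(409)
  substr(g2[["Chr02"]], min(blk$start) + 1, max(blk$end)) <-
    paste(sample(c("A", "C", "G", "T"), nchar(bseq), TRUE), collapse = "")
  g2 <- Biostrings::DNAStringSet(g2)
  ghits2 <- call_raw_blocks(scan_genome(g2, fx$profile))
  qc <- assembly_qc(c(bacA = fx$contig), fx$chits, g2, ghits2)
  expect_equal(qc$report$n_contig_only, nrow(blk))
  expect_equal(nrow(qc$cross_location), nrow(blk))
  expect_true(all(qc$cross_location$identity == 1))
  expect_true(all(qc$cross_location$seq_id == "Chr01"))
})
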