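test_that("final blocks partition the retained units with non-overlapping spans", {
  run <- default_run()
  blk <- call_blocks(run$units, max_gap = 600)
  expect_equal(sum(blk$blocks$n_units), nrow(run$units))
  spans <- blk$blocks |> dplyr::arrange(.data$seq_id, .data$start)
  by_chr <- split(spans, spans$seq_id)
  for (s in by_chr) {
    if (nrow(s) > 1) expect_true(all(s$start[-1] >= s$end[-nrow(s)]))
  }
  # alternating unit / large gap -> singleton blocks
  mk <- function(start) tibble::tibble(
    unit_key = paste0("u", start), seq_id = "c1", start = start,
    end = start + 528L, strand = "+", score = 1, sequence = "A", aligned = "A")
  lone <- dplyr::bind_rows(lapply(seq(0, by = 5528, length.out = 6), mk))
  b6 <- call_blocks(lone, max_gap = 600)
  expect_equal(nrow(b6$blocks), 6L)
  expect_true(all(b6$blocks$n_units == 1L))
})

test_that("a planted centromeric array is located and the largest cluster wins", {
  set.seed(404)
  cent <- paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = "")
  bg <- sample(c("A", "C", "G", "T"), 4e5, TRUE)
  plant_array <- function(bg, at, copies) {
    for (i in seq_len(copies)) {
      ch <- strsplit(cent, "")[[1]]
      pos <- sample(150, 3)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      bg[(at + (i - 1) * 150 + 1):(at + i * 150)] <- ch
    }
    bg
  }
  bg <- plant_array(bg, 2e5, 50)   # major array at 200 kb
  bg <- plant_array(bg, 5e4, 5)    # minor array at 50 kb
  g <- Biostrings::DNAStringSet(c(chr1 = paste(bg, collapse = "")))
  cents <- locate_centromeres(g, c(CentX = cent), merge_gap = 2e4)
  expect_equal(nrow(cents), 1L)
  expect_equal(cents$family, "CentX")
  # interval covers the major array, not the minor one
  expect_lte(cents$start, 2e5 + 150)
  expect_gte(cents$end, 2e5 + 50 * 150 - 150)
  expect_gt(cents$start, 5e4 + 5 * 150)

  none <- locate_centromeres(
    Biostrings::DNAStringSet(c(c2 = paste(sample(c("A", "C", "G", "T"), 5e4, TRUE),
                                          collapse = ""))),
    c(CentX = cent))
  expect_equal(nrow(none), 0L)
})

test_that("arm codes follow the before/inside/after rule with a midpoint fallback", {
  units <- tibble::tibble(
    unit_key = paste0("u", 1:4), seq_id = "Chr01",
    start = c(100L, 5e6L, as.integer(5e6 - 200), 7e6L),
    end = c(628L, as.integer(5e6 + 528), as.integer(5e6 + 328), as.integer(7e6 + 528))
  )
  cent <- tibble::tibble(seq_id = "Chr01", start = 5e6L, end = 6e6L,
                         n_hits = 10L, family = "CentX")
  a <- assign_arms(units, cent)
  expect_equal(a$arm, c("S", "C", "C", "L")) # straddling start -> C
  # arm sequence along a chromosome is monotone S* C* L*
  run <- default_run()
  for (s in split(run$units, run$units$seq_id)) {
    codes <- s$arm[order(s$start)]
    expect_match(paste(codes, collapse = ""), "^S*C*L*$")
  }
  # no centromere: midpoint split with warning
  expect_warning(
    m <- assign_arms(units, NULL, chrom_lengths = c(Chr01 = 1e7)),
    "midpoint")
  expect_equal(m$arm, c("S", "L", "L", "L")) # unit 3 straddles the midpoint rightward
})

test_that("the count matrix conserves totals and reports empty chromosomes", {
  empty <- count_matrix(tibble::tibble(seq_id = character(), arm = character()),
                        chromosomes = c("Chr01", "Chr02"))
  expect_equal(nrow(empty), 3L)
  expect_true(all(empty$total == 0L))

  run <- default_run()
  cm <- run$count_matrix
  body <- cm[cm$seq_id != "Total", ]
  expect_equal(body$total, body$short_arm + body$centromere + body$long_arm)
  tot <- cm[cm$seq_id == "Total", ]
  expect_equal(tot$total, sum(body$total))
  expect_equal(tot$total, nrow(run$units))
  expect_error(count_matrix(tibble::tibble(seq_id = "c", arm = NA_character_)),
               "arm assignment")
})
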