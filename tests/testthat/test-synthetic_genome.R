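test_that("degenerate parameters give identical, arm-confined units", {
  sim <- simulate_genome(sim_params(
    n_chrom = 2, chrom_length = 5e5, subtelomere_span = 1.5e5,
    blocks_per_arm_mean = 3, mu = 0, tau = 0, rho = 0, kappa = 0,
    founder_divergence = 0, seed = 1
  ))
  expect_true(all(sim$truth$sequence == sim$monomer))
  expect_false(any(sim$truth$recombinant))
  arms_per_lineage <- tapply(
    paste0(sim$truth$seq_id, sim$truth$region),
    sim$truth$lineage, function(x) length(unique(x)))
  expect_true(all(arms_per_lineage == 1))
})

test_that("the emitted FASTA slice equals the recorded truth at every unit", {
  sim <- small_sim()
  g <- as.character(sim$genome)
  for (i in seq_len(nrow(sim$truth))) {
    slice <- substr(g[[sim$truth$seq_id[i]]], sim$truth$start[i] + 1,
                    sim$truth$end[i])
    want <- if (sim$truth$strand[i] == "+") sim$truth$sequence[i] else
      reverse_complement(sim$truth$sequence[i])
    expect_equal(slice, want)
  }
})

test_that("simulation is bit-reproducible for a fixed seed", {
  p <- sim_params(n_chrom = 2, chrom_length = 3e5, subtelomere_span = 8e4,
                  blocks_per_arm_mean = 3, seed = 42)
  s1 <- simulate_genome(p)
  s2 <- simulate_genome(p)
  expect_identical(as.character(s1$genome), as.character(s2$genome))
  expect_identical(s1$truth, s2$truth)
})

test_that("block sizes average near their configured mean", {
  sizes <- integer(0)
  s <- 0
  while (length(sizes) < 300 && s < 40) {
    s <- s + 1
    sim <- tryCatch(
      simulate_genome(sim_params(
        n_chrom = 3, chrom_length = 6e5, subtelomere_span = 2.5e5,
        blocks_per_arm_mean = 5, kappa = 0, seed = s
      )),
      error = function(e) NULL # a rare overflow draw is skipped
    )
    if (!is.null(sim)) sizes <- c(sizes, sim$blocks$size)
  }
  expect_gte(length(sizes), 300)
  # truncated-geometric mean: E[min(55, 1 + Geom(1/8))] is slightly under 8
  expect_lt(abs(mean(sizes) - 8) / 8, 0.1)
  expect_lte(max(sizes), 55)
})

test_that("centromeric placement creates lineages shared with subtelomeres", {
  sim <- kappa_sim()
  cent_units <- sim$truth[sim$truth$region == "C", ]
  expect_gt(nrow(cent_units), 0)
  shared <- vapply(unique(cent_units$lineage), function(l) {
    any(sim$truth$lineage == l & sim$truth$region != "C")
  }, logical(1))
  expect_true(any(shared))
})

test_that("truth comparison scores calls against planted units", {
  sim <- small_sim()
  calls <- sim$truth[, c("seq_id", "start", "end")]
  perfect <- truth_compare(sim$truth, calls)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$boundary_mae, 0)

  # terminal-exclusion arithmetic: recall of interior-only calls
  interior <- sim$truth |>
    dplyr::group_by(.data$block_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() > 1, dplyr::row_number() < dplyr::n()) |>
    dplyr::ungroup()
  part <- truth_compare(sim$truth, interior)
  want <- sum(pmax(sim$blocks$size - 2, 0)) / sum(sim$blocks$size)
  expect_equal(part$recall, want)
  expect_equal(part$precision, 1)

  # scrambled background calls match nothing
  junk <- tibble::tibble(seq_id = "Chr01",
                         start = seq(150000L, 170000L, by = 1000L))
  junk$end <- junk$start + 528L
  expect_equal(truth_compare(sim$truth, junk)$precision, 0)
})

test_that("interchromosomal transfer raises arms-per-lineage in the truth", {
  higher <- 0L
  for (s in 1:20) {
    base <- list(n_chrom = 3, chrom_length = 6e5, subtelomere_span = 2e5,
                 blocks_per_arm_mean = 4, kappa = 0, rho = 0, seed = s)
    apl <- function(tau) {
      sim <- simulate_genome(do.call(sim_params, c(base, tau = tau)))
      mean(tapply(paste0(sim$truth$seq_id, sim$truth$region),
                  sim$truth$lineage, function(x) length(unique(x))))
    }
    if (apl(0.5) > apl(0)) higher <- higher + 1L
  }
  expect_gte(higher, 18L)
})
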