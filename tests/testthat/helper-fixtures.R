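# Shared fixtures, memoised so expensive simulations and pipeline runs are
# computed once per test session.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# a tiny profile from three slightly diverged copies of a short monomer
tiny_profile <- function() {
  fixture("tiny_profile", function() {
    set.seed(401)
    mono <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = "")
    rows <- vapply(1:5, function(i) {
      ch <- strsplit(mono, "")[[1]]
      pos <- sample(60, 3)
      for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      paste(ch, collapse = "")
    }, character(1))
    build_profile(do.call(rbind, strsplit(rows, "")))
  })
}

# default study-condition simulation (3 x 2 Mb, ~300 units, mu 0.03, seed 42)
default_sim <- function() {
  fixture("default_sim", function() simulate_genome(sim_params(seed = 42)))
}

# seed alignment sampled from a simulation's planted units, as a user would
# supply one (ungapped rows of equal length)
seed_alignment_of <- function(sim, n = 60) {
  idx <- round(seq(1, nrow(sim$truth), length.out = n))
  do.call(rbind, strsplit(sim$truth$sequence[idx], ""))
}

# full pipeline run on the default scenario
default_run <- function() {
  fixture("default_run", function() {
    sim <- default_sim()
    suppressMessages(run_pipeline(
      sim$genome, seed_alignment_of(sim),
      cent_repeats = c(CentSim1 = sim$cent_monomer), seed = 1
    ))
  })
}

# transfer-free, recombination-free, centromere-free scenario: lineages are
# confined to their home arms
tau0_sim <- function() {
  fixture("tau0_sim", function() {
    simulate_genome(sim_params(tau = 0, rho = 0, kappa = 0, seed = 42))
  })
}

tau0_run <- function() {
  fixture("tau0_run", function() {
    sim <- tau0_sim()
    suppressMessages(run_pipeline(
      sim$genome, seed_alignment_of(sim),
      cent_repeats = c(CentSim1 = sim$cent_monomer), seed = 1
    ))
  })
}

# centromere-exchange scenario: kappa chosen high enough that centromeric
# blocks are present at desk scale
kappa_sim <- function() {
  fixture("kappa_sim", function() simulate_genome(sim_params(kappa = 0.2, seed = 42)))
}

kappa_run <- function() {
  fixture("kappa_run", function() {
    sim <- kappa_sim()
    suppressMessages(run_pipeline(
      sim$genome, seed_alignment_of(sim),
      cent_repeats = c(CentSim1 = sim$cent_monomer), seed = 1
    ))
  })
}

# small genome for scanner/QC tests (fast to scan)
small_sim <- function() {
  fixture("small_sim", function() {
    simulate_genome(sim_params(
      n_chrom = 2, chrom_length = 4e5, subtelomere_span = 1e5,
      blocks_per_arm_mean = 3, kappa = 0, tau = 0, rho = 0, seed = 7
    ))
  })
}

small_scan <- function() {
  fixture("small_scan", function() {
    sim <- small_sim()
    prof <- profile_from_sequence(sim$monomer, pseudocount = 1)
    list(sim = sim, profile = prof,
         hits = scan_genome(sim$genome, prof))
  })
}

# a contig cut from the small genome plus the scans QC needs
qc_fixture <- function() {
  fixture("qc_fixture", function() {
    ss <- small_scan()
    sim <- ss$sim
    g <- as.character(sim$genome)
    tr <- sim$truth[sim$truth$seq_id == "Chr02" & sim$truth$region == "S", ]
    lo <- max(0L, as.integer(min(tr$start)) - 900L) # background before block 1
    hi <- max(tr$end) + 5000L
    contig <- substr(g[["Chr02"]], lo + 1, hi)
    chits <- call_raw_blocks(scan_genome(
      Biostrings::DNAStringSet(c(bacA = contig)), ss$profile))
    ghits <- call_raw_blocks(ss$hits)
    list(sim = sim, profile = ss$profile, genome = sim$genome,
         contig = contig, lo = lo, hi = hi, chits = chits, ghits = ghits)
  })
}

# flat unit family MSA as a character matrix
family_msa <- function(fam) {
  msa <- do.call(rbind, strsplit(fam$seqs, ""))
  rownames(msa) <- names(fam$seqs)
  msa
}
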