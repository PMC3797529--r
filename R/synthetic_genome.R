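#' Parameters for the synthetic satellite-genome simulator
#'
#' The simulator emulates the dynamics inferred for subtelomeric satellites:
#' terminal tandem blocks, a centromeric satellite array, point-mutation
#' divergence among monomers, local tandem duplication (a within-block
#' birth chain), interchromosomal transfer of monomer lineages, occasional
#' recombinant monomers, and occasional centromeric placement of a block.
#'
#' @param n_chrom Number of chromosomes.
#' @param chrom_length Chromosome length in bases.
#' @param monomer Satellite monomer sequence; a random 528-mer by default.
#' @param cent_monomer Centromeric satellite monomer; random 150-mer by
#'   default.
#' @param n_founders Number of independent monomer lineages.
#' @param founder_divergence Per-lineage substitution rate from the
#'   ancestral monomer (pairwise lineage divergence is about twice this).
#' @param blocks_per_arm_mean Poisson mean of the number of blocks per arm.
#' @param block_size_mean Mean block size (geometric, truncated at
#'   `block_size_max`).
#' @param block_size_max Largest simulated block.
#' @param mu Substitutions/site per copy event.
#' @param tau Probability that a new block's founding lineage is drawn from
#'   another chromosome's lineage pool (interchromosomal transfer).
#' @param rho Probability that a copied unit is a two-parent recombinant
#'   (breakpoint uniform in the middle 60 % of the monomer).
#' @param kappa Probability that a block is placed inside the centromere
#'   span instead of the subtelomere.
#' @param subtelomere_span Bases from each chromosome end where blocks are
#'   placed.
#' @param centromere_frac Fractional interval of each chromosome reserved
#'   for the centromere.
#' @param cent_array_copies Copies in the planted centromeric satellite
#'   array.
#' @param seed Master seed; the simulation is bit-reproducible for a fixed
#'   seed.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_chrom = 3, chrom_length = 2e6,
                       monomer = NULL, cent_monomer = NULL,
                       n_founders = 8, founder_divergence = 0.08,
                       blocks_per_arm_mean = 6.5,
                       block_size_mean = 8, block_size_max = 55,
                       mu = 0.03, tau = 0.1, rho = 0.02, kappa = 0.05,
                       subtelomere_span = 3e5,
                       centromere_frac = c(0.45, 0.55),
                       cent_array_copies = 60,
                       seed = 42) {
  p <- list(
    n_chrom = n_chrom, chrom_length = chrom_length,
    monomer = monomer, cent_monomer = cent_monomer,
    n_founders = n_founders, founder_divergence = founder_divergence,
    blocks_per_arm_mean = blocks_per_arm_mean,
    block_size_mean = block_size_mean, block_size_max = block_size_max,
    mu = mu, tau = tau, rho = rho, kappa = kappa,
    subtelomere_span = subtelomere_span,
    centromere_frac = centromere_frac,
    cent_array_copies = cent_array_copies,
    seed = seed
  )
  for (nm in c("mu", "tau", "rho", "kappa")) {
    if (p[[nm]] < 0 || p[[nm]] > 1) stop(nm, " must lie in [0, 1]")
  }
  if (!is.null(monomer) && nchar(monomer) < 100) {
    stop("monomer must be at least 100 bases")
  }
  structure(p, class = "sim_params")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitution-only point mutation at per-site rate mu
mutate_seq <- function(seq, mu) {
  n <- nchar(seq)
  k <- rbinom(1, n, mu)
  if (k == 0) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

#' Simulate a genome with planted satellite arrays and ground truth
#'
#' Background sequence is i.i.d. uniform DNA. A tandem centromeric
#' satellite array is planted at the centre of every centromere span. Each
#' chromosome arm receives a Poisson number of tandem blocks inside the
#' subtelomere span; each block is founded from a lineage drawn from the
#' local arm's pool with probability `1 - tau` (else from another
#' chromosome's pool), grows by a birth chain (each new copy mutates from a
#' randomly chosen existing block member at rate `mu`), and with
#' probability `rho` a copy is a two-parent recombinant of two lineage
#' representatives. With probability `kappa` a block is placed inside the
#' centromere span instead. Deterministic for a fixed seed.
#'
#' @param params A [sim_params()] list.
#' @return An object of class `sat_sim`: list with `genome`
#'   ([Biostrings::DNAStringSet]), `truth` (tibble of planted units:
#'   coordinates, strand, lineage, recombinant flag and parents, block id,
#'   region `S`/`C`/`L`, monomer-orientation sequence), `blocks` (per-block
#'   truth), `centromeres` (planted array intervals), `monomer`,
#'   `cent_monomer`, `founders`, and `params`.
#' @export
simulate_genome <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(params$seed)

  monomer <- params$monomer %||% random_dna(528)
  cent_monomer <- params$cent_monomer %||% random_dna(150)
  L <- nchar(monomer)
  founders <- vapply(seq_len(params$n_founders), function(i) {
    mutate_seq(monomer, params$founder_divergence)
  }, character(1))

  chroms <- sprintf("Chr%02d", seq_len(params$n_chrom))
  arms <- tidyr::expand_grid(seq_id = chroms, side = c("S", "L"))
  # each lineage has a home arm; round robin guarantees coverage when
  # n_founders >= number of arms
  arms$home_lineages <- vector("list", nrow(arms))
  for (l in seq_len(params$n_founders)) {
    a <- ((l - 1) %% nrow(arms)) + 1
    arms$home_lineages[[a]] <- c(arms$home_lineages[[a]], l)
  }

  clen <- params$chrom_length
  cent0 <- round(params$centromere_frac[1] * clen)
  cent1 <- round(params$centromere_frac[2] * clen)

  geno <- list()
  truth <- list()
  cent_tbl <- list()
  block_counter <- 0L

  pick_lineage <- function(arm_idx) {
    if (runif(1) >= params$tau) {
      pool <- arms$home_lineages[[arm_idx]]
      if (length(pool) == 0) pool <- seq_len(params$n_founders)
      pool[sample.int(length(pool), 1)]
    } else {
      # transfer: lineage from a different chromosome's pools
      other <- which(arms$seq_id != arms$seq_id[arm_idx])
      pool <- unique(unlist(arms$home_lineages[other]))
      if (length(pool) == 0) pool <- seq_len(params$n_founders)
      pool[sample.int(length(pool), 1)]
    }
  }

  grow_block <- function(size, lineage) {
    seqs <- character(size)
    rec <- logical(size)
    pa <- integer(size); pb <- integer(size)
    seqs[1] <- mutate_seq(founders[lineage], params$mu)
    for (i in seq_len(size)[-1]) {
      if (runif(1) < params$rho && params$n_founders >= 2) {
        pair <- sample.int(params$n_founders, 2)
        b <- sample(seq.int(round(0.2 * L), round(0.8 * L)), 1)
        child <- paste0(substr(founders[pair[1]], 1, b),
                        substr(founders[pair[2]], b + 1, L))
        seqs[i] <- mutate_seq(child, params$mu)
        rec[i] <- TRUE; pa[i] <- pair[1]; pb[i] <- pair[2]
      } else {
        seqs[i] <- mutate_seq(seqs[sample.int(i - 1, 1)], params$mu)
      }
    }
    list(seqs = seqs, rec = rec, pa = pa, pb = pb)
  }

  write_units <- function(bg, sid, starts, pl) {
    for (i in seq_along(starts)) {
      s0 <- starts[i]
      unit_seq <- pl$gb$seqs[i]
      written <- if (pl$strand == "+") unit_seq else reverse_complement(unit_seq)
      bg[(s0 + 1):(s0 + L)] <- strsplit(written, "", fixed = TRUE)[[1]]
      truth[[length(truth) + 1L]] <<- tibble::tibble(
        seq_id = sid, start = s0, end = s0 + L, strand = pl$strand,
        lineage = pl$lineage, recombinant = pl$gb$rec[i],
        parent_a = ifelse(pl$gb$rec[i], pl$gb$pa[i], NA_integer_),
        parent_b = ifelse(pl$gb$rec[i], pl$gb$pb[i], NA_integer_),
        block_id = pl$bid, region = pl$region, sequence = unit_seq
      )
    }
    bg
  }

  for (ci in seq_along(chroms)) {
    sid <- chroms[ci]
    bg <- sample(c("A", "C", "G", "T"), clen, replace = TRUE)
    cw <- nchar(cent_monomer)

    # sample the arm blocks; with probability kappa a block is diverted to
    # the centromere and laid out there, embedded in the satellite array
    cent_blocks <- list()
    arm_placed <- list()
    for (side in c("S", "L")) {
      arm_idx <- which(arms$seq_id == sid & arms$side == side)
      n_blocks <- rpois(1, params$blocks_per_arm_mean)
      if (n_blocks == 0) next
      cursor <- 1000
      for (bi in seq_len(n_blocks)) {
        size <- min(params$block_size_max,
                    1L + rgeom(1, 1 / params$block_size_mean))
        lineage <- pick_lineage(arm_idx)
        gb <- grow_block(size, lineage)
        strand <- sample(c("+", "-"), 1)
        block_counter <- block_counter + 1L
        bid <- sprintf("tb%04d", block_counter)
        pl <- list(bid = bid, size = size, lineage = lineage,
                   strand = strand, gb = gb)
        if (runif(1) < params$kappa) {
          pl$region <- "C"
          cent_blocks[[length(cent_blocks) + 1L]] <- pl
        } else {
          pl$region <- side
          pl$start <- cursor
          cursor <- cursor + size * L + sample(2000:20000, 1)
          if (cursor > params$subtelomere_span) {
            stop("blocks overflow the subtelomere span; reduce counts")
          }
          arm_placed[[length(arm_placed) + 1L]] <- pl
        }
      }
    }

    for (pl in arm_placed) {
      starts <- pl$start + (seq_len(pl$size) - 1L) * L # 0-based
      if (pl$region == "L") {
        starts <- rev(clen - (pl$start + seq_len(pl$size) * L)) # mirror to 3'
      }
      bg <- write_units(bg, sid, starts, pl)
    }

    # centromeric satellite array at the centre of the centromere span,
    # with any centromeric blocks embedded between array segments (so the
    # merged satellite cluster spans them, as at a real centromere)
    n_cb <- length(cent_blocks)
    seg <- rep(params$cent_array_copies %/% (n_cb + 1), n_cb + 1)
    seg[1] <- seg[1] + params$cent_array_copies %% (n_cb + 1)
    total_len <- params$cent_array_copies * cw +
      sum(vapply(cent_blocks, function(p) as.numeric(p$size), numeric(1))) * L
    astart <- round((cent0 + cent1) / 2 - total_len / 2) # 0-based
    if (astart < cent0 || astart + total_len > cent1) {
      stop("blocks overflow the centromere span")
    }
    pos <- astart
    for (gi in seq_len(n_cb + 1)) {
      for (cp in seq_len(seg[gi])) {
        copy <- mutate_seq(cent_monomer, 0.02)
        bg[(pos + 1):(pos + cw)] <- strsplit(copy, "", fixed = TRUE)[[1]]
        pos <- pos + cw
      }
      if (gi <= n_cb) {
        pl <- cent_blocks[[gi]]
        starts <- pos + (seq_len(pl$size) - 1L) * L
        bg <- write_units(bg, sid, starts, pl)
        pos <- pos + pl$size * L
      }
    }
    cent_tbl[[ci]] <- tibble::tibble(
      seq_id = sid, start = astart, end = astart + total_len
    )
    geno[[ci]] <- paste(bg, collapse = "")
  }

  genome <- Biostrings::DNAStringSet(setNames(unlist(geno), chroms))
  truth <- dplyr::bind_rows(truth) |>
    dplyr::arrange(.data$seq_id, .data$start)
  blocks <- truth |>
    dplyr::group_by(.data$block_id, .data$seq_id, .data$region,
                    lineage = .data$lineage) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     size = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$seq_id, .data$start)
  structure(
    list(
      genome = genome, truth = truth, blocks = blocks,
      centromeres = dplyr::bind_rows(cent_tbl),
      monomer = monomer, cent_monomer = cent_monomer,
      founders = founders, params = params
    ),
    class = "sat_sim"
  )
}

#' @export
print.sat_sim <- function(x, ...) {
  cat("<sat_sim> ", length(x$genome), " chromosome(s) x ",
      x$params$chrom_length, " bp, ", nrow(x$truth), " planted unit(s) in ",
      nrow(x$blocks), " block(s)\n", sep = "")
  invisible(x)
}

#' Simulate a flat monomer family (no genome)
#'
#' A lightweight generator for the recombination-screen and phylogeny
#' tests: `n_units` monomers from `n_lineages` independent lineages grown
#' as per-lineage birth chains, with `n_recombinants` planted mosaics whose
#' parents are representatives of two distinct lineages and whose
#' breakpoint is uniform in the middle 60 % of the monomer.
#'
#' @param n_units Number of monomers.
#' @param n_lineages Number of lineages.
#' @param mu Substitutions/site per copy event.
#' @param lineage_divergence Per-lineage substitution rate from the
#'   ancestral monomer (pairwise divergence about twice this).
#' @param n_recombinants Planted mosaic count.
#' @param recombinant_breakpoint Breakpoint column for planted mosaics;
#'   `NULL` draws uniformly from the middle 60 % of the monomer.
#' @param monomer_length Monomer length in bases.
#' @param seed Seed.
#' @return A list with `seqs` (named character vector), `labels` (tibble
#'   `unit`, `lineage`, `recombinant`, `parent_a`, `parent_b`), `founders`
#'   and `monomer`.
#' @export
simulate_unit_family <- function(n_units = 50, n_lineages = 4, mu = 0.02,
                                 lineage_divergence = 0.08,
                                 n_recombinants = 0,
                                 recombinant_breakpoint = NULL,
                                 monomer_length = 528,
                                 seed = 1) {
  stopifnot(n_recombinants <= n_units, n_lineages >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  monomer <- random_dna(monomer_length)
  founders <- vapply(seq_len(n_lineages), function(i) {
    mutate_seq(monomer, lineage_divergence)
  }, character(1))
  lineage <- rep(seq_len(n_lineages), length.out = n_units)
  seqs <- character(n_units)
  rec <- logical(n_units)
  pa <- rep(NA_integer_, n_units); pb <- rep(NA_integer_, n_units)
  chains <- lapply(seq_len(n_lineages), function(l) character(0))
  for (i in seq_len(n_units)) {
    l <- lineage[i]
    template <- if (length(chains[[l]]) == 0) founders[l] else {
      chains[[l]][sample.int(length(chains[[l]]), 1)]
    }
    seqs[i] <- mutate_seq(template, mu)
    chains[[l]] <- c(chains[[l]], seqs[i])
  }
  if (n_recombinants > 0) {
    if (n_lineages < 2) stop("recombinants need at least 2 lineages")
    idx <- sample.int(n_units, n_recombinants)
    for (i in idx) {
      pair <- sample.int(n_lineages, 2)
      b <- recombinant_breakpoint %||%
        sample(seq.int(round(0.2 * monomer_length), round(0.8 * monomer_length)), 1)
      seqs[i] <- mutate_seq(paste0(
        substr(founders[pair[1]], 1, b),
        substr(founders[pair[2]], b + 1, monomer_length)
      ), mu)
      rec[i] <- TRUE; pa[i] <- pair[1]; pb[i] <- pair[2]
    }
  }
  names(seqs) <- sprintf("u%03d", seq_len(n_units))
  list(
    seqs = seqs,
    labels = tibble::tibble(
      unit = names(seqs), lineage = lineage, recombinant = rec,
      parent_a = pa, parent_b = pb
    ),
    founders = founders,
    monomer = monomer
  )
}

#' Compare called units against the simulator's ground truth
#'
#' A call matches a truth unit when their intervals overlap at least 50 %
#' reciprocally (greedy one-to-one matching by decreasing overlap).
#'
#' @param truth Truth tibble from [simulate_genome()] (or any tibble with
#'   `seq_id`, `start`, `end`).
#' @param calls Called units (same columns).
#' @param slack Boundary tolerance in bases used for the
#'   `n_within_slack` tally.
#' @return One-row tibble: `n_truth`, `n_calls`, `n_matched`, `recall`,
#'   `precision`, `boundary_mae`, `n_within_slack`.
#' @export
truth_compare <- function(truth, calls, slack = 5) {
  truth <- tibble::as_tibble(truth)
  calls <- tibble::as_tibble(calls)
  if (nrow(truth) == 0 || nrow(calls) == 0) {
    return(tibble::tibble(
      n_truth = nrow(truth), n_calls = nrow(calls), n_matched = 0L,
      recall = ifelse(nrow(truth) == 0, NA_real_, 0),
      precision = ifelse(nrow(calls) == 0, NA_real_, 0),
      boundary_mae = NA_real_, n_within_slack = 0L
    ))
  }
  tr <- GenomicRanges::GRanges(truth$seq_id,
                               IRanges::IRanges(truth$start + 1, truth$end))
  cl <- GenomicRanges::GRanges(calls$seq_id,
                               IRanges::IRanges(calls$start + 1, calls$end))
  ov <- GenomicRanges::findOverlaps(tr, cl)
  if (length(ov) == 0) {
    return(tibble::tibble(
      n_truth = nrow(truth), n_calls = nrow(calls), n_matched = 0L,
      recall = 0, precision = 0, boundary_mae = NA_real_, n_within_slack = 0L
    ))
  }
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(tr[qi], cl[si]))
  wt <- truth$end[qi] - truth$start[qi]
  wc <- calls$end[si] - calls$start[si]
  ok <- w > 0.5 * wt & w > 0.5 * wc
  qi <- qi[ok]; si <- si[ok]; w <- w[ok]
  ord <- order(-w)
  seen_t <- logical(nrow(truth)); seen_c <- logical(nrow(calls))
  mt <- integer(0); mc <- integer(0)
  for (k in ord) {
    if (!seen_t[qi[k]] && !seen_c[si[k]]) {
      seen_t[qi[k]] <- TRUE; seen_c[si[k]] <- TRUE
      mt <- c(mt, qi[k]); mc <- c(mc, si[k])
    }
  }
  be <- (abs(truth$start[mt] - calls$start[mc]) +
           abs(truth$end[mt] - calls$end[mc])) / 2
  tibble::tibble(
    n_truth = nrow(truth), n_calls = nrow(calls), n_matched = length(mt),
    recall = length(mt) / nrow(truth),
    precision = length(mt) / nrow(calls),
    boundary_mae = mean(be),
    n_within_slack = sum(be <= slack)
  )
}
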