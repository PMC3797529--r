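#' Run the full satellite-annotation and evolution pipeline
#'
#' Stages, in order: profile construction, both-strand genome scan, raw
#' block calling, terminal/length/ambiguity filtering, centromere
#' localisation and arm assignment, naming, final block calling,
#' count-matrix, recombination screening, implied MSA, bootstrap NJ tree,
#' major-clade extraction, clade-location concordance, and (when a contig
#' is given) contig-versus-assembly QC. All randomness (screen subsampling,
#' bootstrap) flows from one root seed, so a run is reproducible; when
#' `out_dir` is given every output file is written and listed in a manifest
#' with md5 checksums.
#'
#' @param genome A [Biostrings::DNAStringSet] or path to a FASTA file.
#' @param seed_alignment A seed monomer alignment (matrix, path to aligned
#'   FASTA) or a ready-made `sat_profile`.
#' @param cent_repeats Centromeric satellite monomers
#'   ([Biostrings::DNAStringSet], named character vector or FASTA path);
#'   `NULL` activates the midpoint arm rule with a warning.
#' @param contig Optional independently sequenced contig for QC.
#' @param prefix Genotype prefix for unit names.
#' @param min_score_frac,max_gap,min_len Scanner and filter parameters
#'   (see [scan_genome()], [call_raw_blocks()], [filter_units()]).
#' @param cent_min_identity,cent_merge_gap Centromere localisation
#'   parameters (see [locate_centromeres()]).
#' @param alpha,triplet_cap Recombination-screen parameters.
#' @param n_reps,min_support,min_size_frac Phylogeny parameters.
#' @param seed Root seed.
#' @param out_dir Optional output directory.
#' @return An object of class `sat_run`: list with `profile`, `hits`,
#'   `filter_report`, `units` (named, arm-assigned), `centromeres`,
#'   `blocks`, `count_matrix`, `screen`, `msa`, `tree`, `clades`,
#'   `cross_tab`, `spread`, `exchange`, `qc` (or `NULL`), and `manifest`
#'   (or `NULL`).
#' @export
run_pipeline <- function(genome, seed_alignment, cent_repeats = NULL,
                         contig = NULL, prefix = "Pv",
                         min_score_frac = 0.4, max_gap = 600, min_len = 500,
                         cent_min_identity = 0.8, cent_merge_gap = 1e5,
                         alpha = 0.001, triplet_cap = 200000,
                         n_reps = 100, min_support = 0.75,
                         min_size_frac = 0.02,
                         seed = 1, out_dir = NULL) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    genome <- read_genome_fasta(genome)
  }
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)

  profile <- if (inherits(seed_alignment, "sat_profile")) {
    seed_alignment
  } else if (is.character(seed_alignment) && length(seed_alignment) == 1 &&
             file.exists(seed_alignment)) {
    build_profile(read_seed_alignment(seed_alignment))
  } else {
    build_profile(seed_alignment)
  }

  message("scan: profile of ", profile$L, " positions, min score ",
          round(min_score_frac * profile$self_score, 1), " bits")
  hits <- scan_genome(genome, profile, min_score_frac = min_score_frac)
  for (sid in names(genome)) {
    message("scan: ", sid, " raw hits ", sum(hits$seq_id == sid))
  }
  raw_blocks <- call_raw_blocks(hits, max_gap = max_gap)
  filtered <- filter_units(raw_blocks, min_len = min_len)
  message("filter: raw ", filtered$report$n_raw,
          ", terminal -", filtered$report$n_terminal_removed,
          ", short -", filtered$report$n_short_removed,
          ", ambiguous -", filtered$report$n_ambiguous_removed,
          " -> retained ", filtered$report$n_retained)

  if (!is.null(cent_repeats)) {
    if (is.character(cent_repeats) && length(cent_repeats) == 1 &&
        file.exists(cent_repeats)) {
      cent_repeats <- read_genome_fasta(cent_repeats)
    }
    centromeres <- locate_centromeres(genome, cent_repeats,
                                      min_identity = cent_min_identity,
                                      merge_gap = cent_merge_gap)
  } else {
    warning("no centromeric repeats given; falling back to the midpoint arm rule")
    centromeres <- NULL
  }
  chrom_lengths <- stats::setNames(Biostrings::width(genome), names(genome))
  units <- assign_arms(filtered$units, centromeres, chrom_lengths)
  units <- assign_names(units, prefix = prefix)

  blk <- call_blocks(units, max_gap = max_gap)
  units <- blk$units
  cmat <- count_matrix(units, chromosomes = names(genome))
  message("blocks: ", nrow(blk$blocks), " (largest ",
          if (nrow(blk$blocks)) max(blk$blocks$n_units) else 0, " units)")

  msa <- implied_msa(profile, units)
  screen <- screen_all(msa, alpha = alpha, n_triplets_cap = triplet_cap,
                       seed = seed + 1L)
  message("recombination screen: ", length(screen$removed), " unit(s) removed")
  analysed <- msa[setdiff(rownames(msa), screen$removed), , drop = FALSE]
  tree <- bootstrap_support(analysed, n_reps = n_reps, seed = seed + 2L)
  clades <- extract_major_clades(
    tree, min_support = min_support,
    min_size = max(2L, ceiling(min_size_frac * nrow(analysed)))
  )
  message("clades: ", nrow(clades$clades), " major clade(s), ",
          length(clades$unplaced), " unplaced unit(s)")
  tab <- cross_tab(clades, units)
  spread <- spread_metrics(tab)
  exchange <- centromere_exchange(tab)

  qc <- NULL
  if (!is.null(contig)) {
    if (is.character(contig) && length(contig) == 1 && file.exists(contig)) {
      contig <- read_genome_fasta(contig)
    }
    contig_seq <- if (inherits(contig, "DNAStringSet")) contig else
      Biostrings::DNAStringSet(contig)
    chits <- scan_genome(contig_seq, profile, min_score_frac = min_score_frac)
    cblocks <- call_raw_blocks(chits, max_gap = max_gap)
    qc <- assembly_qc(contig_seq, cblocks, genome, units)
  }

  run <- structure(
    list(
      profile = profile, hits = hits, filter_report = filtered$report,
      units = units, centromeres = centromeres, blocks = blk$blocks,
      count_matrix = cmat, screen = screen, msa = msa, tree = tree,
      clades = clades, cross_tab = tab, spread = spread,
      exchange = exchange, qc = qc, manifest = NULL
    ),
    class = "sat_run"
  )
  if (!is.null(out_dir)) run$manifest <- write_run(run, out_dir)
  run
}

#' @export
print.sat_run <- function(x, ...) {
  cat("<sat_run> ", x$filter_report$n_retained, " retained unit(s) in ",
      nrow(x$blocks), " block(s); ", nrow(x$clades$clades),
      " major clade(s)\n", sep = "")
  invisible(x)
}

# write every stage output and return the manifest tibble
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  p <- function(f) file.path(out_dir, f)
  write_profile_tsv(run$profile, p("profile.tsv")); paths <- c(paths, p("profile.tsv"))
  write_gff3(dplyr::select(run$units, "seq_id", "start", "end", "strand",
                           "score", "name"), p("units.gff3"))
  paths <- c(paths, p("units.gff3"))
  write_tsv_table(run$filter_report, p("filter_report.tsv"))
  paths <- c(paths, p("filter_report.tsv"))
  if (!is.null(run$centromeres) && nrow(run$centromeres) > 0) {
    cent <- dplyr::mutate(run$centromeres, strand = "*",
                          feature_type = "centromere",
                          name = paste0(.data$family, "_", .data$seq_id))
    write_gff3(cent, p("centromeres.gff3"))
    paths <- c(paths, p("centromeres.gff3"))
  }
  write_tsv_table(dplyr::select(run$blocks, -"units"), p("blocks.tsv"))
  paths <- c(paths, p("blocks.tsv"))
  write_tsv_table(run$count_matrix, p("count_matrix.tsv"))
  paths <- c(paths, p("count_matrix.tsv"))
  write_tsv_table(run$screen$calls, p("recombination_calls.tsv"))
  paths <- c(paths, p("recombination_calls.tsv"))
  writeLines(run$screen$removed, p("removed_units.txt"))
  paths <- c(paths, p("removed_units.txt"))
  msa_seqs <- apply(run$msa, 1, paste, collapse = "")
  write_fasta(stats::setNames(msa_seqs, rownames(run$msa)), p("implied_msa.fasta"))
  paths <- c(paths, p("implied_msa.fasta"))
  write_newick(run$tree, p("tree.nwk")); paths <- c(paths, p("tree.nwk"))
  write_tsv_table(run$clades$members, p("clade_members.tsv"))
  paths <- c(paths, p("clade_members.tsv"))
  write_tsv_table(run$cross_tab, p("clade_location_table.tsv"))
  paths <- c(paths, p("clade_location_table.tsv"))
  write_tsv_table(run$spread$clades, p("spread_metrics.tsv"))
  paths <- c(paths, p("spread_metrics.tsv"))
  write_tsv_table(run$exchange$exchange, p("centromere_exchange.tsv"))
  paths <- c(paths, p("centromere_exchange.tsv"))
  if (!is.null(run$qc)) {
    write_tsv_table(run$qc$pairing, p("qc_pairing.tsv"))
    write_tsv_table(run$qc$report, p("qc_report.tsv"))
    write_tsv_table(run$qc$cross_location, p("qc_cross_location.tsv"))
    paths <- c(paths, p("qc_pairing.tsv"), p("qc_report.tsv"),
               p("qc_cross_location.tsv"))
  }
  tibble::tibble(
    file = basename(paths),
    md5 = unname(tools::md5sum(paths))
  )
}

#' Summary tables of a pipeline run
#'
#' @param run A `sat_run` object.
#' @return A list of tibbles: the count matrix, the block-size histogram,
#'   clade composition, spread metrics and the centromere-exchange report.
#' @export
run_report <- function(run) {
  stopifnot(inherits(run, "sat_run"))
  list(
    count_matrix = run$count_matrix,
    block_sizes = block_size_histogram(run$blocks),
    clade_composition = tidyr::pivot_wider(run$cross_tab,
                                           names_from = "location",
                                           values_from = "n", values_fill = 0L),
    spread = run$spread$summary,
    exchange = run$exchange$exchange
  )
}
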