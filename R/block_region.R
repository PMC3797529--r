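#' Call final tandem blocks on the retained unit set
#'
#' Applies the same grouping rule as [call_raw_blocks()] to the retained
#' units and summarises each block: size, span and member units. Block
#' spans never overlap and block sizes sum to the number of retained units.
#'
#' @param units Retained unit tibble sorted by `(seq_id, start)`.
#' @param max_gap Maximum inter-unit gap in bases.
#' @return A list with `units` (input plus a recomputed `block_id`) and
#'   `blocks`: one row per block with `block_id`, `seq_id`, `start`, `end`
#'   (span, 0-based half-open), `n_units`, and a `units` list-column of
#'   member unit keys.
#' @export
call_blocks <- function(units, max_gap = 600) {
  units <- call_raw_blocks(dplyr::select(tibble::as_tibble(units), -dplyr::any_of("block_id")),
                           max_gap = max_gap)
  blocks <- units |>
    dplyr::group_by(.data$block_id, .data$seq_id) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_units = dplyr::n(),
      units = list(.data$unit_key),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$seq_id, .data$start)
  list(units = units, blocks = blocks)
}

#' Per-chromosome block-size histogram
#'
#' @param blocks Block tibble from [call_blocks()].
#' @return Tibble of `seq_id`, `n_units`, `n_blocks`.
#' @export
block_size_histogram <- function(blocks) {
  dplyr::count(blocks, .data$seq_id, .data$n_units, name = "n_blocks")
}

#' Locate centromeres from centromeric satellite repeats
#'
#' Each centromeric repeat family is turned into a single-sequence profile
#' ([profile_from_sequence()]) and both strands of every chromosome are
#' scanned for local hits whose score corresponds to at least
#' `min_identity`; hit clusters closer than `merge_gap` are merged and, per
#' chromosome, the largest merged cluster by summed hit length wins and is
#' reported with the winning repeat family. Chromosomes without hits are
#' absent from the result (their units later fall back to the midpoint arm
#' rule, with a warning).
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param cent_repeats A [Biostrings::DNAStringSet] (or named character
#'   vector) of centromeric satellite monomers, e.g. CentPv1 and CentPv2.
#' @param min_identity Minimum per-hit identity (fraction).
#' @param merge_gap Clusters closer than this many bases are merged.
#' @return Tibble with one row per chromosome with a detectable centromere:
#'   `seq_id`, `start`, `end` (0-based half-open), `n_hits`, `family`.
#' @export
locate_centromeres <- function(genome, cent_repeats, min_identity = 0.8,
                               merge_gap = 1e5) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.character(cent_repeats)) cent_repeats <- Biostrings::DNAStringSet(cent_repeats)
  if (length(cent_repeats) == 0L) stop("cent_repeats must be non-empty")
  fams <- names(cent_repeats)
  if (is.null(fams)) fams <- paste0("cent", seq_along(cent_repeats))
  out <- list()
  for (f in seq_along(cent_repeats)) {
    prof <- profile_from_sequence(as.character(cent_repeats[[f]]))
    # map the identity threshold onto the profile's score scale: a hit of
    # identity q scores about q * match + (1 - q) * mismatch per position
    emis <- prof$emissions[, c("A", "C", "G", "T"), drop = FALSE]
    mbar <- mean(apply(emis, 1, max))
    xbar <- mean(apply(emis, 1, function(e) mean(e[-which.max(e)])))
    thr <- prof$L * (min_identity * mbar + (1 - min_identity) * xbar)
    hits <- scan_genome(genome, prof, min_score = max(thr, 1e-6),
                        k = 12, min_seeds = 3)
    if (nrow(hits) > 0L) {
      hits$family <- fams[f]
      out[[length(out) + 1L]] <- hits
    }
  }
  hits <- dplyr::bind_rows(out)
  if (length(hits) == 0L || nrow(hits) == 0L) {
    return(tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), n_hits = integer(),
                          family = character()))
  }
  clusters <- hits |>
    dplyr::arrange(.data$seq_id, .data$family, .data$start) |>
    dplyr::group_by(.data$seq_id, .data$family) |>
    dplyr::mutate(
      .new = dplyr::row_number() == 1L |
        .data$start - dplyr::lag(.data$end, default = NA_integer_) > merge_gap,
      .cl = cumsum(.data$.new)
    ) |>
    dplyr::group_by(.data$seq_id, .data$family, .data$.cl) |>
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      n_hits = dplyr::n(),
      total_len = sum(.data$end - .data$start),
      .groups = "drop"
    )
  clusters |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::slice_max(.data$total_len, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select("seq_id", "start", "end", "n_hits", "family") |>
    dplyr::arrange(.data$seq_id)
}

#' Assign short-arm / centromere / long-arm codes to units
#'
#' A unit wholly before the centromere start is `S`, wholly after the
#' centromere end is `L`, and anything overlapping or inside the centromere
#' interval is `C`. The 5' side of each pseudomolecule is taken to be the
#' short arm. On a chromosome without a located centromere, units are split
#' `S`/`L` at the chromosome midpoint (by unit midpoint) with a warning.
#'
#' @param units Unit tibble (needs `seq_id`, `start`, `end`).
#' @param centromeres Tibble from [locate_centromeres()] (may be empty).
#' @param chrom_lengths Named vector of chromosome lengths, required for the
#'   midpoint fallback.
#' @return The input tibble with an `arm` column (`"S"`, `"C"` or `"L"`).
#' @export
assign_arms <- function(units, centromeres = NULL, chrom_lengths = NULL) {
  units <- tibble::as_tibble(units)
  if (nrow(units) == 0L) {
    units$arm <- character(0)
    return(units)
  }
  cent <- centromeres
  arm <- character(nrow(units))
  for (sid in unique(units$seq_id)) {
    sel <- units$seq_id == sid
    row <- NULL
    if (!is.null(cent) && nrow(cent) > 0) {
      r <- cent[cent$seq_id == sid, ]
      if (nrow(r) >= 1L) row <- r[1, ]
    }
    if (!is.null(row)) {
      arm[sel] <- dplyr::case_when(
        units$end[sel] <= row$start ~ "S",
        units$start[sel] >= row$end ~ "L",
        TRUE ~ "C"
      )
    } else {
      if (is.null(chrom_lengths) || is.na(chrom_lengths[sid])) {
        stop("no centromere for ", sid, " and no chromosome length for the midpoint rule")
      }
      warning("no centromere located on ", sid,
              "; splitting S/L at the chromosome midpoint")
      mid <- chrom_lengths[[sid]] / 2
      arm[sel] <- ifelse((units$start[sel] + units$end[sel]) / 2 < mid, "S", "L")
    }
  }
  units$arm <- arm
  units
}

#' Per-chromosome count matrix of retained units
#'
#' One row per chromosome with short-arm, centromere and long-arm counts
#' plus row totals, and a final `Total` row (the layout of a per-
#' pseudomolecule satellite census table).
#'
#' @param units Unit tibble with `seq_id` and `arm` columns.
#' @param chromosomes Optional character vector of chromosome ids to report
#'   (zero rows included); defaults to the chromosomes present.
#' @return Tibble with columns `seq_id`, `short_arm`, `centromere`,
#'   `long_arm`, `total`.
#' @export
count_matrix <- function(units, chromosomes = NULL) {
  units <- tibble::as_tibble(units)
  if (nrow(units) > 0 && (!"arm" %in% names(units) || anyNA(units$arm))) {
    stop("all units must carry an arm assignment")
  }
  if (is.null(chromosomes)) chromosomes <- sort(unique(units$seq_id))
  base <- tidyr::expand_grid(seq_id = chromosomes, arm = c("S", "C", "L"))
  counts <- units |>
    dplyr::count(.data$seq_id, .data$arm) |>
    dplyr::right_join(base, by = c("seq_id", "arm")) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L)) |>
    tidyr::pivot_wider(names_from = "arm", values_from = "n") |>
    dplyr::transmute(
      seq_id = .data$seq_id,
      short_arm = .data$S, centromere = .data$C, long_arm = .data$L,
      total = .data$S + .data$C + .data$L
    ) |>
    dplyr::arrange(.data$seq_id)
  dplyr::bind_rows(
    counts,
    tibble::tibble(
      seq_id = "Total",
      short_arm = sum(counts$short_arm),
      centromere = sum(counts$centromere),
      long_arm = sum(counts$long_arm),
      total = sum(counts$total)
    )
  )
}
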