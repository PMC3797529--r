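#' Scan a genome for satellite monomer units
#'
#' Both strands of every chromosome are scanned. Candidate windows are
#' seeded by exact k-mer matches against the profile consensus (each match
#' implies a monomer start; implied starts are clustered and clusters with
#' at least `min_seeds` seeds become candidate windows), then each window is
#' scored with [score_glocal()]. Hits below `min_score` are dropped;
#' overlapping hits (> 50 % reciprocal overlap) are resolved greedily by
#' descending score, ties by leftmost start then `+` strand.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param profile A `sat_profile`.
#' @param min_score Minimum hit score in bits; default
#'   `min_score_frac * profile$self_score`.
#' @param min_score_frac Fraction of the consensus self-score used when
#'   `min_score` is not given. The default 0.4 admits units at the
#'   divergence levels seen between satellite clades (>= 72 % identity)
#'   while excluding random background.
#' @param k Seed k-mer length.
#' @param min_seeds Minimum seed matches per candidate window.
#' @param window_margin Bases added on both sides of a candidate window.
#' @return A tibble of hits sorted by `(seq_id, start)` with columns
#'   `unit_key`, `seq_id`, `start`, `end` (0-based half-open), `strand`,
#'   `score`, `sequence` (reverse-complemented for `-` hits so it reads in
#'   monomer orientation) and `aligned` (the profile-anchored row used by
#'   [implied_msa()]).
#' @export
scan_genome <- function(genome, profile, min_score = NULL, min_score_frac = 0.4,
                        k = 12, min_seeds = 3, window_margin = 60) {
  stopifnot(inherits(profile, "sat_profile"))
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (is.null(min_score)) min_score <- min_score_frac * profile$self_score
  if (min_score <= 0) stop("min_score must be > 0")
  empty <- tibble::tibble(
    unit_key = character(), seq_id = character(), start = integer(),
    end = integer(), strand = character(), score = numeric(),
    sequence = character(), aligned = character()
  )
  if (length(genome) == 0L) return(empty)

  L <- profile$L
  cons <- profile$consensus
  n_kmer <- L - k + 1L
  if (n_kmer < 1L) stop("profile shorter than seed k-mer length")
  kmers <- substring(cons, seq_len(n_kmer), seq_len(n_kmer) + k - 1L)
  offsets0 <- seq_len(n_kmer) - 1L
  pdict <- Biostrings::PDict(Biostrings::DNAStringSet(kmers))

  scan_one <- function(seq_chr, seq_id, len, strand) {
    subj <- Biostrings::DNAString(seq_chr)
    mi <- Biostrings::matchPDict(pdict, subj)
    starts <- Biostrings::startIndex(mi)
    implied <- integer(0)
    for (i in seq_along(starts)) {
      if (!is.null(starts[[i]]) && length(starts[[i]]) > 0) {
        implied <- c(implied, starts[[i]] - offsets0[i])
      }
    }
    if (length(implied) == 0L) return(NULL)
    implied <- sort(implied)
    grp <- cumsum(c(1L, as.integer(diff(implied) > 50L)))
    out <- list()
    for (g in split(implied, grp)) {
      if (length(g) < min_seeds) next
      center <- round(stats::median(g)) # 1-based implied monomer start
      w0 <- max(0L, center - 1L - as.integer(window_margin))
      w1 <- min(len, center - 1L + L + as.integer(window_margin))
      if (w1 - w0 < 1L) next
      win <- substr(seq_chr, w0 + 1L, w1)
      sc <- score_glocal(profile, win)
      if (sc$score < min_score) next
      hs <- w0 + sc$seq_start
      he <- w0 + sc$seq_end
      if (he - hs < 1L) next
      if (strand == "+") {
        fs <- hs; fe <- he
      } else {
        fs <- len - he; fe <- len - hs
      }
      out[[length(out) + 1L]] <- tibble::tibble(
        seq_id = seq_id, start = as.integer(fs), end = as.integer(fe),
        strand = strand, score = sc$score,
        sequence = substr(win, sc$seq_start + 1L, sc$seq_end),
        aligned = sc$aligned
      )
    }
    if (length(out) == 0L) NULL else dplyr::bind_rows(out)
  }

  hits <- list()
  for (i in seq_along(genome)) {
    seq_id <- names(genome)[i]
    fwd <- as.character(genome[[i]])
    len <- nchar(fwd)
    hits[[length(hits) + 1L]] <- scan_one(fwd, seq_id, len, "+")
    hits[[length(hits) + 1L]] <- scan_one(
      as.character(Biostrings::reverseComplement(genome[[i]])), seq_id, len, "-")
  }
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0L) return(empty)
  hits <- resolve_overlaps(hits)
  hits <- dplyr::arrange(hits, .data$seq_id, .data$start)
  hits$unit_key <- sprintf("%s_%d_%d_%s", hits$seq_id, hits$start, hits$end,
                           ifelse(hits$strand == "+", "p", "m"))
  dplyr::select(hits, "unit_key", dplyr::everything())
}

# greedy resolution of >50% reciprocally overlapping hits:
# descending score, ties leftmost start then '+' strand
resolve_overlaps <- function(hits) {
  ord <- order(-hits$score, hits$seq_id, hits$start,
               match(hits$strand, c("+", "-")))
  hits <- hits[ord, ]
  kept <- logical(nrow(hits))
  kept_by_seq <- split(integer(0), character(0))
  for (i in seq_len(nrow(hits))) {
    sid <- hits$seq_id[i]
    idx <- kept_by_seq[[sid]]
    s <- hits$start[i]; e <- hits$end[i]; w <- e - s
    clash <- FALSE
    for (j in idx) {
      ov <- min(e, hits$end[j]) - max(s, hits$start[j])
      if (ov > 0.5 * w && ov > 0.5 * (hits$end[j] - hits$start[j])) {
        clash <- TRUE
        break
      }
    }
    if (!clash) {
      kept[i] <- TRUE
      kept_by_seq[[sid]] <- c(idx, i)
    }
  }
  hits[kept, ]
}

#' Group hits into raw tandem blocks
#'
#' Consecutive hits on the same chromosome whose gap (`next start - previous
#' end`) is at most `max_gap` share a block. The grouping is an exhaustive,
#' disjoint partition of the input.
#'
#' @param hits Tibble of hits sorted by `(seq_id, start)`.
#' @param max_gap Maximum inter-hit gap in bases (default 600, about one
#'   monomer length plus slack).
#' @return The input with a `block_id` column added.
#' @export
call_raw_blocks <- function(hits, max_gap = 600) {
  hits <- tibble::as_tibble(hits)
  if (nrow(hits) == 0L) {
    hits$block_id <- character(0)
    return(hits)
  }
  if (!identical(order(hits$seq_id, hits$start), seq_len(nrow(hits)))) {
    stop("hits must be sorted by (seq_id, start)")
  }
  hits |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::mutate(
      .gap = .data$start - dplyr::lag(.data$end, default = NA_integer_),
      .new = is.na(.data$.gap) | .data$.gap > max_gap,
      block_id = sprintf("%s_b%03d", .data$seq_id, cumsum(.data$.new))
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-".gap", -".new")
}

#' Filter scanned units to the clean analysis set
#'
#' Three rules, applied in this order and tallied separately:
#' (1) the first and last element of every tandem block are removed (a
#' one-unit block loses its only unit, a two-unit block loses both);
#' (2) of the remainder, units whose genomic length is `<= min_len` are
#' removed (retention is strictly greater-than);
#' (3) units containing any `N` are removed.
#'
#' @param blocks Tibble of hits with a `block_id` column, from
#'   [call_raw_blocks()].
#' @param min_len Minimum retained unit length in bases (strict).
#' @return A list with `units` (the retained tibble) and `report`, a
#'   one-row tibble tallying `n_raw`, `n_terminal_removed`,
#'   `n_short_removed`, `n_ambiguous_removed`, `n_retained`.
#' @export
filter_units <- function(blocks, min_len = 500) {
  blocks <- tibble::as_tibble(blocks)
  n_raw <- nrow(blocks)
  if (n_raw == 0L) {
    return(list(units = blocks, report = tibble::tibble(
      n_raw = 0L, n_terminal_removed = 0L, n_short_removed = 0L,
      n_ambiguous_removed = 0L, n_retained = 0L
    )))
  }
  stopifnot("block_id" %in% names(blocks))
  interior <- blocks |>
    dplyr::group_by(.data$block_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::filter(dplyr::row_number() > 1, dplyr::row_number() < dplyr::n()) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$seq_id, .data$start)
  n_terminal <- n_raw - nrow(interior)
  long_enough <- interior[interior$end - interior$start > min_len, ]
  n_short <- nrow(interior) - nrow(long_enough)
  clean <- long_enough[!grepl("N", long_enough$sequence, fixed = TRUE), ]
  n_amb <- nrow(long_enough) - nrow(clean)
  list(
    units = clean,
    report = tibble::tibble(
      n_raw = n_raw,
      n_terminal_removed = n_terminal,
      n_short_removed = n_short,
      n_ambiguous_removed = n_amb,
      n_retained = nrow(clean)
    )
  )
}

#' Assign per-pseudomolecule names to retained units
#'
#' Units on each chromosome are ordered 5' to 3' and numbered 10, 20, 30,
#' ... (increments of 10, restarting on every chromosome); the rendered name
#' is `<prefix><chrom><arm>k<#####>` as in [render_unit_name()].
#'
#' @param units Retained unit tibble carrying an `arm` column from
#'   [assign_arms()]; a missing arm is an error.
#' @param prefix Genotype prefix.
#' @return The input tibble with `name` and `ordinal` columns, sorted by
#'   `(seq_id, start)`.
#' @export
assign_names <- function(units, prefix = "Pv") {
  units <- tibble::as_tibble(units)
  if (nrow(units) == 0L) {
    units$name <- character(0)
    units$ordinal <- integer(0)
    return(units)
  }
  if (!"arm" %in% names(units) || anyNA(units$arm)) {
    stop("every unit needs an arm assignment before naming")
  }
  units |>
    dplyr::arrange(.data$seq_id, .data$start) |>
    dplyr::group_by(.data$seq_id) |>
    dplyr::mutate(
      ordinal = 10L * dplyr::row_number(),
      name = render_unit_name(prefix, chrom_label(.data$seq_id),
                              .data$ordinal, .data$arm)
    ) |>
    dplyr::ungroup()
}

# two-digit chromosome label from a sequence id ("Chr01" -> "01"); ids
# without digits are used verbatim (contig-style labels)
chrom_label <- function(seq_id) {
  digits <- stringr::str_extract(seq_id, "\\d+")
  ifelse(is.na(digits), seq_id, sprintf("%02d", as.integer(digits)))
}
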