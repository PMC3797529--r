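#' Place an independently sequenced contig on the assembly
#'
#' K-mers sampled along the contig that are unique both in the contig and
#' in the whole genome serve as anchors; the longest collinear anchor chain
#' (consistent offsets within a band, same orientation) determines the
#' placement and its orientation. Placement intervals whose length falls
#' outside 50-200 % of the contig length are flagged.
#'
#' @param contig A single named DNA string (character or
#'   [Biostrings::DNAStringSet] of length 1).
#' @param genome A [Biostrings::DNAStringSet].
#' @param k Anchor k-mer length (31 by default: unique 31-mers are
#'   near-certain anchors in genomes of this size).
#' @param stride Sampling stride along the contig.
#' @param band Offset tolerance in bases absorbing small indels.
#' @param min_anchors Fewer chained anchors than this is an error.
#' @return One-row tibble: `contig_id`, `seq_id`, `start`, `end` (0-based
#'   half-open), `orientation`, `n_anchors`, `flagged`.
#' @export
place_contig <- function(contig, genome, k = 31, stride = 7, band = 2000,
                         min_anchors = 5) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (inherits(contig, "DNAStringSet")) {
    contig_id <- names(contig)[1]
    contig <- as.character(contig[[1]])
  } else {
    contig_id <- names(contig) %||% "contig"
    contig <- unname(contig)
  }
  clen <- nchar(contig)
  if (clen < 10 * k) stop("contig too short to place (< 10 k-mers long)")

  anchor_hits <- function(seq_chr) {
    pos <- unique(c(seq.int(1L, clen - k + 1L, by = stride), clen - k + 1L))
    kmer <- substring(seq_chr, pos, pos + k - 1L)
    keep <- !grepl("N", kmer, fixed = TRUE) & !duplicated(kmer) &
      !(kmer %in% kmer[duplicated(kmer)])
    pos <- pos[keep]; kmer <- kmer[keep]
    if (length(kmer) == 0) return(NULL)
    pd <- Biostrings::PDict(Biostrings::DNAStringSet(kmer))
    hits <- vector("list", length(genome))
    counts <- integer(length(kmer))
    for (i in seq_along(genome)) {
      mi <- Biostrings::matchPDict(pd, genome[[i]])
      st <- Biostrings::startIndex(mi)
      lens <- lengths(st)
      counts <- counts + lens
      idx <- which(lens > 0)
      if (length(idx)) {
        hits[[i]] <- tibble::tibble(
          seq_id = names(genome)[i],
          cpos = rep(pos[idx], lens[idx]),
          gpos = unlist(st[idx])
        )
      }
    }
    hits <- dplyr::bind_rows(hits)
    if (nrow(hits) == 0) return(NULL)
    # genome-unique anchors only
    uniq <- pos[counts == 1L]
    hits[hits$cpos %in% uniq, ]
  }

  best_chain <- function(hits) {
    if (is.null(hits) || nrow(hits) == 0) return(NULL)
    best <- NULL
    for (sid in unique(hits$seq_id)) {
      h <- hits[hits$seq_id == sid, ]
      off <- sort(h$gpos - h$cpos)
      # largest set of offsets within a window of width `band`
      j <- 1L; top_n <- 0L; top_lo <- off[1]
      for (i in seq_along(off)) {
        while (off[i] - off[j] > band) j <- j + 1L
        if (i - j + 1L > top_n) { top_n <- i - j + 1L; top_lo <- off[j] }
      }
      ch <- h[(h$gpos - h$cpos) >= top_lo & (h$gpos - h$cpos) <= top_lo + band, ]
      if (is.null(best) || nrow(ch) > best$n) {
        best <- list(seq_id = sid, chain = ch, n = nrow(ch))
      }
    }
    best
  }

  fwd <- best_chain(anchor_hits(contig))
  rev_ <- best_chain(anchor_hits(reverse_complement(contig)))
  n_fwd <- if (is.null(fwd)) 0L else fwd$n
  n_rev <- if (is.null(rev_)) 0L else rev_$n
  if (max(n_fwd, n_rev) < min_anchors) {
    stop("contig unplaceable: only ", max(n_fwd, n_rev),
         " chained anchors (need ", min_anchors, "); ",
         n_fwd, " forward / ", n_rev, " reverse candidates")
  }
  orientation <- if (n_fwd >= n_rev) "+" else "-"
  pick <- if (orientation == "+") fwd else rev_
  ch <- pick$chain[order(pick$chain$cpos), ]
  left <- ch[1, ]; right <- ch[nrow(ch), ]
  start0 <- left$gpos - left$cpos # 0-based
  end0 <- right$gpos - right$cpos + clen
  span <- end0 - start0
  tibble::tibble(
    contig_id = contig_id, seq_id = pick$seq_id,
    start = as.integer(start0), end = as.integer(end0),
    orientation = orientation, n_anchors = pick$n,
    flagged = span < 0.5 * clen || span > 2 * clen
  )
}

# percent identity (fraction) between two unit sequences via global
# alignment
unit_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  Biostrings::pid(aln, type = "PID2") / 100
}

#' Pair contig units with genome units one-to-one
#'
#' Greedy matching by descending identity (ties broken by positional
#' order); pairs below `min_identity` stay unmatched. Swapping the inputs
#' swaps the contig-only / genome-only roles.
#'
#' @param contig_units,genome_units Unit tibbles (need `sequence` and a
#'   `name` or `unit_key` column), both annotated by the same scanner and
#'   profile.
#' @param min_identity Minimum identity (fraction) for a matched pair.
#' @return Tibble with one row per contig or genome unit: `contig_unit`,
#'   `genome_unit` (NA when unmatched) and `identity`.
#' @export
pair_units <- function(contig_units, genome_units, min_identity = 0.9) {
  cu <- tibble::as_tibble(contig_units)
  gu <- tibble::as_tibble(genome_units)
  cnames <- cu[["name"]] %||% cu[["unit_key"]]
  gnames <- gu[["name"]] %||% gu[["unit_key"]]
  nc <- nrow(cu); ng <- nrow(gu)
  if (nc == 0 && ng == 0) {
    return(tibble::tibble(contig_unit = character(), genome_unit = character(),
                          identity = numeric()))
  }
  idm <- matrix(0, nrow = max(nc, 1), ncol = max(ng, 1))
  for (i in seq_len(nc)) {
    for (j in seq_len(ng)) {
      # exact equality fast path; alignment otherwise
      idm[i, j] <- if (identical(cu$sequence[i], gu$sequence[j])) 1
      else unit_identity(cu$sequence[i], gu$sequence[j])
    }
  }
  pairs <- list()
  used_c <- logical(nc); used_g <- logical(ng)
  if (nc > 0 && ng > 0) {
    repeat {
      m <- max(idm[!used_c, !used_g, drop = FALSE])
      if (length(m) == 0 || m < min_identity) break
      cand <- which(idm == m, arr.ind = TRUE)
      cand <- cand[!used_c[cand[, 1]] & !used_g[cand[, 2]], , drop = FALSE]
      if (nrow(cand) == 0) break
      cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
      i <- cand[1, 1]; j <- cand[1, 2]
      used_c[i] <- TRUE; used_g[j] <- TRUE
      pairs[[length(pairs) + 1L]] <- tibble::tibble(
        contig_unit = cnames[i], genome_unit = gnames[j], identity = idm[i, j]
      )
      if (all(used_c) || all(used_g)) break
    }
  }
  dplyr::bind_rows(
    dplyr::bind_rows(pairs),
    tibble::tibble(contig_unit = cnames[!used_c],
                   genome_unit = NA_character_, identity = NA_real_),
    tibble::tibble(contig_unit = NA_character_,
                   genome_unit = gnames[!used_g], identity = NA_real_)
  )
}

#' Flag cross-location identical units (misassembly candidates)
#'
#' Contig units left unmatched locally are searched against all genome
#' units; hits at identity at least `identity_exact` located on a
#' different chromosome, or more than `distant_bp` away from the placement
#' on the same chromosome, are misassembly candidates.
#'
#' @param unmatched_contig_units Tibble of contig units with no local
#'   partner (`sequence` plus `name`/`unit_key`).
#' @param all_genome_units Tibble of every genome unit (needs `sequence`,
#'   `seq_id`, `start`, plus `name`/`unit_key`).
#' @param placement One-row tibble from [place_contig()].
#' @param identity_exact Identity threshold (1.0 = exact sequence match).
#' @param distant_bp Same-chromosome distance beyond which a hit counts as
#'   distant.
#' @return Tibble `contig_unit`, `genome_unit`, `identity`, `seq_id`,
#'   `start`.
#' @export
flag_cross_location <- function(unmatched_contig_units, all_genome_units,
                                placement, identity_exact = 1.0,
                                distant_bp = 1e6) {
  cu <- tibble::as_tibble(unmatched_contig_units)
  gu <- tibble::as_tibble(all_genome_units)
  out <- tibble::tibble(contig_unit = character(), genome_unit = character(),
                        identity = numeric(), seq_id = character(),
                        start = integer())
  if (nrow(cu) == 0 || nrow(gu) == 0) return(out)
  cnames <- cu[["name"]] %||% cu[["unit_key"]]
  gnames <- gu[["name"]] %||% gu[["unit_key"]]
  distant <- gu$seq_id != placement$seq_id |
    gu$start + (gu$end - gu$start) / 2 < placement$start - distant_bp |
    gu$start + (gu$end - gu$start) / 2 > placement$end + distant_bp
  hits <- list()
  for (i in seq_len(nrow(cu))) {
    for (j in which(distant)) {
      id <- if (identical(cu$sequence[i], gu$sequence[j])) 1
      else if (identity_exact >= 1) 0 # exact mode needs string equality
      else unit_identity(cu$sequence[i], gu$sequence[j])
      if (id >= identity_exact) {
        hits[[length(hits) + 1L]] <- tibble::tibble(
          contig_unit = cnames[i], genome_unit = gnames[j], identity = id,
          seq_id = gu$seq_id[j], start = gu$start[j]
        )
      }
    }
  }
  dplyr::bind_rows(out, dplyr::bind_rows(hits))
}

#' Contig-versus-assembly quality control
#'
#' Places the contig ([place_contig()]), pairs its units one-to-one with
#' the genome units inside the placement window ([pair_units()]), reports
#' the units missing from either side together with the genomic gap spans
#' they imply, and flags cross-location identical units
#' ([flag_cross_location()]).
#'
#' @inheritParams place_contig
#' @param contig_units Units annotated on the contig (scanner output).
#' @param genome_units Units annotated on the genome (scanner output).
#' @param min_identity Pairing threshold.
#' @param identity_exact Cross-location threshold.
#' @param distant_bp Cross-location distance.
#' @param gap_merge Unmatched contig units whose projected genome positions
#'   lie within this many bases are merged into one gap span.
#' @return An object of class `sat_qc`: list with `placement`, `pairing`,
#'   `report` (one row: `n_paired`, `n_contig_only`, `n_genome_only`),
#'   `gaps` (projected gap spans), `cross_location`.
#' @export
assembly_qc <- function(contig, contig_units, genome, genome_units,
                        k = 31, min_identity = 0.9, identity_exact = 1.0,
                        distant_bp = 1e6, gap_merge = 2000) {
  placement <- place_contig(contig, genome, k = k)
  gu <- tibble::as_tibble(genome_units)
  local <- gu[gu$seq_id == placement$seq_id &
                gu$end > placement$start & gu$start < placement$end, ]
  cu <- tibble::as_tibble(contig_units)
  pairing <- pair_units(cu, local, min_identity = min_identity)
  contig_only <- pairing$contig_unit[!is.na(pairing$contig_unit) &
                                       is.na(pairing$genome_unit)]
  genome_only <- pairing$genome_unit[is.na(pairing$contig_unit) &
                                       !is.na(pairing$genome_unit)]
  cnames <- cu[["name"]] %||% cu[["unit_key"]]
  # project unmatched contig units onto the genome to delimit gap spans
  clen <- if (inherits(contig, "DNAStringSet")) {
    Biostrings::width(contig)[1]
  } else nchar(contig)
  miss <- cu[cnames %in% contig_only, ]
  gaps <- tibble::tibble(seq_id = character(), start = integer(), end = integer(),
                         n_missing_units = integer())
  if (nrow(miss) > 0) {
    if (placement$orientation == "+") {
      gs <- placement$start + miss$start
      ge <- placement$start + miss$end
    } else {
      gs <- placement$start + (clen - miss$end)
      ge <- placement$start + (clen - miss$start)
    }
    ord <- order(gs)
    gs <- gs[ord]; ge <- ge[ord]
    grp <- cumsum(c(1, as.integer(gs[-1] - cummax(ge[-length(ge)]) > gap_merge)))
    gaps <- tibble::tibble(gs = gs, ge = ge, grp = grp) |>
      dplyr::group_by(.data$grp) |>
      dplyr::summarise(start = min(.data$gs), end = max(.data$ge),
                       n_missing_units = dplyr::n(), .groups = "drop") |>
      dplyr::transmute(seq_id = placement$seq_id,
                       start = as.integer(.data$start),
                       end = as.integer(.data$end),
                       n_missing_units = .data$n_missing_units)
  }
  cross <- flag_cross_location(miss, gu, placement,
                               identity_exact = identity_exact,
                               distant_bp = distant_bp)
  structure(
    list(
      placement = placement,
      pairing = pairing,
      report = tibble::tibble(
        n_paired = sum(!is.na(pairing$contig_unit) & !is.na(pairing$genome_unit)),
        n_contig_only = length(contig_only),
        n_genome_only = length(genome_only)
      ),
      gaps = gaps,
      cross_location = cross
    ),
    class = "sat_qc"
  )
}

#' @export
print.sat_qc <- function(x, ...) {
  cat("<sat_qc> contig ", x$placement$contig_id, " -> ", x$placement$seq_id,
      ":", x$placement$start, "-", x$placement$end,
      " (", x$placement$orientation, ")\n", sep = "")
  cat("  paired ", x$report$n_paired, ", contig-only ", x$report$n_contig_only,
      ", genome-only ", x$report$n_genome_only, ", cross-location flags ",
      nrow(x$cross_location), "\n", sep = "")
  invisible(x)
}
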