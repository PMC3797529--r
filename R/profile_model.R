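#' Build a position-specific scoring profile from a seed monomer alignment
#'
#' Alignment columns whose gap fraction exceeds `gap_col_threshold` are
#' treated as insert columns and removed; the remaining columns become the
#' model's match positions in order. Per-position emission scores are
#' log-odds in bits against the background:
#' `log2(((count + pseudocount) / (n_rows + 4 * pseudocount)) / background)`,
#' with `N` residues contributing 1/4 of a count to each base. The consensus
#' takes the per-position argmax (ties broken alphabetically).
#'
#' @param seed Character matrix from [read_seed_alignment()] (or a character
#'   vector of equal-length gapped rows).
#' @param gap_col_threshold Columns with a gap fraction strictly above this
#'   are dropped. In (0, 1].
#' @param pseudocount Additive smoothing, must be > 0 so that every emission
#'   is finite.
#' @param background Base frequencies (A, C, G, T) summing to 1; uniform by
#'   default so that scores do not depend on any particular genome.
#' @param gap_open,gap_extend Affine gap penalties (negative, bits) used by
#'   [score_glocal()].
#' @return An object of class `sat_profile` with elements `emissions`
#'   (L x 5 matrix, columns A, C, G, T, N), `consensus`, `background`,
#'   `gap_open`, `gap_extend`, `L`, and `self_score` (the score of the
#'   consensus itself).
#' @export
build_profile <- function(seed, gap_col_threshold = 0.5, pseudocount = 1,
                          background = rep(0.25, 4),
                          gap_open = -6, gap_extend = -1) {
  if (is.character(seed) && !is.matrix(seed)) {
    if (length(unique(nchar(seed))) != 1L) stop("alignment rows have unequal lengths")
    seed <- do.call(rbind, strsplit(toupper(seed), "", fixed = TRUE))
  }
  stopifnot(is.matrix(seed))
  if (nrow(seed) < 2L) stop("a seed alignment needs at least 2 rows")
  if (gap_col_threshold <= 0 || gap_col_threshold > 1) {
    stop("gap_col_threshold must be in (0, 1]")
  }
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  stopifnot(length(background) == 4, all(background > 0),
            abs(sum(background) - 1) < 1e-8)
  if (gap_open >= 0 || gap_extend >= 0) stop("gap penalties must be negative")

  gap_frac <- colMeans(seed == "-")
  keep <- which(gap_frac <= gap_col_threshold)
  if (length(keep) == 0L) stop("all columns exceed the gap threshold")
  sub <- seed[, keep, drop = FALSE]
  n_rows <- nrow(sub)
  bases <- c("A", "C", "G", "T")
  counts <- vapply(bases, function(b) colSums(sub == b), numeric(ncol(sub)))
  counts <- matrix(counts, ncol = 4,
                   dimnames = list(NULL, bases)) # L x 4 even when L == 1
  # ambiguous residues spread equally over the four bases
  n_amb <- colSums(sub == "N")
  counts <- counts + n_amb / 4
  prob <- (counts + pseudocount) / (n_rows + 4 * pseudocount)
  emis <- log2(sweep(prob, 2, background, "/"))
  consensus_idx <- apply(emis, 1, which.max)
  consensus <- paste(bases[consensus_idx], collapse = "")
  emissions <- cbind(emis, N = 0) # ambiguous residues score neutrally
  structure(
    list(
      emissions = emissions,
      consensus = consensus,
      background = background,
      gap_open = gap_open,
      gap_extend = gap_extend,
      L = nrow(emissions),
      self_score = sum(apply(emis, 1, max)),
      n_seed_rows = n_rows
    ),
    class = "sat_profile"
  )
}

#' @export
print.sat_profile <- function(x, ...) {
  cat("<sat_profile> ", x$L, " match positions, built from ", x$n_seed_rows,
      " seed rows\n", sep = "")
  cat("  consensus self-score: ", round(x$self_score, 1), " bits\n", sep = "")
  invisible(x)
}

#' Build a single-sequence profile
#'
#' Used where one reference monomer (e.g. a centromeric satellite such as
#' CentPv1/CentPv2) stands in for an alignment. A small pseudocount keeps
#' the match/mismatch contrast sharp.
#'
#' @param seq One DNA string.
#' @param pseudocount Additive smoothing.
#' @inheritParams build_profile
#' @return A `sat_profile`.
#' @export
profile_from_sequence <- function(seq, pseudocount = 0.1,
                                  gap_open = -6, gap_extend = -1) {
  stopifnot(is.character(seq), length(seq) == 1L, nchar(seq) >= 1L)
  seed <- rbind(strsplit(toupper(seq), "", fixed = TRUE)[[1]])
  seed <- rbind(seed, seed) # degenerate 2-row alignment of the same sequence
  build_profile(seed, gap_col_threshold = 1, pseudocount = pseudocount,
                gap_open = gap_open, gap_extend = gap_extend)
}

#' Score a sequence against a profile (glocal, affine gaps)
#'
#' The alignment is global over the profile -- every match position is either
#' aligned to a residue or deleted -- and local over the sequence: the
#' monomer may start and end anywhere in `seq`, with unaligned flanking
#' residues free. Ties in the traceback are broken match > delete > insert,
#' so results are deterministic.
#'
#' @param profile A `sat_profile`.
#' @param seq A DNA string over `{A,C,G,T,N}`.
#' @return A list with `score` (bits), `aligned` (a string of length
#'   `profile$L`: the residue placed at each match position, `-` for a
#'   deletion), and `seq_start`/`seq_end` (0-based half-open interval of
#'   `seq` consumed by the alignment).
#' @export
score_glocal <- function(profile, seq) {
  stopifnot(inherits(profile, "sat_profile"))
  if (!is.character(seq) || length(seq) != 1L || nchar(seq) < 1L) {
    stop("seq must be one non-empty DNA string")
  }
  res <- glocal_align(profile$emissions, encode_dna(toupper(seq)),
                      profile$gap_open, profile$gap_extend)
  list(
    score = res$score,
    aligned = decode_dna(res$aligned),
    seq_start = res$seq_start,
    seq_end = res$seq_end
  )
}

#' Reverse complement
#'
#' Standard complement with `N -> N`; an involution.
#'
#' @param seq Character vector of DNA strings.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  vapply(seq, function(s) {
    paste(rev(strsplit(chartr("ACGTNacgtn", "TGCANtgcan", s), "",
                       fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Serialize / read a profile as TSV
#'
#' One row per match position: position, the four emission scores, and the
#' consensus base. Gap penalties and background travel in `#`-comment lines.
#'
#' @param profile A `sat_profile`.
#' @param path File path.
#' @return `write_profile_tsv()` returns `path` invisibly;
#'   `read_profile_tsv()` returns a `sat_profile`.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "sat_profile"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# gap_open=%g gap_extend=%g background=%s",
                     profile$gap_open, profile$gap_extend,
                     paste(profile$background, collapse = ",")), con)
  tb <- data.frame(
    position = seq_len(profile$L),
    A = profile$emissions[, "A"], C = profile$emissions[, "C"],
    G = profile$emissions[, "G"], T = profile$emissions[, "T"],
    consensus = strsplit(profile$consensus, "", fixed = TRUE)[[1]]
  )
  utils::write.table(format(tb, digits = 12), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @export
read_profile_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  m <- regmatches(header, regexec(
    "gap_open=(-?[0-9.]+) gap_extend=(-?[0-9.]+) background=([0-9.,]+)", header))[[1]]
  if (length(m) != 4L) stop("not a satmine profile TSV: ", path)
  tb <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          colClasses = c("integer", rep("numeric", 4), "character"))
  emis <- as.matrix(tb[, c("A", "C", "G", "T")])
  structure(
    list(
      emissions = cbind(emis, N = 0),
      consensus = paste(tb$consensus, collapse = ""),
      background = as.numeric(strsplit(m[4], ",")[[1]]),
      gap_open = as.numeric(m[2]),
      gap_extend = as.numeric(m[3]),
      L = nrow(emis),
      self_score = sum(apply(emis, 1, max)),
      n_seed_rows = NA_integer_
    ),
    class = "sat_profile"
  )
}
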