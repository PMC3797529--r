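#' Read a genome (or any DNA) FASTA file with normalisation
#'
#' Sequences are uppercased and every character outside `{A,C,G,T,N}`
#' (IUPAC ambiguity codes, gaps left over from alignments, ...) is replaced
#' by `N`, with one warning summarising how many residues were replaced.
#' Sequence ids are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("empty FASTA file: ", path)
  if (any(Biostrings::width(raw) == 0L)) {
    stop("FASTA format error: header with no sequence in ", path)
  }
  ids <- sub("\\s.*$", "", names(raw))
  if (any(!nzchar(ids))) stop("FASTA format error: empty sequence id")
  seqs <- toupper(as.character(raw))
  n_bad <- sum(vapply(seqs, function(s) {
    nchar(gsub("[ACGTN]", "", s))
  }, integer(1)))
  if (n_bad > 0L) {
    seqs <- gsub("[^ACGTN]", "N", seqs)
    warning(n_bad, " residue(s) outside {A,C,G,T,N} replaced by N")
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, width = width)
  invisible(path)
}

#' Read a seed monomer alignment (aligned FASTA)
#'
#' @param path Path to an aligned FASTA file; rows must be equal length.
#' @return A character matrix (one row per sequence, one column per
#'   alignment column) over `{A,C,G,T,N,-}`; `.` is normalised to `-`.
#' @export
read_seed_alignment <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) < 2L) stop("a seed alignment needs at least 2 rows")
  w <- Biostrings::width(raw)
  if (length(unique(w)) != 1L) stop("alignment rows have unequal lengths")
  seqs <- chartr(".", "-", toupper(as.character(raw)))
  seqs <- gsub("[^ACGTN-]", "N", seqs)
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- sub("\\s.*$", "", names(raw))
  mat
}

#' Render a satellite unit name
#'
#' Units are named `<prefix><chrom><arm>k<#####>`: e.g. `Pv01Sk00010` is the
#' first unit on pseudomolecule 01, located on the short arm. Units on
#' independently sequenced contigs omit the arm code (e.g. `PvA05Ak00010`).
#' Ordinals run 10, 20, 30, ... along each pseudomolecule 5' to 3'.
#'
#' @param prefix Genotype prefix (e.g. `"Pv"`).
#' @param chrom_label Chromosome (2-digit) or contig label.
#' @param ordinal Positive multiple of 10, at most 99990.
#' @param arm_code `"S"`, `"C"`, `"L"`, or `""` for contig units.
#' @return Character vector of rendered names.
#' @export
render_unit_name <- function(prefix, chrom_label, ordinal, arm_code = "") {
  if (any(ordinal <= 0 | ordinal %% 10 != 0)) {
    stop("ordinal must be a positive multiple of 10")
  }
  if (any(ordinal > 99990)) stop("ordinal exceeds the 5-digit field")
  if (!all(arm_code %in% c("S", "C", "L", ""))) {
    stop("arm_code must be one of S, C, L or empty")
  }
  sprintf("%s%s%sk%05d", prefix, chrom_label, arm_code, as.integer(ordinal))
}

#' Parse a rendered unit name back into its fields
#'
#' Inverse of [render_unit_name()] for genome units (arm code present).
#'
#' @param name Character vector of names such as `"Pv01Sk00010"`.
#' @param prefix Genotype prefix used when rendering.
#' @return A tibble with columns `chrom_label`, `arm_code`, `ordinal`.
#' @export
parse_unit_name <- function(name, prefix = "Pv") {
  pat <- paste0("^", prefix, "(.+?)([SCL])k(\\d{5})$")
  ok <- grepl(pat, name)
  if (!all(ok)) stop("unparseable unit name(s): ", paste(name[!ok], collapse = ", "))
  tibble::tibble(
    chrom_label = sub(pat, "\\1", name),
    arm_code = sub(pat, "\\2", name),
    ordinal = as.integer(sub(pat, "\\3", name))
  )
}

#' Write annotation records as GFF3
#'
#' Internal coordinates are 0-based half-open; conversion to GFF3's 1-based
#' inclusive convention happens here and only here. Records must already be
#' sorted by `(seq_id, start)` -- unsorted input is an error, never silently
#' reordered. The `name` column is carried as the GFF3 `Name` attribute.
#'
#' @param records Tibble with columns `seq_id`, `start`, `end`, `strand`,
#'   `name`, and optionally `feature_type` (default `satellite_DNA`),
#'   `score`, and extra attribute columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(records, path) {
  records <- tibble::as_tibble(records)
  if (nrow(records) > 0) {
    ord <- order(records$seq_id, records$start)
    if (!identical(ord, seq_len(nrow(records)))) {
      stop("records must be sorted by (seq_id, start); refusing to sort silently")
    }
    stopifnot(all(records$start >= 0), all(records$end > records$start))
    gr <- GenomicRanges::GRanges(
      seqnames = records$seq_id,
      ranges = IRanges::IRanges(start = records$start + 1L, end = records$end),
      strand = records[["strand"]] %||% "*"
    )
    gr$source <- "satmine"
    gr$type <- records[["feature_type"]] %||% "satellite_DNA"
    gr$score <- records[["score"]] %||% NA_real_
    gr$Name <- records$name
    for (extra in setdiff(
      names(records),
      c("seq_id", "start", "end", "strand", "feature_type", "score", "name")
    )) {
      S4Vectors::mcols(gr)[[extra]] <- records[[extra]]
    }
    rtracklayer::export(gr, path, format = "gff3")
  } else {
    writeLines("##gff-version 3", path)
  }
  invisible(path)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read a GFF3 file into the package's 0-based half-open convention
#'
#' @param path Path to a GFF3 file.
#' @return Tibble with columns `seq_id`, `start`, `end` (0-based half-open),
#'   `strand`, `feature_type`, `score`, `name`, plus any extra attributes.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  tb <- tibble::tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature_type = as.character(gr$type),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_,
    name = if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_
  )
  for (extra in setdiff(colnames(S4Vectors::mcols(gr)),
                        c("source", "type", "score", "phase", "Name", "ID"))) {
    tb[[extra]] <- as.character(S4Vectors::mcols(gr)[[extra]])
  }
  tb
}

#' Read / write Newick trees
#'
#' Thin wrappers around \pkg{ape} that keep branch lengths (to at least six
#' significant digits) and internal-node support labels across a round trip.
#'
#' @param tree An [ape::phylo] object.
#' @param path File path.
#' @return `write_newick()` returns `path` invisibly; `read_newick()` returns
#'   an [ape::phylo].
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 10)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("Newick file not found: ", path)
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) NULL
  )
  if (is.null(tree)) stop("Newick parse error in ", path)
  tree
}

#' Write a tibble as a TSV file
#'
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
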