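#' Profile-anchored implied multiple sequence alignment
#'
#' Every unit is aligned to the profile's match positions with
#' [score_glocal()]; insertions relative to the profile are discarded and
#' deletions become gaps, so all rows have exactly `profile$L` columns and
#' columns are comparable across units by construction. Units with fewer
#' than half their columns aligned are excluded with a warning.
#'
#' @param profile A `sat_profile`.
#' @param units Either a retained-unit tibble (columns `sequence` and,
#'   when available, precomputed `aligned` rows plus `name`/`unit_key`), or
#'   a named character vector of sequences.
#' @return A character matrix (class keeps plain `matrix`) of residues and
#'   `-`, one named row per unit, `profile$L` columns.
#' @export
implied_msa <- function(profile, units) {
  if (is.character(units)) {
    nm <- names(units)
    if (is.null(nm)) nm <- paste0("u", seq_along(units))
    rows <- vapply(units, function(s) score_glocal(profile, s)$aligned,
                   character(1), USE.NAMES = FALSE)
  } else {
    units <- tibble::as_tibble(units)
    nm <- units[["name"]] %||% units[["unit_key"]] %||% paste0("u", seq_len(nrow(units)))
    if ("aligned" %in% names(units)) {
      rows <- units$aligned
    } else {
      rows <- vapply(units$sequence, function(s) score_glocal(profile, s)$aligned,
                     character(1), USE.NAMES = FALSE)
    }
  }
  mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(mat) <- nm
  frac_aligned <- rowMeans(mat != "-")
  drop <- frac_aligned < 0.5
  if (any(drop)) {
    warning(sum(drop), " unit(s) aligned over < 50% of profile columns; excluded: ",
            paste(utils::head(nm[drop], 5), collapse = ", "))
    mat <- mat[!drop, , drop = FALSE]
  }
  mat
}

#' Pairwise p-distance matrix with pairwise gap deletion
#'
#' The proportion of differing sites over columns where neither row is
#' gapped (`N` treated as missing as well). Pairs sharing no columns get
#' the saturation proportion 0.75.
#'
#' @param msa Character matrix from [implied_msa()].
#' @return Symmetric numeric matrix of p-distances, zero diagonal.
#' @export
pdist_matrix <- function(msa) {
  stopifnot(is.matrix(msa))
  bases <- c("A", "C", "G", "T")
  match_counts <- matrix(0, nrow(msa), nrow(msa))
  for (b in bases) {
    ind <- (msa == b) * 1
    match_counts <- match_counts + tcrossprod(ind)
  }
  present <- (msa %in% bases)
  dim(present) <- dim(msa)
  shared <- tcrossprod(present * 1)
  p <- 1 - match_counts / shared
  p[shared == 0] <- 0.75
  diag(p) <- 0
  dimnames(p) <- list(rownames(msa), rownames(msa))
  p
}

#' Jukes-Cantor distance
#'
#' `d = -(3/4) * ln(1 - (4/3) * p)`, correcting the observed proportion of
#' differing sites for multiple hits. Proportions at or beyond the model's
#' saturation point (`p >= 0.75`) are capped at `d_max` and counted in the
#' `"saturated"` attribute.
#'
#' @param p Proportions of differing sites, in `[0, 1]` (vector or matrix).
#' @param d_max Cap for saturated distances (substitutions/site).
#' @return Distances in substitutions/site, same shape as `p`, with an
#'   attribute `saturated` giving the number of capped entries.
#' @export
jc_distance <- function(p, d_max = 5) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  d <- p
  sat <- p >= 0.75
  d[!sat] <- -0.75 * log(1 - (4 / 3) * p[!sat])
  d[sat] <- d_max
  if (is.matrix(d)) diag(d) <- 0
  attr(d, "saturated") <- sum(sat & (!is.matrix(p) | upper.tri(p)))
  d
}

#' Jukes-Cantor distance matrix of an implied MSA
#'
#' @inheritParams pdist_matrix
#' @inheritParams jc_distance
#' @return Symmetric matrix of JC distances.
#' @export
dist_jc <- function(msa, d_max = 5) {
  d <- jc_distance(pdist_matrix(msa), d_max = d_max)
  attr(d, "saturated") <- NULL
  d
}

#' Neighbor-joining tree
#'
#' Canonical neighbor joining on a symmetric distance matrix (Q-matrix
#' criterion, standard branch-length estimates). Ties in Q are broken by
#' the smallest index pair and negative branch-length estimates are clamped
#' to zero, so the result is deterministic. The tree is unrooted (basal
#' trifurcation); use [midpoint_root()] for display.
#'
#' @param dm Symmetric numeric matrix with row/column names.
#' @return An [ape::phylo] object.
#' @export
nj_tree <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (nrow(dm) < 3) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix is not symmetric")
  labels <- rownames(dm)
  if (is.null(labels)) labels <- paste0("t", seq_len(nrow(dm)))
  res <- nj_joins(dm)
  n <- nrow(dm)
  sub <- as.list(labels) # newick fragment per node id
  fmt <- function(x) sprintf("%.10g", x)
  jn <- res$joins
  ln <- res$lengths
  if (nrow(jn) > 0) {
    for (s in seq_len(nrow(jn))) {
      sub[[jn[s, 3]]] <- paste0(
        "(", sub[[jn[s, 1]]], ":", fmt(ln[s, 1]), ",",
        sub[[jn[s, 2]]], ":", fmt(ln[s, 2]), ")"
      )
    }
  }
  fi <- res$final_ids
  fl <- res$final_lengths
  txt <- paste0("(", sub[[fi[1]]], ":", fmt(fl[1]), ",",
                sub[[fi[2]]], ":", fmt(fl[2]), ",",
                sub[[fi[3]]], ":", fmt(fl[3]), ");")
  ape::read.tree(text = txt)
}

#' Midpoint-root a tree for display
#'
#' @param tree An [ape::phylo].
#' @return A rooted [ape::phylo].
#' @export
midpoint_root <- function(tree) {
  phangorn::midpoint(tree, node.labels = "label")
}

#' Neighbor-joining tree with bootstrap support
#'
#' Columns of the implied MSA are resampled with replacement `n_reps`
#' times (seeded); a JC + NJ tree is built per replicate and the support of
#' every internal edge of the midpoint-rooted main tree is the fraction of
#' replicates containing that bipartition. The replicate trees are kept in
#' the `"replicates"` attribute so a majority-rule consensus
#' ([majority_consensus()]) is also available.
#'
#' @param msa Character matrix from [implied_msa()].
#' @param n_reps Number of bootstrap replicates.
#' @param seed Seed for column resampling.
#' @param d_max Saturation cap for [jc_distance()].
#' @return A rooted [ape::phylo] whose `node.label` holds bootstrap support
#'   fractions (`NA` at the root), with attributes `n_reps` and
#'   `replicates`.
#' @export
bootstrap_support <- function(msa, n_reps = 100, seed = 1, d_max = 5) {
  stopifnot(n_reps >= 1)
  main <- midpoint_root(nj_tree(dist_jc(msa, d_max = d_max)))
  old <- .Random.seed_save()
  set.seed(seed)
  reps <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol(msa), ncol(msa), replace = TRUE)
    reps[[r]] <- nj_tree(dist_jc(msa[, cols, drop = FALSE], d_max = d_max))
  }
  .Random.seed_restore(old)
  class(reps) <- "multiPhylo"
  counts <- ape::prop.clades(main, reps, rooted = FALSE)
  support <- counts / n_reps
  support[is.na(support)] <- 0
  support[1] <- NA # root of the displayed tree carries no bipartition
  main$node.label <- as.character(round(support, 4))
  attr(main, "n_reps") <- n_reps
  attr(main, "replicates") <- reps
  main
}

#' Majority-rule consensus of the bootstrap replicates
#'
#' @param tree Output of [bootstrap_support()].
#' @param p Consensus threshold (0.5 = majority rule).
#' @return An [ape::phylo].
#' @export
majority_consensus <- function(tree, p = 0.5) {
  reps <- attr(tree, "replicates")
  if (is.null(reps)) stop("tree carries no bootstrap replicates")
  ape::consensus(reps, p = p)
}

#' Extract major clades from a supported tree
#'
#' A candidate clade is an internal node whose bootstrap support is
#' strictly above `min_support`, whose tip count is at least `min_size`
#' and at most half the tree (the minority side of its bipartition: the
#' complement of a supported clade spans the unrooted backbone and is not
#' itself a clade). Candidates are accepted greedily by decreasing size
#' subject to disjointness, so each major clade is maximal. Clades are
#' labelled `A`, `B`, ... by decreasing size; leaves in no clade are
#' reported as unplaced.
#'
#' @param tree Rooted tree with numeric-string `node.label` supports, from
#'   [bootstrap_support()].
#' @param min_support Support threshold (strict; the default 0.75 reads
#'   "support > 75 %" strictly).
#' @param min_size Minimum clade size; default 2 % of the tips (at least 2).
#' @return An object of class `sat_clades`: list with `clades` (tibble of
#'   `clade`, `size`, `support`), `members` (tibble of `clade`, `unit`) and
#'   `unplaced` (character vector).
#' @export
extract_major_clades <- function(tree, min_support = 0.75, min_size = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) tree <- midpoint_root(tree)
  n_tip <- ape::Ntip(tree)
  if (is.null(min_size)) min_size <- max(2L, ceiling(0.02 * n_tip))
  support <- suppressWarnings(as.numeric(tree$node.label))
  tips_below <- phangorn::Descendants(tree, (n_tip + 1):(n_tip + tree$Nnode),
                                      type = "tips")
  root <- n_tip + 1L
  sizes_all <- lengths(tips_below)
  cand <- which(!is.na(support) & support > min_support &
                  sizes_all >= min_size & sizes_all <= n_tip / 2) + n_tip
  cand <- setdiff(cand, root)
  # greedy by decreasing size, ties by node id: maximal disjoint clades
  cand <- cand[order(-sizes_all[cand - n_tip], cand)]
  taken <- logical(n_tip)
  accepted <- integer(0)
  for (node in cand) {
    tips <- tips_below[[node - n_tip]]
    if (!any(taken[tips])) {
      taken[tips] <- TRUE
      accepted <- c(accepted, node)
    }
  }
  members <- list()
  clade_ids <- make_clade_labels(length(accepted))
  for (i in seq_along(accepted)) {
    tips <- tree$tip.label[tips_below[[accepted[i] - n_tip]]]
    members[[i]] <- tibble::tibble(clade = clade_ids[i], unit = tips)
  }
  sizes <- sizes_all[accepted - n_tip]
  members <- dplyr::bind_rows(members)
  if (nrow(members) == 0) {
    members <- tibble::tibble(clade = character(), unit = character())
  }
  clades <- tibble::tibble(
    clade = clade_ids,
    size = sizes,
    support = support[accepted - n_tip]
  )
  structure(
    list(
      clades = clades,
      members = members,
      unplaced = setdiff(tree$tip.label, members$unit),
      min_support = min_support,
      min_size = min_size
    ),
    class = "sat_clades"
  )
}

# A, B, ..., Z, AA, AB, ... labels
make_clade_labels <- function(n) {
  if (n == 0) return(character(0))
  if (n <= 26) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26), LETTERS))[seq_len(n)]
}

#' @export
print.sat_clades <- function(x, ...) {
  cat("<sat_clades> ", nrow(x$clades), " major clade(s), ",
      nrow(x$members), " placed unit(s), ", length(x$unplaced),
      " unplaced\n", sep = "")
  if (nrow(x$clades) > 0) print(x$clades, ...)
  invisible(x)
}
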