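#' Maximum chi-square scan of one (child, parent A, parent B) triplet
#'
#' Only columns where the two putative parents differ, neither parent nor
#' the child is gapped, and the child matches one of the parents are
#' informative. At every candidate breakpoint `b` the 2x2 table of
#' (left-of-b vs right-of-b) x (child matches A vs matches B) is scored by
#' the chi-square statistic with Yates continuity correction; the returned
#' breakpoint is the argmax (ties to the smallest `b`), with the p-value
#' from the 1-df chi-square distribution.
#'
#' @param child,parent_a,parent_b Aligned sequences of equal length
#'   (strings or character vectors of single residues).
#' @param min_margin Breakpoints are restricted to
#'   `[min_margin, n - min_margin]`; with fewer than `2 * min_margin`
#'   informative columns the triplet is a no-call (flagged, not an error).
#' @return A one-row tibble: `breakpoint`, `chi2`, `p_raw`,
#'   `n_informative`, `no_call`.
#' @export
max_chi2_triplet <- function(child, parent_a, parent_b, min_margin = 20) {
  if (min_margin < 10) stop("min_margin must be >= 10")
  as_chars <- function(x) {
    if (length(x) == 1L) strsplit(toupper(x), "", fixed = TRUE)[[1]] else toupper(x)
  }
  ch <- as_chars(child); pa <- as_chars(parent_a); pb <- as_chars(parent_b)
  n <- length(ch)
  if (length(pa) != n || length(pb) != n) stop("aligned lengths differ")
  no_gap <- ch != "-" & pa != "-" & pb != "-"
  m_a <- no_gap & pa != pb & ch == pa
  m_b <- no_gap & pa != pb & ch == pb
  n_inf <- sum(m_a) + sum(m_b)
  no_call <- tibble::tibble(
    breakpoint = NA_integer_, chi2 = NA_real_, p_raw = NA_real_,
    n_informative = n_inf, no_call = TRUE
  )
  if (n_inf < 2 * min_margin) return(no_call)
  bps <- seq.int(min_margin, n - min_margin)
  if (length(bps) == 0L) return(no_call)
  ca <- cumsum(m_a); cb <- cumsum(m_b)
  ta <- ca[n]; tb <- cb[n]
  la <- ca[bps]; lb <- cb[bps]
  ra <- ta - la; rb <- tb - lb
  chi2 <- chi2_yates(la, lb, ra, rb)
  best <- which.max(chi2) # ties -> smallest b (which.max takes the first)
  best_chi2 <- chi2[best]
  tibble::tibble(
    breakpoint = bps[best],
    chi2 = best_chi2,
    p_raw = stats::pchisq(best_chi2, df = 1, lower.tail = FALSE),
    n_informative = n_inf,
    no_call = FALSE
  )
}

# vectorised 2x2 chi-square with Yates continuity correction; tables with
# an empty margin score 0
chi2_yates <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  num <- pmax(abs(a * d - b * c) - n / 2, 0)
  den <- r1 * r2 * c1 * c2
  out <- ifelse(den > 0, n * num^2 / den, 0)
  as.numeric(out)
}

#' Screen all units for recombinant (mosaic) monomers
#'
#' For every unit taken as the putative child, candidate parents are
#' representatives of the *other* sequence clusters: units are grouped by
#' average-linkage clustering of the p-distance matrix (cut at half the
#' median pairwise distance), each foreign cluster contributes its member
#' closest to the child, and the two nearest plus two furthest
#' representatives form the candidate pool; all pairs among that pool give
#' up to six triplets per child. (Keeping parents outside the child's own
#' cluster stops near-identical relatives -- including fellow mosaics --
#' from crowding out the true parental lineages.) When fewer than two
#' foreign clusters exist, the child's two nearest and two furthest
#' neighbours are used instead. When the triplet count exceeds
#' `n_triplets_cap` a seeded random subset of that size is tested. The
#' Bonferroni correction uses the number of triplets actually scored
#' (no-calls excluded). Significant calls are then attributed greedily
#' (strongest first): each attributed call removes its child, and weaker
#' significant calls involving an already-removed unit in any role are
#' discounted -- a mosaic also produces signal in triplets where it serves
#' as a parent, and those echoes must not remove innocent children. The
#' removal set is excluded from downstream phylogeny.
#'
#' @param msa Character matrix (rows = units) from [implied_msa()].
#' @param alpha Maximum corrected p-value for accepting recombination
#'   (default 0.001, after Bonferroni correction).
#' @param n_triplets_cap Cap on the number of triplets tested.
#' @param seed Seed for the (only) random step, subsampling above the cap.
#' @param min_margin Passed to [max_chi2_triplet()].
#' @param min_cluster Minimum cluster size for a cluster to contribute
#'   candidate parents.
#' @return An object of class `sat_screen`: list with `removed` (unit
#'   names), `calls` (tibble of all scored triplets with `p_corrected` and
#'   `accepted`), and `n_tests`.
#' @export
screen_all <- function(msa, alpha = 0.001, n_triplets_cap = 200000,
                       seed = 1, min_margin = 20, min_cluster = 3) {
  stopifnot(is.matrix(msa), nrow(msa) >= 3)
  units <- rownames(msa)
  if (is.null(units)) units <- paste0("u", seq_len(nrow(msa)))
  n <- nrow(msa)
  p <- pdist_matrix(msa)
  h <- 0.5 * stats::median(p[upper.tri(p)])
  cl <- if (h > 0) {
    stats::cutree(stats::hclust(stats::as.dist(p), method = "average"), h = h)
  } else rep(1L, n)
  cl_sizes <- tabulate(cl)
  triplets <- list()
  for (i in seq_len(n)) {
    foreign <- setdiff(unique(cl), cl[i])
    # parents must represent substantial clusters: tiny clusters are mostly
    # mosaics themselves, and a mosaic parent fakes a breakpoint signal in
    # an innocent child
    big <- foreign[cl_sizes[foreign] >= min_cluster]
    if (length(big) >= 2) foreign <- big
    if (length(foreign) >= 2) {
      reps <- vapply(foreign, function(g) {
        m <- which(cl == g)
        m[which.min(p[i, m])]
      }, integer(1))
      reps <- reps[order(p[i, reps])]
      pool <- unique(c(utils::head(reps, 2), utils::tail(reps, 2)))
    } else {
      others <- setdiff(seq_len(n), i)
      d <- p[i, others]
      pool <- unique(c(others[order(d)][seq_len(min(2, length(others)))],
                       others[order(-d)][seq_len(min(2, length(others)))]))
    }
    if (length(pool) < 2) next
    prs <- utils::combn(pool, 2)
    triplets[[i]] <- cbind(child = i, a = prs[1, ], b = prs[2, ])
  }
  triplets <- do.call(rbind, triplets)
  if (nrow(triplets) > n_triplets_cap) {
    old <- .Random.seed_save()
    set.seed(seed)
    triplets <- triplets[sample.int(nrow(triplets), n_triplets_cap), , drop = FALSE]
    .Random.seed_restore(old)
  }
  calls <- vector("list", nrow(triplets))
  for (t in seq_len(nrow(triplets))) {
    res <- max_chi2_triplet(msa[triplets[t, 1], ], msa[triplets[t, 2], ],
                            msa[triplets[t, 3], ], min_margin = min_margin)
    res$child <- units[triplets[t, 1]]
    res$parent_a <- units[triplets[t, 2]]
    res$parent_b <- units[triplets[t, 3]]
    calls[[t]] <- res
  }
  calls <- dplyr::bind_rows(calls)
  n_tests <- sum(!calls$no_call)
  calls$p_corrected <- pmin(1, calls$p_raw * n_tests)
  calls$accepted <- !calls$no_call & !is.na(calls$p_corrected) &
    calls$p_corrected <= alpha
  # attribution: a mosaic also lights up every triplet in which it serves as
  # a parent, so significant calls are attributed greedily -- strongest call
  # first, its child removed, and remaining calls that involve an already
  # removed unit (in any role) discounted rather than removed themselves
  removed <- character(0)
  sig <- calls[calls$accepted, , drop = FALSE]
  sig <- sig[order(sig$p_corrected, sig$chi2 * -1), , drop = FALSE]
  for (r in seq_len(nrow(sig))) {
    trio <- c(sig$child[r], sig$parent_a[r], sig$parent_b[r])
    if (!any(trio %in% removed)) removed <- c(removed, sig$child[r])
  }
  calls$attributed <- calls$accepted & calls$child %in% removed
  calls <- dplyr::select(
    calls, "child", "parent_a", "parent_b", "breakpoint", "chi2",
    "p_raw", "p_corrected", "n_informative", "no_call", "accepted",
    "attributed"
  )
  structure(
    list(
      removed = removed,
      calls = calls,
      n_tests = n_tests,
      alpha = alpha
    ),
    class = "sat_screen"
  )
}

#' @export
print.sat_screen <- function(x, ...) {
  cat("<sat_screen> ", x$n_tests, " triplets tested, ",
      sum(x$calls$accepted), " accepted calls, ",
      length(x$removed), " unit(s) removed at alpha = ", x$alpha, "\n", sep = "")
  invisible(x)
}

# save/restore the global RNG state so that seeded subsampling does not
# perturb a caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
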