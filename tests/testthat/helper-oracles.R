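# Independent oracles used by the unit and acceptance tests. These are
# deliberately naive implementations kept separate from the package code
# paths they validate.

# --- brute-force maximum chi-square scan -----------------------------------
# plain loop over every breakpoint, 2x2 table built by counting, statistic
# from stats::chisq.test (Yates correction); zero-margin tables score 0
brute_max_chi2 <- function(child, parent_a, parent_b, min_margin = 20) {
  ch <- strsplit(child, "")[[1]]
  pa <- strsplit(parent_a, "")[[1]]
  pb <- strsplit(parent_b, "")[[1]]
  n <- length(ch)
  best_b <- NA_integer_
  best_chi2 <- -Inf
  for (bp in min_margin:(n - min_margin)) {
    idx <- seq_len(n)
    inf <- ch != "-" & pa != "-" & pb != "-" & pa != pb & (ch == pa | ch == pb)
    la <- sum(inf & ch == pa & idx <= bp)
    lb <- sum(inf & ch == pb & idx <= bp)
    ra <- sum(inf & ch == pa & idx > bp)
    rb <- sum(inf & ch == pb & idx > bp)
    tab <- matrix(c(la, lb, ra, rb), 2)
    chi2 <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      0
    } else {
      unname(suppressWarnings(stats::chisq.test(tab, correct = TRUE)$statistic))
    }
    if (chi2 > best_chi2) {
      best_chi2 <- chi2
      best_b <- bp
    }
  }
  list(breakpoint = best_b, chi2 = best_chi2)
}

# --- exhaustive least-squares tree search ----------------------------------
# enumerate every unrooted binary topology on n leaves as an edge list
enum_topologies <- function(n) {
  trees <- list(list(edges = rbind(c(n + 1, 1), c(n + 1, 2), c(n + 1, 3)),
                     next_node = n + 2L))
  if (n == 3) return(trees)
  for (t in 4:n) {
    grown <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        ed <- tr$edges
        w <- tr$next_node
        grown[[length(grown) + 1L]] <- list(
          edges = rbind(ed[-e, , drop = FALSE],
                        c(ed[e, 1], w), c(w, ed[e, 2]), c(w, t)),
          next_node = w + 1L
        )
      }
    }
    trees <- grown
  }
  trees
}

# leaf set on the far side of each edge (logical over leaves 1..n)
edge_sides <- function(edges, n) {
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], e)
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], e)
  }
  other <- function(e, v) if (edges[e, 1] == v) edges[e, 2] else edges[e, 1]
  lapply(seq_len(nrow(edges)), function(e) {
    side <- logical(n)
    # collect leaves reachable from edges[e, 2] without crossing edge e
    stack <- edges[e, 2]
    seen_e <- rep(FALSE, nrow(edges))
    seen_e[e] <- TRUE
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v <= n) side[v] <- TRUE
      for (e2 in adj[[v]]) {
        if (!seen_e[e2]) {
          seen_e[e2] <- TRUE
          stack <- c(stack, other(e2, v))
        }
      }
    }
    side
  })
}

# design matrix: pairs (i<j) x edges, 1 when the edge lies on the i-j path
topology_design <- function(edges, n) {
  sides <- edge_sides(edges, n)
  prs <- utils::combn(n, 2)
  X <- matrix(0, ncol(prs), nrow(edges))
  for (e in seq_along(sides)) {
    s <- sides[[e]]
    X[, e] <- as.numeric(xor(s[prs[1, ]], s[prs[2, ]]))
  }
  X
}

# canonical split signature of a topology (for comparing trees): the sorted
# minority leaf sets of the internal edges
splits_of_edges <- function(edges, n) {
  sides <- edge_sides(edges, n)
  sig <- vapply(sides, function(s) {
    k <- sum(s)
    if (k < 2 || k > n - 2) return(NA_character_)
    if (k > n / 2 || (k == n / 2 && !s[1])) s <- !s
    paste(which(s), collapse = ",")
  }, character(1))
  sort(sig[!is.na(sig)])
}

splits_of_phylo <- function(tree) {
  tree <- ape::unroot(tree)
  n <- ape::Ntip(tree)
  labs <- as.integer(tree$tip.label)
  parts <- ape::prop.part(tree)
  sig <- vapply(parts, function(p) {
    s <- logical(n)
    s[labs[p]] <- TRUE
    k <- sum(s)
    if (k < 2 || k > n - 2) return(NA_character_)
    if (k > n / 2 || (k == n / 2 && !s[1])) s <- !s
    paste(which(s), collapse = ",")
  }, character(1))
  sort(sig[!is.na(sig)])
}

# exhaustive least-squares: the topology (among all on n leaves) whose best
# nonnegative branch-length fit has the smallest residual sum of squares
ls_best_topology <- function(d, topo_cache) {
  n <- nrow(d)
  prs <- utils::combn(n, 2)
  y <- d[cbind(prs[1, ], prs[2, ])]
  best <- NULL
  best_ss <- Inf
  for (tp in topo_cache[[as.character(n)]]) {
    fit <- stats::lm.fit(tp$X, y)
    ss <- sum(fit$residuals^2)
    if (ss < best_ss - 1e-12) {
      best_ss <- ss
      best <- tp
    }
  }
  list(splits = best$splits, ss = best_ss)
}

make_topo_cache <- function(ns) {
  cache <- list()
  for (n in ns) {
    cache[[as.character(n)]] <- lapply(enum_topologies(n), function(tr) {
      list(X = topology_design(tr$edges, n), splits = splits_of_edges(tr$edges, n))
    })
  }
  cache
}

# random unrooted tree with positive branch lengths; returns its additive
# (path-length) distance matrix with sorted integer tip labels
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE, br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- sample(as.character(seq_len(n)))
  d <- stats::cophenetic(tr)
  ord <- as.character(seq_len(n))
  d[ord, ord]
}
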