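test_that("the implied MSA anchors units to profile columns", {
  p <- tiny_profile()
  msa <- implied_msa(p, c(u1 = p$consensus))
  expect_equal(paste(msa[1, ], collapse = ""), p$consensus)
  # a deletion becomes a gap at its column, later columns stay in register
  cons <- strsplit(p$consensus, "")[[1]]
  del <- paste(cons[-30], collapse = "")
  msa2 <- implied_msa(p, c(u1 = del))
  expect_equal(sum(msa2[1, ] == "-"), 1L)
  gap_at <- which(msa2[1, ] == "-")
  expect_equal(msa2[1, (gap_at + 1):p$L], cons[(gap_at + 1):p$L],
               ignore_attr = TRUE)
  # substitutions map to exactly that many differing columns
  mut <- cons
  idx <- c(5L, 18L, 41L)
  for (i in idx) mut[i] <- setdiff(c("A", "C", "G", "T"), mut[i])[1]
  msa3 <- implied_msa(p, c(a = p$consensus, b = paste(mut, collapse = "")))
  expect_equal(sum(msa3[1, ] != msa3[2, ]), length(idx))
  # a fragment covering under half the profile is excluded with a warning
  expect_warning(
    msa4 <- implied_msa(p, c(ok = p$consensus, frag = substr(p$consensus, 1, 20))),
    "excluded")
  expect_equal(rownames(msa4), "ok")
})

test_that("the Jukes-Cantor transform matches its closed form and caps saturation", {
  expect_equal(jc_distance(0), 0, ignore_attr = TRUE)
  expect_equal(jc_distance(0.1), -0.75 * log(1 - 0.4 / 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(unname(jc_distance(0.1)), 0.1073256, tolerance = 1e-6,
               ignore_attr = TRUE)
  d <- jc_distance(0.75)
  expect_equal(unname(as.numeric(d)), 5)
  expect_equal(attr(d, "saturated"), 1L)
  expect_error(jc_distance(-0.1), "\\[0, 1\\]")
  expect_error(jc_distance(1.2), "\\[0, 1\\]")
  p <- seq(0, 0.74, by = 0.01)
  expect_true(all(jc_distance(p) >= p))
})

test_that("neighbor joining recovers additive trees exactly", {
  # the worked 4-taxon case: ((A:1,B:2):1,(C:3,D:1))
  d <- matrix(c(0, 3, 5, 3,
                3, 0, 6, 4,
                5, 6, 0, 4,
                3, 4, 4, 0), 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_equal(stats::cophenetic(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-9)
  ref <- ape::read.tree(text = "((A:1,B:2):1,C:3,D:1);")
  expect_equal(as.numeric(ape::dist.topo(tr, ref)), 0)
  # n = 3 uses the three-point formulas
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- nj_tree(d3)
  lens <- stats::setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(lens[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2)), "at least 3")
  dns <- d
  dns[1, 2] <- 99
  expect_error(nj_tree(dns), "symmetric")
})

test_that("neighbor joining agrees with an independent implementation", {
  set.seed(407)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    d <- random_additive_matrix(n)
    d <- d + matrix(stats::runif(n * n, 0, 0.02), n)
    d <- (d + t(d)) / 2
    diag(d) <- 0
    mine <- nj_tree(d)
    theirs <- ape::nj(d)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(mine), ape::unroot(theirs))), 0)
  }
})

test_that("equal distances still give a deterministic tree", {
  d <- matrix(1, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
})

test_that("bootstrap support separates well-diverged groups and is reproducible", {
  fam <- simulate_unit_family(16, n_lineages = 2, mu = 0.01,
                              lineage_divergence = 0.15, seed = 21)
  msa <- family_msa(fam)
  tr <- bootstrap_support(msa, n_reps = 100, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  # the lineage split is an internal bipartition with near-full support
  cl <- extract_major_clades(tr, min_support = 0.75, min_size = 2)
  expect_equal(nrow(cl$clades), 2L)
  expect_true(all(cl$clades$support >= 0.95))
  # reproducibility and the n_reps = 1 degenerate case
  tr2 <- bootstrap_support(msa, n_reps = 100, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  tr1 <- bootstrap_support(msa, n_reps = 1, seed = 5)
  s1 <- suppressWarnings(as.numeric(tr1$node.label))
  expect_true(all(s1[!is.na(s1)] %in% c(0, 1)))
  # supports are invariant to row permutation of the MSA
  set.seed(6)
  perm <- msa[sample(nrow(msa)), ]
  trp <- bootstrap_support(perm, n_reps = 50, seed = 5)
  clp <- extract_major_clades(trp, min_support = 0.75, min_size = 2)
  expect_equal(
    lapply(split(cl$members$unit, cl$members$clade), sort),
    lapply(split(clp$members$unit, clp$members$clade), sort)
  )
})

test_that("major clades recover planted lineages and respect thresholds", {
  fam <- simulate_unit_family(40, n_lineages = 8, mu = 0.01,
                              lineage_divergence = 0.1, seed = 5)
  msa <- family_msa(fam)
  tr <- bootstrap_support(msa, n_reps = 100, seed = 3)
  cl <- extract_major_clades(tr, min_support = 0.75, min_size = 2)
  expect_equal(nrow(cl$clades), 8L)
  m <- dplyr::left_join(cl$members, fam$labels, by = "unit")
  purity <- m |>
    dplyr::group_by(.data$clade) |>
    dplyr::summarise(p = max(table(.data$lineage)) / dplyr::n())
  expect_true(all(purity$p >= 0.95))
  # a star tree (zero support everywhere) yields no major clades
  star <- tr
  star$node.label <- rep("0", length(star$node.label))
  none <- extract_major_clades(star, min_support = 0.75, min_size = 2)
  expect_equal(nrow(none$clades), 0L)
  expect_length(none$unplaced, ape::Ntip(tr))
  # support exactly at the threshold is not enough (strict reading of >75%)
  att <- tr
  att$node.label <- rep("0.75", length(att$node.label))
  expect_equal(nrow(extract_major_clades(att, 0.75, 2)$clades), 0L)
})
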