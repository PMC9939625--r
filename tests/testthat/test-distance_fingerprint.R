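test_that("allele differences: identity, single difference, missing skip", {
  gm <- gm_from_strings(
    list(A = c("1/2", "3/3"), B = c("1/2", "3/3"),
         C = c("1/3", "3/3"), D = c("NA/NA", "3/4")),
    c("L1", "L2"))
  same <- allele_diff(gm, "A", "B")
  expect_equal(same$allele_differences, 0L)
  expect_false(same$distinguishable)

  one <- allele_diff(gm, "A", "C")  # 1/2 vs 1/3 -> one allele
  expect_equal(one$allele_differences, 1L)
  expect_equal(one$loci_different, 1L)
  expect_false(one$distinguishable)          # threshold 2
  expect_true(allele_diff(gm, "A", "C", threshold = 1L)$distinguishable)

  # missing locus skipped: only L2 compared
  ad <- allele_diff(gm, "A", "D")
  expect_equal(ad$loci_compared, 1L)
  expect_equal(ad$allele_differences, 1L)   # 3/3 vs 3/4

  none <- gm_from_strings(list(A = c("1/1"), B = c("NA/NA")), "L1")
  expect_error(allele_diff(none, "A", "B"), "co-typed")
})

test_that("pairwise allele differences match the brute-force oracle", {
  set.seed(5)
  for (rep in 1:25) {
    gm <- random_gm(10, 5, n_alleles = 3, missing = 0.15)
    adm <- allele_diff_matrix(gm)
    for (pair in list(c(1, 2), c(3, 9), c(4, 10), c(5, 6))) {
      i <- pair[1]; j <- pair[2]
      expected <- 0
      compared <- 0
      for (l in gm$loci) {
        pa <- c(gm$a1[i, l], gm$a2[i, l])
        pb <- c(gm$a1[j, l], gm$a2[j, l])
        if (anyNA(pa) || anyNA(pb)) next
        compared <- compared + 1
        expected <- expected + allele_diff_bruteforce(pa, pb)
      }
      expect_equal(adm$diffs[i, j], expected)
      expect_equal(adm$compared[i, j], compared)
    }
  }
})

test_that("Nei distance: identity, hand example, cap, symmetry", {
  gm <- gm_from_strings(list(A = "a/a", B = "a/a"), "L1")
  expect_equal(unname(nei_distance(gm)["A", "B"]), 0)

  # one locus, A/A vs A/B: Jxy = 0.5, Jx = 1, Jy = 0.5
  gm2 <- gm_from_strings(list(X = "a/a", Y = "a/b"), "L1")
  expect_equal(unname(nei_distance(gm2)["X", "Y"]),
               -log(0.5 / sqrt(0.5)), tolerance = 1e-12)

  gm3 <- gm_from_strings(list(X = "a/a", Y = "b/b"), "L1")
  expect_warning(d3 <- nei_distance(gm3), "capped")
  expect_equal(unname(d3["X", "Y"]), 10)

  set.seed(9)
  gm4 <- random_gm(12, 6)
  d4 <- suppressWarnings(nei_distance(gm4))
  expect_equal(unclass(d4), t(unclass(d4)), tolerance = 1e-12)
  expect_true(all(diag(d4) == 0))
  expect_true(all(d4 >= 0))
})

test_that("Nei distance against an independent per-pair computation", {
  set.seed(77)
  for (rep in 1:20) {
    gm <- random_gm(6, 4, missing = 0.1)
    nd <- suppressWarnings(nei_distance(gm))
    i <- sample(6, 1); j <- sample(setdiff(1:6, i), 1)
    jxy <- jx <- jy <- 0
    for (l in gm$loci) {
      pa <- c(gm$a1[i, l], gm$a2[i, l])
      pb <- c(gm$a1[j, l], gm$a2[j, l])
      if (anyNA(pa) || anyNA(pb)) next
      alleles <- unique(c(pa, pb))
      x <- vapply(alleles, function(al) mean(pa == al), 0.0)
      y <- vapply(alleles, function(al) mean(pb == al), 0.0)
      jxy <- jxy + sum(x * y)
      jx <- jx + sum(x^2)
      jy <- jy + sum(y^2)
    }
    expected <- if (jxy == 0) 10 else max(0, -log(jxy / sqrt(jx * jy)))
    expect_equal(unname(nd[i, j]), expected, tolerance = 1e-12)
  }
})

test_that("UPGMA: two leaves, clones as zero-height sisters, ultrametric", {
  dm <- matrix(c(0, 0.8, 0.8, 0), 2, 2,
               dimnames = list(c("A", "B"), c("A", "B")))
  tr <- upgma(dm)
  expect_equal(tr$height, 0.8)  # merge distance; node height = d/2
  phy <- ape::read.tree(text = upgma_newick(tr))
  expect_equal(sort(phy$tip.label), c("A", "B"))
  expect_equal(phy$edge.length, c(0.4, 0.4))

  set.seed(31)
  gm <- random_gm(8, 6)
  gm <- clone_pairs(gm, 1, 0, seed = 4)
  nd <- suppressWarnings(nei_distance(gm))
  tr2 <- upgma(nd)
  cl <- attr(gm, "clones")
  # the clone pair merges first at height 0
  expect_equal(tr2$height[1], 0)
  expect_equal(upgma_merge_sets(tr2)[[1]],
               sort(c(cl$source, cl$clone)))

  # ultrametric: all root-to-leaf depths equal
  phy2 <- ape::read.tree(text = upgma_newick(tr2))
  depths <- ape::node.depth.edgelength(phy2)[seq_along(phy2$tip.label)]
  expect_lt(diff(range(depths)), 1e-9)

  # heights are monotone non-decreasing along the merge sequence
  expect_true(all(diff(tr2$height) >= -1e-12))

  dm_bad <- dm; dm_bad[1, 2] <- NA
  expect_error(upgma(dm_bad), "NA")
})

test_that("UPGMA equals the brute-force average-linkage oracle", {
  set.seed(13)
  for (rep in 1:40) {
    n <- sample(4:7, 1)
    m <- matrix(runif(n * n), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(LETTERS[1:n], LETTERS[1:n])
    tr <- upgma(m)
    oracle <- upgma_bruteforce(m)
    expect_equal(tr$height, oracle$heights, tolerance = 1e-9)
    expect_equal(upgma_merge_sets(tr), oracle$merges)
  }
})

test_that("UPGMA heights agree with hclust average linkage", {
  set.seed(19)
  n <- 12
  m <- as.matrix(dist(matrix(rnorm(n * 3), n)))
  dimnames(m) <- list(letters[1:n], letters[1:n])
  tr <- upgma(m)
  hc <- hclust(as.dist(m), method = "average")
  expect_equal(sort(tr$height), sort(hc$height), tolerance = 1e-9)
})

test_that("discrimination rate formula and bounds", {
  expect_equal(discrimination_rate(423, 5),
               ((423 * 422) / 2 - 5) / ((423 * 422) / 2))
  expect_equal(discrimination_rate(100, 0), 1.0)
  expect_equal(discrimination_rate(4, 6), 0.0)
  expect_error(discrimination_rate(4, 7), "exceeds")
  expect_error(discrimination_rate(10, -1), ">= 0")
})

test_that("undistinguished groups: triangle, empty case, clone truth", {
  # three mutually identical varieties -> one group of 3, U = 3
  gm <- gm_from_strings(
    list(A = c("1/2", "1/1"), B = c("1/2", "1/1"), C = c("1/2", "1/1"),
         D = c("5/6", "2/3"), E = c("7/8", "4/5")),
    c("L1", "L2"))
  ug <- undistinguished_groups(gm, threshold = 2)
  expect_equal(length(ug$groups), 1L)
  expect_equal(ug$groups[[1]], c("A", "B", "C"))
  expect_equal(ug$n_pairs, 3L)

  set.seed(55)
  clean <- random_gm(20, 8, n_alleles = 6)
  expect_equal(length(undistinguished_groups(clean)$groups), 0L)
  expect_equal(undistinguished_groups(clean)$n_pairs, 0L)

  with_clones <- clone_pairs(clean, 2, 1, seed = 6)
  ug2 <- undistinguished_groups(with_clones, threshold = 2)
  cl <- attr(with_clones, "clones")
  expect_equal(length(ug2$groups), 2L)
  expect_equal(ug2$n_pairs, 2L)
  flagged <- lapply(ug2$groups, identity)
  expected <- lapply(seq_len(2), function(i)
    sort(c(cl$source[i], cl$clone[i])))
  expect_setequal(vapply(flagged, paste, "", collapse = "|"),
                  vapply(expected, paste, "", collapse = "|"))
})

test_that("threshold monotonicity: higher threshold never lowers U", {
  set.seed(66)
  gm <- clone_pairs(random_gm(15, 5, n_alleles = 3), 2, 1, seed = 2)
  us <- vapply(1:6, function(th)
    undistinguished_groups(gm, th)$n_pairs, 0L)
  expect_true(all(diff(us) >= 0))
})

test_that("similar-variety screening ranks an injected clone first", {
  set.seed(23)
  gm <- random_gm(15, 8, n_alleles = 6)
  gm2 <- clone_pairs(gm, 1, 1, seed = 3)
  cl <- attr(gm2, "clones")
  res <- similar_varieties(gm2, cl$clone, k = 3)
  expect_equal(res$variety[1], cl$source)
  expect_false(res$distinguishable[1])
  # self excluded; k larger than the database returns everyone else
  res_all <- similar_varieties(gm2, cl$clone, k = 100)
  expect_equal(nrow(res_all), length(gm2$varieties) - 1L)
  expect_false(cl$clone %in% res_all$variety)
})
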