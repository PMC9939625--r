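test_that("K = 1 is the degenerate pooled-frequency model", {
  sim <- simulate_genotypes(K = 1, n_per_pop = 40, n_loci = 6,
                            fst = 0.05, missing_rate = 0, seed = 81)
  fit <- admixture_gibbs(sim$genotypes, K = 1, burn_in = 100,
                         mcmc = 300, seed = 82)
  expect_true(all(fit$q == 1))
  # lnP(D) close to the multinomial log-likelihood at pooled
  # frequencies: the MLE bounds it above; posterior sampling sits below
  # by an amount on the order of the free parameter count
  ll_pooled <- sum(vapply(sim$genotypes$loci, function(l) {
    spec <- allele_frequencies(sim$genotypes, l)
    counts <- spec$freqs * 2 * spec$n_typed
    sum(counts * log(spec$freqs))
  }, 0.0))
  n_par <- sum(vapply(sim$genotypes$loci, function(l) {
    length(allele_frequencies(sim$genotypes, l)$freqs) - 1
  }, 0.0))
  expect_lte(fit$lnpd, ll_pooled + 1)
  expect_gte(fit$lnpd, ll_pooled - 3 * n_par - 10)
})

test_that("identical individuals get identical ancestry within MC error", {
  set.seed(83)
  gm <- random_gm(12, 8, n_alleles = 5)
  gm2 <- clone_pairs(gm, 1, 0, seed = 84)
  cl <- attr(gm2, "clones")
  fit <- admixture_gibbs(gm2, K = 2, burn_in = 200, mcmc = 800,
                         seed = 85)
  expect_lt(max(abs(fit$q[cl$source, ] - fit$q[cl$clone, ])), 0.1)
  expect_equal(rowSums(fit$q), setNames(rep(1, 13), gm2$varieties),
               tolerance = 1e-12)
})

test_that("likelihood trace is finite and stationary at desk scale", {
  sim <- simulate_genotypes(K = 2, n_per_pop = 25, n_loci = 10,
                            fst = 0.15, selfing = 0, seed = 86)
  fit <- admixture_gibbs(sim$genotypes, K = 2, burn_in = 300,
                         mcmc = 1000, seed = 87)
  tr <- fit$lnl_trace
  expect_true(all(is.finite(tr)))
  h1 <- tr[1:500]; h2 <- tr[501:1000]
  pooled_se <- sqrt(var(h1) / 500 + var(h2) / 500)
  # no drift: first/second half means within a generous MC band
  expect_lt(abs(mean(h1) - mean(h2)), 12 * pooled_se + 2)
})

test_that("admixture errors on impossible inputs", {
  gm <- gm_from_strings(list(A = "1/2", B = "1/1"), "L1")
  expect_error(admixture_gibbs(gm, K = 5), "exceeds")
  gm_miss <- gm_from_strings(list(A = "1/2", B = "NA/NA"), "L1")
  expect_error(admixture_gibbs(gm_miss, K = 1), "all-missing")
})

test_that("evanno: hand-computed curvature example picks K = 2", {
  lnpd <- expand.grid(K = 1:4, replicate = 1:2)
  lnpd$lnpd <- c(-100, -50, -48, -47)[lnpd$K]
  ev <- evanno_delta_k(lnpd, sd_floor = 1e-6)
  # curvatures: K2 |(-48) - 2(-50) + (-100)| = 48; K3 = 1
  expect_equal(ev$table$delta_k[2] * 1e-6, 48)
  expect_equal(ev$table$delta_k[3] * 1e-6, 1)
  expect_equal(ev$K_star, 2)
  # with sd = 0 and no floor, delta K is undefined everywhere
  ev0 <- evanno_delta_k(lnpd)
  expect_true(all(is.na(ev0$table$delta_k)))
  expect_true(is.na(ev0$K_star))
})

test_that("evanno: linear lnP(D) is flagged unreliable, scale-invariant", {
  set.seed(88)
  lnpd <- expand.grid(K = 1:5, replicate = 1:4)
  lnpd$lnpd <- -1000 + 10 * lnpd$K + rnorm(nrow(lnpd), 0, 0.5)
  ev <- evanno_delta_k(lnpd)
  expect_false(ev$reliable)
  shifted <- lnpd
  shifted$lnpd <- shifted$lnpd + 5000
  expect_equal(evanno_delta_k(shifted)$table$delta_k,
               ev$table$delta_k, tolerance = 1e-9)
  expect_error(evanno_delta_k(lnpd[lnpd$K %in% c(1, 3, 5), ]),
               "contiguous")
})

test_that("ancestry recovery on 3-deme data (accuracy >= 0.9)", {
  sim <- simulate_genotypes(K = 3, n_per_pop = 67, n_loci = 23,
                            fst = 0.15, selfing = 0, admixture_alpha = 0,
                            missing_rate = 0.02, seed = 89)
  fit <- admixture_gibbs(sim$genotypes, K = 3, burn_in = 300,
                         mcmc = 1200, seed = 90)
  expect_gte(assignment_accuracy(fit$q, sim$labels), 0.9)
})

test_that("align_q undoes a column permutation", {
  set.seed(91)
  q <- matrix(rgamma(30, 1), 10, 3)
  q <- q / rowSums(q)
  rownames(q) <- sprintf("V%02d", 1:10)
  perm <- c(3, 1, 2)
  expect_equal(unname(align_q(q[, perm], q)), unname(q))
})

test_that("PCA: mirrored clusters, duplicates, SVD oracle", {
  sim <- simulate_genotypes(K = 2, n_per_pop = 20, n_loci = 10,
                            fst = 0.3, selfing = 0, missing_rate = 0,
                            seed = 92)
  pc <- pca_genotypes(sim$genotypes)
  expect_true(all(pc$explained >= 0))
  expect_lte(sum(pc$explained), 1 + 1e-9)
  # PC1 separates the two demes
  side <- split(pc$coords[, 1], sim$labels[rownames(pc$coords)])
  expect_true(max(side$pop1) < min(side$pop2) ||
                max(side$pop2) < min(side$pop1))

  # duplicated variety maps to identical coordinates
  gm2 <- clone_pairs(sim$genotypes, 1, 0, seed = 93)
  cl <- attr(gm2, "clones")
  pc2 <- pca_genotypes(gm2)
  expect_equal(pc2$coords[cl$source, ], pc2$coords[cl$clone, ],
               tolerance = 1e-9)

  # eigendecomposition agrees with an SVD of the centered matrix
  sv <- svd(pc$dosage)
  ev_svd <- sv$d^2 / (nrow(pc$dosage) - 1)
  ev_ours <- pc$explained * sum(ev_svd)
  k <- length(ev_ours)
  expect_equal(ev_ours, ev_svd[seq_len(k)], tolerance = 1e-9)
  expect_equal(abs(pc$coords[, 1]),
               abs(sv$u[, 1] * sv$d[1]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("AMOVA: fixed demes give ~100% among-population variance", {
  gm <- gm_from_strings(
    list(A = c("1/1", "3/3"), B = c("1/1", "3/3"),
         C = c("2/2", "4/4"), D = c("2/2", "4/4")),
    c("L1", "L2"))
  labels <- c(A = "p1", B = "p1", C = "p2", D = "p2")
  res <- amova(gm, labels, n_perm = 99, seed = 94)
  pct <- res$components$percent
  expect_equal(pct[res$components$stratum == "among_populations"], 100)
  expect_equal(res$phi_st, 1)
})

test_that("AMOVA components sum to the total and percentages to 100", {
  set.seed(95)
  gm <- random_gm(24, 6, missing = 0.05)
  labels <- setNames(rep(c("x", "y", "z"), each = 8), gm$varieties)
  res <- amova(gm, labels, n_perm = 0)
  comp <- res$components
  strata <- comp[comp$stratum != "total", ]
  expect_equal(sum(strata$SS), comp$SS[comp$stratum == "total"],
               tolerance = 1e-9)
  expect_equal(sum(strata$percent), 100, tolerance = 0.01)
  # invariance to allele relabeling
  map <- setNames(paste0("z", 1:8),
                  sort(unique(c(gm$a1[, 1], gm$a2[, 1]))))
  a1 <- gm$a1; a2 <- gm$a2
  a1[, 1] <- map[a1[, 1]]; a2[, 1] <- map[a2[, 1]]
  res2 <- amova(genotype_matrix(a1, a2), labels, n_perm = 0)
  expect_equal(res2$components$variance, res$components$variance,
               tolerance = 1e-9)
})

test_that("AMOVA null: random labels give small Phi and non-extreme p", {
  set.seed(96)
  sim <- simulate_genotypes(K = 1, n_per_pop = 45, n_loci = 8,
                            fst = 0.02, seed = 97)
  labels <- setNames(sample(rep(c("a", "b", "c"), 15)),
                     sim$genotypes$varieties)
  res <- amova(sim$genotypes, labels, n_perm = 199, seed = 98)
  expect_lt(res$phi_st, 0.05)
  expect_gt(res$p_value, 0.01)
})

test_that("AMOVA detects structured data with significant Phi", {
  sim <- simulate_genotypes(K = 3, n_per_pop = 30, n_loci = 12,
                            fst = 0.2, seed = 99)
  res <- amova(sim$genotypes, sim$labels, n_perm = 199, seed = 100)
  expect_gt(res$phi_st, 0.05)
  expect_lt(res$p_value, 0.02)
  expect_error(amova(sim$genotypes,
                     setNames(rep("one", 90), sim$genotypes$varieties)),
               "two populations")
})
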