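# Model-based admixture inference (Gibbs sampler), Evanno delta-K model
# choice, genotype PCA and AMOVA.

#' Admixture inference for one K by Gibbs sampling
#'
#' Fits the standard no-admixture-prior-structure model: each allele copy
#' has a latent deme of origin drawn from the individual's ancestry
#' vector `q_i ~ Dirichlet(alpha)`; deme allele frequencies carry
#' symmetric `Dirichlet(lambda)` priors. The marginal data likelihood
#' `ln P(D)` is estimated from the post-burn-in log-likelihood trace as
#' `mean(lnL) - var(lnL)/2` (the harmonic-style estimator used by the
#' classic structure software). Missing calls contribute nothing.
#'
#' @param gm an `ssr_genotypes` object.
#' @param K number of demes (1 <= K <= number of varieties).
#' @param burn_in discarded sweeps (desk-scale default 500).
#' @param mcmc retained sweeps (desk-scale default 2000). Classic
#'   full-scale runs use 5000 / 50000; see [structure_preset()].
#' @param alpha_prior Dirichlet concentration on ancestry (default 1).
#' @param lambda Dirichlet concentration on frequencies (default 1).
#' @param seed integer seed.
#' @return A list of class `admixture_fit`: `K`, `q` (variety x K
#'   posterior-mean ancestry, rows sum to 1), `lnpd` (ln P(D) estimate),
#'   `lnl_trace`, `p_mean` (per-locus posterior-mean frequencies).
#' @export
admixture_gibbs <- function(gm, K, burn_in = 500L, mcmc = 2000L,
                            alpha_prior = 1.0, lambda = 1.0, seed = NULL) {
  stopifnot(burn_in >= 0, mcmc >= 1, alpha_prior > 0, lambda > 0)
  if (K > length(gm$varieties)) {
    stop("K exceeds the number of varieties")
  }
  all_missing <- rowSums(!is.na(gm$a1)) == 0
  if (any(all_missing)) {
    stop("all-missing individual(s): ",
         paste(gm$varieties[all_missing], collapse = ", "))
  }
  if (!is.null(seed)) set.seed(seed)
  enc <- .encode_alleles(gm)
  n_alleles <- vapply(gm$loci, function(l) {
    length(unique(stats::na.omit(c(gm$a1[, l], gm$a2[, l]))))
  }, 0L)
  res <- .admixture_gibbs_cpp(enc$a1 - 1L, enc$a2 - 1L, n_alleles,
                              as.integer(K),
                              as.integer(burn_in), as.integer(mcmc),
                              alpha_prior, lambda)
  q <- res$q_mean
  q <- q / rowSums(q)
  dimnames(q) <- list(gm$varieties, paste0("K", seq_len(K)))
  lnl <- res$lnl
  structure(list(K = K, q = q, lnpd = mean(lnl) - var(lnl) / 2,
                 lnl_trace = lnl, p_mean = res$p_mean),
            class = "admixture_fit")
}

#' Replicated admixture runs over a K range
#'
#' Runs [admixture_gibbs()] `replicates` times per K and collects the
#' `ln P(D)` estimates (the input to [evanno_delta_k()]) and, per K, the
#' replicate-averaged ancestry matrix after greedy label alignment.
#'
#' @param gm an `ssr_genotypes` object.
#' @param K_range contiguous integer vector of K values.
#' @param replicates runs per K (>= 2 for the Evanno statistic).
#' @param seed integer seed; replicate r of K uses a sub-seed derived
#'   from it deterministically.
#' @param ... passed to [admixture_gibbs()].
#' @return A list of class `structure_scan`: `lnpd` (data.frame K,
#'   replicate, lnpd), `q_by_k` (list of averaged Q matrices), `K_range`.
#' @export
structure_scan <- function(gm, K_range = 1:6, replicates = 5L,
                           seed = NULL, ...) {
  stopifnot(replicates >= 1)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- matrix(sample.int(.Machine$integer.max %/% 2,
                                 length(K_range) * replicates),
                      nrow = length(K_range))
  rows <- list()
  q_by_k <- list()
  for (ki in seq_along(K_range)) {
    K <- K_range[ki]
    qacc <- NULL
    qref <- NULL
    for (r in seq_len(replicates)) {
      fit <- admixture_gibbs(gm, K, seed = sub_seeds[ki, r], ...)
      rows[[length(rows) + 1L]] <-
        data.frame(K = K, replicate = r, lnpd = fit$lnpd)
      qa <- fit$q
      if (is.null(qref)) {
        qref <- qa
        qacc <- qa
      } else {
        qacc <- qacc + align_q(qa, qref)
      }
    }
    q_by_k[[as.character(K)]] <- qacc / replicates
  }
  structure(list(lnpd = do.call(rbind, rows), q_by_k = q_by_k,
                 K_range = K_range),
            class = "structure_scan")
}

#' Align ancestry-matrix columns across runs
#'
#' Label switching between replicate runs is resolved by greedily
#' matching columns on correlation against a reference matrix.
#'
#' @param q,q_ref ancestry matrices with the same dimensions.
#' @return `q` with columns permuted to best match `q_ref`.
#' @export
align_q <- function(q, q_ref) {
  K <- ncol(q)
  if (K == 1L) return(q)
  cc <- suppressWarnings(cor(q, q_ref))  # rows: columns of q; cols: of ref
  cc[!is.finite(cc)] <- 0
  perm <- integer(K)      # perm[target] = source column of q
  src_used <- rep(FALSE, K)
  tgt_used <- rep(FALSE, K)
  for (step in seq_len(K)) {
    # greedy Hungarian-style: best remaining (source, target) pair
    masked <- cc
    masked[src_used, ] <- -Inf
    masked[, tgt_used] <- -Inf
    pick <- which(masked == max(masked), arr.ind = TRUE)[1, ]
    perm[pick[2]] <- pick[1]
    src_used[pick[1]] <- TRUE
    tgt_used[pick[2]] <- TRUE
  }
  out <- q[, perm, drop = FALSE]
  colnames(out) <- colnames(q_ref)
  out
}

#' Evanno delta-K statistic and model choice
#'
#' `deltaK(K) = mean_reps |L(K+1) - 2 L(K) + L(K-1)| / sd_reps(L(K))`;
#' the chosen `K*` maximizes deltaK over interior K. Where the replicate
#' standard deviation is 0 the statistic is undefined and that K is
#' excluded (set `sd_floor > 0` to clamp instead). Under a flat or
#' linear `L(K)` (no curvature signal) the statistic hovers around 2 —
#' the expectation of `|second difference| / sd` for pure replicate
#' noise — so a maximum delta-K below `delta_min` flags `K*` as
#' unreliable.
#'
#' @param lnpd data.frame with columns `K`, `replicate`, `lnpd` (as
#'   produced by [structure_scan()]), covering a contiguous K range of at
#'   least 3 values with 2+ replicates each (1 allowed with `sd_floor`).
#' @param sd_floor lower clamp for the replicate sd (default 0).
#' @param delta_min smallest max-delta-K considered a real signal
#'   (default 10, an order above the noise-only level).
#' @return A list of class `evanno`: `table` (K, mean_lnpd, sd_lnpd,
#'   delta_k), `K_star`, `reliable`.
#' @export
evanno_delta_k <- function(lnpd, sd_floor = 0, delta_min = 10) {
  ks <- sort(unique(lnpd$K))
  if (length(ks) < 3L) stop("need >= 3 contiguous K values")
  if (any(diff(ks) != 1L)) stop("K range must be contiguous")
  mean_l <- tapply(lnpd$lnpd, lnpd$K, mean)[as.character(ks)]
  sd_l <- tapply(lnpd$lnpd, lnpd$K, sd)[as.character(ks)]
  sd_l[is.na(sd_l)] <- 0
  # per-replicate second differences, averaged as |.|
  reps <- split(lnpd, lnpd$replicate)
  curv <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    vals <- vapply(reps, function(df) {
      l <- setNames(df$lnpd, df$K)
      kk <- as.character(ks[i] + c(-1, 0, 1))
      if (!all(kk %in% names(l))) return(NA_real_)
      abs(l[kk[3]] - 2 * l[kk[2]] + l[kk[1]])
    }, 0.0)
    curv[i] <- mean(vals, na.rm = TRUE)
  }
  sd_eff <- pmax(sd_l, sd_floor)
  delta <- curv / sd_eff
  delta[sd_eff == 0] <- NA_real_
  tab <- data.frame(K = ks, mean_lnpd = as.numeric(mean_l),
                    sd_lnpd = as.numeric(sd_l), delta_k = delta)
  interior <- !is.na(delta)
  k_star <- if (any(interior)) ks[which.max(ifelse(interior, delta, -Inf))]
            else NA_integer_
  reliable <- any(interior) && max(delta[interior]) >= delta_min
  # maximum-mean-likelihood selector reported alongside
  k_maxl <- ks[which.max(mean_l)]
  structure(list(table = tab, K_star = k_star, reliable = reliable,
                 K_max_lnpd = k_maxl),
            class = "evanno")
}

#' Accuracy of hard assignments against true labels
#'
#' Maximum over label permutations (K <= 8) of the fraction of
#' individuals whose max-Q deme matches their true population.
#'
#' @param q ancestry matrix (varieties x K).
#' @param labels named true population labels.
#' @return Accuracy in `[0, 1]`.
#' @export
assignment_accuracy <- function(q, labels) {
  labels <- labels[rownames(q)]
  hard <- max.col(q, ties.method = "first")
  true <- as.integer(factor(unname(labels)))
  K <- max(ncol(q), max(true))
  if (K > 8L) stop("permutation search supported for K <= 8")
  perms <- .permutations(K)
  best <- 0
  for (p in perms) {
    best <- max(best, mean(p[hard] == true))
  }
  best
}

.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (p in .permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Principal component analysis of SSR genotypes
#'
#' One-hot allele dosage encoding (one column per observed allele,
#' values 0/1/2), missing dosages imputed with the column mean, columns
#' centered; coordinates and explained-variance fractions come from the
#' eigendecomposition of the covariance matrix.
#'
#' @param gm an `ssr_genotypes` object.
#' @param n_axes number of axes to return (default all informative).
#' @return A list of class `ssr_pca`: `coords` (varieties x axes),
#'   `explained` (fractions of total variance), `dosage` (the centered
#'   matrix used).
#' @export
pca_genotypes <- function(gm, n_axes = NULL) {
  X <- genotype_dosage(gm)
  # mean-impute missing, then center
  for (j in seq_len(ncol(X))) {
    mis <- is.na(X[, j])
    if (any(mis)) X[mis, j] <- mean(X[!mis, j])
  }
  X <- scale(X, center = TRUE, scale = FALSE)
  cv <- crossprod(X) / (nrow(X) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-12
  vecs <- eg$vectors[, pos, drop = FALSE]
  vals <- eg$values[pos]
  coords <- X %*% vecs
  if (!is.null(n_axes)) {
    n_axes <- min(n_axes, ncol(coords))
    coords <- coords[, seq_len(n_axes), drop = FALSE]
    vals_keep <- vals[seq_len(n_axes)]
  } else {
    vals_keep <- vals
  }
  colnames(coords) <- paste0("PC", seq_len(ncol(coords)))
  rownames(coords) <- gm$varieties
  structure(list(coords = coords,
                 explained = vals_keep / sum(eg$values[eg$values > 0]),
                 dosage = X),
            class = "ssr_pca")
}

#' Allele dosage matrix
#'
#' @param gm an `ssr_genotypes` object.
#' @return Numeric matrix, varieties x (locus, allele) columns, entries
#'   0/1/2 (copies of that allele) or `NA` for missing calls.
#' @export
genotype_dosage <- function(gm) {
  cols <- list()
  for (l in gm$loci) {
    alleles <- sort(unique(stats::na.omit(c(gm$a1[, l], gm$a2[, l]))))
    for (al in alleles) {
      d <- (gm$a1[, l] == al) + (gm$a2[, l] == al)
      cols[[paste(l, al, sep = ".")]] <- as.numeric(d)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- gm$varieties
  out
}

#' Analysis of molecular variance (AMOVA)
#'
#' Hierarchical partition of allele-level variation into among
#' populations, among individuals within populations, and within
#' individuals, using per-locus sums of squares on 0/1 allele mismatch
#' distances and method-of-moments variance components. Loci are summed;
#' at each locus only copies typed there enter (so the SS partition
#' identity holds exactly with missing data). Significance of the
#' among-population component (Phi-ST) is assessed by permuting
#' individuals among populations.
#'
#' @param gm an `ssr_genotypes` object.
#' @param labels named population labels (>= 2 populations).
#' @param n_perm permutations for the Phi-ST test (default 999; 0 skips).
#' @param seed integer seed for the permutations.
#' @return A list of class `amova_table`: `components` (data.frame of
#'   strata: df, SS, MS, variance, percent), `phi_st`, `p_value`.
#' @export
amova <- function(gm, labels, n_perm = 999L, seed = NULL) {
  labels <- labels[names(labels) %in% gm$varieties]
  if (length(unique(unname(labels))) < 2L) {
    stop("need at least two populations")
  }
  if (!is.null(seed)) set.seed(seed)
  sizes <- table(unname(labels))
  if (any(sizes < 2)) {
    warning("population(s) of size 1 (",
            paste(names(sizes)[sizes < 2], collapse = ", "),
            "): the among-individuals-within stratum is degenerate there")
  }
  base <- .amova_components(gm, labels)
  p_val <- NA_real_
  if (n_perm > 0L) {
    obs <- base$phi_st
    cnt <- 0L
    vs <- names(labels)
    for (b in seq_len(n_perm)) {
      perm <- setNames(sample(unname(labels)), vs)
      if (.amova_components(gm, perm, quick = TRUE)$phi_st >= obs) {
        cnt <- cnt + 1L
      }
    }
    p_val <- (1 + cnt) / (n_perm + 1)
  }
  structure(c(base, list(p_value = p_val)), class = "amova_table")
}

.amova_components <- function(gm, labels, quick = FALSE) {
  vs <- names(labels)
  pops <- unique(unname(labels))
  P <- length(pops)
  N <- length(vs)
  n_p <- as.integer(table(factor(unname(labels), levels = pops)))
  ss_tot <- ss_wp <- ss_wi <- 0
  for (l in gm$loci) {
    a1 <- gm$a1[vs, l]; a2 <- gm$a2[vs, l]
    keep <- !is.na(a1)
    if (!any(keep)) next
    copies <- c(a1[keep], a2[keep])
    grp_all <- rep(unname(labels)[keep], 2L)
    ss_group <- function(x) {
      # (1/m) * sum_{i<j} d2_ij for 0/1 mismatch = (m^2 - sum c_a^2)/(2m)
      m <- length(x)
      if (m < 2L) return(0)
      cnt <- table(x)
      (m^2 - sum(cnt^2)) / (2 * m)
    }
    ss_tot <- ss_tot + ss_group(copies)
    for (p in pops) {
      ss_wp <- ss_wp + ss_group(copies[grp_all == p])
    }
    # within individuals: each het contributes (1/2)*1
    ss_wi <- ss_wi + sum(a1[keep] != a2[keep]) / 2
  }
  ss_ap <- ss_tot - ss_wp
  ss_ai <- ss_wp - ss_wi
  df_ap <- P - 1L
  df_ai <- N - P
  df_wi <- N
  ms_ap <- ss_ap / df_ap
  ms_ai <- ss_ai / df_ai
  ms_wi <- ss_wi / df_wi
  # coefficient for the among-pop component: individuals per pop,
  # 2 copies each (balanced at the copy level within individuals)
  n_c <- (N - sum(n_p^2) / N) / (P - 1)
  sig_wi <- ms_wi
  sig_ai <- (ms_ai - ms_wi) / 2
  sig_ap <- (ms_ap - ms_ai) / (2 * n_c)
  clamped <- c(ap = sig_ap < 0, ai = sig_ai < 0)
  sig <- c(ap = max(sig_ap, 0), ai = max(sig_ai, 0), wi = max(sig_wi, 0))
  tot <- sum(sig)
  phi <- if (tot > 0) sig[["ap"]] / tot else NA_real_
  if (quick) return(list(phi_st = phi))
  comp <- data.frame(
    stratum = c("among_populations", "among_individuals_within",
                "within_individuals", "total"),
    df = c(df_ap, df_ai, df_wi, df_ap + df_ai + df_wi),
    SS = c(ss_ap, ss_ai, ss_wi, ss_tot),
    MS = c(ms_ap, ms_ai, ms_wi, NA),
    variance = c(sig[["ap"]], sig[["ai"]], sig[["wi"]], tot),
    percent = 100 * c(sig[["ap"]], sig[["ai"]], sig[["wi"]], tot) /
      ifelse(tot > 0, tot, NA)
  )
  list(components = comp, phi_st = phi,
       raw_components = c(ap = sig_ap, ai = sig_ai, wi = sig_wi),
       clamped = clamped)
}

#' Classic full-scale structure run settings
#'
#' The run design used for full variety collections: K = 1-10, 20
#' replicates per K, 5,000 burn-in sweeps and 50,000 retained sweeps.
#' Desk-scale analyses use [structure_scan()]'s defaults instead.
#'
#' @return A list: `K_range`, `replicates`, `burn_in`, `mcmc`.
#' @export
structure_preset <- function() {
  list(K_range = 1:10, replicates = 20L, burn_in = 5000L, mcmc = 50000L)
}
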