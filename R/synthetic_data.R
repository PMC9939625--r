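# Seeded generators for SSR genotype and morphological trait data with
# the population structure the downstream analyses assume (the F-model),
# so every stage of the pipeline is testable against known truth.

.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = alpha, rate = 1),
              nrow = n, byrow = TRUE)
  # guard: all-zero draws (tiny alpha) fall back to a random vertex
  zero <- rowSums(x) == 0
  if (any(zero)) {
    vi <- sample.int(k, sum(zero), replace = TRUE)
    x[zero, ] <- 0
    x[cbind(which(zero), vi)] <- 1
  }
  x / rowSums(x)
}

#' Simulate codominant SSR genotypes under the F-model
#'
#' Ancestral allele frequencies per locus are drawn from a symmetric
#' Dirichlet; each subpopulation's frequencies from
#' `Dirichlet(p_anc * (1 - F) / F)`, so `F` is the expected Wright-style
#' differentiation among demes. Individuals draw two allele copies from
#' their own subpopulation, or — when `admixture_alpha > 0` — from demes
#' sampled via an individual ancestry vector `Q ~ Dirichlet(alpha)`.
#' With probability `selfing` the second copy duplicates the first
#' (generating the heterozygote deficit, Ho < He, typical of inbred-line
#' variety collections). Calls are masked to missing at `missing_rate`.
#'
#' Defaults emulate a variety-registration collection: 3 subpopulations
#' of 141 varieties (423 total) typed at the 23-marker core panel, 5-40
#' alleles per locus, differentiation F = 0.13, selfing 0.5, 2% missing.
#'
#' @param K number of subpopulations.
#' @param n_per_pop varieties per subpopulation (scalar or length-K
#'   vector for unbalanced demes).
#' @param n_loci number of loci.
#' @param alleles_per_locus integer range `c(min, max)` of allele counts
#'   (truncated to what each marker's size range can hold).
#' @param fst differentiation parameter `F` in (0, 1).
#' @param admixture_alpha Dirichlet concentration for individual ancestry
#'   (0 = none: every individual is a pure member of its deme).
#' @param selfing probability the second allele copy duplicates the first.
#' @param missing_rate per-call missing probability.
#' @param panel optional `marker_panel` supplying names/size ranges; by
#'   default the packaged 23-marker core panel (recycled if `n_loci` is
#'   larger). Allele bin centers are `size_min + motif * index` with a
#'   2 bp (dinucleotide) motif when the panel does not declare one.
#' @param seed integer seed; fixing it fixes the output byte-for-byte.
#' @return A list of class `ssr_sim`: `genotypes` (an `ssr_genotypes`),
#'   `labels` (named population labels), `q` (true ancestry matrix),
#'   `freq_ancestral` and `freq_pop` (true frequencies per locus).
#' @export
simulate_genotypes <- function(K = 3, n_per_pop = 141, n_loci = 23,
                               alleles_per_locus = c(5, 40), fst = 0.13,
                               admixture_alpha = 0, selfing = 0.5,
                               missing_rate = 0.02, panel = NULL,
                               seed = NULL) {
  stopifnot(K >= 1, all(n_per_pop >= 1), n_loci >= 1,
            fst > 0, fst < 1, selfing >= 0, selfing <= 1,
            missing_rate >= 0, missing_rate <= 1, admixture_alpha >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(panel)) panel <- ssr_core_panel()
  idx <- rep_len(seq_len(nrow(panel)), n_loci)
  loci <- panel$name[idx]
  if (n_loci > nrow(panel)) loci <- make.unique(loci, sep = "_r")
  motif <- ifelse(is.na(panel$motif_length[idx]), 2L,
                  panel$motif_length[idx])
  span <- floor((panel$size_max[idx] - panel$size_min[idx]) / motif) + 1L
  n_alleles <- pmin(span,
                    sample(alleles_per_locus[1]:alleles_per_locus[2],
                           n_loci, replace = TRUE))
  n_alleles <- pmax(n_alleles, 2L)

  n_per_pop <- rep_len(n_per_pop, K)
  n <- sum(n_per_pop)
  varieties <- sprintf("V%03d", seq_len(n))
  labels <- setNames(rep(paste0("pop", seq_len(K)), times = n_per_pop),
                     varieties)
  qmat <- matrix(0, n, K, dimnames = list(varieties,
                                          paste0("pop", seq_len(K))))
  if (admixture_alpha > 0) {
    qmat[] <- .rdirichlet(n, rep(admixture_alpha, K))
    labels[] <- colnames(qmat)[max.col(qmat)]
  } else {
    qmat[cbind(seq_len(n), rep(seq_len(K), times = n_per_pop))] <- 1
  }

  bins_list <- vector("list", n_loci)
  freq_anc <- vector("list", n_loci)
  freq_pop <- vector("list", n_loci)
  a1 <- matrix(NA_character_, n, n_loci, dimnames = list(varieties, loci))
  a2 <- a1
  for (l in seq_len(n_loci)) {
    A <- n_alleles[l]
    centers <- panel$size_min[idx[l]] + motif[l] * (seq_len(A) - 1L)
    bins_list[[l]] <- allele_bins(loci[l], centers)
    p_anc <- drop(.rdirichlet(1, rep(1, A)))
    pk <- .rdirichlet(K, p_anc * (1 - fst) / fst)  # K x A
    freq_anc[[l]] <- setNames(p_anc, bins_list[[l]]$bin)
    freq_pop[[l]] <- pk
    # deme of origin per copy, then allele conditional on deme
    z1 <- vapply(seq_len(n), function(i) {
      sample.int(K, 1, prob = qmat[i, ])
    }, 0L)
    z2 <- vapply(seq_len(n), function(i) {
      sample.int(K, 1, prob = qmat[i, ])
    }, 0L)
    c1 <- vapply(seq_len(n), function(i) {
      sample.int(A, 1, prob = pk[z1[i], ])
    }, 0L)
    c2 <- vapply(seq_len(n), function(i) {
      sample.int(A, 1, prob = pk[z2[i], ])
    }, 0L)
    selfed <- runif(n) < selfing
    c2[selfed] <- c1[selfed]
    lab <- bins_list[[l]]$bin
    a1[, l] <- lab[c1]
    a2[, l] <- lab[c2]
    if (missing_rate > 0) {
      miss <- runif(n) < missing_rate
      a1[miss, l] <- NA_character_
      a2[miss, l] <- NA_character_
    }
  }
  bins <- bind_bins(bins_list)
  gm <- genotype_matrix(a1, a2, bins = bins, pops = labels)
  structure(list(genotypes = gm, labels = labels, q = qmat,
                 freq_ancestral = freq_anc, freq_pop = freq_pop,
                 panel = panel[idx, , drop = FALSE]),
            class = "ssr_sim")
}

#' Simulate coded morphological characteristics
#'
#' Each characteristic's state is drawn from the mixture
#' `(1 - d) * shared + d * population-specific` categorical
#' distribution: `d = 0` makes traits independent of population (null
#' for the marker-morphology correlation), large `d` makes trait
#' similarity track population membership.
#'
#' @param labels named population labels (variety ID -> population).
#' @param n_traits number of characteristics; defaults to the packaged
#'   30-characteristic DUS schema, whose coded state sets are reused.
#' @param states_per_trait integer vector (recycled) of state counts;
#'   default taken from the schema.
#' @param pop_divergence mixing weight `d` in `[0, 1]`.
#' @param seed integer seed.
#' @return A data.frame (varieties x traits) of integer state codes.
#' @export
simulate_traits <- function(labels, n_traits = 30, states_per_trait = NULL,
                            pop_divergence = 0.5, seed = NULL) {
  stopifnot(length(labels) > 0, pop_divergence >= 0, pop_divergence <= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(states_per_trait)) {
    schema <- morpho_schema()
    states_per_trait <- vapply(schema$codes, length, 0L)
  }
  states_per_trait <- rep_len(states_per_trait, n_traits)
  pops <- unique(unname(labels))
  out <- matrix(NA_integer_, length(labels), n_traits,
                dimnames = list(names(labels),
                                sprintf("trait%02d", seq_len(n_traits))))
  d <- pop_divergence
  for (t in seq_len(n_traits)) {
    S <- states_per_trait[t]
    shared <- drop(.rdirichlet(1, rep(1, S)))
    specific <- .rdirichlet(length(pops), rep(1, S))
    rownames(specific) <- pops
    for (v in seq_along(labels)) {
      p <- (1 - d) * shared + d * specific[unname(labels[v]), ]
      out[v, t] <- if (S == 1L) 1L else sample.int(S, 1, prob = p)
    }
  }
  as.data.frame(out)
}

#' Inject near-duplicate varieties
#'
#' Appends copies of randomly chosen varieties, each perturbed at exactly
#' `n_allele_diffs` allele calls — the ground truth for testing
#' undistinguished-group detection (a clone with 0 or 1 allele difference
#' must fall below the default distinctness threshold).
#'
#' @param gm an `ssr_genotypes` object.
#' @param n_pairs number of clones to append.
#' @param n_allele_diffs exact number of allele calls changed per clone.
#' @param seed integer seed.
#' @return A new `ssr_genotypes` with `n_pairs` extra varieties (IDs
#'   `<source>_dup<i>`); attribute `clones` is a data.frame
#'   (`source`, `clone`, `n_allele_diffs`).
#' @export
clone_pairs <- function(gm, n_pairs, n_allele_diffs = 0L, seed = NULL) {
  stopifnot(n_pairs >= 1, n_allele_diffs >= 0)
  if (!is.null(seed)) set.seed(seed)
  sources <- sample(gm$varieties, n_pairs)
  a1 <- gm$a1; a2 <- gm$a2
  clones <- character(n_pairs)
  for (i in seq_len(n_pairs)) {
    src <- sources[i]
    cid <- paste0(src, "_dup", i)
    clones[i] <- cid
    r1 <- gm$a1[src, , drop = TRUE]
    r2 <- gm$a2[src, , drop = TRUE]
    if (n_allele_diffs > 0L) {
      # a perturbable slot is one whose locus is typed and has >= 2
      # distinct labels available to switch to
      lab_sets <- lapply(gm$loci, function(l) {
        u <- unique(c(gm$a1[, l], gm$a2[, l]))
        u[!is.na(u)]
      })
      names(lab_sets) <- gm$loci
      ok_locus <- !is.na(r1) & vapply(lab_sets, length, 0L) >= 2L
      slots <- expand.grid(locus = gm$loci[ok_locus], copy = 1:2,
                           stringsAsFactors = FALSE)
      if (n_allele_diffs > nrow(slots)) {
        stop("n_allele_diffs exceeds the number of perturbable allele slots")
      }
      pick <- slots[sample.int(nrow(slots), n_allele_diffs), , drop = FALSE]
      for (r in seq_len(nrow(pick))) {
        l <- pick$locus[r]
        cur <- if (pick$copy[r] == 1L) r1[[l]] else r2[[l]]
        alt <- sample(setdiff(lab_sets[[l]], cur), 1)
        if (pick$copy[r] == 1L) r1[[l]] <- alt else r2[[l]] <- alt
      }
    }
    a1 <- rbind(a1, setNames(r1, gm$loci))
    a2 <- rbind(a2, r2)
    rownames(a1)[nrow(a1)] <- cid
    rownames(a2)[nrow(a2)] <- cid
  }
  pops <- attr(gm, "pops")
  if (!is.null(pops)) {
    pops <- c(pops, setNames(unname(pops[sources]), clones))
  }
  out <- genotype_matrix(a1, a2, bins = attr(gm, "bins"), pops = pops)
  attr(out, "clones") <- data.frame(source = sources, clone = clones,
                                    n_allele_diffs = n_allele_diffs,
                                    stringsAsFactors = FALSE)
  out
}
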