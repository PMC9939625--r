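# Shared in-code fixtures and brute-force oracles.

# build a genotype matrix from a named list:
# list(V1 = c("188/190", "110/110"), V2 = ...) with loci names
gm_from_strings <- function(calls, loci) {
  varieties <- names(calls)
  a1 <- matrix(NA_character_, length(varieties), length(loci),
               dimnames = list(varieties, loci))
  a2 <- a1
  for (v in varieties) {
    parts <- strsplit(calls[[v]], "/", fixed = TRUE)
    for (j in seq_along(loci)) {
      p <- parts[[j]]
      if (!identical(p[1], "NA")) {
        a1[v, j] <- p[1]
        a2[v, j] <- p[2]
      }
    }
  }
  genotype_matrix(a1, a2)
}

# random small genotype matrix (no missing unless asked)
random_gm <- function(n = 10, L = 5, n_alleles = 4, missing = 0,
                      prefix = "V") {
  varieties <- sprintf("%s%02d", prefix, seq_len(n))
  loci <- sprintf("L%02d", seq_len(L))
  labels <- as.character(100 + 2 * seq_len(n_alleles))
  a1 <- matrix(sample(labels, n * L, replace = TRUE), n, L,
               dimnames = list(varieties, loci))
  a2 <- matrix(sample(labels, n * L, replace = TRUE), n, L,
               dimnames = list(varieties, loci))
  if (missing > 0) {
    mask <- matrix(runif(n * L) < missing, n, L)
    a1[mask] <- NA
    a2[mask] <- NA
  }
  genotype_matrix(a1, a2)
}

random_spectrum <- function(k) {
  p <- rgamma(k, 1)
  p / sum(p)
}

# --- independent oracles -------------------------------------------------

pic_bruteforce <- function(p) {
  out <- 1 - sum(p^2)
  k <- length(p)
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        out <- out - 2 * p[i]^2 * p[j]^2
      }
    }
  }
  out
}

he_bruteforce <- function(p) {
  # P(two draws differ) summed over ordered pairs
  tot <- 0
  for (i in seq_along(p)) {
    for (j in seq_along(p)) {
      if (i != j) tot <- tot + p[i] * p[j]
    }
  }
  tot
}

allele_diff_bruteforce <- function(pair_a, pair_b) {
  # multiset symmetric difference / 2 via explicit counting
  tab_a <- table(pair_a)
  tab_b <- table(pair_b)
  alleles <- union(names(tab_a), names(tab_b))
  inter <- 0
  for (al in alleles) {
    ca <- if (al %in% names(tab_a)) tab_a[[al]] else 0
    cb <- if (al %in% names(tab_b)) tab_b[[al]] else 0
    inter <- inter + min(ca, cb)
  }
  2 - inter
}

sm_bruteforce <- function(m) {
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      out[i, j] <- mean(m[i, ] == m[j, ])
    }
  }
  out
}

# UPGMA oracle: cluster distances recomputed from the ORIGINAL matrix at
# every step (unweighted average over original leaf pairs), lexicographic
# tie-break on (smallest, second-smallest) cluster leaf labels.
upgma_bruteforce <- function(dm) {
  labs <- rownames(dm)
  clusters <- as.list(labs)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- mean(dm[clusters[[i]], clusters[[j]]])
        key <- c(min(min(clusters[[i]]), min(clusters[[j]])),
                 max(min(clusters[[i]]), min(clusters[[j]])))
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    heights <- c(heights, best$d)
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    merges[[length(merges) + 1]] <- sort(merged)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(heights = heights, merges = merges)
}

# cluster membership sets of an hclust-style tree, in merge order
upgma_merge_sets <- function(tree) {
  n <- length(tree$labels)
  sets <- vector("list", n - 1)
  members <- function(node) {
    if (node < 0) return(tree$labels[-node])
    sets[[node]]
  }
  for (s in seq_len(n - 1)) {
    sets[[s]] <- sort(c(members(tree$merge[s, 1]),
                        members(tree$merge[s, 2])))
  }
  sets
}
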