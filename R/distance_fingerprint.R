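# Variety-pair comparison, Nei (1972) distance, UPGMA clustering,
# discrimination-rate assessment and similar-variety screening.

# integer-coded allele matrices for the C++ backend
.encode_alleles <- function(gm) {
  a1 <- matrix(NA_integer_, nrow(gm$a1), ncol(gm$a1),
               dimnames = dimnames(gm$a1))
  a2 <- a1
  for (l in gm$loci) {
    lv <- sort(unique(c(gm$a1[, l], gm$a2[, l])), na.last = NA)
    a1[, l] <- match(gm$a1[, l], lv)
    a2[, l] <- match(gm$a2[, l], lv)
  }
  list(a1 = a1, a2 = a2)
}

.pairwise_stats <- function(gm) {
  enc <- .encode_alleles(gm)
  .pairwise_stats_cpp(enc$a1, enc$a2)
}

#' Allele-difference report for a variety pair
#'
#' Per locus co-typed in both varieties, the allele difference is the
#' size of the multiset symmetric difference of the two allele pairs,
#' divided by two (equivalently `2 - |multiset intersection|`). A locus
#' missing in either variety is skipped (neither same nor different).
#'
#' @param gm an `ssr_genotypes` object.
#' @param a,b variety IDs.
#' @param threshold minimum total allele differences for a pair to count
#'   as distinguishable (default 2: a panel that leaves two profiles
#'   within one allele of each other has not separated them).
#' @return A list of class `pair_report`: `variety_a`, `variety_b`,
#'   `loci_compared`, `loci_different`, `allele_differences`,
#'   `distinguishable`.
#' @export
allele_diff <- function(gm, a, b, threshold = 2L) {
  for (v in c(a, b)) {
    if (!v %in% gm$varieties) stop("unknown variety: ", v)
  }
  d <- 0L; nc <- 0L; ld <- 0L
  for (l in gm$loci) {
    xa <- c(gm$a1[a, l], gm$a2[a, l])
    xb <- c(gm$a1[b, l], gm$a2[b, l])
    if (anyNA(xa) || anyNA(xb)) next
    nc <- nc + 1L
    inter <- if (xa[1] == xa[2]) sum(xb == xa[1]) else
      as.integer(xa[1] %in% xb) + as.integer(xa[2] %in% xb)
    dd <- 2L - min(inter, 2L)
    d <- d + dd
    if (dd > 0L) ld <- ld + 1L
  }
  if (nc == 0L) stop("varieties ", a, " and ", b, " share no co-typed loci")
  structure(list(variety_a = a, variety_b = b, loci_compared = nc,
                 loci_different = ld, allele_differences = d,
                 distinguishable = d >= threshold),
            class = "pair_report")
}

#' Pairwise Nei (1972) genetic distance
#'
#' Each variety is treated as a population of size one: a heterozygote
#' contributes frequencies 0.5/0.5 at a locus, a homozygote 1. With
#' identity sums `Jxy`, `Jx`, `Jy` accumulated over all co-typed loci
#' before the ratio, `D = -ln(Jxy / sqrt(Jx * Jy))`. A pair sharing no
#' allele anywhere has infinite distance and is capped (with a warning).
#'
#' @param gm an `ssr_genotypes` object with >= 2 varieties.
#' @param cap value replacing infinite distances (default 10).
#' @return A symmetric matrix of class `ssr_dist` with zero diagonal;
#'   attribute `metric` is `"nei1972"`.
#' @export
nei_distance <- function(gm, cap = 10) {
  if (length(gm$varieties) < 2L) stop("need at least two varieties")
  st <- .pairwise_stats(gm)
  with_ratio <- st$jxy / sqrt(st$jx * st$jy)
  d <- -log(with_ratio)
  inf <- !is.finite(d)
  diag(inf) <- FALSE
  if (any(inf)) {
    warning(sum(inf) / 2, " variety pair(s) share no alleles; ",
            "distance capped at ", cap)
    d[inf] <- cap
  }
  diag(d) <- 0
  d[d < 0] <- 0  # guard tiny negatives from rounding
  dimnames(d) <- list(gm$varieties, gm$varieties)
  structure(d, metric = "nei1972", class = c("ssr_dist", "matrix", "array"))
}

#' Pairwise allele-difference count matrix
#'
#' @inheritParams nei_distance
#' @return List with integer matrices `diffs` (allele differences) and
#'   `compared` (co-typed loci) over all pairs.
#' @export
allele_diff_matrix <- function(gm) {
  st <- .pairwise_stats(gm)
  dimnames(st$diffs) <- dimnames(st$compared) <-
    list(gm$varieties, gm$varieties)
  list(diffs = st$diffs, compared = st$compared)
}

#' UPGMA clustering of a distance matrix
#'
#' Standard unweighted average-linkage agglomeration. Ties in the minimum
#' inter-cluster distance are broken deterministically: among tied pairs,
#' the one whose clusters have the lexicographically smallest (smallest
#' leaf label, second-smallest leaf label) wins. The result is an
#' `hclust`-compatible object whose `$height` are merge distances; the
#' corresponding ultrametric tree places each node at half the merge
#' distance (see [upgma_newick()]).
#'
#' @param dm symmetric distance matrix with variety dimnames (an
#'   `ssr_dist` or plain matrix).
#' @return An object of classes `ssr_upgma` and `hclust`.
#' @export
upgma <- function(dm) {
  dm <- unclass(dm)
  if (any(is.na(dm)) || any(!is.finite(dm))) {
    stop("distance matrix contains NA or non-finite values")
  }
  n <- nrow(dm)
  labs <- rownames(dm)
  if (is.null(labs)) labs <- as.character(seq_len(n))
  # active clusters: id (negative singleton / positive merge), size,
  # representative (smallest leaf label)
  id <- -seq_len(n)
  size <- rep(1L, n)
  rep_lab <- labs
  d <- dm
  diag(d) <- Inf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  active <- rep(TRUE, n)
  for (s in seq_len(n - 1L)) {
    dmin <- min(d[active, active, drop = FALSE])
    cand <- which(d <= dmin + 1e-12 & outer(active, active, "&"),
                  arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lab1 <- pmin(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    lab2 <- pmax(rep_lab[cand[, 1]], rep_lab[cand[, 2]])
    pick <- order(lab1, lab2)[1L]
    i <- cand[pick, 1]; j <- cand[pick, 2]
    merge[s, ] <- sort(c(id[i], id[j]))
    height[s] <- d[i, j]
    # UPGMA (unweighted) Lance-Williams update into slot i
    ni <- size[i]; nj <- size[j]
    new_d <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
    d[i, ] <- new_d
    d[, i] <- new_d
    d[i, i] <- Inf
    active[j] <- FALSE
    d[j, ] <- Inf; d[, j] <- Inf
    id[i] <- s
    size[i] <- ni + nj
    rep_lab[i] <- min(rep_lab[i], rep_lab[j])
  }
  ord <- .hclust_order(merge)
  structure(list(merge = merge, height = height, order = ord,
                 labels = labs, method = "average",
                 call = match.call(), dist.method = attr(dm, "metric")),
            class = c("ssr_upgma", "hclust"))
}

# leaf order for plotting (left-to-right DFS)
.hclust_order <- function(merge) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(nrow(merge))
}

#' Newick export of a UPGMA tree
#'
#' Converts the clustering to a rooted ultrametric `phylo` tree (node
#' heights = merge distances / 2) and returns its Newick string.
#'
#' @param tree an `ssr_upgma` / `hclust` object.
#' @param path optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
upgma_newick <- function(tree, path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(unclass_hclust(tree)))
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

unclass_hclust <- function(tree) {
  class(tree) <- "hclust"
  tree
}

#' Discrimination rate of a marker panel
#'
#' `(P - U) / P` with `P = n(n-1)/2` variety pairs and `U` the number of
#' pairs the panel cannot distinguish. Computed with integer arithmetic
#' before the division.
#'
#' @param n_varieties number of varieties in the database.
#' @param undistinguished_pairs number of confounded pairs `U`.
#' @return The discrimination rate in `[0, 1]`.
#' @export
discrimination_rate <- function(n_varieties, undistinguished_pairs) {
  n <- as.numeric(n_varieties)
  u <- as.numeric(undistinguished_pairs)
  if (n < 2) stop("need at least two varieties")
  if (u < 0) stop("undistinguished_pairs must be >= 0")
  p <- n * (n - 1) / 2
  if (u > p) stop("undistinguished_pairs exceeds the number of pairs")
  (p - u) / p
}

#' Find groups of varieties a panel cannot distinguish
#'
#' Builds a graph with an edge between every pair whose allele-difference
#' count is below `threshold`, and returns its connected components of
#' size >= 2 together with the sub-threshold pair count `U` that feeds
#' [discrimination_rate()].
#'
#' @param gm an `ssr_genotypes` object.
#' @param threshold distinctness threshold in allele differences
#'   (default 2).
#' @return A list: `groups` (list of character vectors), `n_pairs` (U),
#'   `pairs` (data.frame of confounded pairs with their counts).
#' @export
undistinguished_groups <- function(gm, threshold = 2L) {
  adm <- allele_diff_matrix(gm)
  n <- length(gm$varieties)
  sub <- which(adm$diffs < threshold & adm$compared > 0 &
                 upper.tri(adm$diffs), arr.ind = TRUE)
  pairs <- data.frame(
    variety_a = gm$varieties[sub[, 1]],
    variety_b = gm$varieties[sub[, 2]],
    allele_differences = adm$diffs[sub],
    stringsAsFactors = FALSE
  )
  # union-find over confounded pairs
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  for (r in seq_len(nrow(sub))) {
    ra <- find(sub[r, 1]); rb <- find(sub[r, 2])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_len(n), find, 0L)
  comp <- split(gm$varieties, roots)
  groups <- unname(comp[vapply(comp, length, 0L) >= 2L])
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, "", 1L))]
  list(groups = groups, n_pairs = nrow(pairs), pairs = pairs)
}

#' Screen the database for varieties similar to a candidate
#'
#' Ranks all other varieties by Nei distance to the candidate (ties broken
#' by allele-difference count, then label) — the fingerprint-database
#' query used to pick comparison varieties for a distinctness trial.
#'
#' @param gm an `ssr_genotypes` object.
#' @param candidate variety ID present in `gm`.
#' @param k number of neighbours to return (truncated to the database
#'   size; the candidate itself is excluded).
#' @param threshold distinctness threshold for the per-pair reports.
#' @return A data.frame: variety, nei_distance, allele_differences,
#'   loci_compared, distinguishable.
#' @export
similar_varieties <- function(gm, candidate, k = 5L, threshold = 2L) {
  if (!candidate %in% gm$varieties) stop("unknown variety: ", candidate)
  nd <- nei_distance(gm)
  adm <- allele_diff_matrix(gm)
  others <- setdiff(gm$varieties, candidate)
  d <- nd[candidate, others]
  ad <- adm$diffs[candidate, others]
  nc <- adm$compared[candidate, others]
  ord <- order(d, ad, others)
  sel <- ord[seq_len(min(k, length(others)))]
  data.frame(
    variety = others[sel],
    nei_distance = unname(d[sel]),
    allele_differences = unname(ad[sel]),
    loci_compared = unname(nc[sel]),
    distinguishable = unname(ad[sel] >= threshold),
    stringsAsFactors = FALSE
  )
}

#' Write a distance matrix
#'
#' @param dm a symmetric distance matrix with dimnames.
#' @param path output path.
#' @param format `"csv"` (square, with header) or `"phylip"`
#'   (lower-triangle).
#' @return `path`, invisibly.
#' @export
write_distance <- function(dm, path, format = c("csv", "phylip")) {
  format <- match.arg(format)
  if (format == "csv") {
    write.csv(as.data.frame(unclass(dm)), path, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(as.character(nrow(dm)), con, useBytes = TRUE)
    for (i in seq_len(nrow(dm))) {
      row <- c(rownames(dm)[i],
               sprintf("%.6f", dm[i, seq_len(i - 1)]))
      writeLines(paste(row, collapse = " "), con, useBytes = TRUE)
    }
  }
  invisible(path)
}
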