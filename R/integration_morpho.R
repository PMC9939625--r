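# Morphological 0/1 coding, simple-matching similarity, Mantel tests and
# combined marker + morphology identification reports.

#' One-hot (0/1) encoding of a coded trait table
#'
#' Expands each characteristic into one indicator column per observed
#' expression state: the expressed state is coded 1, all others 0 (the
#' standard qualitative-data coding for similarity analysis). The same
#' encoding is applied to SSR genotypes by [genotype_presence()] for
#' cross-domain comparisons. Quantitative characteristics participate
#' through their 1-9 codes like any other state — no interval scaling.
#'
#' @param tt data.frame or matrix (varieties x characteristics) of
#'   integer state codes; `NA` = state missing (an all-zero row block).
#' @return A 0/1 matrix of class `binary_matrix` with columns named
#'   `<trait>.<code>`; attribute `traits` maps columns back to traits.
#' @export
encode_binary <- function(tt) {
  tt <- as.data.frame(tt)
  cols <- list()
  trait_of <- character(0)
  for (tr in names(tt)) {
    states <- sort(unique(stats::na.omit(tt[[tr]])))
    for (s in states) {
      v <- as.integer(!is.na(tt[[tr]]) & tt[[tr]] == s)
      cols[[paste(tr, s, sep = ".")]] <- v
      trait_of <- c(trait_of, tr)
    }
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(tt)
  attr(out, "traits") <- trait_of
  class(out) <- c("binary_matrix", class(out))
  out
}

#' Decode a one-hot matrix back to state codes
#'
#' @param bm a `binary_matrix` from [encode_binary()].
#' @return data.frame of integer codes (round-trip inverse of
#'   [encode_binary()]).
#' @export
decode_binary <- function(bm) {
  trait_of <- attr(bm, "traits")
  traits <- unique(trait_of)
  out <- lapply(traits, function(tr) {
    sub <- bm[, trait_of == tr, drop = FALSE]
    codes <- as.integer(sub("^.*\\.", "", colnames(sub)))
    idx <- max.col(sub, ties.method = "first")
    val <- codes[idx]
    val[rowSums(sub) == 0] <- NA_integer_
    val
  })
  names(out) <- traits
  out <- as.data.frame(out)
  rownames(out) <- rownames(bm)
  out
}

#' One-hot allele-presence encoding of SSR genotypes
#'
#' Per (locus, allele) indicator: 1 if the variety carries at least one
#' copy. Used when genotypes and morphology are compared on the same
#' 0/1 footing.
#'
#' @param gm an `ssr_genotypes` object.
#' @return A 0/1 `binary_matrix` (missing locus = all-zero block).
#' @export
genotype_presence <- function(gm) {
  d <- genotype_dosage(gm)
  d[is.na(d)] <- 0
  out <- (d > 0) + 0L
  attr(out, "traits") <- sub("\\.[^.]*$", "", colnames(out))
  class(out) <- c("binary_matrix", class(out))
  out
}

#' Pairwise similarity of 0/1 profiles
#'
#' Default is the simple-matching coefficient, (1-1 matches + 0-0
#' matches) / columns — the "qualitative" similarity used for one-hot
#' morphological and marker data. Dice and Jaccard are available.
#'
#' @param bm a 0/1 matrix (varieties in rows).
#' @param method `"sm"` (default), `"jaccard"` or `"dice"`.
#' @return Symmetric similarity matrix in `[0, 1]`, unit diagonal,
#'   class `ssr_similarity`.
#' @export
sm_similarity <- function(bm, method = c("sm", "jaccard", "dice")) {
  method <- match.arg(method)
  m <- as.matrix(unclass(bm))
  n_col <- ncol(m)
  both1 <- tcrossprod(m)
  ones <- rowSums(m)
  a_plus_b <- outer(ones, ones, "+") - both1  # |union of 1s|
  sim <- switch(method,
    sm = {
      both0 <- n_col - a_plus_b
      (both1 + both0) / n_col
    },
    jaccard = ifelse(a_plus_b > 0, both1 / a_plus_b, 1),
    dice = ifelse(outer(ones, ones, "+") > 0,
                  2 * both1 / outer(ones, ones, "+"), 1)
  )
  diag(sim) <- 1
  dimnames(sim) <- list(rownames(m), rownames(m))
  structure(sim, metric = paste0(method, "_similarity"),
            class = c("ssr_similarity", "matrix", "array"))
}

#' Mantel test between two distance (or similarity) matrices
#'
#' `r` is the Pearson correlation of the upper off-diagonal triangles;
#' the p-value is `(1 + #{permuted r >= observed}) / (n_perm + 1)`,
#' permuting rows and columns of the second matrix jointly (one-sided,
#' positive association).
#'
#' @param m1,m2 symmetric matrices with identical dimnames ordering.
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed.
#' @return A list of class `mantel_result`: `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(m1, m2, n_perm = 999L, seed = NULL) {
  m1 <- as.matrix(unclass(m1)); m2 <- as.matrix(unclass(m2))
  if (!identical(dim(m1), dim(m2))) stop("matrix dimensions differ")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    stop("matrices must share an identical variety ordering")
  }
  if (!is.null(seed)) set.seed(seed)
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- cor(v1, m2[ut])
  cnt <- 0L
  n <- nrow(m1)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    if (cor(v1, m2[p, p][ut]) >= r_obs) cnt <- cnt + 1L
  }
  structure(list(r = r_obs, p_value = (1 + cnt) / (n_perm + 1),
                 n_perm = n_perm),
            class = "mantel_result")
}

#' Combined marker + morphology identification report
#'
#' For one candidate variety: its top-k SSR-nearest neighbours (Nei
#' distance), each annotated with morphological simple-matching
#' similarity and the list of characteristics whose states differ.
#' Neighbours below the distinctness threshold are flagged for
#' field-test follow-up. Both similarity orientations of the global
#' marker-morphology Mantel comparison are reported when requested.
#'
#' @param gm an `ssr_genotypes` object.
#' @param tt coded trait table (varieties x characteristics) covering
#'   the same varieties.
#' @param candidate candidate variety ID.
#' @param k neighbours to report.
#' @param threshold distinctness threshold in allele differences.
#' @return A list of class `combined_report`: `candidate`, `neighbours`
#'   (data.frame), `flagged` (subset below threshold), `trait_diffs`
#'   (named list of per-neighbour differing characteristics).
#' @export
combined_report <- function(gm, tt, candidate, k = 5L, threshold = 2L) {
  tt <- as.data.frame(tt)
  if (!all(gm$varieties %in% rownames(tt))) {
    stop("trait table does not cover all genotyped varieties")
  }
  tt <- tt[gm$varieties, , drop = FALSE]
  nb <- similar_varieties(gm, candidate, k = k, threshold = threshold)
  bm <- encode_binary(tt)
  sim <- sm_similarity(bm)
  nb$morph_similarity <- sim[candidate, nb$variety]
  trait_diffs <- lapply(nb$variety, function(v) {
    diff <- names(tt)[vapply(names(tt), function(tr) {
      a <- tt[candidate, tr]; b <- tt[v, tr]
      !is.na(a) && !is.na(b) && a != b
    }, TRUE)]
    diff
  })
  names(trait_diffs) <- nb$variety
  nb$n_trait_diffs <- vapply(trait_diffs, length, 0L)
  structure(list(candidate = candidate, neighbours = nb,
                 flagged = nb[!nb$distinguishable, , drop = FALSE],
                 trait_diffs = trait_diffs),
            class = "combined_report")
}

#' @export
print.combined_report <- function(x, ...) {
  cat("Candidate:", x$candidate, "\n")
  cat("Nearest varieties by Nei distance:\n")
  print(x$neighbours, row.names = FALSE)
  if (nrow(x$flagged)) {
    cat("\nFlagged for field-test follow-up (below distinctness",
        "threshold):\n")
    for (v in x$flagged$variety) {
      cat("  ", v, "- differing characteristics:",
          if (length(x$trait_diffs[[v]]))
            paste(x$trait_diffs[[v]], collapse = ", ")
          else "none recorded", "\n")
    }
  } else {
    cat("\nNo neighbour falls below the distinctness threshold.\n")
  }
  invisible(x)
}
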