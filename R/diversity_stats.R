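# Per-locus genetic diversity parameters (MAF, Na, Ho, He, PIC, Fst)
# and the Shannon-Wiener index for coded morphological characteristics.

#' Allele frequency spectrum at one locus
#'
#' Counts each allele copy (two per typed individual); missing genotypes
#' are excluded entirely.
#'
#' @param gm an `ssr_genotypes` object.
#' @param locus locus name.
#' @return A list of class `allele_spectrum`: `locus`, `freqs` (named
#'   numeric, sums to 1), `n_typed` (non-missing individuals).
#' @export
allele_frequencies <- function(gm, locus) {
  if (!locus %in% gm$loci) stop("unknown locus: ", locus)
  a <- c(gm$a1[, locus], gm$a2[, locus])
  a <- a[!is.na(a)]
  if (!length(a)) stop("locus ", locus, " has no non-missing calls")
  tab <- table(a)
  freqs <- as.numeric(tab) / sum(tab)
  names(freqs) <- names(tab)
  structure(list(locus = locus, freqs = freqs, n_typed = length(a) / 2),
            class = "allele_spectrum")
}

#' Major allele frequency
#'
#' Frequency of the most common allele. The published tables label this
#' column "MAF"; values above 0.5 show it is the major, not minor, allele
#' frequency (the PowerMarker convention), and that convention is kept
#' here for fidelity to those tables.
#'
#' @param spec an `allele_spectrum`.
#' @return The largest allele frequency.
#' @export
maf <- function(spec) max(spec$freqs)

#' Observed and expected heterozygosity
#'
#' `Ho` is the fraction of typed individuals carrying two distinct
#' alleles. `He` is Nei's gene diversity `1 - sum(p^2)` with no
#' small-sample correction (the convention of the standard codominant
#' toolchains); set `unbiased = TRUE` for the `2n/(2n-1)` correction.
#'
#' @param gm an `ssr_genotypes` object.
#' @param locus locus name.
#' @param unbiased apply the small-sample correction to He?
#' @return Named numeric vector `c(Ho=, He=)`.
#' @export
heterozygosities <- function(gm, locus, unbiased = FALSE) {
  a1 <- gm$a1[, locus]
  a2 <- gm$a2[, locus]
  keep <- !is.na(a1)
  if (!any(keep)) stop("locus ", locus, " has no non-missing calls")
  ho <- mean(a1[keep] != a2[keep])
  spec <- allele_frequencies(gm, locus)
  he <- 1 - sum(spec$freqs^2)
  if (unbiased) {
    n2 <- 2 * spec$n_typed
    he <- he * n2 / (n2 - 1)
  }
  c(Ho = ho, He = he)
}

#' Expected heterozygosity from a spectrum
#' @param spec an `allele_spectrum` or numeric frequency vector.
#' @return Nei gene diversity `1 - sum(p^2)`.
#' @export
expected_het <- function(spec) {
  p <- if (inherits(spec, "allele_spectrum")) spec$freqs else spec
  1 - sum(p^2)
}

#' Polymorphic information content (Botstein)
#'
#' `PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2`; always `<= He`.
#'
#' @param spec an `allele_spectrum` or numeric frequency vector.
#' @return PIC value in `[0, 1)`.
#' @export
pic <- function(spec) {
  p <- if (inherits(spec, "allele_spectrum")) spec$freqs else spec
  s2 <- sum(p^2)
  s4 <- sum(p^4)
  # sum_{i<j} 2 p_i^2 p_j^2 = (sum p^2)^2 - sum p^4, all over i<j pairs
  1 - s2 - (s2^2 - s4)
}

#' Per-locus fixation index
#'
#' Primary estimator is Nei's GST decomposition:
#' `Fst = (Ht - Hs) / Ht`, with `Hs` the unweighted mean of subpopulation
#' gene diversities and `Ht` the gene diversity of the unweighted mean
#' allele frequencies. `method = "wc"` gives the Weir-Cockerham theta
#' variance-component estimator instead (less biased when only a few
#' demes are sampled, hence the estimator used for simulation recovery).
#'
#' @param gm an `ssr_genotypes` object.
#' @param labels named character vector (variety ID -> population ID).
#' @param locus locus name.
#' @param method `"gst"` (default) or `"wc"`.
#' @return Fst estimate; `NA` when undefined (`Ht = 0`).
#' @export
fst_per_locus <- function(gm, labels, locus, method = c("gst", "wc")) {
  method <- match.arg(method)
  labels <- labels[names(labels) %in% gm$varieties]
  pops <- unique(unname(labels))
  if (length(pops) < 2L) stop("need at least two populations")
  if (method == "wc") {
    comp <- .wc_components(gm, labels, locus)
    tot <- comp["a"] + comp["b"] + comp["c"]
    return(if (tot == 0) NA_real_ else unname(comp["a"] / tot))
  }
  sub_he <- numeric(0)
  freq_list <- list()
  alleles <- character(0)
  for (p in pops) {
    vs <- names(labels)[labels == p]
    a <- c(gm$a1[vs, locus], gm$a2[vs, locus])
    a <- a[!is.na(a)]
    if (!length(a)) next
    tab <- table(a)
    f <- as.numeric(tab) / sum(tab)
    names(f) <- names(tab)
    freq_list[[p]] <- f
    alleles <- union(alleles, names(f))
    sub_he <- c(sub_he, 1 - sum(f^2))
  }
  if (length(freq_list) < 2L) stop("need at least two populations with calls")
  fm <- sapply(freq_list, function(f) {
    out <- setNames(numeric(length(alleles)), alleles)
    out[names(f)] <- f
    out
  })
  pbar <- rowMeans(fm)
  ht <- 1 - sum(pbar^2)
  hs <- mean(sub_he)
  if (ht <= 0) return(NA_real_)
  max(0, (ht - hs) / ht)
}

# Weir & Cockerham (1984) per-locus variance components, summed over alleles.
.wc_components <- function(gm, labels, locus) {
  pops <- unique(unname(labels))
  r <- 0L
  ni <- numeric(0); pmat <- NULL; hmat <- NULL
  alleles <- sort(unique(stats::na.omit(c(gm$a1[, locus], gm$a2[, locus]))))
  p_list <- list(); h_list <- list()
  for (p in pops) {
    vs <- names(labels)[labels == p]
    a1 <- gm$a1[vs, locus]; a2 <- gm$a2[vs, locus]
    keep <- !is.na(a1)
    n <- sum(keep)
    if (n == 0) next
    r <- r + 1L
    ni <- c(ni, n)
    a <- c(a1[keep], a2[keep])
    cnt <- table(factor(a, levels = alleles))
    p_list[[r]] <- as.numeric(cnt) / (2 * n)
    het <- vapply(alleles, function(al) {
      mean((a1[keep] == al) != (a2[keep] == al))
    }, 0.0)
    h_list[[r]] <- het
  }
  if (r < 2L) stop("need at least two populations with calls")
  pm <- do.call(cbind, p_list)   # alleles x pops
  hm <- do.call(cbind, h_list)
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  a_tot <- b_tot <- c_tot <- 0
  for (k in seq_along(alleles)) {
    pbar <- sum(ni * pm[k, ]) / (r * nbar)
    s2 <- sum(ni * (pm[k, ] - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hm[k, ]) / (r * nbar)
    if (nbar <= 1) next
    a_k <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4) / (nbar - 1))
    b_k <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    c_k <- hbar / 2
    a_tot <- a_tot + a_k; b_tot <- b_tot + b_k; c_tot <- c_tot + c_k
  }
  c(a = a_tot, b = b_tot, c = c_tot)
}

#' Multi-locus Fst
#'
#' For `method = "wc"`, Weir-Cockerham components are summed over loci
#' before the ratio (the standard multi-locus theta); for `"gst"`, Ht and
#' Hs are averaged over loci before the ratio.
#'
#' @inheritParams fst_per_locus
#' @param loci loci to use (default all).
#' @return A single Fst estimate.
#' @export
fst_multilocus <- function(gm, labels, loci = gm$loci,
                           method = c("wc", "gst")) {
  method <- match.arg(method)
  if (method == "wc") {
    comp <- rowSums(vapply(loci, function(l) .wc_components(gm, labels, l),
                           c(a = 0, b = 0, c = 0)))
    return(unname(comp["a"] / sum(comp)))
  }
  hts <- hss <- numeric(0)
  for (l in loci) {
    labels2 <- labels[names(labels) %in% gm$varieties]
    pops <- unique(unname(labels2))
    fl <- list(); he <- numeric(0); alleles <- character(0)
    for (p in pops) {
      vs <- names(labels2)[labels2 == p]
      a <- c(gm$a1[vs, l], gm$a2[vs, l]); a <- a[!is.na(a)]
      if (!length(a)) next
      tab <- table(a); f <- as.numeric(tab) / sum(tab); names(f) <- names(tab)
      fl[[p]] <- f; alleles <- union(alleles, names(f))
      he <- c(he, 1 - sum(f^2))
    }
    if (length(fl) < 2L) next
    fm <- sapply(fl, function(f) {
      out <- setNames(numeric(length(alleles)), alleles); out[names(f)] <- f
      out
    })
    pbar <- rowMeans(fm)
    hts <- c(hts, 1 - sum(pbar^2)); hss <- c(hss, mean(he))
  }
  max(0, (mean(hts) - mean(hss)) / mean(hts))
}

#' Per-locus diversity table
#'
#' One row per locus with MAF, Na, Ho, He, PIC and (when population labels
#' are given) per-locus Fst, plus an arithmetic mean row — the layout of a
#' published marker-characterization table.
#'
#' @param gm an `ssr_genotypes` object.
#' @param labels optional population labels for the Fst column.
#' @param unbiased passed to [heterozygosities()].
#' @return A data.frame with columns Marker, MAF, Na, Ho, He, PIC, Fst;
#'   last row is `Mean`.
#' @export
diversity_table <- function(gm, labels = NULL, unbiased = FALSE) {
  rows <- lapply(gm$loci, function(l) {
    spec <- allele_frequencies(gm, l)
    het <- heterozygosities(gm, l, unbiased = unbiased)
    fst <- if (is.null(labels)) NA_real_ else fst_per_locus(gm, labels, l)
    data.frame(Marker = l, MAF = maf(spec), Na = length(spec$freqs),
               Ho = unname(het["Ho"]), He = unname(het["He"]),
               PIC = pic(spec), Fst = fst, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(Marker = "Mean", MAF = mean(out$MAF),
                         Na = mean(out$Na), Ho = mean(out$Ho),
                         He = mean(out$He), PIC = mean(out$PIC),
                         Fst = if (all(is.na(out$Fst))) NA_real_
                               else mean(out$Fst, na.rm = TRUE))
  rbind(out, mean_row)
}

#' Shannon-Wiener index of a coded characteristic
#'
#' `H' = -sum(Pi * ln(Pi))` over the observed expression-state
#' proportions (natural log); unobserved states contribute 0.
#'
#' @param states vector of coded expression states (one per variety);
#'   `NA` values are dropped.
#' @return A list of class `trait_distribution`: `Pi` (named proportions)
#'   and `H_prime`.
#' @export
shannon_index <- function(states) {
  states <- states[!is.na(states)]
  if (!length(states)) stop("no non-missing states")
  tab <- table(states)
  pi <- as.numeric(tab) / sum(tab)
  names(pi) <- names(tab)
  h <- -sum(pi * log(pi))
  structure(list(Pi = pi, H_prime = h), class = "trait_distribution")
}
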