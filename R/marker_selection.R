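# Core-marker screening, minimal discriminating set selection, and
# multiplex fluorescent panel grouping.

#' Screening criteria for core-marker selection
#'
#' Published core panels are screened for markers with a stable, simple
#' fluorescence signal, low missing rate, high polymorphism and even
#' chromosome coverage. Signal quality is judged on electropherograms by
#' eye in practice; here it is operationalized as "at most
#' `max_peak_complexity` distinct fragment peaks per individual" applied
#' to a raw peak table when one is available.
#'
#' @param min_pic minimum PIC (default 0.5: the conventional bound for
#'   "highly polymorphic").
#' @param max_missing_rate maximum per-marker missing-call fraction.
#' @param max_peak_complexity maximum peaks per individual (diploid: 2).
#' @param require_chromosome_coverage drop nothing, but report
#'   chromosomes left uncovered by the passing set.
#' @return A list of class `screen_criteria`.
#' @export
screen_criteria <- function(min_pic = 0.5, max_missing_rate = 0.2,
                            max_peak_complexity = 2L,
                            require_chromosome_coverage = TRUE) {
  stopifnot(min_pic >= 0, min_pic < 1,
            max_missing_rate >= 0, max_missing_rate <= 1,
            max_peak_complexity >= 1)
  structure(list(min_pic = min_pic, max_missing_rate = max_missing_rate,
                 max_peak_complexity = max_peak_complexity,
                 require_chromosome_coverage = require_chromosome_coverage),
            class = "screen_criteria")
}

#' Screen candidate markers against quality criteria
#'
#' Filters by missing rate and PIC (and peak complexity when a raw peak
#' count table is supplied); the audit table records one pass/fail row
#' per marker with the reasons for failure.
#'
#' @param gm an `ssr_genotypes` object.
#' @param panel optional `marker_panel` (for chromosome coverage report).
#' @param criteria a [screen_criteria()] object.
#' @param peak_counts optional numeric matrix (varieties x loci) of raw
#'   peak counts per individual.
#' @return A list: `passed` (character vector of marker names) and
#'   `audit` (data.frame: marker, missing_rate, PIC, max_peaks, pass,
#'   reasons), plus `uncovered_chromosomes` when a panel is given.
#' @export
screen_markers <- function(gm, panel = NULL, criteria = screen_criteria(),
                           peak_counts = NULL) {
  mr <- missing_rate(gm)
  audit <- do.call(rbind, lapply(gm$loci, function(l) {
    p <- tryCatch(pic(allele_frequencies(gm, l)), error = function(e) 0)
    mp <- if (is.null(peak_counts)) NA_real_ else max(peak_counts[, l],
                                                      na.rm = TRUE)
    reasons <- character(0)
    if (mr[[l]] > criteria$max_missing_rate) reasons <- c(reasons,
                                                          "missing_rate")
    if (p < criteria$min_pic) reasons <- c(reasons, "low_pic")
    if (!is.na(mp) && mp > criteria$max_peak_complexity) {
      reasons <- c(reasons, "peak_complexity")
    }
    data.frame(marker = l, missing_rate = unname(mr[[l]]), PIC = p,
               max_peaks = mp, pass = length(reasons) == 0L,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  passed <- audit$marker[audit$pass]
  if (!length(passed)) {
    warning("screening criteria exclude all markers")
  }
  out <- list(passed = passed, audit = audit)
  if (!is.null(panel) && criteria$require_chromosome_coverage) {
    covered <- unique(panel$chromosome[panel$name %in% passed])
    out$uncovered_chromosomes <-
      setdiff(seq_len(attr(panel, "n_chromosomes") %||% 10L), covered)
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# confounded pairs (allele diff < threshold) using only `loci`
.confounded_pairs <- function(gm, loci, threshold) {
  if (!length(loci)) {
    n <- length(gm$varieties)
    return(which(upper.tri(matrix(0, n, n)), arr.ind = TRUE))
  }
  sub <- gm[, loci]
  adm <- allele_diff_matrix(sub)
  which(adm$diffs < threshold & upper.tri(adm$diffs), arr.ind = TRUE)
}

#' Select a minimal core marker set by greedy set cover
#'
#' Starting from no markers (all variety pairs confounded), repeatedly
#' adds the candidate that resolves the most currently-confounded pairs
#' (pairs whose allele-difference count on the selected loci is below
#' `threshold`); ties go to the higher-PIC marker, then the
#' alphabetically first name. Stops when no pair remains confounded, no
#' candidate makes progress, or candidates are exhausted. With
#' `exact = TRUE` (feasible for <= 20 candidates) a branch-and-bound
#' search over subsets returns a provably minimum-cardinality set with
#' the same residual confounded pairs.
#'
#' @param gm an `ssr_genotypes` object.
#' @param candidates marker names to choose from (default all loci).
#' @param threshold distinctness threshold in allele differences.
#' @param exact find the optimum by subset search (<= 20 candidates).
#' @return A list: `markers` (ordered as selected), `n_confounded_left`,
#'   `history` (data.frame of per-step resolution counts).
#' @export
select_core_set <- function(gm, candidates = gm$loci, threshold = 2L,
                            exact = FALSE) {
  stopifnot(length(candidates) > 0)
  pics <- vapply(candidates, function(l) {
    tryCatch(pic(allele_frequencies(gm, l)), error = function(e) 0)
  }, 0.0)
  # per-marker allele-difference contribution per pair
  enc <- .encode_alleles(gm[, candidates])
  per_marker <- lapply(seq_along(candidates), function(ci) {
    st <- .pairwise_stats_cpp(enc$a1[, ci, drop = FALSE],
                              enc$a2[, ci, drop = FALSE])
    st$diffs[upper.tri(st$diffs)]
  })
  names(per_marker) <- candidates
  n_pairs <- length(per_marker[[1]])
  target_left <- {
    tot <- Reduce(`+`, per_marker)
    sum(tot < threshold)
  }
  if (exact) {
    if (length(candidates) > 20L) {
      stop("exact search supported for at most 20 candidates")
    }
    best <- .exact_core_set(per_marker, threshold, target_left)
    return(list(markers = best,
                n_confounded_left = target_left,
                history = NULL))
  }
  selected <- character(0)
  acc <- rep(0L, n_pairs)
  confounded <- rep(TRUE, n_pairs)
  hist <- list()
  remaining <- candidates
  while (any(confounded) && length(remaining)) {
    gains <- vapply(remaining, function(m) {
      sum(confounded & (acc + per_marker[[m]] >= threshold))
    }, 0L)
    # partial progress: allele differences added to still-confounded
    # pairs (matters when threshold > 1 and no single marker finishes one)
    partial <- vapply(remaining, function(m) {
      sum(pmin(per_marker[[m]][confounded],
               threshold - acc[confounded]))
    }, 0)
    if (max(gains) == 0L && max(partial) == 0) break
    ord <- order(-gains, -partial, -pics[remaining], remaining)
    best <- remaining[ord[1L]]
    acc <- acc + per_marker[[best]]
    confounded <- acc < threshold
    selected <- c(selected, best)
    hist[[length(hist) + 1L]] <- data.frame(
      marker = best, resolved = gains[ord[1L]],
      confounded_left = sum(confounded), stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, best)
  }
  list(markers = selected, n_confounded_left = sum(confounded),
       history = do.call(rbind, hist))
}

# smallest subset whose residual confounded count equals that of the
# full candidate set (iterative deepening over subset size)
.exact_core_set <- function(per_marker, threshold, target_left) {
  cand <- names(per_marker)
  for (size in seq_along(cand)) {
    combs <- combn(cand, size, simplify = FALSE)
    for (cc in combs) {
      tot <- Reduce(`+`, per_marker[cc])
      if (sum(tot < threshold) <= target_left) return(cc)
    }
  }
  cand
}

#' Group markers into multiplex panels
#'
#' Assigns each marker a (group, dye) slot such that markers sharing a
#' group and dye have fragment-size ranges separated by at least
#' `buffer` bp, using first-fit-decreasing greedy (markers sorted by
#' range width); an exhaustive search over group counts is available as
#' a fallback for small panels. Fewer groups means fewer capillary runs.
#'
#' @param panel a `marker_panel`.
#' @param n_dyes number of dye channels (default 4).
#' @param buffer minimum bp separation between same-group same-dye
#'   ranges (default 10).
#' @param dyes dye names to use.
#' @return A list of class `panel_assignment`: `assignment` (data.frame
#'   marker, group, dye, size_min, size_max), `n_groups`.
#' @export
group_panels <- function(panel, n_dyes = 4L, buffer = 10,
                         dyes = SSR_DYES[seq_len(n_dyes)]) {
  stopifnot(n_dyes >= 1, buffer >= 0)
  ord <- order(-(panel$size_max - panel$size_min), panel$name)
  mk <- panel[ord, , drop = FALSE]
  # slots[[g]][[d]] = list of assigned (min, max)
  slots <- list()
  assign_rows <- list()
  fits <- function(g, d, lo, hi) {
    for (iv in slots[[g]][[d]]) {
      if (!(hi + buffer <= iv[1] || lo >= iv[2] + buffer)) return(FALSE)
    }
    TRUE
  }
  for (r in seq_len(nrow(mk))) {
    lo <- mk$size_min[r]; hi <- mk$size_max[r]
    placed <- FALSE
    for (g in seq_along(slots)) {
      for (d in seq_along(dyes)) {
        if (fits(g, d, lo, hi)) {
          slots[[g]][[d]] <- c(slots[[g]][[d]], list(c(lo, hi)))
          assign_rows[[length(assign_rows) + 1L]] <-
            data.frame(marker = mk$name[r], group = g, dye = dyes[d],
                       size_min = lo, size_max = hi,
                       stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (placed) break
    }
    if (!placed) {
      g <- length(slots) + 1L
      slots[[g]] <- rep(list(list()), length(dyes))
      slots[[g]][[1L]] <- list(c(lo, hi))
      assign_rows[[length(assign_rows) + 1L]] <-
        data.frame(marker = mk$name[r], group = g, dye = dyes[1L],
                   size_min = lo, size_max = hi, stringsAsFactors = FALSE)
    }
  }
  assignment <- do.call(rbind, assign_rows)
  assignment <- assignment[order(assignment$group, assignment$dye,
                                 assignment$size_min), ]
  rownames(assignment) <- NULL
  structure(list(assignment = assignment,
                 n_groups = length(slots),
                 n_dyes = length(dyes), buffer = buffer),
            class = "panel_assignment")
}

#' Validate a multiplex assignment
#'
#' Independent check of the separation constraint: within every
#' (group, dye) cell, all size ranges must be pairwise separated by at
#' least `buffer` bp, and every marker must appear exactly once.
#'
#' @param pa a `panel_assignment` (or its `assignment` data.frame).
#' @param buffer separation in bp (default taken from the assignment).
#' @return `TRUE` if valid, otherwise a character vector of violations.
#' @export
validate_panel_assignment <- function(pa, buffer = NULL) {
  df <- if (inherits(pa, "panel_assignment")) pa$assignment else pa
  if (is.null(buffer)) {
    buffer <- if (inherits(pa, "panel_assignment")) pa$buffer else 10
  }
  problems <- character(0)
  if (anyDuplicated(df$marker)) {
    problems <- c(problems, "marker assigned more than once")
  }
  for (key in split(df, list(df$group, df$dye), drop = TRUE)) {
    if (nrow(key) < 2L) next
    key <- key[order(key$size_min), ]
    for (i in seq_len(nrow(key) - 1L)) {
      gap <- key$size_min[i + 1L] - key$size_max[i]
      if (gap < buffer) {
        problems <- c(problems, sprintf(
          "group %s dye %s: %s and %s separated by %d < %d bp",
          key$group[1], key$dye[1], key$marker[i], key$marker[i + 1L],
          gap, as.integer(buffer)))
      }
    }
  }
  if (length(problems)) problems else TRUE
}

#' Exhaustive minimum-group multiplex search
#'
#' Backtracking search for an assignment with the fewest groups; only
#' practical for small panels (<= 30 markers). Used as an oracle for the
#' greedy solver.
#'
#' @inheritParams group_panels
#' @param max_groups upper bound to try (default the greedy solution).
#' @return A `panel_assignment`, or `NULL` if `max_groups` is infeasible.
#' @export
group_panels_exact <- function(panel, n_dyes = 4L, buffer = 10,
                               dyes = SSR_DYES[seq_len(n_dyes)],
                               max_groups = NULL) {
  if (nrow(panel) > 30L) stop("exact search supported for <= 30 markers")
  greedy <- group_panels(panel, n_dyes, buffer, dyes)
  if (is.null(max_groups)) max_groups <- greedy$n_groups
  best <- greedy
  for (gtry in seq_len(max_groups - 1L)) {
    sol <- .exact_pack(panel, gtry, dyes, buffer)
    if (!is.null(sol)) {
      best <- structure(list(assignment = sol, n_groups = gtry,
                             n_dyes = length(dyes), buffer = buffer),
                        class = "panel_assignment")
      break
    }
  }
  best
}

.exact_pack <- function(panel, n_groups, dyes, buffer) {
  ord <- order(-(panel$size_max - panel$size_min), panel$name)
  mk <- panel[ord, , drop = FALSE]
  n <- nrow(mk)
  cells <- expand.grid(group = seq_len(n_groups), dye = seq_along(dyes))
  occupied <- rep(list(list()), nrow(cells))
  assign_cell <- integer(n)
  fits <- function(cell, lo, hi) {
    for (iv in occupied[[cell]]) {
      if (!(hi + buffer <= iv[1] || lo >= iv[2] + buffer)) return(FALSE)
    }
    TRUE
  }
  rec <- function(r) {
    if (r > n) return(TRUE)
    lo <- mk$size_min[r]; hi <- mk$size_max[r]
    # symmetry breaking: never open group g before g-1 has been used
    used_groups <- if (r == 1L) 0L else max(cells$group[
      assign_cell[seq_len(r - 1L)]])
    for (cell in seq_len(nrow(cells))) {
      if (cells$group[cell] > used_groups + 1L) next
      if (!fits(cell, lo, hi)) next
      occupied[[cell]] <<- c(occupied[[cell]], list(c(lo, hi)))
      assign_cell[r] <<- cell
      if (rec(r + 1L)) return(TRUE)
      occupied[[cell]] <<- occupied[[cell]][-length(occupied[[cell]])]
      assign_cell[r] <<- 0L
    }
    FALSE
  }
  if (!rec(1L)) return(NULL)
  data.frame(marker = mk$name, group = cells$group[assign_cell],
             dye = dyes[cells$dye[assign_cell]],
             size_min = mk$size_min, size_max = mk$size_max,
             stringsAsFactors = FALSE)
}
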