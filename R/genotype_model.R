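#' @useDynLib ssrfp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor rmultinom runif rbinom sd var setNames aggregate
#' @importFrom utils read.csv write.csv combn head
NULL

# ---------------------------------------------------------------------------
# Marker panels
# ---------------------------------------------------------------------------

SSR_DYES <- c("6-FAM", "HEX", "ROX", "TAMRA")

#' Construct a marker panel
#'
#' A marker panel holds per-locus metadata for a set of SSR markers: primer
#' name, chromosome, fluorescent dye (if assigned), expected fragment-size
#' range in base pairs and, optionally, the repeat-motif length.
#'
#' @param name character vector of unique marker names.
#' @param chromosome integer chromosome numbers (1-based).
#' @param size_min,size_max integer fragment-size range bounds in bp;
#'   `size_min < size_max` elementwise.
#' @param dye fluorescent dye per marker, one of `"6-FAM"`, `"HEX"`,
#'   `"ROX"`, `"TAMRA"`, or `NA` when unassigned.
#' @param motif_length optional repeat-unit length in bp (used as the
#'   default calibration tolerance `motif_length / 2`).
#' @param n_chromosomes size of the declared genome (default 10, the
#'   *Brassica campestris* A genome).
#' @return A `data.frame` of class `marker_panel`.
#' @export
marker_panel <- function(name, chromosome, size_min, size_max,
                         dye = NA_character_, motif_length = NA_integer_,
                         n_chromosomes = 10L) {
  name <- as.character(name)
  if (anyDuplicated(name)) {
    stop("duplicate marker names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  chromosome <- as.integer(chromosome)
  size_min <- as.integer(size_min)
  size_max <- as.integer(size_max)
  if (any(is.na(chromosome)) || any(chromosome < 1L) ||
      any(chromosome > n_chromosomes)) {
    stop("chromosome must be an integer in 1..", n_chromosomes)
  }
  if (any(size_min <= 0L) || any(size_max <= 0L) || any(size_min >= size_max)) {
    stop("size ranges must satisfy 0 < size_min < size_max")
  }
  dye <- rep_len(as.character(dye), length(name))
  bad_dye <- !is.na(dye) & !(dye %in% SSR_DYES)
  if (any(bad_dye)) {
    stop("unknown dye(s): ", paste(unique(dye[bad_dye]), collapse = ", "))
  }
  out <- data.frame(
    name = name, chromosome = chromosome,
    size_min = size_min, size_max = size_max,
    dye = dye, motif_length = rep_len(as.integer(motif_length), length(name)),
    stringsAsFactors = FALSE
  )
  attr(out, "n_chromosomes") <- as.integer(n_chromosomes)
  class(out) <- c("marker_panel", "data.frame")
  out
}

#' Merge two marker panels
#'
#' Markers present in both panels must agree on chromosome; disagreeing
#' size ranges are widened to their envelope with a warning (size ranges
#' reported for the same primer can differ between publications and
#' detection platforms).
#'
#' @param a,b `marker_panel` objects.
#' @return The merged `marker_panel`.
#' @export
merge_panels <- function(a, b) {
  stopifnot(inherits(a, "marker_panel"), inherits(b, "marker_panel"))
  shared <- intersect(a$name, b$name)
  for (m in shared) {
    ra <- a[a$name == m, ]
    rb <- b[b$name == m, ]
    if (ra$chromosome != rb$chromosome) {
      stop("marker ", m, " maps to chromosome ", ra$chromosome,
           " in one panel and ", rb$chromosome, " in the other")
    }
    if (ra$size_min != rb$size_min || ra$size_max != rb$size_max) {
      warning("marker ", m, ": size ranges ", ra$size_min, "-", ra$size_max,
              " and ", rb$size_min, "-", rb$size_max,
              " widened to their envelope")
    }
  }
  only_b <- b[!(b$name %in% shared), , drop = FALSE]
  out <- rbind(as.data.frame(a), as.data.frame(only_b))
  for (m in shared) {
    rb <- b[b$name == m, ]
    i <- which(out$name == m)
    out$size_min[i] <- min(out$size_min[i], rb$size_min)
    out$size_max[i] <- max(out$size_max[i], rb$size_max)
    if (is.na(out$dye[i])) out$dye[i] <- rb$dye
    if (is.na(out$motif_length[i])) out$motif_length[i] <- rb$motif_length
  }
  marker_panel(out$name, out$chromosome, out$size_min, out$size_max,
               out$dye, out$motif_length,
               n_chromosomes = max(attr(a, "n_chromosomes"),
                                   attr(b, "n_chromosomes")))
}

#' Read / write a marker panel CSV
#'
#' The CSV mirrors the published panel-table layout: `name`, forward and
#' reverse primer sequences, `chromosome`, `size_min`, `size_max`, and
#' optionally `dye` and `motif_length`.
#'
#' @param path file path.
#' @return `read_marker_panel` returns a `marker_panel`;
#'   `write_marker_panel` returns `path` invisibly.
#' @export
read_marker_panel <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "chromosome", "size_min", "size_max")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols)) {
    stop("marker panel CSV lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pan <- marker_panel(
    df$name, df$chromosome, df$size_min, df$size_max,
    dye = if ("dye" %in% names(df)) df$dye else NA_character_,
    motif_length = if ("motif_length" %in% names(df)) df$motif_length
                   else NA_integer_
  )
  if (all(c("primer_f", "primer_r") %in% names(df))) {
    pan$primer_f <- df$primer_f
    pan$primer_r <- df$primer_r
  }
  pan
}

#' @rdname read_marker_panel
#' @param panel a `marker_panel`.
#' @export
write_marker_panel <- function(panel, path) {
  write.csv(as.data.frame(panel), path, row.names = FALSE, quote = FALSE,
            na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Allele bins
# ---------------------------------------------------------------------------

#' Define calibrated allele bins for one marker
#'
#' Allele "bins" are the named allelic sites of the fingerprint database:
#' each bin has a label (a string, so the database is portable across
#' platforms) and a numeric center in bp, and may record the reference
#' variety used to calibrate it across batches.
#'
#' @param marker marker name.
#' @param centers strictly increasing numeric bin centers (bp).
#' @param labels bin labels; default the rounded centers.
#' @param reference optional reference-variety ID per bin.
#' @param size_range optional `c(min, max)`; centers must lie within
#'   `[min - tol, max + tol]`.
#' @param tol tolerance for the size-range check (default 1 bp).
#' @return A `data.frame` of class `allele_bins` with columns
#'   `marker`, `bin`, `center`, `reference`.
#' @export
allele_bins <- function(marker, centers, labels = NULL, reference = NULL,
                        size_range = NULL, tol = 1.0) {
  centers <- as.numeric(centers)
  if (is.unsorted(centers, strictly = TRUE)) {
    stop("bin centers must be strictly increasing for marker ", marker)
  }
  if (is.null(labels)) labels <- as.character(round(centers))
  labels <- as.character(labels)
  if (anyDuplicated(labels)) {
    stop("duplicate bin labels for marker ", marker)
  }
  if (!is.null(size_range)) {
    if (any(centers < size_range[1] - tol | centers > size_range[2] + tol)) {
      stop("bin centers outside declared size range for marker ", marker)
    }
  }
  if (is.null(reference)) reference <- NA_character_
  out <- data.frame(marker = marker, bin = labels, center = centers,
                    reference = rep_len(as.character(reference),
                                        length(centers)),
                    stringsAsFactors = FALSE)
  class(out) <- c("allele_bins", "data.frame")
  out
}

#' Combine per-marker bin sets
#'
#' @param ... `allele_bins` objects (or a single list of them).
#' @return A stacked `allele_bins` data.frame covering several markers.
#' @export
bind_bins <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1]]) &&
      !inherits(parts[[1]], "data.frame")) {
    parts <- parts[[1]]
  }
  out <- do.call(rbind, lapply(parts, as.data.frame))
  class(out) <- c("allele_bins", "data.frame")
  out
}

# ---------------------------------------------------------------------------
# Genotype matrix
# ---------------------------------------------------------------------------

# numeric-aware ordering of allele labels so that "99" < "101"
.label_order <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (anyNA(num)) order(x) else order(num)
}

.canonical_pair <- function(a1, a2) {
  swap <- !is.na(a1) & !is.na(a2) & .pair_gt(a1, a2)
  tmp <- a1[swap]
  a1[swap] <- a2[swap]
  a2[swap] <- tmp
  list(a1 = a1, a2 = a2)
}

.pair_gt <- function(a, b) {
  na <- suppressWarnings(as.numeric(a))
  nb <- suppressWarnings(as.numeric(b))
  ifelse(!is.na(na) & !is.na(nb), na > nb, a > b)
}

#' Construct a codominant SSR genotype matrix
#'
#' Stores, per (variety, locus), an unordered pair of allele labels or a
#' missing call. Pairs are canonicalized (sorted, numeric-aware) so that
#' `("a","b")` and `("b","a")` are the same genotype; homozygotes carry the
#' same label twice. A half-called genotype (one allele observed) is
#' treated as missing — conservative for distinctness claims.
#'
#' @param a1,a2 character matrices (varieties x loci) of allele labels;
#'   `NA` marks a missing allele. Row names are variety IDs, column names
#'   locus names.
#' @param bins optional `allele_bins` covering all labels used.
#' @param pops optional named character vector of population labels
#'   (names = variety IDs).
#' @return An object of class `ssr_genotypes`: a list with elements
#'   `varieties`, `loci`, `a1`, `a2` and attributes `bins`, `pops`.
#' @export
genotype_matrix <- function(a1, a2, bins = NULL, pops = NULL) {
  stopifnot(is.matrix(a1), is.matrix(a2), all(dim(a1) == dim(a2)))
  varieties <- rownames(a1)
  loci <- colnames(a1)
  if (is.null(varieties) || is.null(loci)) {
    stop("a1 must carry variety row names and locus column names")
  }
  if (anyDuplicated(varieties)) stop("duplicate variety IDs")
  if (anyDuplicated(loci)) stop("duplicate locus names")
  mode(a1) <- "character"
  mode(a2) <- "character"
  # half-called -> missing
  half <- xor(is.na(a1), is.na(a2))
  a1[half] <- NA_character_
  a2[half] <- NA_character_
  cp <- .canonical_pair(as.vector(a1), as.vector(a2))
  a1[] <- cp$a1
  a2[] <- cp$a2
  if (!is.null(bins)) {
    for (l in loci) {
      lab <- unique(c(a1[, l], a2[, l]))
      lab <- lab[!is.na(lab)]
      known <- bins$bin[bins$marker == l]
      unknown <- setdiff(lab, known)
      if (length(unknown)) {
        stop("locus ", l, ": allele label(s) not in bin set: ",
             paste(unknown, collapse = ", "))
      }
    }
  }
  if (!is.null(pops)) {
    extra <- setdiff(names(pops), varieties)
    if (length(extra)) {
      stop("population labels refer to unknown varieties: ",
           paste(head(extra, 5), collapse = ", "))
    }
    pops <- pops[varieties[varieties %in% names(pops)]]
  }
  structure(
    list(varieties = varieties, loci = loci, a1 = a1, a2 = a2),
    bins = bins, pops = pops, class = "ssr_genotypes"
  )
}

#' @export
print.ssr_genotypes <- function(x, ...) {
  miss <- mean(is.na(x$a1))
  cat("SSR genotype matrix:", length(x$varieties), "varieties x",
      length(x$loci), "loci;", sprintf("%.1f%%", 100 * miss),
      "missing calls\n")
  invisible(x)
}

#' @export
dim.ssr_genotypes <- function(x) c(length(x$varieties), length(x$loci))

#' Subset an SSR genotype matrix
#'
#' @param x an `ssr_genotypes` object.
#' @param i,j variety and locus selectors (names, indices or logical).
#' @param ... ignored.
#' @export
`[.ssr_genotypes` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$varieties)
  if (missing(j)) j <- seq_along(x$loci)
  pops <- attr(x, "pops")
  a1 <- x$a1[i, j, drop = FALSE]
  genotype_matrix(a1, x$a2[i, j, drop = FALSE],
                  bins = attr(x, "bins"),
                  pops = if (is.null(pops)) NULL
                         else pops[names(pops) %in% rownames(a1)])
}

#' Per-locus missing-call rate
#'
#' @param gm an `ssr_genotypes` object.
#' @return Named numeric vector, fraction of varieties missing per locus.
#' @export
missing_rate <- function(gm) colMeans(is.na(gm$a1))

MISSING_TOKENS <- c("0", "", "NA", ".", "na")

# ---------------------------------------------------------------------------
# I/O
# ---------------------------------------------------------------------------

#' Read a codominant SSR genotype table
#'
#' Two dialects are supported. `genalex_csv` is the GenAlEx-style layout
#' (three header rows: counts; title and population names; sample/pop/locus
#' header with two columns per locus; `0` = missing). `long_csv` is a tidy
#' table `variety,locus,allele1,allele2`. Missing alleles may be coded
#' `0`, empty, `NA` or `.`; a half-called genotype becomes missing.
#'
#' @param path file path.
#' @param dialect `"genalex_csv"` (default) or `"long_csv"`.
#' @return An `ssr_genotypes` object (with population labels attached for
#'   the GenAlEx dialect).
#' @export
read_genotypes <- function(path, dialect = c("genalex_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "long_csv") .read_long_csv(path) else .read_genalex(path)
}

.norm_allele <- function(x) {
  x <- trimws(as.character(x))
  x[x %in% MISSING_TOKENS] <- NA_character_
  x
}

.read_long_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = "character")
  need <- c("variety", "locus", "allele1", "allele2")
  if (!all(need %in% names(df))) {
    stop("long CSV must have columns variety,locus,allele1,allele2; got: ",
         paste(names(df), collapse = ","))
  }
  varieties <- unique(df$variety)
  loci <- unique(df$locus)
  a1 <- matrix(NA_character_, length(varieties), length(loci),
               dimnames = list(varieties, loci))
  a2 <- a1
  idx <- cbind(match(df$variety, varieties), match(df$locus, loci))
  a1[idx] <- .norm_allele(df$allele1)
  a2[idx] <- .norm_allele(df$allele2)
  genotype_matrix(a1, a2)
}

.read_genalex <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 4L) stop("GenAlEx file too short: ", path)
  split1 <- strsplit(lines[[1]], ",", fixed = TRUE)[[1]]
  counts <- suppressWarnings(as.integer(split1))
  if (is.na(counts[1]) || is.na(counts[2])) {
    stop("malformed GenAlEx header line 1 (expected n_loci,n_samples,...): ",
         lines[[1]])
  }
  n_loci <- counts[1]
  n_samples <- counts[2]
  hdr <- strsplit(lines[[3]], ",", fixed = TRUE)[[1]]
  locus_cols <- 3L + 2L * (seq_len(n_loci) - 1L)
  if (length(hdr) < max(locus_cols)) {
    stop("malformed GenAlEx header line 3: expected ", n_loci,
         " locus columns, found ", floor((length(hdr) - 2) / 2))
  }
  loci <- trimws(hdr[locus_cols])
  if (any(loci == "")) {
    stop("malformed GenAlEx header line 3: empty locus name at column ",
         locus_cols[which(loci == "")[1]])
  }
  body <- lines[seq(4L, length.out = n_samples)]
  cells <- strsplit(body, ",", fixed = TRUE)
  varieties <- vapply(cells, function(r) trimws(r[[1]]), "")
  popv <- vapply(cells, function(r) trimws(r[[2]]), "")
  a1 <- matrix(NA_character_, n_samples, n_loci,
               dimnames = list(varieties, loci))
  a2 <- a1
  for (r in seq_len(n_samples)) {
    row <- cells[[r]]
    v1 <- row[locus_cols]
    v2 <- row[locus_cols + 1L]
    a1[r, ] <- .norm_allele(v1)
    a2[r, ] <- .norm_allele(v2)
  }
  pops <- setNames(popv, varieties)
  genotype_matrix(a1, a2, pops = pops)
}

#' Write a codominant SSR genotype table
#'
#' @param gm an `ssr_genotypes` object.
#' @param path output file path.
#' @param dialect `"genalex_csv"` (default) or `"long_csv"`.
#' @return `path`, invisibly. Output is UTF-8, comma-separated, LF-ended.
#' @export
write_genotypes <- function(gm, path,
                            dialect = c("genalex_csv", "long_csv")) {
  dialect <- match.arg(dialect)
  con <- file(path, open = "wb")
  on.exit(close(con))
  put <- function(x) writeLines(x, con, sep = "\n", useBytes = TRUE)
  enc0 <- function(x) ifelse(is.na(x), "0", x)
  if (dialect == "long_csv") {
    put("variety,locus,allele1,allele2")
    for (l in gm$loci) {
      put(paste(gm$varieties, l, enc0(gm$a1[, l]), enc0(gm$a2[, l]),
                sep = ","))
    }
  } else {
    pops <- attr(gm, "pops")
    if (is.null(pops)) {
      pops <- setNames(rep("pop1", length(gm$varieties)), gm$varieties)
    }
    pop_names <- unique(unname(pops))
    sizes <- as.integer(table(factor(pops, levels = pop_names)))
    put(paste(c(length(gm$loci), length(gm$varieties), length(pop_names),
                sizes), collapse = ","))
    put(paste(c("ssrfp genotype export", "", pop_names), collapse = ","))
    hdr <- c("Sample", "Pop",
             as.vector(rbind(gm$loci, rep("", length(gm$loci)))))
    put(paste(hdr, collapse = ","))
    for (i in seq_along(gm$varieties)) {
      row <- c(gm$varieties[i], unname(pops[gm$varieties[i]]),
               as.vector(rbind(enc0(gm$a1[i, ]), enc0(gm$a2[i, ]))))
      put(paste(row, collapse = ","))
    }
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Allele calibration
# ---------------------------------------------------------------------------

#' Calibrate raw fragment sizes against reference allele bins
#'
#' Assigns each raw fragment size (bp) to the nearest reference bin center
#' within `tol`; a size equidistant from two bins goes to the lower center
#' (deterministic, reported as a warning). Sizes with no bin within `tol`
#' open a new bin labelled by the rounded size and are listed in the
#' novel-allele report. This is the reference-variety calibration step
#' that removes systematic size errors between experimental batches.
#'
#' @param raw_sizes data.frame with columns `variety`, `locus`, `size1`,
#'   `size2` (numeric bp; `NA` or `0` = missing).
#' @param bins `allele_bins` covering the loci present.
#' @param tol positive tolerance in bp; default `motif_length / 2` when
#'   the panel in `panel` declares a motif length, else 1.0.
#' @param panel optional `marker_panel` supplying motif lengths.
#' @return An `ssr_genotypes` object; attribute `calibration` is a list
#'   with `n_assigned`, `n_recalibrated` (sizes not already equal to a bin
#'   center), `ties` and `novel` (data.frame of new bins).
#' @export
calibrate_alleles <- function(raw_sizes, bins, tol = NULL, panel = NULL) {
  need <- c("variety", "locus", "size1", "size2")
  if (!all(need %in% names(raw_sizes))) {
    stop("raw_sizes must have columns variety,locus,size1,size2")
  }
  loci <- unique(raw_sizes$locus)
  varieties <- unique(raw_sizes$variety)
  default_tol <- function(l) {
    if (!is.null(tol)) return(tol)
    if (!is.null(panel)) {
      ml <- panel$motif_length[panel$name == l]
      if (length(ml) == 1L && !is.na(ml)) return(ml / 2)
    }
    1.0
  }
  a1 <- matrix(NA_character_, length(varieties), length(loci),
               dimnames = list(varieties, loci))
  a2 <- a1
  n_assigned <- 0L; n_recal <- 0L; n_tie <- 0L
  novel <- list()
  all_bins <- bins
  for (l in loci) {
    lb <- all_bins[all_bins$marker == l, , drop = FALSE]
    tl <- default_tol(l)
    if (tl <= 0) stop("tol must be > 0")
    sub <- raw_sizes[raw_sizes$locus == l, , drop = FALSE]
    assign_one <- function(size) {
      if (is.na(size) || size == 0) return(NA_character_)
      if (nrow(lb) == 0L ||
          min(abs(lb$center - size)) > tl + 1e-12) {
        lab <- as.character(round(size))
        if (!(lab %in% lb$bin)) {
          lb <<- rbind(lb, data.frame(marker = l, bin = lab,
                                      center = round(size),
                                      reference = NA_character_))
          lb <<- lb[order(lb$center), ]
          novel[[length(novel) + 1L]] <<-
            data.frame(locus = l, size = size, bin = lab)
        }
        n_assigned <<- n_assigned + 1L
        return(lab)
      }
      d <- abs(lb$center - size)
      hits <- which(abs(d - min(d)) < 1e-9)
      if (length(hits) > 1L) {
        n_tie <<- n_tie + 1L
        hits <- hits[which.min(lb$center[hits])]
      }
      n_assigned <<- n_assigned + 1L
      if (abs(lb$center[hits] - size) > 1e-12) n_recal <<- n_recal + 1L
      lb$bin[hits]
    }
    for (r in seq_len(nrow(sub))) {
      vi <- sub$variety[r]
      a1[vi, l] <- assign_one(sub$size1[r])
      a2[vi, l] <- assign_one(sub$size2[r])
    }
    all_bins <- rbind(all_bins[all_bins$marker != l, , drop = FALSE], lb)
  }
  if (n_tie > 0L) {
    warning(n_tie, " size(s) equidistant from two bins; ",
            "assigned to the lower center")
  }
  class(all_bins) <- c("allele_bins", "data.frame")
  gm <- genotype_matrix(a1, a2, bins = all_bins)
  attr(gm, "calibration") <- list(
    n_assigned = n_assigned, n_recalibrated = n_recal, ties = n_tie,
    novel = if (length(novel)) do.call(rbind, novel)
            else data.frame(locus = character(), size = numeric(),
                            bin = character())
  )
  gm
}
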