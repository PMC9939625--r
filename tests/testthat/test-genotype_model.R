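test_that("parsing, canonicalization and missing conventions", {
  gm <- gm_from_strings(list(A = c("188/190"), B = c("190/190")), "L1")
  expect_equal(dim(gm), c(2L, 1L))
  expect_equal(unname(gm$a1["A", "L1"]), "188")
  expect_equal(unname(gm$a2["A", "L1"]), "190")
  expect_equal(unname(gm$a1["B", "L1"]), "190")

  # pair order is canonicalized: ("b","a") stored as ("a","b")
  a1 <- matrix(c("190", "188"), 2, 1, dimnames = list(c("A", "B"), "L1"))
  a2 <- matrix(c("188", "190"), 2, 1, dimnames = list(c("A", "B"), "L1"))
  gm2 <- genotype_matrix(a1, a2)
  expect_equal(gm2$a1[, 1], c(A = "188", B = "188"))
  # numeric-aware ordering: "99" before "101"
  a1 <- matrix("101", 1, 1, dimnames = list("A", "L1"))
  a2 <- matrix("99", 1, 1, dimnames = list("A", "L1"))
  expect_equal(unname(genotype_matrix(a1, a2)$a1[1, 1]), "99")

  # half-called genotype becomes fully missing
  a1 <- matrix(c("188", NA), 1, 2, dimnames = list("A", c("L1", "L2")))
  a2 <- matrix(c(NA, NA), 1, 2, dimnames = list("A", c("L1", "L2")))
  gm3 <- genotype_matrix(a1, a2)
  expect_true(all(is.na(gm3$a1)))

  expect_error(genotype_matrix(
    matrix("1", 2, 1, dimnames = list(c("A", "A"), "L1")),
    matrix("1", 2, 1, dimnames = list(c("A", "A"), "L1"))),
    "duplicate variety")
})

test_that("long CSV and GenAlEx readers agree on missing conventions", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("variety,locus,allele1,allele2",
               "A,L1,188,190",
               "B,L1,190,190",
               "C,L1,0,0",
               "D,L1,.,."), tmp)
  gm <- read_genotypes(tmp, "long_csv")
  expect_equal(unname(gm$a1["A", "L1"]), "188")
  expect_true(is.na(gm$a1["C", "L1"]))
  expect_true(is.na(gm$a1["D", "L1"]))

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y\n1,2", bad)
  expect_error(read_genotypes(bad, "long_csv"), "variety,locus")
  expect_error(read_genotypes(file.path(tempdir(), "no-such-file.csv")),
               "not found")
})

test_that("write-read round trip is the identity for both dialects", {
  set.seed(11)
  gm <- random_gm(n = 8, L = 4, missing = 0.2)
  for (dialect in c("genalex_csv", "long_csv")) {
    tmp <- withr::local_tempfile(fileext = ".csv")
    write_genotypes(gm, tmp, dialect)
    back <- read_genotypes(tmp, dialect)
    expect_identical(back$a1, gm$a1, label = dialect)
    expect_identical(back$a2, gm$a2, label = dialect)
  }
})

test_that("GenAlEx reader validates its header", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("oops,header", "t", "s,p,L1,", "A,p,1,1"), tmp)
  expect_error(read_genotypes(tmp, "genalex_csv"), "header line 1")
})

test_that("allele calibration: nearest bin, ties, novel alleles, idempotence", {
  bins <- allele_bins("L1", c(188, 190))
  raw <- data.frame(variety = c("A", "A2", "B"), locus = "L1",
                    size1 = c(188.6, 195.0, 188.0),
                    size2 = c(190.2, 195.0, 189.0))
  expect_warning(gm <- calibrate_alleles(raw, bins, tol = 1.0),
                 "equidistant")
  expect_equal(unname(gm$a1["A", "L1"]), "188")   # 188.6 -> 188
  expect_equal(unname(gm$a2["A", "L1"]), "190")   # 190.2 -> 190
  # 189.0 equidistant -> lower center
  expect_equal(unname(gm$a2["B", "L1"]), "188")
  # 195 outside tol -> novel bin + report
  expect_equal(unname(gm$a1["A2", "L1"]), "195")
  cal <- attr(gm, "calibration")
  expect_equal(nrow(cal$novel), 1L)
  expect_equal(cal$novel$bin, "195")

  # idempotent: recalibrating already-binned data changes nothing
  binned <- data.frame(variety = gm$varieties, locus = "L1",
                       size1 = as.numeric(gm$a1[, "L1"]),
                       size2 = as.numeric(gm$a2[, "L1"]))
  gm2 <- calibrate_alleles(binned, attr(gm, "bins"), tol = 1.0)
  expect_identical(gm2$a1, gm$a1)
  expect_identical(gm2$a2, gm$a2)
  expect_equal(attr(gm2, "calibration")$n_recalibrated, 0L)
})

test_that("simulated jittered sizes are fully recovered within tolerance", {
  set.seed(42)
  centers <- seq(100, 140, by = 4)
  bins <- allele_bins("L1", centers)
  truth <- sample(centers, 100, replace = TRUE)
  raw <- data.frame(variety = sprintf("V%03d", 1:100), locus = "L1",
                    size1 = truth + rnorm(100, 0, 0.3),
                    size2 = truth + rnorm(100, 0, 0.3))
  gm <- calibrate_alleles(raw, bins, tol = 1.0)
  got <- as.numeric(c(gm$a1[, 1], gm$a2[, 1]))
  expect_equal(sort(got), sort(rep(truth, 2)))
  expect_equal(nrow(attr(gm, "calibration")$novel), 0L)
})

test_that("panel merging widens ranges and rejects chromosome conflicts", {
  a <- marker_panel(c("SSR101", "SSR90"), c(5, 10), c(188, 202),
                    c(227, 211))
  b <- marker_panel(c("SSR101", "SSR56"), c(5, 9), c(197, 241),
                    c(225, 272))
  expect_warning(m <- merge_panels(a, b), "SSR101")
  expect_equal(nrow(m), 3L)
  expect_equal(m$size_min[m$name == "SSR101"], 188L)
  expect_equal(m$size_max[m$name == "SSR101"], 227L)

  # disjoint panels: plain union
  d <- merge_panels(marker_panel("A", 1, 100, 120),
                    marker_panel(c("B", "C"), c(2, 3), c(1, 1),
                                 c(50, 60)))
  expect_equal(nrow(d), 3L)
  # merge with self is the identity
  self <- merge_panels(a, a)
  expect_equal(as.data.frame(self), as.data.frame(a))

  conflict <- marker_panel("SSR101", 6, 188, 227)
  expect_error(merge_panels(a, conflict), "chromosome")
})

test_that("packaged panel fixture matches its declared invariants", {
  pan <- ssr_core_panel()
  expect_equal(nrow(pan), 23L)
  expect_true(all(pan$size_min < pan$size_max))
  expect_true(all(pan$chromosome %in% 1:10))
  expect_equal(min(pan$size_min), 99L)   # smallest allele (bp)
  expect_equal(max(pan$size_max), 355L)  # largest allele (bp)
})
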