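# Combinatorial assembly of peaks into library-validated rotamers.

mkPeaks <- function(angles, heights = NULL, restype = "SER", chi = 1L) {
  if (is.null(heights)) heights <- rep(1, length(angles))
  p <- data.frame(chain = character(0), resno = integer(0),
                  insert = character(0), restype = character(0),
                  chi = integer(0), angle = numeric(0), height = numeric(0),
                  area = numeric(0))
  if (length(angles) > 0)
    p <- data.frame(chain = "A", resno = 1L, insert = "", restype = restype,
                    chi = chi, angle = angles, height = heights,
                    area = heights * 50)
  normalizePeakAreas(p[order(-p$height), , drop = FALSE])
}

test_that("two peaks on each of two dihedrals give four combinations", {
  pk <- list(mkPeaks(c(60, 180), chi = 1L), mkPeaks(c(30, 150), chi = 2L))
  combos <- enumerateCombinations(pk)
  expect_identical(nrow(combos), 4L)
  expect_setequal(paste(combos$chi1, combos$chi2),
                  c("60 30", "60 150", "180 30", "180 150"))
})

test_that("combination counts match a nested-loop enumeration", {
  pk <- list(mkPeaks(c(60, 180), chi = 1L),
             mkPeaks(100, chi = 2L),
             mkPeaks(c(-60, 60, 180) %% 360, chi = 3L))
  combos <- enumerateCombinations(pk)
  # brute force
  ref <- 0
  for (a in 1:2) for (b in 1:1) for (cc in 1:3) ref <- ref + 1
  expect_identical(nrow(combos), as.integer(ref))
  expect_identical(nrow(enumerateCombinations(list(mkPeaks(45)))), 1L)
  expect_error(enumerateCombinations(list(mkPeaks(45), mkPeaks(numeric(0)))),
               "at least one")
})

test_that("support is the weakest contributing peak", {
  pk <- list(mkPeaks(c(60, 180), heights = c(3, 2), chi = 1L),
             mkPeaks(100, heights = 1.5, chi = 2L))
  combos <- enumerateCombinations(pk)
  expect_true(all(combos$support == 1.5))
})

test_that("library matching respects the angular tolerance exactly", {
  lib <- loadRotamerLibrary()
  # serine p is modal at 62
  hit <- matchToLibrary(70, "SER", lib, tolerance = 30)
  expect_identical(hit$name, "p")
  expect_equal(hit$maxDeviation, 8)
  # an angle exactly tolerance+1 from every serine modal angle is rejected
  expect_null(matchToLibrary(93, "SER", lib, tolerance = 30))
  expect_identical(matchToLibrary(93, "SER", lib, tolerance = 31)$name, "p")
  expect_error(matchToLibrary(0, "XXX", lib), "unsupported residue")
})

test_that("ties go to the more frequent entry, as an exhaustive scan shows", {
  lib <- loadRotamerLibrary()
  # ASN t-20 (chi2 -20, f 0.12) and t30 (chi2 30, f 0.15) both within 30
  # degrees of chi2 = 5
  hit <- matchToLibrary(c(-176, 5), "ASN", lib, tolerance = 30)
  entries <- rotamersFor(lib, "ASN")
  best <- NULL
  for (i in seq_len(nrow(entries))) {
    d1 <- min(abs(-176 - entries$chi1[i]) %% 360,
              360 - abs(-176 - entries$chi1[i]) %% 360)
    d2 <- min(abs(5 - entries$chi2[i]) %% 360,
              360 - abs(5 - entries$chi2[i]) %% 360)
    if (max(d1, d2) <= 30 &&
        (is.null(best) || entries$frequency[i] > best$frequency))
      best <- entries[i, ]
  }
  expect_identical(hit$name, best$rotamer_name)
  expect_identical(hit$name, "t30")
})

test_that("symmetric terminal dihedrals match with a 180-degree period", {
  lib <- loadRotamerLibrary()
  # ASP m-20 is (-70, -15); chi2 is two-fold symmetric so -15 + 180 = 165
  # must match equally well
  a <- matchToLibrary(c(-70, -15), "ASP", lib, tolerance = 30)
  b <- matchToLibrary(c(-70, 165), "ASP", lib, tolerance = 30)
  expect_identical(a$name, b$name)
  expect_equal(a$maxDeviation, b$maxDeviation)
})

test_that("duplicate names collapse and the result is ordered by support", {
  lib <- loadRotamerLibrary()
  # two chi1 peaks both near serine p collapse onto one named rotamer
  pk <- list(mkPeaks(c(55, 75), heights = c(2, 1)))
  rot <- assembleRotamers(pk, "SER", lib)
  expect_identical(nrow(rot), 1L)
  expect_identical(rot$rotamer, "p")
  # the collapsed representative keeps the best geometry
  expect_equal(rot$maxDeviation, abs(55 - 62))
  # set-of-names oracle
  expect_identical(nrow(rot),
                   length(unique(na.omit(vapply(c(55, 75), function(a) {
                     h <- matchToLibrary(a, "SER", lib)
                     if (is.null(h)) NA_character_ else h$name
                   }, character(1))))))
})

test_that("with two matching peaks on one chi at least two rotamers emerge", {
  lib <- loadRotamerLibrary()
  pk <- list(mkPeaks(c(60, 295), heights = c(2, 1)))
  rot <- assembleRotamers(pk, "SER", lib)
  expect_gte(nrow(rot), 2L)
  expect_setequal(rot$rotamer, c("p", "m"))
  # ordered by support: the stronger peak's rotamer first
  expect_identical(rot$rotamer[1], "p")
})

test_that("rejected combinations produce an empty result", {
  lib <- loadRotamerLibrary()
  rot <- assembleRotamers(list(mkPeaks(110)), "SER", lib, tolerance = 20)
  expect_identical(nrow(rot), 0L)
})

test_that("enlarging the tolerance never loses matches", {
  lib <- loadRotamerLibrary()
  set.seed(21)
  for (rep in 1:10) {
    angles <- runif(3, 0, 360)
    pk <- list(mkPeaks(angles[1], chi = 1L), mkPeaks(angles[2], chi = 2L),
               mkPeaks(angles[3], chi = 3L))
    counts <- vapply(c(10, 20, 30, 45, 60), function(tol)
      nrow(assembleRotamers(pk, "MET", lib, tolerance = tol)), integer(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("the input conformation is flagged as the original rotamer", {
  lib <- loadRotamerLibrary()
  pk <- list(mkPeaks(c(60, 295), heights = c(1, 2)))
  rot <- assembleRotamers(pk, "SER", lib, currentChi = -64)
  expect_true(rot$isOriginal[rot$rotamer == "m"])
  expect_false(rot$isOriginal[rot$rotamer == "p"])
})

test_that("equal support breaks ties lexicographically by name", {
  lib <- loadRotamerLibrary()
  pk <- list(mkPeaks(c(60, 295), heights = c(1, 1)))
  rot <- assembleRotamers(pk, "SER", lib)
  expect_identical(rot$rotamer, c("m", "p"))
})
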