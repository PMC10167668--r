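# Conformer building, occupancy seeding, pruning, validation metrics and
# model output.

libG <- loadRotamerLibrary()

twoRotamerMet <- function() {
  xyz <- buildIdealResidue("MET", "mtp", libG, center = c(10, 10, 10))
  model <- MultiConformerModel(flexbuild:::residueAtomBlock(
    xyz, "MET", "A", 1, "", 1, 15))
  rot <- data.frame(restype = "MET", rotamer = c("mtp", "mtm"),
                    chi1 = c(-67, -67), chi2 = c(180, 180),
                    chi3 = c(75, -75), maxDeviation = 0,
                    support = c(5, 4), seedRelativeArea = c(0.5, 0.5),
                    isOriginal = c(TRUE, FALSE))
  list(model = model, rot = rot)
}

test_that("built conformers carry altlocs A/B and the modal chi angles", {
  x <- twoRotamerMet()
  out <- buildConformers(x$model, "A", 1, rotamers = x$rot, library = libG)
  expect_identical(residueAltlocs(out, "A", 1), c("A", "B"))
  cB <- residueCoords(out, "A", 1, alt = "B")
  expect_equal(measureChi(cB, "MET", 3), -75, tolerance = 1e-4)
  expect_equal(measureChi(cB, "MET", 1), -67, tolerance = 1e-4)
  # conformer A is bit-identical to the original conformation
  cA <- residueCoords(out, "A", 1, alt = "A")
  orig <- residueCoords(x$model, "A", 1)
  expect_identical(cA[rownames(orig), ], orig)
})

test_that("calpha mode keeps a single shared backbone", {
  x <- twoRotamerMet()
  out <- buildConformers(x$model, "A", 1, rotamers = x$rot, library = libG,
                         mode = "calpha")
  at <- modelAtoms(out)
  bb <- at[at$elety %in% c("N", "CA", "C", "O"), ]
  expect_true(all(bb$alt == ""))
  expect_true(all(bb$o == 1))
  expect_identical(sum(at$elety == "CA"), 1L)
  # full mode duplicates the backbone per conformer
  out2 <- buildConformers(x$model, "A", 1, rotamers = x$rot, library = libG,
                          mode = "full")
  expect_identical(sum(modelAtoms(out2)$elety == "CA"), 2L)
})

test_that("an empty rotamer list leaves the residue untouched", {
  x <- twoRotamerMet()
  none <- x$rot[0, ]
  out <- buildConformers(x$model, "A", 1, rotamers = none, library = libG)
  expect_identical(modelAtoms(out), modelAtoms(x$model))
})

test_that("building every library rotamer round-trips through measureChi", {
  # for a sample of residue types, build each entry as an alternate and
  # confirm the built conformer reproduces the modal angles
  for (rt in c("SER", "THR", "MET", "LYS")) {
    entries <- rotamersFor(libG, rt)
    base <- buildIdealResidue(rt, entries$rotamer_name[1], libG,
                              center = c(10, 10, 10))
    model <- MultiConformerModel(flexbuild:::residueAtomBlock(
      base, rt, "A", 1, "", 1, 15))
    n <- nChi(rt)
    rot <- data.frame(restype = rt, rotamer = entries$rotamer_name,
                      maxDeviation = 0,
                      support = rev(seq_len(nrow(entries))),
                      seedRelativeArea = 1 / nrow(entries),
                      isOriginal = seq_len(nrow(entries)) == 1)
    for (k in seq_len(n)) rot[[paste0("chi", k)]] <- entries[[paste0("chi", k)]]
    out <- buildConformers(model, "A", 1, rotamers = rot, library = libG)
    alts <- residueAltlocs(out, "A", 1)
    expect_identical(length(alts), nrow(entries))
    for (j in which(!rot$isOriginal)) {
      coords <- residueCoords(out, "A", 1, alt = LETTERS[j])
      got <- measureAllChi(coords, rt)
      want <- as.numeric(entries[j, paste0("chi", seq_len(n))])
      d <- abs(((got - want + 180) %% 360) - 180)
      expect_lt(max(d), 1e-4)
    }
  }
})

test_that("occupancies seed from areas, round to 2 decimals and sum to 1", {
  x <- twoRotamerMet()
  out <- buildConformers(x$model, "A", 1, rotamers = x$rot, library = libG)
  u <- assignOccupancies(out, "A", 1, scheme = "uniform")
  at <- modelAtoms(u)
  expect_equal(unique(at$o[at$alt == "A"]), 0.5)
  expect_equal(unique(at$o[at$alt == "B"]), 0.5)
  a <- assignOccupancies(out, "A", 1, scheme = "area",
                         seedAreas = c(A = 0.74, B = 0.26))
  at <- modelAtoms(a)
  expect_equal(unique(at$o[at$alt == "A"]), 0.74)
  expect_equal(unique(at$o[at$alt == "B"]), 0.26)
  expect_equal(unname(occupancySums(a)), 1)
  expect_warning(assignOccupancies(out, "A", 1, scheme = "area"),
                 "falling back to uniform")
})

test_that("rounding remainders go to conformer A so sums are exactly 1.00", {
  # three conformers with awkward fractions
  xyz <- buildIdealResidue("SER", "m", libG, center = c(10, 10, 10))
  model <- MultiConformerModel(flexbuild:::residueAtomBlock(
    xyz, "SER", "A", 1, "", 1, 15))
  rot <- data.frame(restype = "SER", rotamer = c("m", "p", "t"),
                    chi1 = c(-65, 62, -177), maxDeviation = 0,
                    support = c(3, 2, 1),
                    seedRelativeArea = c(1 / 3, 1 / 3, 1 / 3),
                    isOriginal = c(TRUE, FALSE, FALSE))
  out <- buildConformers(model, "A", 1, rotamers = rot, library = libG)
  a <- assignOccupancies(out, "A", 1, scheme = "area",
                         seedAreas = c(A = 0.5, B = 0.3, C = 0.2))
  expect_equal(unname(occupancySums(a)), 1)
  u <- assignOccupancies(out, "A", 1, scheme = "uniform")
  at <- modelAtoms(u)
  occ <- vapply(c("A", "B", "C"),
                function(l) at$o[at$alt == l][1], numeric(1))
  # brute-force remainder allocation: floor to 2 decimals, remainder to A
  ref <- round(rep(1 / 3, 3), 2)
  ref[1] <- ref[1] + round(1 - sum(ref), 2)
  expect_equal(unname(occ), ref)
  expect_equal(sum(occ), 1)
})

test_that("pruning removes weak conformers and renormalizes", {
  x <- twoRotamerMet()
  out <- buildConformers(x$model, "A", 1, rotamers = x$rot, library = libG)
  z <- assignOccupancies(out, "A", 1, scheme = "area",
                         seedAreas = c(A = 1, B = 0))
  pruned <- pruneLowOccupancy(z, 0.01)
  expect_identical(residueAltlocs(pruned, "A", 1), character(0))
  expect_true(all(modelAtoms(pruned)$o == 1))
  # all conformers above the floor: untouched
  ok <- assignOccupancies(out, "A", 1, scheme = "area",
                          seedAreas = c(A = 0.6, B = 0.4))
  expect_identical(modelAtoms(pruneLowOccupancy(ok, 0.01)), modelAtoms(ok))
  # survivor count is non-increasing in the threshold
  counts <- vapply(c(0, 0.1, 0.3, 0.45, 0.7), function(th) {
    length(residueAltlocs(suppressWarnings(pruneLowOccupancy(ok, th)),
                          "A", 1))
  }, integer(1))
  expect_true(all(diff(counts) <= 0))
  # pruning everything keeps the strongest conformer with a warning
  expect_warning(allGone <- pruneLowOccupancy(ok, 0.9), "keeping the highest")
  expect_true(all(modelAtoms(allGone)$o == 1))
})

test_that("normalized B factors match hand arithmetic for n = 2", {
  at <- flexbuild:::residueAtomBlock(
    buildIdealResidue("SER", "m", libG), "SER", "A", 1, "", 1, 15)[1:2, ]
  at$b <- c(10, 20)
  model <- MultiConformerModel(at)
  # hand arithmetic: mean 15, deviations +/-5; population sd 5, sample sd
  # 5 * sqrt(2)
  expect_equal(bNorm(model), c(-1, 1), tolerance = 1e-12)
  expect_equal(bNorm(model, sdType = "sample"), c(-1, 1) / sqrt(2),
               tolerance = 1e-12)
  # adding a constant leaves B_norm unchanged
  at2 <- at
  at2$b <- at$b + 7.5
  expect_equal(bNorm(MultiConformerModel(at2)), bNorm(model))
  at3 <- at
  at3$b <- c(12, 12)
  expect_error(bNorm(MultiConformerModel(at3)), "zero standard deviation")
})

test_that("rscc is near 1 against the generating model and -1 when flipped", {
  fx <- makeFixture("single_conformer", noiseLevel = 0)
  map <- sigmaScale(fx$map)
  sel <- seq_len(nrow(modelAtoms(fx$inputModel)))
  expect_gte(rscc(map, fx$inputModel, sel), 0.999)
  flipped <- DensityMap(-mapGrid(fx$map), mapCell(fx$map))
  expect_lte(rscc(sigmaScale(flipped), fx$inputModel, sel), -0.999)
  expect_error(rscc(map, fx$inputModel, sel, radius = 0.05),
               "selection too small")
})

test_that("per-conformer rscc validates built alternates", {
  fx <- makeFixture("serine_70_30", seed = 1)
  map <- sigmaScale(fx$map)
  r <- runPipeline(map, fx$inputModel)
  at <- modelAtoms(r$model)
  for (lab in c("A", "B")) {
    sel <- which(at$alt == lab & at$elety == "OG")
    expect_gte(rscc(map, r$model, sel), 0.8)
  }
  # omitting the minor conformer degrades the fit in its region: add a
  # zero-occupancy marker atom at the minor OG position so the mask covers
  # that region while the calculated density comes from the major conformer
  majorOnly <- stripAltlocs(r$model, keep = "A")
  selB <- which(at$alt == "B" & at$elety == "OG")
  ghost <- at[selB, , drop = FALSE]
  ghost$o <- 0
  atM <- modelAtoms(majorOnly)
  probe <- MultiConformerModel(rbind(atM, ghost))
  expect_lt(rscc(map, probe, nrow(atM) + 1L),
            rscc(map, r$model, selB))
})

test_that("models round-trip through PDB with formatted occupancies", {
  x <- twoRotamerMet()
  out <- buildConformers(x$model, "A", 1, rotamers = x$rot, library = libG)
  out <- assignOccupancies(out, "A", 1, scheme = "area",
                           seedAreas = c(A = 0.6, B = 0.4))
  f <- tempfile(fileext = ".pdb")
  writeModel(out, f)
  back <- readModel(f)
  a1 <- modelAtoms(out)
  a2 <- modelAtoms(back)
  expect_identical(nrow(a1), nrow(a2))
  expect_identical(a1$elety, a2$elety)
  expect_identical(a1$alt, a2$alt)
  expect_equal(as.matrix(a1[, c("x", "y", "z")]),
               as.matrix(a2[, c("x", "y", "z")]), tolerance = 1e-3)
  expect_setequal(unique(a2$o), c(0.6, 0.4))
  # independent fixed-width parse of the occupancy column
  lines <- readLines(f)
  atomLines <- grep("^ATOM", lines, value = TRUE)
  occCol <- unique(substr(atomLines, 55, 60))
  expect_setequal(trimws(occCol), c("0.60", "0.40"))
  altCol <- unique(substr(atomLines, 17, 17))
  expect_setequal(altCol, c("A", "B"))
})

test_that("mmCIF output parses in an independent reader", {
  x <- twoRotamerMet()
  out <- buildConformers(x$model, "A", 1, rotamers = x$rot, library = libG)
  out <- assignOccupancies(out, "A", 1, scheme = "uniform")
  f <- tempfile(fileext = ".cif")
  writeModel(out, f)
  back <- suppressWarnings(bio3d::read.cif(f, verbose = FALSE,
                                           rm.alt = FALSE))
  expect_identical(nrow(back$atom), nrow(modelAtoms(out)))
  expect_setequal(unique(back$atom$alt), c("A", "B"))
})

test_that("the clash report flags overlapping conformers but never blocks", {
  # two serines placed on top of each other must clash
  xyz <- buildIdealResidue("SER", "m", libG, center = c(10, 10, 10))
  a1 <- flexbuild:::residueAtomBlock(xyz, "SER", "A", 1, "", 1, 15)
  a2 <- flexbuild:::residueAtomBlock(xyz, "SER", "A", 2, "", 1, 15)
  clashing <- MultiConformerModel(rbind(a1, a2))
  expect_gt(nrow(clashReport(clashing)), 0)
  # atoms in different altlocs never clash with each other
  x <- twoRotamerMet()
  out <- buildConformers(x$model, "A", 1, rotamers = x$rot, library = libG)
  rep <- clashReport(out)
  expect_false(any(rep$alt1 != "" & rep$alt2 != "" & rep$alt1 != rep$alt2))
})
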