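# Synthetic ground-truth generation: ideal residues, the Gaussian forward
# model and the fixture registry.

test_that("every library entry builds and measures back to its modal angles", {
  lib <- loadRotamerLibrary()
  for (i in seq_len(nrow(lib))) {
    rt <- lib$residue_type[i]
    xyz <- buildIdealResidue(rt, lib$rotamer_name[i], lib)
    got <- measureAllChi(xyz, rt)
    want <- as.numeric(lib[i, paste0("chi", seq_along(got))])
    d <- abs(((got - want + 180) %% 360) - 180)
    expect_lt(max(d), 1e-4)
  }
})

test_that("residues without rotamers are rejected", {
  expect_error(buildIdealResidue("GLY", "p"), "no rotamers")
  expect_error(buildIdealResidue("SER", "zz"), "valid names")
})

test_that("a single atom renders a Gaussian peaking at its nearest node", {
  at <- data.frame(type = "ATOM", eleno = 1L, elety = "CA", alt = "",
                   resid = "ALA", chain = "A", resno = 1L, insert = "",
                   x = 10.1, y = 9.9, z = 10.0, o = 1, b = 15, elesy = "C")
  m <- renderMap(MultiConformerModel(at), spacing = 0.25)
  g <- mapGrid(m)
  idx <- which(g == max(g), arr.ind = TRUE)
  # nearest node to (10.1, 9.9, 10.0) at 0.25 A spacing (0-based 40, 40, 40)
  expect_identical(as.integer(idx), c(41L, 41L, 41L))
})

test_that("peak density scales linearly with occupancy", {
  mk <- function(occ) {
    at <- data.frame(type = "ATOM", eleno = 1L, elety = "CA", alt = "",
                     resid = "ALA", chain = "A", resno = 1L, insert = "",
                     x = 10, y = 10, z = 10, o = occ, b = 15, elesy = "C")
    max(mapGrid(renderMap(MultiConformerModel(at))))
  }
  expect_equal(mk(0.5) / mk(1), 0.5, tolerance = 1e-9)
})

test_that("rendering is linear in the conformer mixture", {
  lib <- loadRotamerLibrary()
  mkModel <- function(rot, occ) {
    xyz <- buildIdealResidue("SER", rot, lib, center = c(10, 10, 10))
    MultiConformerModel(flexbuild:::residueAtomBlock(xyz, "SER", "A", 1, "",
                                                     occ, 15))
  }
  mixAtoms <- rbind(modelAtoms(mkModel("m", 0.7)), modelAtoms(mkModel("p", 0.3)))
  mix <- renderMap(MultiConformerModel(mixAtoms))
  gA <- mapGrid(renderMap(mkModel("m", 1)))
  gB <- mapGrid(renderMap(mkModel("p", 1)))
  expect_lt(max(abs(mapGrid(mix) - (0.7 * gA + 0.3 * gB))), 1e-9)
})

test_that("fixtures are deterministic for a fixed seed", {
  f1 <- makeFixture("serine_70_30", seed = 5)
  f2 <- makeFixture("serine_70_30", seed = 5)
  expect_identical(mapGrid(f1$map), mapGrid(f2$map))
  expect_identical(modelAtoms(f1$inputModel), modelAtoms(f2$inputModel))
  f3 <- makeFixture("serine_70_30", seed = 6)
  expect_false(identical(mapGrid(f1$map), mapGrid(f3$map)))
  expect_error(makeFixture("no_such_case"), "available")
})

test_that("fixture files are written and read back consistently", {
  dir <- tempfile()
  fx <- makeFixture("serine_70_30", seed = 1, dir = dir)
  expect_true(file.exists(fx$modelPath))
  expect_true(file.exists(fx$mapPath))
  truth <- read.csv(fx$truthPath)
  expect_identical(truth$rotamer, fx$truth$rotamer)
  m <- readCCP4Map(fx$mapPath)
  expect_equal(mapGrid(m), mapGrid(fx$map), tolerance = 1e-6)
})

test_that("chi1 trace peak heights reflect the 0.7/0.3 occupancy split", {
  fx <- makeFixture("serine_70_30", noiseLevel = 0)
  map <- sigmaScale(fx$map)
  tr <- ringerTrace(map, fx$inputModel, "A", 1, chiIndex = 1)
  pk <- findDensityPeaks(tr, threshold = 0.3)
  expect_gte(nrow(pk), 2L)
  ratio <- pk$height[1] / pk$height[2]
  expect_lt(abs(ratio - 7 / 3) / (7 / 3), 0.15)
})

test_that("minor-conformer detection degrades monotonically with occupancy", {
  # at a noise level that drowns a 0.1-occupancy conformer, a 0.3 conformer
  # must still be detected whenever the weaker one is
  lib <- loadRotamerLibrary()
  detects <- function(minorOcc, seed) {
    mixAtoms <- rbind(
      modelAtoms(MultiConformerModel(flexbuild:::residueAtomBlock(
        buildIdealResidue("SER", "m", lib, center = c(10, 10, 10)),
        "SER", "A", 1, "A", 1 - minorOcc, 15))),
      modelAtoms(MultiConformerModel(flexbuild:::residueAtomBlock(
        buildIdealResidue("SER", "p", lib, center = c(10, 10, 10)),
        "SER", "A", 1, "B", minorOcc, 15))))
    truthModel <- MultiConformerModel(mixAtoms)
    map <- renderMap(truthModel, noiseSd = 0.09, seed = seed)
    input <- stripAltlocs(truthModel, keep = "A")
    tr <- ringerTrace(sigmaScale(map), input, "A", 1, chiIndex = 1)
    pk <- findDensityPeaks(tr, threshold = 0.3)
    any(abs(((pk$angle - 62 + 180) %% 360) - 180) <= 15)
  }
  for (seed in 1:5) {
    found <- vapply(c(0.05, 0.15, 0.3, 0.45), detects, logical(1),
                    seed = seed)
    # once detected at some occupancy, detection persists at higher ones
    expect_true(all(diff(as.integer(found)) >= 0))
  }
})
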