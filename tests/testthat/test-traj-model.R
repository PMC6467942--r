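# Core data model: topology/trajectory/selection, readers/writers,
# preprocessing.

threeAtomTraj <- function(nFrames = 2) {
  top <- Topology(data.frame(name = "CA", resname = "ALA", resid = 1:3,
                             chain = "A"),
                  data.frame(chain = "A", first = 1, last = 3, kind = "helix"))
  set.seed(99)
  Trajectory(top, array(rnorm(nFrames * 3 * 3, sd = 2), dim = c(nFrames, 3, 3)))
}

test_that("multi-model PDB round trip: 3-atom topology, 2 models", {
  traj <- threeAtomTraj(2)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(traj, f, "pdb")
  back <- readTrajectory(f, dialect = "pdb",
                         segments = segments(topology(traj)))
  expect_equal(nFrames(back), 2)
  expect_equal(nAtoms(back), 3)
  expect_lt(max(abs(coords(back) - coords(traj))), 1e-3)
  expect_equal(atoms(topology(back))$resid, 1:3)
})

test_that("PDB frame atom-count mismatch names the frame", {
  traj <- threeAtomTraj(2)
  ftop <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(subsampleTrajectory(traj, 2), ftop, "pdb")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(traj, f, "pdb")
  lines <- readLines(f)
  atomLines <- which(startsWith(lines, "ATOM"))
  writeLines(lines[-atomLines[5]], f)   # drop one atom from model 2
  expect_error(readTrajectory(ftop, f, dialect = "pdb"), "frame 2")
})

test_that("unparseable PDB record errors with line number", {
  traj <- threeAtomTraj(2)
  ftop <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(subsampleTrajectory(traj, 2), ftop, "pdb")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(traj, f, "pdb")
  lines <- readLines(f)
  i <- which(startsWith(lines, "ATOM"))[2]
  lines[i] <- substr(lines[i], 1, 40)   # truncate into the coordinate field
  writeLines(lines, f)
  expect_error(readTrajectory(ftop, f, dialect = "pdb"),
               sprintf("line %d", i))
})

test_that("xtc dialect raises a clear unsupported error", {
  f <- withr::local_tempfile(fileext = ".xtc")
  writeLines("", f)
  expect_error(readTrajectory(f, dialect = "xtc"), "xtc")
})

test_that("XYZ dialect round trip is bit-faithful to writer precision", {
  traj <- threeAtomTraj(4)
  ftop <- withr::local_tempfile(fileext = ".pdb")
  writeTrajectory(subsampleTrajectory(traj, nFrames(traj)), ftop, "pdb")
  fxyz <- withr::local_tempfile(fileext = ".xyz")
  writeTrajectory(traj, fxyz, "xyz")
  back <- readTrajectory(ftop, fxyz, dialect = "xyz",
                         segments = segments(topology(traj)))
  expect_equal(nFrames(back), 4)
  expect_lt(max(abs(coords(back) - coords(traj))), 1e-6)
  expect_equal(frameTimes(back), frameTimes(traj))
  # malformed: wrong atom count on a frame header
  lines <- readLines(fxyz)
  lines[1] <- "2"
  writeLines(lines, fxyz)
  expect_error(readTrajectory(ftop, fxyz, dialect = "xyz"), "frame 1")
})

test_that("stripSolvent removes solvent atoms and preserves order", {
  top <- Topology(data.frame(
    name = c("CA", "CA", rep("O", 10)),
    resname = c("ALA", "GLY", rep("HOH", 10)),
    resid = c(1, 2, 3:12), chain = "A"),
    data.frame(chain = "A", first = 1, last = 2, kind = "helix"))
  traj <- Trajectory(top, array(rnorm(2 * 12 * 3), dim = c(2, 12, 3)))
  dry <- stripSolvent(traj, "HOH")
  expect_equal(nAtoms(dry), 2)
  expect_equal(atoms(topology(dry))$resname, c("ALA", "GLY"))
  expect_equal(coords(dry), coords(traj)[, 1:2, , drop = FALSE])
  # identity cases: empty set and absent resname return the same object
  expect_identical(stripSolvent(traj, character(0)), traj)
  expect_identical(stripSolvent(traj, "XYZ"), traj)
  # idempotence
  expect_identical(stripSolvent(dry, "HOH"), dry)
  # stripping everything is an error
  expect_error(stripSolvent(traj, c("ALA", "GLY", "HOH")), "every atom")
})

test_that("resolveSelection applies clauses conjunctively", {
  tpl <- makeDimerTemplate(10, 12.5)
  top <- topology(tpl)
  seg <- segments(top)
  helix <- seg[seg$kind == "helix", ]
  # default: Ca of helix segments only
  idx <- resolveSelection(top, AtomSelection())
  a <- atoms(top)[idx, ]
  expect_true(all(a$name == "CA"))
  inHelix <- vapply(seq_len(nrow(a)), function(i)
    any(helix$chain == a$chain[i] & helix$first <= a$resid[i] &
        helix$last >= a$resid[i]), logical(1))
  expect_true(all(inHelix))
  expect_equal(length(idx), sum(helix$last - helix$first + 1))
  # segment filter off: all Ca atoms
  all_ca <- resolveSelection(top, AtomSelection(segmentKinds = NULL))
  expect_equal(length(all_ca), nAtoms(tpl))
  # chain filter on the symmetric dimer halves the default
  idxA <- resolveSelection(top, AtomSelection(chains = "A"))
  expect_equal(length(idxA), length(idx) / 2)
  # strictly increasing and idempotent
  expect_true(all(diff(idx) > 0))
  expect_identical(idx, resolveSelection(top, AtomSelection()))
  # empty result names the first failing clause
  expect_error(resolveSelection(top, AtomSelection(atomNames = "ZZ")),
               "atomNames")
  expect_error(resolveSelection(top, AtomSelection(segmentKinds = "sheet")),
               "segmentKinds")
})

test_that("subsampleTrajectory keeps strided frames with their times", {
  traj <- threeAtomTraj(10)
  s3 <- subsampleTrajectory(traj, 3)
  expect_equal(nFrames(s3), 4)
  expect_equal(frameTimes(s3), frameTimes(traj)[c(1, 4, 7, 10)])
  expect_equal(coords(s3), coords(traj)[c(1, 4, 7, 10), , , drop = FALSE])
  expect_equal(coords(subsampleTrajectory(traj, 1)), coords(traj))
  expect_equal(nFrames(subsampleTrajectory(traj, 99)), 1)
  expect_error(subsampleTrajectory(traj, 0), "stride")
})

test_that("AnalysisConfig and Trajectory validity reject bad values", {
  expect_error(AnalysisConfig(rmsdCutoff = 0))
  expect_error(AnalysisConfig(nPcaComponents = 0L))
  expect_error(AnalysisConfig(stride = 0L))
  expect_silent(AnalysisConfig(ticaLag = 5L, kmeansK = 3L))
  top <- Topology(data.frame(name = "CA", resname = "ALA", resid = 1:3,
                             chain = "A"))
  co <- array(0, dim = c(2, 3, 3))
  expect_error(Trajectory(top, co, times = c(1, 1)))      # not increasing
  co[2, 1, 1] <- NaN
  expect_error(Trajectory(top, co))                        # non-finite
})

test_that("checkImagingArtifacts flags jumps over half a box length", {
  traj <- threeAtomTraj(3)
  co <- coords(traj)
  expect_silent(bad0 <- checkImagingArtifacts(traj, c(100, 100, 100)))
  expect_equal(nrow(bad0), 0)
  co[2, 1, ] <- co[1, 1, ] + c(30, 0, 0)   # 30 A jump, box 40 -> flagged
  jumpy <- Trajectory(topology(traj), co)
  expect_warning(bad <- checkImagingArtifacts(jumpy, c(40, 40, 40)),
                 "reimaged")
  expect_true(2 %in% bad$frame && 1 %in% bad$atom)
})
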