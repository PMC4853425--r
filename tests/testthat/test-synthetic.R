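test_that("helix bundles have the expected atom counts and axial length", {
  bun <- generateHelixBundle(nres = 30, rise = 1.5)
  at <- atoms(bun)
  expect_equal(nrow(at), 4 * 30 * 4)       # 4 chains x 30 residues x N,CA,C,O
  expect_setequal(unique(at$chain), c("A", "B", "C", "D"))
  expect_equal(sort(unique(at$resno)), 1:30)
  ## CA trace spans exactly 29 rises along the helix axis
  ca <- at[at$chain == "A" & at$atom == "CA", ]
  expect_equal(max(ca$z) - min(ca$z), 29 * 1.5, tolerance = 1e-9)
  ## antiparallel: chain B runs the other way
  cb <- at[at$chain == "B" & at$atom == "CA", ]
  expect_lt(stats::cor(cb$resno, cb$z), 0)
})

test_that("bundle geometry parameters propagate and regeneration is
           bit-identical", {
  b1 <- generateHelixBundle(nres = 12, rise = 1.48, bundleRadius = 9)
  b2 <- generateHelixBundle(nres = 12, rise = 1.48, bundleRadius = 9)
  expect_identical(atoms(b1), atoms(b2))
  ## chains sit on a square of circumradius bundleRadius: adjacent axes are
  ## a side apart (radius * sqrt(2)), opposite axes a diagonal (2 * radius)
  at <- atoms(b1)
  axis2d <- function(ch) colMeans(as.matrix(at[at$chain == ch,
                                               c("x", "y")]))
  expect_equal(sqrt(sum((axis2d("A") - axis2d("B"))^2)), 9 * sqrt(2),
               tolerance = 0.02)
  expect_equal(sqrt(sum((axis2d("A") - axis2d("C"))^2)), 18,
               tolerance = 0.02)
})

test_that("planted motifs are recovered at their ground-truth location", {
  bun <- makeMotifHost()
  q <- extractMotif(bun, data.frame(chain = c("A", "C"), start = c(3, 5),
                                    end = c(8, 10)))
  host <- generateHelixBundle(nres = 20, rise = 1.45, resPerTurn = 3.63,
                              bundleRadius = 13)
  ## zero noise: found at (numerically) zero rmsd
  p0 <- plantMotif(host, q, sigma = 0, seed = 1,
                   segments = data.frame(chain = c("A", "B"),
                                         start = c(2, 2)))
  h0 <- searchMotif(q, list(x = p0$structure), cutoff = 0.1)
  expect_gt(nrow(h0), 0)
  expect_lt(h0$rmsd[1], 1e-6)
  ## repeated seeds at sigma = 0.3: the plant is recovered below the 1.9 A
  ## cutoff in nearly all replicates
  found <- vapply(1:20, function(s) {
    p <- plantMotif(host, q, sigma = 0.3, seed = s,
                    segments = data.frame(chain = c("C", "D"),
                                          start = c(3, 6)))
    h <- searchMotif(q, list(x = p$structure), cutoff = 1.9)
    nrow(h) > 0 && any(vapply(h$placements, function(pl)
      all(pl$chain == c("C", "D")) && all(pl$start == c(3, 6)),
      logical(1)))
  }, logical(1))
  expect_gte(mean(found), 0.95)
})

test_that("planting ground truth survives file round-trips", {
  bun <- makeMotifHost()
  q <- extractMotif(bun, data.frame(chain = "A", start = 3, end = 8))
  p <- plantMotif(generateHelixBundle(nres = 15), q, sigma = 0.2, seed = 3)
  tf <- tempfile(fileext = ".json")
  jsonlite::write_json(p$truth, tf, auto_unbox = TRUE, digits = NA)
  back <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(back$segments$chain, p$truth$segments$chain)
  expect_equal(back$segments$start, p$truth$segments$start)
  expect_equal(back$sigma, p$truth$sigma)
})

test_that("structures survive PDB round-trips including cell metadata", {
  st <- generateLatticeFixture(cell = c(30, 30, 40, 90, 90, 120),
                               spaceGroup = "P 62")
  tf <- tempfile(fileext = ".pdb")
  writeStructurePDB(st, tf)
  back <- readStructure(tf)
  expect_equal(cellParams(back), cellParams(st), tolerance = 1e-3)
  expect_equal(spaceGroup(back), "P 62")
  expect_equal(atoms(back)$x, atoms(st)$x, tolerance = 1e-3)
  expect_equal(atoms(back)$resno, atoms(st)$resno)
})

test_that("FEP fixtures expose analytic truth and regenerate identically", {
  f1 <- generateFepFixture("harmonic")
  expect_true(is.finite(f1$meta$analyticDeltaG))
  s1 <- generateFepFixture("host-guest", seed = 4)$factory(1, 1)
  s2 <- generateFepFixture("host-guest", seed = 4)$factory(1, 1)
  expect_identical(positions(s1), positions(s2))
  s3 <- generateFepFixture("host-guest", seed = 5)$factory(1, 1)
  expect_false(identical(positions(s1), positions(s3)))
  expect_error(generateFepFixture("plasma"), "arg")
  ## the two alchemical sets are the ligand and dummy, mutually exclusive
  expect_length(s1@decoupleSet, 1)
  expect_length(s1@coupleSet, 1)
  ## lj-solute fixture provides both steps
  f2 <- generateFepFixture("lj-solute", nSolvent = 10)
  expect_s4_class(f2$factory(2, 1), "ParticleSystem")
  expect_s4_class(f2$factory(2, 2), "ParticleSystem")
})

test_that("particle systems survive YAML config round-trips", {
  fx <- generateFepFixture("host-guest", seed = 2, nSolvent = 6)
  sys <- fx$factory(1, 1)
  tf <- tempfile(fileext = ".yaml")
  writeParticleSystem(sys, tf)
  back <- readParticleSystem(tf)
  expect_equal(positions(back), positions(sys), tolerance = 1e-12)
  expect_equal(back@decoupleSet, sys@decoupleSet)
  expect_equal(length(back@restraints), length(sys@restraints))
  expect_equal(systemEnergy(back, 0.3)[["total"]],
               systemEnergy(sys, 0.3)[["total"]], tolerance = 1e-12)
})

test_that("AUC datasets carry a complete truth record and regenerate
           identically", {
  d1 <- generateAucDataset(noise = 0.005, seed = 6)
  d2 <- generateAucDataset(noise = 0.005, seed = 6)
  expect_identical(d1$scans[[1]]@absorbance, d2$scans[[1]]@absorbance)
  expect_length(d1$scans, 4)
  expect_equal(vapply(d1$scans, function(s) s@speed, numeric(1)),
               c(25000, 30000, 35000, 40000))
  need <- c("kd", "baseMass", "crefs", "baseline", "noise", "seed",
            "cLoad", "vbar", "rho", "epsilon", "path", "speeds")
  expect_true(all(need %in% names(d1$truth)))
  ## mass conservation across speeds: window-average signal concentration
  ## matches the loading concentration (checked through the noise-free set)
  d0 <- generateAucDataset(noise = 0, seed = 6)
  for (s in d0$scans) {
    conc <- (s@absorbance - 0.02) / (3000 * 1.2)
    expect_equal(mean(conc), d0$truth$cLoad, tolerance = 1e-10)
  }
})
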