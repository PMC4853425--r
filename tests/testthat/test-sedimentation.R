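test_that("the reduced-mass exponent has the right limits, linearity and
           CGS value", {
  expect_equal(reducedMassSigma(13000, 0.73, 1.0, 0), 0)
  s1 <- reducedMassSigma(13000, 0.73, 1.0, 25000)
  expect_equal(reducedMassSigma(26000, 0.73, 1.0, 25000), 2 * s1,
               tolerance = 1e-12)
  ## independent hand evaluation in CGS units
  omega <- 25000 * 2 * pi / 60
  want <- 13000 * (1 - 0.73) * omega^2 / (2 * 8.31446261815324e7 * 298.15)
  expect_equal(s1, want, tolerance = 1e-12)
  expect_error(reducedMassSigma(13000, 1.1, 1.0, 25000), "sediment")
})

test_that("a noise-free single-species scan is log-linear in r^2 with
           slope sigma", {
  m <- AssociationModel(13400, scheme = "none")
  sc <- simulateScan(m, 30000, cref = 4e-5, baseline = 0.015, noise = 0)
  sigma <- reducedMassSigma(13400, 0.73, 1.0, 30000)
  y <- log(sc@absorbance - 0.015)
  fit <- stats::lm(y ~ I(sc@radii^2))
  expect_equal(unname(stats::coef(fit)[2]), sigma, tolerance = 1e-8)
})

test_that("association limits: a huge Kd removes the octamer and a tiny Kd
           leaves pure octamer behaviour", {
  radii <- seq(6.9, 7.15, length.out = 40)
  mNone <- AssociationModel(13400, scheme = "none")
  mWeak <- AssociationModel(13400, scheme = "self", kd = 1e6)
  aNone <- simulateScan(mNone, 30000, radii, cref = 4e-5, baseline = 0,
                        noise = 0)@absorbance
  aWeak <- simulateScan(mWeak, 30000, radii, cref = 4e-5, baseline = 0,
                        noise = 0)@absorbance
  expect_equal(aWeak, aNone, tolerance = 1e-6)
  ## complete association: profile has the octamer exponent everywhere
  ## tiny Kd at high loading: tetramer admixture ~ Kd / (2 cref)
  mTight <- AssociationModel(13400, scheme = "self", kd = 1e-12)
  aT <- simulateScan(mTight, 30000, radii, cref = 1e-3, baseline = 0,
                     noise = 0)@absorbance
  sig8 <- 2 * reducedMassSigma(13400, 0.73, 1.0, 30000)
  slope <- unname(stats::coef(stats::lm(log(aT) ~ I(radii^2)))[2])
  expect_equal(slope, sig8, tolerance = 1e-6)
})

test_that("simulated two-species scans satisfy the mass-action radial link
           everywhere", {
  m <- AssociationModel(13400, scheme = "self", kd = 118e-6)
  radii <- seq(6.9, 7.15, length.out = 50)
  for (sp in c(25000, 40000)) {
    sigma <- reducedMassSigma(13400, 0.73, 1.0, sp)
    cref <- 4e-5
    ct <- cref * exp(sigma * (radii^2 - radii[1]^2))
    sc <- simulateScan(m, sp, radii, cref = cref, baseline = 0, noise = 0)
    ## recover the octamer signal from the total and check c8 Kd / c4^2 = 1
    co <- (sc@absorbance / (3000 * 1.2) - ct) / 2
    link <- co * 118e-6 / ct^2
    expect_lt(max(abs(link - 1)), 1e-8)
  }
})

test_that("noise-free global fits recover the generating parameters
           essentially exactly", {
  ds <- generateAucDataset(noise = 0, seed = 2)
  m <- AssociationModel(13400, scheme = "self")
  fit <- fitGlobalAuc(ds$scans, m)
  expect_true(fit$converged)
  expect_lt(fit$rms, 1e-9)
  expect_equal(fit$kd, 118e-6, tolerance = 1e-6)
  expect_equal(fit$baseline, rep(0.02, 4), tolerance = 1e-8)
})

test_that("the four-speed protocol at Kd 118 uM recovers the constant
           within ten percent", {
  kds <- vapply(1:6, function(s) {
    ds <- generateAucDataset(noise = 0.005, seed = s)
    fitGlobalAuc(ds$scans, AssociationModel(13400, scheme = "self"))$kd
  }, numeric(1))
  expect_lt(abs(stats::median(kds) - 118e-6) / 118e-6, 0.10)
})

test_that("model selection keeps the single-species model for
           single-species truth", {
  m0 <- AssociationModel(13400, scheme = "none")
  scans <- lapply(c(25000, 30000, 35000, 40000), function(sp)
    simulateScan(m0, sp, cref = 4e-5, baseline = 0.02, noise = 0.005,
                 seed = sp))
  sel <- selectAucModel(scans, m0)
  expect_equal(sel$model, "single")
  ## and the self-association model for associating truth
  ds <- generateAucDataset(noise = 0.005, seed = 9)
  sel2 <- selectAucModel(ds$scans, AssociationModel(13400))
  expect_equal(sel2$model, "self")
})

test_that("profiles are invariant to radius rescaling with compensated
           sigma", {
  radii <- seq(6.9, 7.15, length.out = 30)
  sigma <- reducedMassSigma(13400, 0.73, 1.0, 30000)
  prof1 <- exp(sigma * (radii^2 - radii[1]^2))
  alpha <- 10   # cm -> mm
  prof2 <- exp(sigma / alpha^2 * ((alpha * radii)^2 - (alpha * radii[1])^2))
  expect_equal(prof1, prof2, tolerance = 1e-12)
})

test_that("scans survive CSV round-trips with their metadata", {
  m <- AssociationModel(13400, scheme = "self", kd = 118e-6)
  sc <- simulateScan(m, 35000, cref = 4e-5, baseline = 0.02,
                     noise = 0.003, seed = 8)
  tf <- tempfile(fileext = ".csv")
  writeAucScan(sc, tf)
  back <- readAucScan(tf)
  expect_equal(back@speed, 35000)
  expect_equal(back@wavelength, sc@wavelength)
  expect_equal(back@temperature, sc@temperature)
  expect_equal(back@radii, sc@radii, tolerance = 1e-10)
  expect_equal(back@absorbance, sc@absorbance, tolerance = 1e-10)
})

test_that("species distributions obey mass action and sum to one", {
  m <- AssociationModel(13400, scheme = "self", kd = 118e-6)
  grid <- 10^seq(-8, -2, length.out = 25)
  sd <- speciesDistribution(m, grid)
  expect_equal(sd$fracBase + sd$fracDimer, rep(1, 25), tolerance = 1e-12)
  ## mass-action identity at every grid point
  expect_equal(sd$cBase + 2 * sd$cDimer, grid, tolerance = 1e-12)
  expect_equal(sd$cDimer, sd$cBase^2 / 118e-6, tolerance = 1e-12)
  ## dilute limit is pure base species; octamer grows with concentration
  expect_gt(sd$fracBase[1], 0.999)
  expect_true(all(diff(sd$fracDimer) > 0))
  ## at cBase = Kd the dimer carries 2 Kd of monomer equivalents
  ct <- 118e-6 + 2 * 118e-6
  sd2 <- speciesDistribution(m, ct)
  expect_equal(sd2$cBase, 118e-6, tolerance = 1e-9)
  expect_error(speciesDistribution(AssociationModel(13400,
                                                    scheme = "none"),
                                   1e-5), "association")
})
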